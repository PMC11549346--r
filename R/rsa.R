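#' Cross-validated Mahalanobis (crossnobis) RDM for one data slice
#'
#' Unbiased estimator of the squared Mahalanobis distance between tone
#' patterns: trials are split into stratified folds; for each fold the
#' distance is the inner product of the train-set and test-set mean
#' pattern differences, whitened by the Ledoit-Wolf-shrunk covariance of
#' the train-set residuals (trial minus its tone mean, pooled over all
#' tones); the fold values are averaged. Under the null the estimate is
#' centred on zero, so negative values occur.
#'
#' @param x trials x features matrix (one time sample, or a time-window
#'   average).
#' @param tones 0-based tone label per trial.
#' @param folds number of cross-validation folds (default 10). Fold
#'   assignment is stratified by tone using contiguous chunks in trial
#'   order, preserving learning-stage homogeneity within folds.
#' @param n_tones alphabet size.
#' @return A symmetric n_tones x n_tones matrix of cvMD values (squared
#'   distance units; diagonal 0).
#' @export
cvmd_rdm <- function(x, tones, folds = 10, n_tones = 12) {
  x <- as.matrix(x)
  if (ncol(x) < 2) rlang::abort("need at least 2 features")
  n <- nrow(x)
  if (length(tones) != n) rlang::abort("`tones` must match rows of `x`")
  counts <- tabulate(tones + 1L, n_tones)
  if (any(counts < folds)) {
    rlang::abort(sprintf(
      "stratification error: every tone needs >= %d trials (min is %d)", folds, min(counts)
    ))
  }
  # contiguous stratified fold assignment
  fold <- integer(n)
  for (tn in 0:(n_tones - 1L)) {
    ix <- which(tones == tn)
    fold[ix] <- pmin(((seq_along(ix) - 1L) %/% ceiling(length(ix) / folds)) + 1L, folds)
  }

  rdm <- matrix(0, n_tones, n_tones)
  pair_n <- matrix(0, n_tones, n_tones)
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- !tr
    mu_tr <- rowsum(x[tr, , drop = FALSE], tones[tr])
    mu_tr <- mu_tr / as.vector(table(tones[tr])[rownames(mu_tr)])
    mu_te <- rowsum(x[te, , drop = FALSE], tones[te])
    mu_te <- mu_te / as.vector(table(tones[te])[rownames(mu_te)])
    present <- intersect(rownames(mu_tr), rownames(mu_te))
    if (length(present) < 2) next
    # residuals: trial minus its tone mean, pooled over tones (train set)
    res <- x[tr, , drop = FALSE] - mu_tr[match(as.character(tones[tr]), rownames(mu_tr)), , drop = FALSE]
    sigma <- ledoit_wolf(res, center = FALSE)
    w <- tryCatch(chol2inv(chol(sigma)),
      error = function(e) rlang::abort("regularisation failure: shrunk covariance is singular")
    )
    ids <- as.integer(present)
    for (ai in seq_along(ids)) {
      for (bi in seq_len(ai - 1L)) {
        a <- as.character(ids[ai]); b <- as.character(ids[bi])
        d_tr <- mu_tr[a, ] - mu_tr[b, ]
        d_te <- mu_te[a, ] - mu_te[b, ]
        val <- drop(d_tr %*% w %*% d_te)
        i <- ids[ai] + 1L; j <- ids[bi] + 1L
        rdm[i, j] <- rdm[i, j] + val
        pair_n[i, j] <- pair_n[i, j] + 1
      }
    }
  }
  rdm <- rdm / pmax(pair_n, 1)
  rdm[pair_n == 0] <- NA_real_
  rdm[upper.tri(rdm)] <- t(rdm)[upper.tri(rdm)]
  diag(rdm) <- 0
  rdm
}

#' Reorder an RDM by the triplet inventory
#'
#' Permutes rows and columns so that tones appear as (triplet 1 tone 1,
#' triplet 1 tone 2, triplet 1 tone 3, triplet 2 tone 1, ...), putting
#' within-triplet pairs into 3 x 3 blocks along the diagonal.
#'
#' @param rdm an n x n dissimilarity matrix indexed by tone (row i = tone
#'   i-1).
#' @param inventory list of 4 disjoint ordered integer triples covering all
#'   tones (e.g. `attr(seq, "triplet_types")` of a high-regularity
#'   sequence).
#' @return The permuted RDM with attribute `ordering` (0-based tone
#'   permutation).
#' @export
order_rdm <- function(rdm, inventory) {
  perm <- unlist(inventory)
  n <- nrow(rdm)
  if (length(perm) != n || !setequal(perm, 0:(n - 1))) {
    rlang::abort("`inventory` must cover every tone exactly once")
  }
  out <- rdm[perm + 1L, perm + 1L]
  attr(out, "ordering") <- as.integer(perm)
  out
}

#' Within- and between-triplet dissimilarity summary
#'
#' For a triplet-ordered RDM: `within` is the mean over the off-diagonal
#' entries inside the four 3 x 3 diagonal blocks (self-pairs excluded);
#' `between` is the mean over all upper-triangle entries outside those
#' blocks.
#'
#' @param rdm_ordered a triplet-ordered RDM from [order_rdm()].
#' @return A named list with `within` and `between`.
#' @export
within_between <- function(rdm_ordered) {
  n <- nrow(rdm_ordered)
  block <- (seq_len(n) - 1L) %/% 3L
  ut <- upper.tri(rdm_ordered)
  same <- outer(block, block, "==")
  list(
    within = mean(rdm_ordered[ut & same]),
    between = mean(rdm_ordered[ut & !same])
  )
}

#' Theoretical triplet RDM
#'
#' Model dissimilarity structure under perfect chunking: 0 for tones in the
#' same triplet, 1 otherwise (under the triplet ordering, zero 3 x 3 blocks
#' on the diagonal).
#'
#' @param n_tones alphabet size (multiple of 3).
#' @return An n x n 0/1 matrix.
#' @export
theoretical_rdm <- function(n_tones = 12) {
  block <- (seq_len(n_tones) - 1L) %/% 3L
  m <- 1 - outer(block, block, function(a, b) as.numeric(a == b))
  diag(m) <- 0
  m
}

#' Model-based RSA fit
#'
#' Spearman rank correlation between a triplet-ordered brain RDM and the
#' theoretical chunking RDM over the upper triangle (self-diagonal
#' excluded). Positive values mean within-triplet distances are smaller
#' than between-triplet distances.
#'
#' @param rdm_ordered triplet-ordered RDM.
#' @param theory theoretical RDM (default [theoretical_rdm()]).
#' @return Spearman's rho, or `NA` with a warning for a zero-variance RDM.
#' @export
model_rsa <- function(rdm_ordered, theory = theoretical_rdm(nrow(rdm_ordered))) {
  ut <- upper.tri(rdm_ordered)
  v <- rdm_ordered[ut]
  m <- theory[ut]
  if (stats::sd(v) == 0 || anyNA(v)) {
    rlang::warn("zero-variance or incomplete RDM; model fit undefined")
    return(NA_real_)
  }
  stats::cor(v, m, method = "spearman")
}

#' OLS slope across learning blocks
#'
#' Slope of a per-block summary against the block index 1..n.
#'
#' @param values numeric vector of block values (typically 5).
#' @return The OLS slope, or `NA` with a warning on non-finite input.
#' @examples
#' block_slope(c(5, 3, 1, -1, -3)) # -2
#' @export
block_slope <- function(values) {
  if (any(!is.finite(values))) {
    rlang::warn("non-finite block values; slope undefined")
    return(NA_real_)
  }
  x <- seq_along(values)
  sum((x - mean(x)) * (values - mean(values))) / sum((x - mean(x))^2)
}

#' Block- and time-resolved representational geometry
#'
#' Runs the crossnobis RDM analysis for each learning block and each time
#' sample (whole-brain features = all parcels), orders RDMs by the triplet
#' inventory, and summarises within-/between-triplet distances and the
#' model-based RSA fit, together with their OLS slopes across blocks.
#'
#' @param epochs an `epoch_array` (the first trial, which has no prediction
#'   error, is retained here: RSA does not use the PE).
#' @param inventory triplet inventory defining the RDM ordering (list of 4
#'   ordered triples). Use the high-regularity inventory for both
#'   conditions, as the ordering must be common.
#' @param folds cross-validation folds.
#' @param time_idx indices of time samples to analyse (default all).
#' @return A list of class `rdm_series`: `rdm` (blocks x time x tones x
#'   tones array, triplet-ordered), `summary` (tibble: `block`, `time`,
#'   `within`, `between`, `model_rho`), `slopes` (tibble: `time`, `metric`,
#'   `slope`), `time`, `inventory`.
#' @export
rsa_timecourse <- function(epochs, inventory, folds = 10, time_idx = NULL) {
  n_tones <- length(unlist(inventory))
  time <- epochs$time
  if (is.null(time_idx)) time_idx <- seq_along(time)
  blocks <- sort(unique(epochs$meta$block))
  folds <- effective_folds(epochs$meta, folds, n_tones)
  nb <- length(blocks)
  nt <- length(time_idx)
  rdm_arr <- array(NA_real_, dim = c(nb, nt, n_tones, n_tones))
  rows <- list()
  for (bi in seq_along(blocks)) {
    in_b <- epochs$meta$block == blocks[bi]
    tones_b <- epochs$meta$tone[in_b]
    for (ti in seq_len(nt)) {
      x <- epochs$data[in_b, , time_idx[ti]]
      rdm <- cvmd_rdm(x, tones_b, folds = folds, n_tones = n_tones)
      rdm_o <- order_rdm(rdm, inventory)
      rdm_arr[bi, ti, , ] <- rdm_o
      wb <- within_between(rdm_o)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = blocks[bi], time = time[time_idx[ti]],
        within = wb$within, between = wb$between,
        model_rho = model_rsa(rdm_o)
      )
    }
  }
  summary <- dplyr::bind_rows(rows)
  slopes <- summary |>
    tidyr::pivot_longer(c("within", "between", "model_rho"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$time, .data$metric) |>
    dplyr::summarise(slope = block_slope(.data$value), .groups = "drop")
  structure(
    list(rdm = rdm_arr, summary = summary, slopes = slopes,
         time = time[time_idx], inventory = inventory),
    class = "rdm_series"
  )
}

#' @export
print.rdm_series <- function(x, ...) {
  d <- dim(x$rdm)
  cat("<rdm_series> ", d[1], " blocks x ", d[2], " time samples x ",
      d[3], "x", d[4], " tones\n", sep = "")
  invisible(x)
}

#' Window-averaged representational geometry per block
#'
#' Averages the data over a time window first, then computes one
#' triplet-ordered crossnobis RDM per block and the within/between/model
#' summaries and their block slopes. This is the whole-brain counterpart of
#' the searchlight analysis and the unit of the "representational shift".
#'
#' @param epochs an `epoch_array`.
#' @param inventory triplet inventory for ordering.
#' @param window time window in seconds (default 110-120 ms, which on the
#'   5 ms grid includes the samples at 110, 115 and 120 ms).
#' @param folds cross-validation folds.
#' @param features parcel ids to use (default all).
#' @return A tibble with `block`, `within`, `between`, `model_rho` plus
#'   attribute `slopes` (named: within, between, model_rho).
#' @export
rsa_block_summary <- function(epochs, inventory, window = c(0.110, 0.120),
                              folds = 10, features = NULL) {
  sel <- window_index(epochs$time, window)
  n_tones <- length(unlist(inventory))
  if (is.null(features)) features <- seq_len(dim(epochs$data)[2])
  xw <- apply(epochs$data[, features, sel, drop = FALSE], c(1, 2), mean)
  folds <- effective_folds(epochs$meta, folds, n_tones)
  blocks <- sort(unique(epochs$meta$block))
  out <- lapply(blocks, function(b) {
    in_b <- epochs$meta$block == b
    rdm_o <- order_rdm(
      cvmd_rdm(xw[in_b, , drop = FALSE], epochs$meta$tone[in_b],
               folds = folds, n_tones = n_tones),
      inventory
    )
    wb <- within_between(rdm_o)
    tibble::tibble(block = b, within = wb$within, between = wb$between,
                   model_rho = model_rsa(rdm_o))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "slopes") <- c(
    within = block_slope(out$within),
    between = block_slope(out$between),
    model_rho = block_slope(out$model_rho)
  )
  out
}

# largest usable fold count given per-block tone counts; warns when the
# requested folds must be reduced
effective_folds <- function(meta, folds, n_tones) {
  minc <- min(vapply(split(meta$tone, meta$block), function(tn) {
    min(tabulate(tn + 1L, n_tones))
  }, numeric(1)))
  if (minc < 2) rlang::abort("need at least 2 trials per tone per block")
  if (minc < folds) {
    rlang::warn(sprintf("reducing folds from %d to %d (sparsest tone/block cell)", folds, minc))
    folds <- minc
  }
  as.integer(folds)
}

window_index <- function(time, window) {
  sel <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  if (length(sel) == 0) rlang::abort("window lies outside the epoch time range")
  sel
}

#' Searchlight representational-shift map
#'
#' For every parcel, uses the parcel plus its 5 spatial nearest neighbours
#' as features, averages the data across the given time window, computes
#' per-block triplet-ordered crossnobis RDMs, and returns the OLS block
#' slopes of the within-/between-triplet distances and the model-based RSA
#' fit.
#'
#' @param epochs an `epoch_array`.
#' @param inventory triplet inventory for ordering.
#' @param window time window in seconds (default 110-120 ms).
#' @param folds cross-validation folds.
#' @param k number of spatial neighbours (default 5).
#' @return A tibble with one row per parcel: `parcel`, `within_slope`,
#'   `between_slope`, `model_slope`.
#' @export
searchlight_rsa <- function(epochs, inventory, window = c(0.110, 0.120),
                            folds = 10, k = 5) {
  nb <- parcel_neighbors(epochs$atlas, k = k)
  folds <- effective_folds(epochs$meta, folds,
                           length(unlist(inventory)))
  res <- purrr::map_dfr(seq_len(nrow(nb)), function(i) {
    feats <- c(nb$parcel[i], nb$neighbors[[i]])
    s <- rsa_block_summary(epochs, inventory, window = window,
                           folds = folds, features = feats)
    sl <- attr(s, "slopes")
    tibble::tibble(
      parcel = nb$parcel[i],
      within_slope = sl[["within"]],
      between_slope = sl[["between"]],
      model_slope = sl[["model_rho"]]
    )
  })
  res
}
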