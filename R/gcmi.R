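#' Rank-based inverse normal (copula) transform
#'
#' Maps each column to a standard-normal marginal by evaluating the inverse
#' normal CDF at the empirical CDF value `rank / (n + 1)` (average ranks for
#' ties). Ranks — and therefore all downstream copula-based information
#' estimates — are invariant to any strictly increasing per-column
#' transform of the input.
#'
#' @param x numeric vector or samples x features matrix.
#' @return A matrix of the same shape with standard-normal marginals.
#' @examples
#' copula_normalize(c(10, 20, 30)) # qnorm(c(.25, .5, .75))
#' @export
copula_normalize <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) rlang::abort("need at least 3 samples")
  out <- apply(x, 2, function(col) {
    if (!all(is.finite(col))) rlang::abort("non-finite values in input")
    if (length(unique(col)) == 1) rlang::abort("degenerate (constant) marginal")
    stats::qnorm(rank(col, ties.method = "average") / (n + 1))
  })
  matrix(out, nrow = n)
}

# log-determinant via Cholesky with a conditioning guard: each pivot must
# retain at least `floor` of its marginal variance, else the joint
# covariance is treated as singular (e.g. duplicated variables).
logdet_chol <- function(sigma, floor = 1e-12) {
  sigma <- as.matrix(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) rlang::abort("conditioning error: singular covariance")
  piv <- diag(ch)^2 / diag(sigma)
  if (any(piv < floor)) {
    rlang::abort("conditioning error: covariance pivot below relative floor")
  }
  2 * sum(log(diag(ch)))
}

#' Gaussian-copula mutual information
#'
#' Estimates MI between a (possibly multivariate) X and a univariate or
#' multivariate Y: both are copula-normalised per column, then the Gaussian
#' closed form
#' `MI = 1/(2 ln 2) * ln(|Sigma_X| |Sigma_Y| / |Sigma_XY|)`
#' is evaluated (bits). The estimate is a robust lower bound on the true
#' MI; for jointly Gaussian data it is consistent.
#'
#' @param x samples x features matrix (or vector).
#' @param y samples vector (or matrix).
#' @param normalized set `TRUE` when inputs are already copula-normalised.
#' @return MI in bits.
#' @examples
#' # two halves of a correlated Gaussian
#' n <- 5000
#' z <- rnorm(n)
#' gcmi(z + rnorm(n), z + rnorm(n))
#' @export
gcmi <- function(x, y, normalized = FALSE) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) rlang::abort("`x` and `y` need the same number of samples")
  if (nrow(x) <= ncol(x) + ncol(y) + 2) {
    rlang::abort("need more samples than features + 2")
  }
  if (!normalized) {
    x <- copula_normalize(x)
    y <- copula_normalize(y)
  }
  sx <- stats::cov(x)
  sy <- stats::cov(y)
  sxy <- stats::cov(cbind(x, y))
  (logdet_chol(sx) + logdet_chol(sy) - logdet_chol(sxy)) / (2 * log(2))
}

#' Time-resolved prediction-error encoding (GCMI)
#'
#' Mutual information between the multivariate parcel signal at each time
#' sample and the scalar prediction-error trajectory, baseline-corrected by
#' subtracting the mean MI over the pre-tone window. Trials without a
#' prediction error (the first tone) are dropped.
#'
#' @param epochs an `epoch_array`.
#' @param features parcel ids to use jointly (default all).
#' @param baseline pre-tone window in seconds (default -50-0 ms).
#' @param pe prediction-error value per trial; defaults to `epochs$meta$pe`.
#' @return A tibble with `time`, `mi_bits` (raw) and `mi_corrected`.
#' @export
gcmi_timecourse <- function(epochs, features = NULL, baseline = c(-0.05, 0), pe = NULL) {
  if (is.null(pe)) pe <- epochs$meta$pe
  keep <- !is.na(pe)
  if (is.null(features)) features <- seq_len(dim(epochs$data)[2])
  y <- copula_normalize(pe[keep])
  base_idx <- window_index(epochs$time, baseline)
  nt <- length(epochs$time)
  mi <- vapply(seq_len(nt), function(ti) {
    x <- copula_normalize(epochs$data[keep, features, ti])
    gcmi(x, y, normalized = TRUE)
  }, numeric(1))
  mi_base <- mean(mi[base_idx])
  tibble::tibble(time = epochs$time, mi_bits = mi, mi_corrected = mi - mi_base)
}

#' Searchlight prediction-error encoding map
#'
#' For each parcel, the searchlight features (parcel + k spatial nearest
#' neighbours) are averaged over a time window and their joint GCMI with
#' the prediction-error trajectory is computed, baseline-corrected with the
#' same searchlight over the pre-tone window.
#'
#' @param epochs an `epoch_array`.
#' @param window analysis window in seconds (default 90-120 ms, the
#'   strongest-encoding interval).
#' @param baseline pre-tone window (default -50-0 ms).
#' @param k neighbours per searchlight.
#' @param pe prediction-error per trial; defaults to `epochs$meta$pe`.
#' @return A tibble with `parcel`, `mi_bits`, `mi_baseline`, `mi_corrected`.
#' @export
searchlight_gcmi <- function(epochs, window = c(0.090, 0.120),
                             baseline = c(-0.05, 0), k = 5, pe = NULL) {
  if (is.null(pe)) pe <- epochs$meta$pe
  keep <- !is.na(pe)
  y <- copula_normalize(pe[keep])
  sel <- window_index(epochs$time, window)
  base <- window_index(epochs$time, baseline)
  nb <- parcel_neighbors(epochs$atlas, k = k)
  purrr::map_dfr(seq_len(nrow(nb)), function(i) {
    feats <- c(nb$parcel[i], nb$neighbors[[i]])
    xw <- apply(epochs$data[keep, feats, sel, drop = FALSE], c(1, 2), mean)
    xb <- apply(epochs$data[keep, feats, base, drop = FALSE], c(1, 2), mean)
    mi <- gcmi(xw, y)
    mib <- gcmi(xb, y)
    tibble::tibble(parcel = nb$parcel[i], mi_bits = mi,
                   mi_baseline = mib, mi_corrected = mi - mib)
  })
}
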