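#' Gaussian-copula partial information decomposition for two sources
#'
#' Decomposes the joint mutual information of two univariate sources about
#' a target, `JMI(X1, X2; Y) = R + U1 + U2 + S`, using copula-normalised
#' variables and Gaussian closed forms: redundancy is the minimal-MI
#' functional `R = min(MI(X1;Y), MI(X2;Y))` (which coincides with the
#' Williams-Beer minimum intersection information for univariate Gaussian
#' sources), the unique terms are `MI(Xi;Y) - R`, and synergy is the
#' remainder. The accounting identity holds exactly by construction.
#'
#' @param x1,x2 source samples (univariate).
#' @param y target samples.
#' @param normalized set `TRUE` when inputs are already copula-normalised.
#' @return A tibble with `jmi`, `redundancy`, `unique_1`, `unique_2`,
#'   `synergy` (bits).
#' @export
pid_gaussian <- function(x1, x2, y, normalized = FALSE) {
  if (!normalized) {
    x1 <- copula_normalize(x1)
    x2 <- copula_normalize(x2)
    y <- copula_normalize(y)
  }
  mi1 <- gcmi(x1, y, normalized = TRUE)
  mi2 <- gcmi(x2, y, normalized = TRUE)
  # duplicated sources make the joint covariance singular; the JMI limit of
  # a perfectly redundant pair is the larger single-source MI
  if (abs(stats::cor(as.vector(x1), as.vector(x2))) > 1 - 1e-12) {
    jmi <- max(mi1, mi2)
  } else {
    jmi <- gcmi(cbind(x1, x2), y, normalized = TRUE)
  }
  r <- min(mi1, mi2)
  u1 <- mi1 - r
  u2 <- mi2 - r
  s <- jmi - u1 - u2 - r
  tibble::tibble(jmi = jmi, redundancy = r, unique_1 = u1, unique_2 = u2, synergy = s)
}

#' Discrete Williams-Beer partial information decomposition
#'
#' Exact minimum-intersection-information (I_min) decomposition on a finite
#' joint probability table: for each target outcome y, the specific
#' information each source provides about y is computed and the smaller one
#' is credited as redundancy. Serves as the brute-force oracle for small
#' discrete systems (e.g. XOR: R = 0, S = 1 bit).
#'
#' @param pmf a 3-d array of joint probabilities with dimensions (x1, x2,
#'   y); must be nonnegative and sum to 1.
#' @return A tibble with `jmi`, `redundancy`, `unique_1`, `unique_2`,
#'   `synergy` (bits).
#' @export
pid_discrete_imin <- function(pmf) {
  pmf <- as.array(pmf)
  if (length(dim(pmf)) != 3) rlang::abort("`pmf` must be a 3-d array (x1, x2, y)")
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-9) {
    rlang::abort("`pmf` must be nonnegative and sum to 1")
  }
  px1 <- apply(pmf, 1, sum)
  px2 <- apply(pmf, 2, sum)
  py <- apply(pmf, 3, sum)
  p1y <- apply(pmf, c(1, 3), sum)
  p2y <- apply(pmf, c(2, 3), sum)
  p12y <- pmf

  mi_from_joint <- function(pxy, px, py) {
    s <- 0
    for (i in seq_along(px)) {
      for (j in seq_along(py)) {
        if (pxy[i, j] > 0) s <- s + pxy[i, j] * log2(pxy[i, j] / (px[i] * py[j]))
      }
    }
    s
  }
  mi1 <- mi_from_joint(p1y, px1, py)
  mi2 <- mi_from_joint(p2y, px2, py)
  # JMI: treat (x1, x2) jointly
  p12 <- apply(pmf, c(1, 2), sum)
  jmi <- 0
  for (i in seq_along(px1)) {
    for (j in seq_along(px2)) {
      for (k in seq_along(py)) {
        if (p12y[i, j, k] > 0) {
          jmi <- jmi + p12y[i, j, k] * log2(p12y[i, j, k] / (p12[i, j] * py[k]))
        }
      }
    }
  }
  # specific information of each source about each y
  spec <- function(pxy, px, py, k) {
    s <- 0
    for (i in seq_along(px)) {
      if (pxy[i, k] > 0) {
        pxgy <- pxy[i, k] / py[k]
        s <- s + pxgy * log2(pxgy / px[i])
      }
    }
    s
  }
  r <- 0
  for (k in seq_along(py)) {
    if (py[k] > 0) {
      r <- r + py[k] * min(spec(p1y, px1, py, k), spec(p2y, px2, py, k))
    }
  }
  u1 <- mi1 - r
  u2 <- mi2 - r
  s <- jmi - u1 - u2 - r
  tibble::tibble(jmi = jmi, redundancy = r, unique_1 = u1, unique_2 = u2, synergy = s)
}

#' Redundancy and synergy networks of prediction-error encoding
#'
#' For every unordered pair of parcels, the PID atoms about the
#' prediction-error trajectory are computed per time sample in the analysis
#' window, averaged, and baseline-corrected atom-wise by the same
#' computation over the pre-tone window. Redundancy and synergy matrices
#' are assembled, their global means taken, and node importance summarised
#' by weighted betweenness centrality (on negative-clipped weights) and
#' node strength.
#'
#' All pairwise atoms at one time sample derive from the copula-normalised
#' (parcels + PE) correlation matrix, so the whole network costs one
#' covariance per sample plus closed-form algebra per pair.
#'
#' @param epochs an `epoch_array`.
#' @param window analysis window (default 90-120 ms).
#' @param baseline pre-tone window (default -50-0 ms).
#' @param pe prediction-error per trial; defaults to `epochs$meta$pe`.
#' @return A list of class `info_network`: `redundancy`, `synergy` (72 x 72
#'   symmetric, baseline-corrected bits), `redundancy_raw`, `synergy_raw`,
#'   `global` (tibble), `centrality` (tibble with betweenness and strength
#'   per parcel and component), `window`, `baseline`.
#' @export
pid_network <- function(epochs, window = c(0.090, 0.120),
                        baseline = c(-0.05, 0), pe = NULL) {
  if (is.null(pe)) pe <- epochs$meta$pe
  keep <- !is.na(pe)
  y <- copula_normalize(pe[keep])
  n_parcels <- dim(epochs$data)[2]

  win_idx <- window_index(epochs$time, window)
  base_idx <- window_index(epochs$time, baseline)

  acc <- function(idx) {
    red <- syn <- matrix(0, n_parcels, n_parcels)
    for (ti in idx) {
      z <- copula_normalize(epochs$data[keep, , ti])
      at <- pid_atoms_from_corr(stats::cov(cbind(z, y)))
      red <- red + at$redundancy
      syn <- syn + at$synergy
    }
    list(redundancy = red / length(idx), synergy = syn / length(idx))
  }
  w <- acc(win_idx)
  b <- acc(base_idx)
  red <- w$redundancy - b$redundancy
  syn <- w$synergy - b$synergy

  centr <- dplyr::bind_rows(
    network_centrality(red, "redundancy"),
    network_centrality(syn, "synergy")
  )
  ut <- upper.tri(red)
  structure(
    list(
      redundancy = red, synergy = syn,
      redundancy_raw = w$redundancy, synergy_raw = w$synergy,
      global = tibble::tibble(
        component = c("redundancy", "synergy"),
        global_mean = c(mean(red[ut]), mean(syn[ut]))
      ),
      centrality = centr, window = window, baseline = baseline
    ),
    class = "info_network"
  )
}

# Closed-form PID atoms for every parcel pair from the joint covariance of
# (parcels, y); cv must have the target as its last row/column.
pid_atoms_from_corr <- function(cv) {
  p <- nrow(cv) - 1L
  vy <- cv[p + 1L, p + 1L]
  vx <- diag(cv)[seq_len(p)]
  cxy <- cv[seq_len(p), p + 1L]
  # single-source MI (bits)
  mi <- -0.5 * log2(pmax(1 - cxy^2 / (vx * vy), 1e-300))
  # pairwise JMI via 3x3 determinants:
  # |S_xx| |S_yy| / |S_joint| with S_joint the 3x3 of (xi, xj, y)
  cxx <- cv[seq_len(p), seq_len(p), drop = FALSE]
  vi <- matrix(vx, p, p)
  vj <- t(vi)
  ci <- matrix(cxy, p, p) # cov(xi, y)
  cj <- t(ci)
  # det of 2x2 source block
  det2 <- vi * vj - cxx^2
  # det of 3x3 joint: vy*det2 - ci*(ci*vj - cxx*cj) + cxx*(ci*cj - det... )
  det3 <- vi * (vj * vy - cj^2) - cxx * (cxx * vy - cj * ci) + ci * (cxx * cj - vj * ci)
  ratio <- pmax(det2 * vy, 1e-300) / pmax(det3, 1e-300)
  jmi <- 0.5 * log2(ratio)
  mii <- matrix(mi, p, p)
  mij <- t(mii)
  r <- pmin(mii, mij)
  u1 <- mii - r
  u2 <- mij - r
  s <- jmi - u1 - u2 - r
  s <- (s + t(s)) / 2 # algebraically symmetric; enforce bitwise symmetry
  diag(r) <- diag(s) <- 0
  list(redundancy = r, synergy = s)
}

network_centrality <- function(adj, component) {
  w <- adj
  w[w < 0] <- 0
  diag(w) <- 0
  strength <- rowMeans(w)
  n <- nrow(w)
  if (all(w == 0)) {
    rlang::warn("all-zero network; centrality undefined (returning zeros)")
    btw <- rep(0, n)
  } else {
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                               normalized = TRUE)
    full <- rep(0, n)
    full[as.integer(igraph::V(g))] <- btw
    btw <- full
  }
  tibble::tibble(parcel = seq_len(n), component = component,
                 betweenness = btw, strength = strength)
}

#' Weighted betweenness centrality
#'
#' Normalised betweenness on a nonnegative symmetric weight matrix: edge
#' lengths are the reciprocal weights (stronger edges are shorter), edges
#' at or below `floor` are removed, and counts are normalised by
#' `(n-1)(n-2)/2`.
#'
#' @param adj symmetric nonnegative weight matrix.
#' @param floor minimum edge weight retained.
#' @return A numeric vector of centralities (one per node).
#' @export
betweenness_centrality <- function(adj, floor = 0) {
  if (any(adj < 0)) rlang::abort("weights must be nonnegative")
  if (!isTRUE(all.equal(adj, t(adj)))) rlang::abort("adjacency must be symmetric")
  w <- adj
  w[w <= floor] <- 0
  diag(w) <- 0
  n <- nrow(w)
  if (all(w == 0)) {
    rlang::warn("all-zero network; centrality undefined (returning zeros)")
    return(rep(0, n))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::betweenness(g, weights = 1 / igraph::E(g)$weight, normalized = TRUE)
}

#' @export
print.info_network <- function(x, ...) {
  cat("<info_network> ", nrow(x$redundancy), " parcels; global redundancy ",
      signif(x$global$global_mean[1], 3), ", global synergy ",
      signif(x$global$global_mean[2], 3), " bits\n", sep = "")
  invisible(x)
}

#' @rdname pid_network
#' @param x an `info_network`.
#' @param ... unused.
#' @method tidy info_network
#' @export
tidy.info_network <- function(x, ...) {
  n <- nrow(x$redundancy)
  ut <- which(upper.tri(x$redundancy), arr.ind = TRUE)
  tibble::tibble(
    from = ut[, 1], to = ut[, 2],
    redundancy = x$redundancy[ut],
    synergy = x$synergy[ut]
  )
}
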