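#' Ledoit-Wolf shrinkage covariance estimator
#'
#' Well-conditioned covariance estimate that shrinks the sample covariance
#' toward a scaled identity, with the asymptotically optimal analytic
#' shrinkage intensity of Ledoit & Wolf (2004). Used to whiten residuals in
#' the cross-validated Mahalanobis distance, where the feature count (72
#' parcels) is not small relative to the per-fold trial count.
#'
#' @param x samples x features matrix; rows are observations. Means are
#'   removed internally (maximum-likelihood normalisation, i.e. divide by
#'   n, matching the estimator's derivation).
#' @param center subtract column means first (default `TRUE`; set to
#'   `FALSE` when `x` already holds residuals with known zero mean).
#' @return The shrunk covariance matrix with attribute `shrinkage` (the
#'   intensity in [0, 1]) and `mu` (the identity scale).
#' @export
ledoit_wolf <- function(x, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2) rlang::abort("need at least 2 samples")
  if (center) x <- sweep(x, 2, colMeans(x))
  S <- crossprod(x) / n
  mu <- sum(diag(S)) / p
  # squared Frobenius distance (normalised by p) between S and target mu*I
  d2 <- sum((S - diag(mu, p))^2) / p
  # average squared distance of per-sample outer products from S:
  # sum_k ||x_k x_k' - S||^2 / n^2 = (sum_k |x_k|^4 - n ||S||^2) / n^2
  b2_bar <- (sum(rowSums(x^2)^2) - n * sum(S^2)) / n^2 / p
  b2 <- min(b2_bar, d2)
  shrink <- if (d2 > 0) b2 / d2 else 1
  sigma <- shrink * diag(mu, p) + (1 - shrink) * S
  attr(sigma, "shrinkage") <- shrink
  attr(sigma, "mu") <- mu
  sigma
}
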