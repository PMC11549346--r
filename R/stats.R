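#' Gaussian-likelihood Bayesian Information Criterion
#'
#' `BIC = n * log(RSS / n) + k * log(n)`, the Gaussian-likelihood form in
#' which the additive noise-variance term cancels when comparing models fit
#' to the same data. `k` counts mean-function parameters only.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations (> k).
#' @param k number of mean-function parameters.
#' @return The BIC value.
#' @examples
#' bic(100, 100, 2) # 2 * log(100)
#' @export
bic <- function(rss, n, k) {
  if (rss <= 0) rlang::abort("`rss` must be positive")
  if (n <= k) rlang::abort("`n` must exceed `k`")
  n * log(rss / n) + k * log(n)
}

#' Paired Cohen's d
#'
#' Effect size for paired samples: mean difference divided by the standard
#' deviation of the differences.
#'
#' @param a,b paired numeric vectors.
#' @return Cohen's d, or `NA` with a warning when the differences have zero
#'   standard deviation.
#' @export
cohens_d_paired <- function(a, b) {
  d <- a - b
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) {
    rlang::warn("zero or undefined standard deviation of differences; d undefined")
    return(NA_real_)
  }
  mean(d) / s
}

#' Right-tailed Pearson correlation with Bonferroni correction
#'
#' Pearson correlation with a one-sided (positive) p-value multiplied by the
#' number of tests in the family and capped at 1.
#'
#' @param x,y numeric vectors (equal length >= 3).
#' @param m_tests number of tests in the family.
#' @return A tibble with `r`, `p`, `p_corrected`, `n`, `m_tests`.
#' @export
correlate_bonferroni <- function(x, y, m_tests = 1) {
  if (length(x) != length(y) || length(x) < 3) {
    rlang::abort("`x` and `y` must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("zero variance input; correlation undefined")
    return(tibble::tibble(r = NA_real_, p = NA_real_, p_corrected = NA_real_,
                          n = length(x), m_tests = m_tests))
  }
  ct <- stats::cor.test(x, y, alternative = "greater", method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), p = ct$p.value,
    p_corrected = min(1, ct$p.value * m_tests),
    n = length(x), m_tests = m_tests
  )
}

# Paired t-values for all columns at once, via sign-flip matrix `flips`
# (n_perm x n_subjects, entries +-1). Uses the fact that sign flips leave
# per-subject squared values unchanged, so only the mean varies.
flip_tvalues <- function(d, flips) {
  s <- nrow(d)
  ss <- colSums(d^2)
  m <- (flips %*% d) / s # n_perm x elements
  varp <- sweep(-(m^2) * s, 2, ss, "+") / (s - 1)
  varp[varp < .Machine$double.eps] <- NA_real_
  m / sqrt(sweep(varp, 1, s, "/"))
}

# connected components of suprathreshold elements under an adjacency matrix;
# returns a list of integer vectors
supra_clusters <- function(mask, adjacency) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  if (length(idx) == 1) return(list(idx))
  sub <- adjacency[idx, idx, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  unname(split(idx, comp))
}

#' Cluster-based paired permutation test
#'
#' Mass-univariate paired two-tailed permutation test with the maxsum
#' cluster statistic: element-wise paired t-values are thresholded at the
#' two-tailed parametric critical value (df = subjects - 1), suprathreshold
#' elements are clustered under the supplied adjacency (separately for
#' positive and negative t), and each observed cluster's summed t is
#' compared against the permutation null of the maximum absolute cluster
#' sum obtained by randomly sign-flipping the paired differences.
#'
#' @param a,b subjects x elements matrices (paired conditions).
#' @param adjacency elements x elements 0/1 matrix; for a time course use
#'   [temporal_adjacency()].
#' @param alpha cluster-forming (and reporting) significance level.
#' @param n_perm number of sign-flip permutations.
#' @param seed permutation seed.
#' @return A list of class `cluster_result`: `clusters` (list of member
#'   indices), `cluster_stats` (summed t), `p_values`, `t_values`
#'   (element-wise), `threshold`, `alpha`, `n_perm`.
#' @export
cluster_permutation_paired <- function(a, b, adjacency, alpha = 0.05,
                                       n_perm = 10000, seed = 1) {
  stopifnot(all(dim(a) == dim(b)))
  s <- nrow(a)
  if (s < 2) rlang::abort("need at least 2 subjects")
  e <- ncol(a)
  if (nrow(adjacency) != e) rlang::abort("adjacency must cover all elements")
  d <- a - b

  sds <- apply(d, 2, stats::sd)
  degenerate <- which(!is.finite(sds) | sds == 0)
  if (length(degenerate)) {
    rlang::warn(sprintf("%d element(s) with degenerate variance excluded", length(degenerate)))
  }
  tcrit <- stats::qt(1 - alpha / 2, df = s - 1)
  tobs <- colMeans(d) / (sds / sqrt(s))
  tobs[degenerate] <- 0

  pos <- supra_clusters(tobs > tcrit, adjacency)
  neg <- supra_clusters(tobs < -tcrit, adjacency)
  clusters <- c(pos, neg)
  stats_obs <- vapply(clusters, function(ix) sum(tobs[ix]), numeric(1))

  null_max <- withr::with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * s, replace = TRUE), n_perm, s)
    tperm <- flip_tvalues(d, flips)
    tperm[, degenerate] <- 0
    tperm[!is.finite(tperm)] <- 0
    apply(tperm, 1, function(tv) {
      cl <- c(supra_clusters(tv > tcrit, adjacency), supra_clusters(tv < -tcrit, adjacency))
      if (length(cl) == 0) return(0)
      max(abs(vapply(cl, function(ix) sum(tv[ix]), numeric(1))))
    })
  })

  p <- vapply(stats_obs, function(st) (1 + sum(null_max >= abs(st))) / (1 + n_perm), numeric(1))
  ord <- order(p, -abs(stats_obs))
  structure(
    list(
      clusters = clusters[ord], cluster_stats = stats_obs[ord], p_values = p[ord],
      t_values = tobs, threshold = tcrit, alpha = alpha, n_perm = n_perm
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$clusters), " cluster(s), ",
      sum(x$p_values < x$alpha), " significant at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' @rdname cluster_permutation_paired
#' @param x a `cluster_result`.
#' @param ... unused.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  if (length(x$clusters) == 0) {
    return(tibble::tibble(cluster = integer(), size = integer(),
                          maxsum = numeric(), p_value = numeric()))
  }
  tibble::tibble(
    cluster = seq_along(x$clusters),
    size = lengths(x$clusters),
    maxsum = x$cluster_stats,
    p_value = x$p_values
  )
}

#' Adjacency matrix for consecutive samples
#'
#' @param n number of ordered elements (e.g. time samples).
#' @return An n x n 0/1 matrix linking consecutive elements.
#' @export
temporal_adjacency <- function(n) {
  adj <- matrix(0L, n, n)
  if (n > 1) {
    ix <- cbind(1:(n - 1), 2:n)
    adj[ix] <- 1L
    adj[ix[, 2:1]] <- 1L
  }
  adj
}

#' Spatial adjacency from parcel centroids
#'
#' Parcels are adjacent when their centroid distance falls below a quantile
#' of all pairwise distances.
#'
#' @param atlas a parcel atlas tibble from [make_atlas()].
#' @param quantile distance quantile defining adjacency (default 0.1).
#' @return A 0/1 adjacency matrix.
#' @export
spatial_adjacency <- function(atlas, quantile = 0.1) {
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  thr <- stats::quantile(dm[upper.tri(dm)], quantile)
  adj <- (dm <= thr) * 1L
  diag(adj) <- 0L
  adj
}

#' Network-based statistic for paired connectivity matrices
#'
#' Edge-wise paired t-tests on the upper triangle are thresholded at the
#' two-tailed `edge_alpha` critical value; the sizes (edge counts) of
#' connected components of suprathreshold edges are compared against a
#' sign-flip permutation null of the maximum component size.
#'
#' @param a,b subjects x n x n arrays of symmetric matrices.
#' @param edge_alpha edge-forming significance level (two-tailed).
#' @param alpha component-level significance level.
#' @param n_perm number of permutations.
#' @param seed permutation seed.
#' @return A list of class `nbs_result`: `components` (list of edge tibbles
#'   with `from`, `to`, `t`), `component_sizes`, `p_values`, `edge_t`
#'   (n x n observed t matrix), thresholds and settings.
#' @export
nbs_paired <- function(a, b, edge_alpha = 0.05, alpha = 0.05,
                       n_perm = 10000, seed = 1) {
  stopifnot(length(dim(a)) == 3, all(dim(a) == dim(b)))
  s <- dim(a)[1]
  n <- dim(a)[2]
  ut <- which(upper.tri(matrix(0, n, n)))
  # subjects x edges
  da <- matrix(a, s, n * n)[, ut, drop = FALSE]
  db <- matrix(b, s, n * n)[, ut, drop = FALSE]
  d <- da - db
  tcrit <- stats::qt(1 - edge_alpha / 2, df = s - 1)

  sds <- apply(d, 2, stats::sd)
  degenerate <- which(!is.finite(sds) | sds == 0)
  tobs <- colMeans(d) / (sds / sqrt(s))
  tobs[degenerate] <- 0

  comp_of <- function(tv) {
    sup <- which(abs(tv) > tcrit)
    if (length(sup) == 0) return(list())
    eidx <- ut[sup]
    from <- ((eidx - 1) %% n) + 1
    to <- ((eidx - 1) %/% n) + 1
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    memb <- igraph::components(g)$membership
    split(seq_along(sup), memb[from])
  }

  obs_comp <- comp_of(tobs)
  sizes <- lengths(obs_comp)

  null_max <- withr::with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * s, replace = TRUE), n_perm, s)
    tperm <- flip_tvalues(d, flips)
    tperm[, degenerate] <- 0
    tperm[!is.finite(tperm)] <- 0
    apply(tperm, 1, function(tv) {
      cl <- comp_of(tv)
      if (length(cl) == 0) 0L else max(lengths(cl))
    })
  })

  p <- vapply(sizes, function(sz) (1 + sum(null_max >= sz)) / (1 + n_perm), numeric(1))
  tmat <- matrix(0, n, n)
  tmat[ut] <- tobs
  tmat <- tmat + t(tmat)
  components <- lapply(obs_comp, function(ix) {
    eidx <- ut[ix]
    tibble::tibble(
      from = ((eidx - 1) %% n) + 1,
      to = ((eidx - 1) %/% n) + 1,
      t = tobs[ix]
    )
  })
  ord <- order(p, -sizes)
  structure(
    list(
      components = components[ord], component_sizes = unname(sizes[ord]),
      p_values = unname(p[ord]), edge_t = tmat, edge_threshold = tcrit,
      edge_alpha = edge_alpha, alpha = alpha, n_perm = n_perm
    ),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("<nbs_result> ", length(x$components), " component(s), ",
      sum(x$p_values < x$alpha), " significant at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' @rdname nbs_paired
#' @param x an `nbs_result`.
#' @param ... unused.
#' @method tidy nbs_result
#' @export
tidy.nbs_result <- function(x, ...) {
  if (length(x$components) == 0) {
    return(tibble::tibble(component = integer(), size = integer(), p_value = numeric()))
  }
  tibble::tibble(
    component = seq_along(x$components),
    size = x$component_sizes,
    p_value = x$p_values
  )
}
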