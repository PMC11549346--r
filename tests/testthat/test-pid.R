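test_that("Gaussian PID matches the closed-form oracle for an additive system", {
  # x1, x2 iid N(0,1), y = x1 + x2 + eps, var(eps) = 1:
  # MI_each = 0.5*log2(3/2), JMI = 0.5*log2(3), R = MI_each, S = 0.5 bits
  atoms <- withr::with_seed(1, {
    n <- 100000
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- x1 + x2 + rnorm(n)
    pid_gaussian(x1, x2, y)
  })
  expect_equal(atoms$jmi, 0.5 * log2(3), tolerance = 0.02)
  expect_equal(atoms$redundancy, 0.5 * log2(1.5), tolerance = 0.02)
  expect_lt(max(abs(c(atoms$unique_1, atoms$unique_2))), 0.02)
  expect_equal(atoms$synergy, 0.5, tolerance = 0.03)
  # accounting identity to machine precision
  expect_equal(atoms$jmi,
               atoms$redundancy + atoms$unique_1 + atoms$unique_2 + atoms$synergy,
               tolerance = 1e-12)
})

test_that("irrelevant and duplicated sources land on the expected atoms", {
  withr::with_seed(2, {
    n <- 20000
    x1 <- rnorm(n)
    y <- x1 + rnorm(n)
    noise <- rnorm(n)
    a <- pid_gaussian(x1, noise, y)
    expect_lt(a$redundancy, 0.01)
    expect_equal(a$unique_1, gcmi(x1, y), tolerance = 0.02)
    expect_lt(abs(a$synergy), 0.02)

    b <- pid_gaussian(x1, x1, y)
    expect_equal(b$redundancy, gcmi(x1, y), tolerance = 0.02)
    expect_lt(abs(b$synergy), 1e-9)
    expect_lt(max(abs(c(b$unique_1, b$unique_2))), 1e-9)
  })
})

test_that("PID is symmetric in its sources and synergy is bounded below", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      n <- 2000
      w <- matrix(rnorm(9), 3, 3)
      z <- matrix(rnorm(n * 3), n, 3) %*% w
      a <- pid_gaussian(z[, 1], z[, 2], z[, 3])
      b <- pid_gaussian(z[, 2], z[, 1], z[, 3])
      expect_equal(a$redundancy, b$redundancy, tolerance = 1e-10)
      expect_equal(a$synergy, b$synergy, tolerance = 1e-10)
      expect_equal(a$unique_1, b$unique_2, tolerance = 1e-10)
      expect_gt(a$synergy, -1e-6) # JMI >= max single MI for Gaussians
    }
  })
})

test_that("discrete Williams-Beer oracle solves XOR, unique-only and copy cases exactly", {
  # XOR: y = x1 xor x2, uniform inputs
  pmf <- array(0, c(2, 2, 2))
  for (i in 0:1) for (j in 0:1) pmf[i + 1, j + 1, xor(i, j) + 1] <- 0.25
  a <- pid_discrete_imin(pmf)
  expect_equal(a$redundancy, 0)
  expect_equal(a$unique_1, 0)
  expect_equal(a$unique_2, 0)
  expect_equal(a$synergy, 1)

  # y = x1, x2 independent uniform
  pmf2 <- array(0, c(2, 2, 2))
  for (i in 0:1) for (j in 0:1) pmf2[i + 1, j + 1, i + 1] <- 0.25
  b <- pid_discrete_imin(pmf2)
  expect_equal(b$unique_1, 1)
  expect_equal(b$redundancy + b$unique_2 + b$synergy, 0)

  # x1 = x2 = y uniform binary: pure redundancy
  pmf3 <- array(0, c(2, 2, 2))
  pmf3[1, 1, 1] <- 0.5
  pmf3[2, 2, 2] <- 0.5
  cc <- pid_discrete_imin(pmf3)
  expect_equal(cc$redundancy, 1)
  expect_equal(cc$jmi, 1)
  expect_equal(cc$synergy, 0)

  expect_error(pid_discrete_imin(array(1, c(2, 2, 2))), "sum to 1")
})

test_that("Gaussian and discretised I_min redundancies agree in ordering", {
  # jointly Gaussian triples across a grid of correlation structures,
  # discretised to 8 levels; redundancy orderings must track each other
  withr::with_seed(4, {
    n <- 50000
    grid <- expand.grid(r1 = c(0.2, 0.5, 0.8), r2 = c(0.3, 0.6))
    red_g <- red_d <- numeric(nrow(grid))
    for (k in seq_len(nrow(grid))) {
      z <- rnorm(n)
      x1 <- grid$r1[k] * z + sqrt(1 - grid$r1[k]^2) * rnorm(n)
      x2 <- grid$r2[k] * z + sqrt(1 - grid$r2[k]^2) * rnorm(n)
      red_g[k] <- pid_gaussian(x1, x2, z)$redundancy
      disc <- function(v) pmin(pmax(findInterval(v, qnorm((1:7) / 8, sd = sd(v))) + 1, 1), 8)
      tab <- table(factor(disc(x1), levels = 1:8),
                   factor(disc(x2), levels = 1:8),
                   factor(disc(z), levels = 1:8)) / n
      red_d[k] <- pid_discrete_imin(array(tab, c(8, 8, 8)))$redundancy
    }
    expect_gt(cor(red_g, red_d, method = "spearman"), 0.9)
  })
})

test_that("betweenness matches hand-enumerated path counts", {
  # star: centre on every leaf pair's only path
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  b <- betweenness_centrality(star)
  expect_equal(b[1], 1)
  expect_equal(b[2:5], rep(0, 4))

  # path a-b-c-d-e: interior counts enumerated by hand over all 10 pairs
  path <- matrix(0, 5, 5)
  for (i in 1:4) path[i, i + 1] <- path[i + 1, i] <- 1
  bp <- betweenness_centrality(path)
  expect_equal(bp, c(0, 3, 4, 3, 0) / 6)

  # complete graph: no intermediaries
  comp <- matrix(1, 6, 6); diag(comp) <- 0
  expect_equal(betweenness_centrality(comp), rep(0, 6))

  expect_warning(z <- betweenness_centrality(matrix(0, 4, 4)), "all-zero")
  expect_equal(z, rep(0, 4))
  expect_error(betweenness_centrality(matrix(-1, 2, 2)), "nonnegative")
})

test_that("vectorised pairwise atoms equal the per-pair estimator", {
  withr::with_seed(5, {
    n <- 3000
    z <- copula_normalize(matrix(rnorm(n * 4), n, 4) %*% matrix(rnorm(16), 4, 4))
    y <- copula_normalize(0.5 * z[, 1] + rnorm(n))
    at <- predgeom:::pid_atoms_from_corr(stats::cov(cbind(z, y)))
    for (pair in list(c(1, 2), c(2, 4), c(3, 4))) {
      ref <- pid_gaussian(z[, pair[1]], z[, pair[2]], y, normalized = TRUE)
      expect_equal(at$redundancy[pair[1], pair[2]], ref$redundancy, tolerance = 1e-8)
      expect_equal(at$synergy[pair[1], pair[2]], ref$synergy, tolerance = 1e-8)
    }
  })
})

test_that("the planted synergistic pair tops the network and beats its redundancy", {
  fx <- fixture_epochs()
  net <- pid_network(fx$epochs)
  syn <- net$synergy
  ut <- upper.tri(syn)
  top <- which(syn == max(syn[ut]), arr.ind = TRUE)[1, ]
  expect_setequal(as.integer(top), c(20, 56))
  # masking noise dominates the coupling: synergy exceeds redundancy there
  expect_gt(net$synergy[20, 56], net$redundancy[20, 56])
  expect_equal(net$synergy, t(net$synergy))
  expect_true(all(diag(net$synergy) == 0))
  expect_equal(nrow(net$centrality), 144)
  td <- tidy(net)
  expect_equal(nrow(td), 72 * 71 / 2)
})

test_that("parcels driven by one PE-coupled signal rank top in redundancy", {
  # hand-built 4-parcel epoch array: parcels 1 and 2 share the same
  # PE-locked component, parcels 3 and 4 are noise
  n <- 600
  atlas <- make_atlas(seed = 1, n_parcels = 4)
  time <- seq(-0.05, 0.33, by = 0.005)
  kern <- exp(-0.5 * ((time - 0.1) / 0.02)^2)
  withr::with_seed(6, {
    pe <- c(NA, abs(rnorm(n - 1)))
    pez <- c(0, as.numeric(scale(pe[-1])))
    arr <- array(rnorm(n * 4 * length(time)), c(n, 4, length(time)))
    for (tr in 1:n) {
      arr[tr, 1, ] <- arr[tr, 1, ] + 1.5 * pez[tr] * kern
      arr[tr, 2, ] <- arr[tr, 2, ] + 1.5 * pez[tr] * kern
    }
  })
  ep <- structure(
    list(data = arr,
         meta = tibble::tibble(trial = 1:n, tone = 0L, triplet_id = 1L,
                               block = 1L, condition = "high", pe = pe),
         time = time, atlas = atlas, cfg = NULL, subject = 1),
    class = "epoch_array"
  )
  net <- pid_network(ep)
  red <- net$redundancy
  ut <- which(upper.tri(red), arr.ind = TRUE)
  top <- ut[which.max(red[upper.tri(red)]), ]
  expect_setequal(as.integer(top), c(1, 2))
})
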