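test_that("crossnobis distance is centred on zero under the null", {
  # two tones with identical generating distributions; negative values must
  # occur and the mean must sit within 3 standard errors of zero
  vals <- withr::with_seed(1, vapply(1:300, function(r) {
    x <- matrix(rnorm(60 * 8), 60, 8)
    tones <- rep(0:1, each = 30)
    cvmd_rdm(x, tones, folds = 5, n_tones = 2)[1, 2]
  }, numeric(1)))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
  expect_gt(sum(vals < 0), 0)
})

test_that("crossnobis recovers a planted squared separation", {
  # one feature shifted by delta, identity noise: cvMD -> delta^2
  delta <- 1.5
  val <- withr::with_seed(2, {
    n <- 20000
    x <- matrix(rnorm(2 * n * 8), 2 * n, 8)
    x[seq_len(n), 1] <- x[seq_len(n), 1] + delta
    cvmd_rdm(x, rep(0:1, each = n), folds = 10, n_tones = 2)[1, 2]
  })
  expect_equal(val, delta^2, tolerance = 0.03)
})

test_that("crossnobis is invariant to feature order and symmetric", {
  withr::with_seed(3, {
    x <- matrix(rnorm(240 * 6), 240, 6)
    tones <- rep(0:3, each = 60)
    r1 <- cvmd_rdm(x, tones, folds = 5, n_tones = 4)
    r2 <- cvmd_rdm(x[, 6:1], tones, folds = 5, n_tones = 4)
    expect_equal(r1, r2, tolerance = 1e-10)
    expect_equal(r1, t(r1))
  })
})

test_that("stratification and feature-count preconditions are enforced", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(cvmd_rdm(x, rep(0:1, each = 10), folds = 11, n_tones = 2), "stratification")
  expect_error(cvmd_rdm(matrix(rnorm(20), 20, 1), rep(0:1, each = 10), folds = 2, n_tones = 2),
               "2 features")
})

test_that("triplet ordering permutes the RDM and is undone by its inverse", {
  identity_inv <- list(0:2, 3:5, 6:8, 9:11)
  m <- withr::with_seed(4, {
    m <- matrix(rnorm(144), 12, 12)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })
  expect_equal(order_rdm(m, identity_inv), m, ignore_attr = TRUE)

  inv <- list(c(4L, 0L, 7L), c(1L, 10L, 2L), c(11L, 3L, 8L), c(5L, 9L, 6L))
  om <- order_rdm(m, inv)
  perm <- attr(om, "ordering")
  back <- order_rdm(om, list(as.integer(order(perm) - 1L)[1:3],
                             as.integer(order(perm) - 1L)[4:6],
                             as.integer(order(perm) - 1L)[7:9],
                             as.integer(order(perm) - 1L)[10:12]))
  expect_equal(back, m, ignore_attr = TRUE)
  expect_error(order_rdm(m, list(0:2, 3:5, 6:8, c(9L, 10L, 10L))), "every tone")
})

test_that("ordering surfaces planted within-triplet structure as diagonal blocks", {
  inv <- list(c(4L, 0L, 7L), c(1L, 10L, 2L), c(11L, 3L, 8L), c(5L, 9L, 6L))
  m <- matrix(3, 12, 12)
  for (g in inv) for (a in g) for (b in g) m[a + 1, b + 1] <- 1
  diag(m) <- 0
  om <- order_rdm(m, inv)
  wb <- within_between(om)
  expect_equal(wb$within, 1)
  expect_equal(wb$between, 3)
})

test_that("within/between means equal a brute-force index classification", {
  m <- withr::with_seed(5, {
    m <- matrix(runif(144), 12, 12)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })
  wb <- within_between(m)
  w <- b <- c()
  for (i in 1:11) {
    for (j in (i + 1):12) {
      if ((i - 1) %/% 3 == (j - 1) %/% 3) w <- c(w, m[i, j]) else b <- c(b, m[i, j])
    }
  }
  expect_equal(wb$within, mean(w))
  expect_equal(wb$between, mean(b))
  cst <- matrix(2, 12, 12); diag(cst) <- 0
  expect_equal(unlist(within_between(cst)), c(within = 2, between = 2))
})

test_that("model-based RSA hits the trivial anchors and is null-centred", {
  th <- theoretical_rdm()
  expect_equal(model_rsa(th), 1)
  expect_equal(model_rsa(1 - th), -1)
  mean_rho <- withr::with_seed(6, mean(vapply(1:200, function(i) {
    m <- matrix(runif(144), 12, 12)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    model_rsa(m)
  }, numeric(1))))
  expect_lt(abs(mean_rho), 0.05)
  expect_warning(rho <- model_rsa(matrix(0, 12, 12)), "zero-variance")
  expect_true(is.na(rho))
})

test_that("block slope is the OLS slope against 1..5", {
  expect_equal(block_slope(1:5), 1)
  expect_equal(block_slope(rep(3, 5)), 0)
  expect_equal(block_slope(c(5, 3, 1, -1, -3)), -2)
  expect_warning(s <- block_slope(c(1, NA, 3, 4, 5)), "non-finite")
  expect_true(is.na(s))
})

test_that("tone decodability peaks at the generator's evoked latency", {
  fx <- fixture_epochs()
  inv <- attr(fx$seq, "triplet_types")
  idx <- which(fx$epochs$time >= 0 & fx$epochs$time <= 0.2)
  rs <- suppressWarnings(rsa_timecourse(fx$epochs, inv, folds = 4, time_idx = idx))
  per_time <- rs$summary |>
    dplyr::group_by(time) |>
    dplyr::summarise(d = mean((within + between) / 2), .groups = "drop")
  peak <- per_time$time[which.max(per_time$d)]
  expect_lte(abs(peak - 0.100), 0.005 + 1e-9)
})

test_that("searchlight maps cover all parcels and localise a planted morph", {
  fx <- fixture_epochs()
  inv <- attr(fx$seq, "triplet_types")
  sl <- suppressWarnings(searchlight_rsa(fx$epochs, inv, folds = 4))
  expect_equal(nrow(sl), 72)
  expect_true(all(is.finite(sl$within_slope)))
  # the fixture plants the morph in all parcels; the map-wide mean slope is
  # negative (within-triplet convergence)
  expect_lt(mean(sl$within_slope), 0)
  expect_error(rsa_block_summary(fx$epochs, inv, window = c(2, 3)), "outside")
})
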