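test_that("a uniform prior predicts uniformly and learns a hand-computed update", {
  st <- observer_init()
  out <- observer_step(st, 0, 1)
  expect_equal(out$record$y_hat, rep(1 / 12, 12))
  expect_equal(out$record$omega, log(12))
  # single update from the uniform prior, derived by hand from the
  # softmax/cross-entropy algebra: target entry rises by ln12 * 11/12
  expect_equal(out$state$W[1, 2], 1 / 12 + log(12) * 11 / 12, tolerance = 1e-10)
  expect_equal(out$state$W[1, 1], 1 / 12 - log(12) / 12, tolerance = 1e-10)
  # only the active input row moves
  expect_equal(out$state$W[2:12, ], matrix(1 / 12, 11, 12))
})

test_that("repeated deterministic transitions drive certainty and zero error", {
  # entropy-gated learning converges slowly near certainty (omega shrinks
  # with the update), so the asymptote is approached logarithmically
  st <- observer_init()
  oms <- numeric(3)
  for (i in 1:2000) {
    out <- observer_step(st, 3, 7)
    st <- out$state
    if (i %in% c(100, 500, 2000)) oms[which(c(100, 500, 2000) == i)] <- out$record$omega
  }
  expect_gt(out$record$y_hat[8], 0.99)
  expect_lt(out$record$omega, 0.05)
  expect_lt(out$record$pe_norm, 1e-3)
  expect_true(all(diff(oms) < 0)) # monotone approach to zero uncertainty
})

test_that("learning-rate stays within the entropy bounds of a 12-way choice", {
  s <- generate_sequence("high", 80, seed = 1)
  tr <- run_observer(s)
  expect_true(all(tr$steps$omega >= 0))
  expect_true(all(tr$steps$omega <= log(12) + 1e-12))
})

test_that("trace length, alignment and degenerate inputs behave", {
  two <- tibble::tibble(tone = c(0L, 5L))
  tr <- run_observer(two)
  expect_equal(nrow(tr$steps), 1)
  expect_error(run_observer(tibble::tibble(tone = 3L)), "at least 2")
  expect_error(observer_step(observer_init(), 12, 0), "indices")
})

test_that("prediction error decays and accuracy exceeds chance on regular streams", {
  s_hi <- generate_sequence("high", 800, seed = 7)
  s_lo <- generate_sequence("low", 800, seed = 7)
  tr_hi <- run_observer(s_hi)
  tr_lo <- run_observer(s_lo)
  pe <- tr_hi$steps$pe
  n10 <- floor(length(pe) / 10)
  expect_lt(mean(utils::tail(pe, n10)), mean(utils::head(pe, n10)))
  # loss decreases in expectation on the stationary high-regularity stream
  q <- floor(length(pe) / 4)
  expect_lt(mean(utils::tail(tr_hi$steps$loss, q)), mean(utils::head(tr_hi$steps$loss, q)))
  # final-stretch accuracy higher for the predictable stream
  acc_last <- function(tr) mean(utils::tail(tr$steps$correct, n10))
  expect_gt(acc_last(tr_hi), acc_last(tr_lo))
})

test_that("trained weights recover the empirical transition structure", {
  s <- generate_sequence("high", 800, seed = 7)
  tr <- run_observer(s)
  tm <- transition_matrix(s)
  fw <- final_weights_vs_transitions(tr, tm)
  expect_gt(attr(fw, "mean_correlation"), 0.9)

  # long deterministic cycle: every defined row correlation is 1
  cyc <- tibble::tibble(tone = rep(c(0L, 1L, 2L), 400))
  tr_c <- run_observer(cyc)
  fw_c <- suppressWarnings(final_weights_vs_transitions(tr_c, transition_matrix(cyc)))
  defined <- fw_c$correlation[!is.na(fw_c$correlation)]
  expect_true(all(defined > 1 - 1e-6))

  # an untrained observer has a flat softmax: rows are skipped with a warning
  flat <- list(W_final = matrix(1 / 12, 12, 12), n_tones = 12)
  expect_warning(final_weights_vs_transitions(flat, tm), "skipped")
})

test_that("softmax rows converge to conditional transition probabilities at length", {
  s <- generate_sequence("high", 800, seed = 3) # 2400 tones
  tr <- run_observer(s)
  tm <- transition_matrix(s)
  # deterministic rows (middle-of-triplet tones) must be spot on
  det_rows <- which(apply(tm$probabilities, 1, max) == 1)
  for (i in det_rows) {
    z <- tr$W_final[i, ] - max(tr$W_final[i, ])
    p <- exp(z) / sum(exp(z))
    expect_gt(p[which.max(tm$probabilities[i, ])], 0.9)
  }
})

test_that("decay-model comparison recovers noiseless generative truth", {
  x <- 1:200
  y_exp <- 3 * exp(-0.5 * x) + 1
  fit <- fit_decay_models(y_exp, n_restarts = 50, seed = 1)
  expect_equal(unname(fit$exp_params["a"]), 3, tolerance = 1e-3)
  expect_equal(unname(fit$exp_params["b"]), 0.5, tolerance = 1e-3)
  expect_equal(unname(fit$exp_params["c"]), 1, tolerance = 1e-3)
  expect_equal(fit$winner, "exponential")

  y_lin <- 2 + 0.1 * x
  fit_l <- fit_decay_models(y_lin, n_restarts = 50, seed = 1)
  expect_equal(fit_l$winner, "linear")

  expect_error(fit_decay_models(c(1, 2, 3)), "too short")
})

test_that("tidy and glance expose decay-fit terms", {
  fit <- fit_decay_models(3 * exp(-0.1 * (1:50)) + 1, n_restarts = 20, seed = 2)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c", "intercept", "slope"))
  gl <- glance(fit)
  expect_true(gl$exp_bic < gl$lin_bic)
  expect_equal(gl$winner, "exponential")
})

test_that("both PE scalarisations are exposed and differ", {
  s <- generate_sequence("high", 40, seed = 5)
  a <- run_observer(s, "entropy_weighted_norm")$steps$pe
  b <- run_observer(s, "entropy_weighted_surprise")$steps$pe
  expect_false(isTRUE(all.equal(a, b)))
  expect_true(all(a >= 0))
})

test_that("trace serialisation writes the step table and weights", {
  s <- generate_sequence("high", 8, seed = 4)
  tr <- run_observer(s)
  path <- file.path(withr::local_tempdir(), "trace.tsv")
  write_trace(tr, path)
  expect_true(file.exists(path))
  w <- as.matrix(utils::read.csv(paste0(path, ".weights.csv"), header = FALSE))
  expect_equal(dim(w), c(12, 12))
})
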