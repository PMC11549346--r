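#' Initial state of the ideal observer
#'
#' The observer is a softmax perceptron over the tone alphabet — a
#' categorical, dynamic-learning-rate variant of the Rescorla-Wagner model.
#' Its weight matrix starts as a uniform prior with every entry `1/n`.
#'
#' @param n_tones alphabet size (default 12).
#' @return A list of class `observer_state` with `W` (n x n weights) and `t`
#'   (transition counter).
#' @export
observer_init <- function(n_tones = 12) {
  structure(
    list(W = matrix(1 / n_tones, n_tones, n_tones), t = 0L),
    class = "observer_state"
  )
}

#' One learning step of the ideal observer
#'
#' Given the current tone the observer predicts the next via a softmax over
#' its weight row, scores the prediction by cross-entropy against the actual
#' next tone, and updates the weights by the entropy-weighted gradient: the
#' learning rate equals the Shannon entropy of the predictive distribution,
#' so an uncertain observer learns fast and a confident one barely moves.
#' The update (the prediction error) touches only the weight row of the
#' active input tone.
#'
#' @param state an `observer_state`.
#' @param current_tone,next_tone 0-based tone indices.
#' @return A list with the updated `state` and a `record` list: `y_hat`
#'   (predictive simplex), `z` (pre-softmax activations), `loss`
#'   (cross-entropy, nats), `omega` (learning rate = entropy, nats),
#'   `pe_row` (the nonzero row of the update matrix), `pe_norm`
#'   (entropy-weighted L2 norm of the update), `pe_surprise`
#'   (entropy-weighted surprisal of the realised tone), `correct`.
#' @export
observer_step <- function(state, current_tone, next_tone) {
  n <- nrow(state$W)
  if (current_tone < 0 || current_tone >= n || next_tone < 0 || next_tone >= n) {
    rlang::abort("tone indices must lie in [0, n_tones - 1]")
  }
  i <- current_tone + 1L
  z <- state$W[i, ]
  z_shift <- z - max(z)
  y_hat <- exp(z_shift) / sum(exp(z_shift))
  omega <- -sum(y_hat * log(y_hat))
  target <- numeric(n)
  target[next_tone + 1L] <- 1
  grad <- y_hat - target
  pe_row <- omega * grad
  state$W[i, ] <- state$W[i, ] - pe_row
  state$t <- state$t + 1L
  if (!all(is.finite(state$W[i, ]))) {
    rlang::abort(sprintf("non-finite observer weights after transition %d", state$t))
  }
  record <- list(
    y_hat = y_hat, z = z,
    loss = -log(y_hat[next_tone + 1L]),
    omega = omega,
    pe_row = pe_row,
    pe_norm = omega * sqrt(sum(grad^2)),
    pe_surprise = omega * (-log(y_hat[next_tone + 1L])),
    correct = which.max(y_hat) == next_tone + 1L
  )
  list(state = state, record = record)
}

#' Run the ideal observer over a tone sequence
#'
#' Trains the observer on every adjacent tone pair in presentation order and
#' records the prediction-error trajectory. The first tone elicits no
#' prediction error, so the trace has one entry per transition
#' (sequence length - 1) and is aligned to the tone that elicits the error.
#'
#' Two scalarisations of the matrix-valued prediction error are available:
#' `"entropy_weighted_norm"` (default) is the L2 norm of the update, i.e.
#' entropy times the gradient norm; `"entropy_weighted_surprise"` is entropy
#' times the surprisal of the realised tone.
#'
#' @param seq a `tone_sequence` (any data frame with a 0-based `tone`
#'   column works).
#' @param pe_mode scalar prediction-error definition, see Details.
#' @return An object of class `observer_trace`: a list with `steps` (a
#'   tibble: `transition`, `tone`, `next_tone`, `pe`, `loss`, `omega`,
#'   `correct`, `accuracy` — the causal running mean of `correct`),
#'   `W_final`, `pe_mode` and `n_tones`.
#' @examples
#' seq_hr <- generate_sequence("high", n_triplets = 8, seed = 1)
#' tr <- run_observer(seq_hr)
#' head(tr$steps)
#' @export
run_observer <- function(seq, pe_mode = c("entropy_weighted_norm", "entropy_weighted_surprise")) {
  pe_mode <- match.arg(pe_mode)
  tones <- seq$tone
  if (length(tones) < 2) rlang::abort("need at least 2 tones")
  n <- if (!is.null(attr(seq, "toneset"))) nrow(attr(seq, "toneset")) else max(12L, max(tones) + 1L)
  n_steps <- length(tones) - 1L

  W <- matrix(1 / n, n, n)
  pe <- loss <- omega <- numeric(n_steps)
  correct <- logical(n_steps)
  for (t in seq_len(n_steps)) {
    i <- tones[t] + 1L
    j <- tones[t + 1L] + 1L
    z <- W[i, ]
    z <- z - max(z)
    ez <- exp(z)
    y <- ez / sum(ez)
    om <- -sum(y * log(y))
    grad <- y
    grad[j] <- grad[j] - 1
    W[i, ] <- W[i, ] - om * grad
    if (!all(is.finite(W[i, ]))) {
      rlang::abort(sprintf("non-finite observer weights after transition %d", t))
    }
    omega[t] <- om
    loss[t] <- -log(y[j])
    pe[t] <- if (pe_mode == "entropy_weighted_norm") om * sqrt(sum(grad^2)) else om * loss[t]
    correct[t] <- which.max(y) == j
  }

  steps <- tibble::tibble(
    transition = seq_len(n_steps),
    tone = tones[-length(tones)],
    next_tone = tones[-1],
    pe = pe, loss = loss, omega = omega,
    correct = correct,
    accuracy = cumsum(correct) / seq_len(n_steps)
  )
  structure(
    list(steps = steps, W_final = W, pe_mode = pe_mode, n_tones = n),
    class = "observer_trace"
  )
}

#' @export
print.observer_trace <- function(x, ...) {
  cat("<observer_trace> ", nrow(x$steps), " transitions, pe_mode = ",
      x$pe_mode, "\n", sep = "")
  cat("  final accuracy (running): ",
      round(utils::tail(x$steps$accuracy, 1), 3), "\n", sep = "")
  invisible(x)
}

#' Compare the learned weights with the empirical transition matrix
#'
#' After training, the softmax of each weight row should approximate the
#' empirical conditional next-tone distribution. This computes the Pearson
#' correlation per tone row and their mean; rows with no observed
#' transitions are skipped with a warning.
#'
#' @param trace an `observer_trace`.
#' @param tm the [transition_matrix()] of the same sequence.
#' @return A tibble with one row per tone (`tone`, `correlation`) plus the
#'   attribute `mean_correlation`.
#' @export
final_weights_vs_transitions <- function(trace, tm) {
  n <- trace$n_tones
  rows <- seq_len(n)
  cors <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in rows) {
    if (i %in% tm$empty_rows) {
      skipped <- c(skipped, i)
      next
    }
    z <- trace$W_final[i, ]
    z <- z - max(z)
    p_model <- exp(z) / sum(exp(z))
    p_emp <- tm$probabilities[i, ]
    if (stats::sd(p_emp) == 0 || stats::sd(p_model) == 0) {
      skipped <- c(skipped, i)
      next
    }
    cors[i] <- stats::cor(p_model, p_emp)
  }
  if (length(skipped)) {
    rlang::warn(sprintf("skipped %d row(s) with no transitions or zero variance", length(skipped)))
  }
  out <- tibble::tibble(tone = rows - 1L, correlation = cors)
  attr(out, "mean_correlation") <- mean(cors, na.rm = TRUE)
  out
}

#' Fit exponential vs linear decay models to a prediction-error trajectory
#'
#' Fits `y = a * exp(-b * x) + c` by nonlinear least squares with random
#' restarts of the starting values (unbounded parameters) and a straight
#' line by ordinary least squares, with `x = 1..length(y)`. Models are
#' compared with the Gaussian-likelihood BIC
#' `n * log(RSS / n) + k * log(n)` (k = 3 exponential, 2 linear); the
#' smaller BIC wins.
#'
#' @param pe numeric trajectory (length > 4).
#' @param n_restarts number of random starting points for the nonlinear fit.
#' @param seed seed for the restart draws.
#' @return An object of class `decay_fit`: list with `exp_params` (a, b, c),
#'   `lin_params` (intercept, slope), `exp_bic`, `lin_bic`, `winner`,
#'   `exp_rss`, `lin_rss`, `n`.
#' @examples
#' y <- 3 * exp(-0.5 * (1:100)) + 1
#' fit_decay_models(y)$winner
#' @export
fit_decay_models <- function(pe, n_restarts = 100, seed = 1) {
  n <- length(pe)
  if (n <= 4) rlang::abort("trajectory too short to compare decay models")
  x <- seq_len(n)
  df <- data.frame(x = x, y = pe)

  lin <- stats::lm(y ~ x, data = df)
  lin_rss <- sum(stats::residuals(lin)^2)

  rng <- pe[is.finite(pe)]
  spread <- max(rng) - min(rng)
  if (spread == 0) spread <- 1
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      start <- list(
        a = stats::rnorm(1, spread, spread),
        b = exp(stats::runif(1, log(1e-3), log(2))),
        c = stats::rnorm(1, min(rng), spread / 2)
      )
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-b * x) + c,
          data = df, start = start,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  })
  if (is.null(best)) {
    rlang::abort("exponential fit failed on all restarts; trajectory may be degenerate")
  }
  exp_rss <- best$rss
  # a noiseless generative match drives RSS to numerical zero; floor it so
  # the Gaussian BIC stays finite (the comparison is unaffected)
  rss_floor <- n * .Machine$double.xmin
  exp_bic <- bic(max(exp_rss, rss_floor), n, 3)
  lin_bic <- bic(max(lin_rss, rss_floor), n, 2)
  cf <- stats::coef(best$fit)
  structure(
    list(
      exp_params = c(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"])),
      lin_params = c(intercept = unname(stats::coef(lin)[1]), slope = unname(stats::coef(lin)[2])),
      exp_bic = exp_bic, lin_bic = lin_bic,
      winner = if (exp_bic < lin_bic) "exponential" else "linear",
      exp_rss = exp_rss, lin_rss = lin_rss, n = n
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> exponential BIC ", round(x$exp_bic, 1),
      " vs linear BIC ", round(x$lin_bic, 1),
      " -> ", x$winner, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_decay_models
#' @param x a `decay_fit`.
#' @param ... unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    model = c(rep("exponential", 3), rep("linear", 2)),
    term = c("a", "b", "c", "intercept", "slope"),
    estimate = c(x$exp_params, x$lin_params)
  )
}

#' @rdname fit_decay_models
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    exp_bic = x$exp_bic, lin_bic = x$lin_bic, winner = x$winner,
    exp_rss = x$exp_rss, lin_rss = x$lin_rss, n = x$n
  )
}
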