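#' Generate a regularity-controlled tone-triplet sequence
#'
#' Builds an auditory statistical-learning stream: tones are grouped into
#' ordered triplets (1 s per triplet; tones last 300 ms and start every
#' 333 ms) whose three tones never span more than one octave. Every tone of
#' the alphabet occurs equally often, no tone repeats back-to-back, and no
#' triplet is immediately repeated. In the high-regularity stream only four
#' fixed triplet types recur (each tone belongs to exactly one type); in the
#' low-regularity stream the triplets are resampled throughout under the same
#' octave and count-balance constraints.
#'
#' The default `n_triplets = 800` with the 12-tone alphabet reproduces the
#' stimulus-scale stream: 2400 tones with each tone occurring exactly 200
#' times.
#'
#' @param regularity `"high"` or `"low"`.
#' @param n_triplets number of triplets. For `"high"` it must be divisible by
#'   the number of triplet types (alphabet size / 3) so tone counts balance.
#' @param seed integer seed; the same arguments always give the same stream.
#' @param toneset tone alphabet tibble, see [tone_set()].
#' @param variant counterbalancing variant (0, 1 or 2): cyclic rotation of
#'   the within-triplet tone order of the high-regularity triplet types.
#' @param max_restarts bound on full resampling attempts before the
#'   constraint solver gives up with an error.
#' @return A tibble of class `tone_sequence` with one row per tone:
#'   `position` (1-based), `tone` (0-based index), `label`, `freq_hz`,
#'   `triplet_id` (1-based ordinal), `onset_s`. Attributes: `regularity`,
#'   `seed`, `variant`, `triplet_types` (list of ordered integer triples for
#'   high regularity; the observed inventory for low), `toneset`.
#' @examples
#' seq_hr <- generate_sequence("high", n_triplets = 8, seed = 1)
#' table(seq_hr$tone)
#' @export
generate_sequence <- function(regularity = c("high", "low"), n_triplets = 800,
                              seed = 1, toneset = tone_set(), variant = 0,
                              max_restarts = 100) {
  regularity <- match.arg(regularity)
  validate_toneset(toneset)
  n_tones <- nrow(toneset)
  if (n_triplets < 2 || n_triplets != round(n_triplets)) {
    rlang::abort("`n_triplets` must be an integer >= 2")
  }
  if ((3L * n_triplets) %% n_tones != 0) {
    rlang::abort("3 * n_triplets must be divisible by the alphabet size for exact tone-count balance")
  }
  if (!variant %in% 0:2) rlang::abort("`variant` must be 0, 1 or 2")

  if (regularity == "high") {
    if (n_tones %% 3 != 0) rlang::abort("high regularity needs an alphabet size divisible by 3")
    n_types <- n_tones %/% 3L
    if (n_triplets %% n_types != 0) {
      rlang::abort(sprintf("`n_triplets` must be divisible by %d (number of triplet types)", n_types))
    }
    built <- withr::with_seed(seed, {
      types <- sample_triplet_types(toneset, n_types, variant, max_restarts)
      list(tones = arrange_type_tokens(types, n_triplets, max_restarts), inv = types)
    })
    tones <- built$tones
    inventory <- built$inv
  } else {
    tones <- withr::with_seed(seed, sample_low_regularity(toneset, n_triplets, max_restarts))
    inventory <- unique(unname(split(tones, rep(seq_len(n_triplets), each = 3L))))
    inventory <- lapply(inventory, as.integer)
  }

  out <- tibble::tibble(
    position = seq_along(tones),
    tone = as.integer(tones),
    label = if ("label" %in% names(toneset)) toneset$label[tones + 1L] else as.character(tones),
    freq_hz = toneset$freq_hz[tones + 1L],
    triplet_id = rep(seq_len(n_triplets), each = 3L),
    onset_s = (seq_along(tones) - 1L) * 0.333
  )
  structure(out,
    class = c("tone_sequence", class(out)),
    regularity = regularity, seed = seed, variant = variant,
    triplet_types = inventory, toneset = toneset
  )
}

# Partition the alphabet into n_types disjoint ordered triples, each spanning
# <= one octave, by rejection sampling; `variant` cyclically rotates the
# within-triplet order.
sample_triplet_types <- function(toneset, n_types, variant, max_restarts) {
  n_tones <- nrow(toneset)
  for (attempt in seq_len(max_restarts * 20L)) {
    perm <- sample(0:(n_tones - 1L))
    groups <- split(perm, rep(seq_len(n_types), each = 3L))
    ok <- all(vapply(groups, function(g) octave_span(g, toneset) <= 2, logical(1)))
    if (ok) {
      groups <- lapply(groups, function(g) {
        g <- as.integer(g)
        if (variant > 0) g <- c(g[-seq_len(variant)], g[seq_len(variant)])
        g
      })
      names(groups) <- NULL
      return(groups)
    }
  }
  rlang::abort("could not partition the alphabet into octave-legal triplet types")
}

# Shuffle equal numbers of tokens of each triplet type, then repair
# adjacent-identical-type violations by swapping with a compatible position.
arrange_type_tokens <- function(types, n_triplets, max_restarts) {
  n_types <- length(types)
  reps <- n_triplets %/% n_types
  for (attempt in seq_len(max_restarts)) {
    order_types <- sample(rep(seq_len(n_types), reps))
    order_types <- repair_adjacent(order_types)
    if (!is.null(order_types)) {
      return(unlist(types[order_types], use.names = FALSE))
    }
  }
  rlang::abort("could not arrange triplet tokens without consecutive repeats")
}

# Resolve x[i] == x[i+1] by swapping x[i+1] with a position j where both
# sides of the swap stay violation-free; NULL if some violation is stuck.
repair_adjacent <- function(x) {
  n <- length(x)
  for (pass in seq_len(4L * n + 50L)) {
    bad <- which(x[-n] == x[-1])
    if (length(bad) == 0) return(x)
    i <- bad[1] + 1L
    cand <- which(x != x[i])
    cand <- cand[cand != i]
    fixed <- FALSE
    for (j in sample(cand)) {
      xi <- x[i]; xj <- x[j]
      ok_j <- (j == 1 || x[j - 1] != xi) && (j == n || x[j + 1] != xi)
      ok_i <- (i == 1 || x[i - 1] != xj) && (i == n || x[i + 1] != xj)
      # adjacent swap: re-check the pair itself
      if (abs(i - j) == 1) ok_j <- ok_i <- xi != xj
      if (ok_i && ok_j) {
        x[c(i, j)] <- c(xj, xi)
        fixed <- TRUE
        break
      }
    }
    if (!fixed) return(NULL)
  }
  NULL
}

# Quota-balanced sampler for the low-regularity stream: each triplet is a
# fresh ordered triple under the octave constraint, drawn with probability
# proportional to the remaining per-tone quota; dead ends restart the stream.
sample_low_regularity <- function(toneset, n_triplets, max_restarts) {
  n_tones <- nrow(toneset)
  freq <- toneset$freq_hz
  quota_each <- (3L * n_triplets) %/% n_tones
  legal_pair <- outer(freq, freq, function(a, b) pmax(a, b) / pmin(a, b) <= 2)

  for (attempt in seq_len(max_restarts)) {
    quota <- rep(quota_each, n_tones)
    tones <- integer(3L * n_triplets)
    prev_triple <- NULL
    ok <- TRUE
    for (k in seq_len(n_triplets)) {
      triple <- draw_triple(quota, legal_pair, freq,
        forbid_first = if (k > 1) tones[3 * k - 3] else -1L,
        forbid_triple = prev_triple
      )
      if (is.null(triple)) { ok <- FALSE; break }
      tones[(3 * k - 2):(3 * k)] <- triple
      quota <- quota - tabulate(triple + 1L, n_tones)
      prev_triple <- triple
    }
    if (ok) return(tones)
  }
  rlang::abort("low-regularity constraint satisfaction failed after bounded restarts")
}

# One ordered triple (a,b,c): a != forbid_first, b != a, c != b, octave span
# of {a,b,c} <= 2, quota respected, triple != forbid_triple. Quota-weighted.
draw_triple <- function(quota, legal_pair, freq, forbid_first, forbid_triple) {
  n_tones <- length(quota)
  idx <- seq_len(n_tones) - 1L
  for (try_a in 1:20) {
    wa <- quota
    if (forbid_first >= 0) wa[forbid_first + 1L] <- 0
    if (sum(wa) <= 0) return(NULL)
    a <- sample(idx, 1, prob = wa)
    qa <- quota; qa[a + 1L] <- qa[a + 1L] - 1L
    for (try_b in 1:10) {
      wb <- qa * legal_pair[a + 1L, ]
      wb[a + 1L] <- 0
      if (sum(wb) <= 0) break
      b <- sample(idx, 1, prob = wb)
      qb <- qa; qb[b + 1L] <- qb[b + 1L] - 1L
      span_ok <- legal_pair[a + 1L, ] & legal_pair[b + 1L, ] &
        outer_span_ok(freq, a, b)
      wc <- qb * span_ok
      wc[b + 1L] <- 0
      if (!is.null(forbid_triple) && forbid_triple[1] == a && forbid_triple[2] == b) {
        wc[forbid_triple[3] + 1L] <- 0
      }
      if (sum(wc) > 0) {
        c_ <- sample(idx, 1, prob = wc)
        return(as.integer(c(a, b, c_)))
      }
    }
  }
  NULL
}

# candidates c keeping max(freq)/min(freq) of {a,b,c} <= 2
outer_span_ok <- function(freq, a, b) {
  lo <- min(freq[a + 1L], freq[b + 1L])
  hi <- max(freq[a + 1L], freq[b + 1L])
  pmax(hi, freq) / pmin(lo, freq) <= 2
}

#' Tone-to-tone transition matrix of a sequence
#'
#' Counts transitions between consecutive tones and row-normalises them into
#' conditional next-tone probabilities. Because no tone may repeat
#' back-to-back, the diagonal is structurally zero.
#'
#' @param seq a `tone_sequence` (or any data frame with a `tone` column).
#' @return An object of class `transition_matrix`: a list with integer
#'   `counts` (n x n), `probabilities` (rows summing to 1; all-zero rows kept
#'   as zeros and listed in `empty_rows`), and `n_tones`.
#' @export
transition_matrix <- function(seq) {
  tones <- seq$tone
  if (length(tones) < 2) rlang::abort("need at least 2 tones for transitions")
  n <- max(12L, max(tones) + 1L)
  if (!is.null(attr(seq, "toneset"))) n <- nrow(attr(seq, "toneset"))
  counts <- matrix(0L, n, n)
  from <- tones[-length(tones)] + 1L
  to <- tones[-1] + 1L
  for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1L
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(
    list(counts = counts, probabilities = probs,
         empty_rows = which(rs == 0), n_tones = n),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", x$n_tones, "x", x$n_tones,
      " (", sum(x$counts), " transitions)\n", sep = "")
  invisible(x)
}

#' Mean row entropy of a transition matrix
#'
#' Shannon entropy (nats) of each non-empty conditional next-tone
#' distribution, averaged across rows. Lower values indicate a more
#' predictable stream; the high-regularity sequence has strictly lower
#' transition entropy than the low-regularity one.
#'
#' @param tm a [transition_matrix()].
#' @return Mean row entropy in nats.
#' @export
transition_entropy <- function(tm) {
  rows <- setdiff(seq_len(tm$n_tones), tm$empty_rows)
  h <- vapply(rows, function(i) {
    p <- tm$probabilities[i, ]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mean(h)
}

#' Check a sequence against the stimulus construction rules
#'
#' Report-only validation of every construction invariant: length divisible
#' by 3, exact tone-count balance, no consecutive tone repeats, no
#' consecutive identical triplets, one-octave span inside each triplet, and
#' (for high regularity) exactly four distinct ordered triplet types.
#'
#' @param seq a `tone_sequence` tibble.
#' @param toneset tone alphabet; defaults to the sequence's own.
#' @return A tibble with columns `check`, `pass`, `first_fail` (position of
#'   the first offending tone, NA when passing) and `detail`.
#' @export
validate_sequence <- function(seq, toneset = NULL) {
  if (is.null(toneset)) toneset <- attr(seq, "toneset")
  if (is.null(toneset)) toneset <- tone_set()
  tones <- seq$tone
  n <- length(tones)
  checks <- list()

  checks$length_divisible_by_3 <- list(
    pass = n %% 3 == 0, first_fail = if (n %% 3 == 0) NA_integer_ else n,
    detail = sprintf("%d tones", n)
  )

  cnt <- tabulate(tones + 1L, nrow(toneset))
  checks$tone_count_balance <- list(
    pass = max(cnt) == min(cnt), first_fail = NA_integer_,
    detail = sprintf("counts %d..%d", min(cnt), max(cnt))
  )

  rep_pos <- which(tones[-n] == tones[-1])
  checks$no_consecutive_tone_repeat <- list(
    pass = length(rep_pos) == 0,
    first_fail = if (length(rep_pos)) rep_pos[1] + 1L else NA_integer_,
    detail = sprintf("%d repeats", length(rep_pos))
  )

  trip <- matrix(tones[seq_len(n - n %% 3)], nrow = 3)
  n_trip <- ncol(trip)
  same <- which(colSums(trip[, -n_trip, drop = FALSE] == trip[, -1, drop = FALSE]) == 3)
  checks$no_consecutive_identical_triplet <- list(
    pass = length(same) == 0,
    first_fail = if (length(same)) same[1] * 3L + 1L else NA_integer_,
    detail = sprintf("%d repeated triplets", length(same))
  )

  spans <- apply(trip, 2, octave_span, toneset = toneset)
  bad_span <- which(spans > 2)
  checks$octave_span_within_triplet <- list(
    pass = length(bad_span) == 0,
    first_fail = if (length(bad_span)) (bad_span[1] - 1L) * 3L + 1L else NA_integer_,
    detail = sprintf("max span ratio %.3f", max(spans))
  )

  if (identical(attr(seq, "regularity"), "high")) {
    n_types <- length(unique(apply(trip, 2, paste, collapse = ",")))
    checks$four_triplet_types <- list(
      pass = n_types == nrow(toneset) / 3,
      first_fail = NA_integer_,
      detail = sprintf("%d distinct ordered triplets", n_types)
    )
  }

  tibble::tibble(
    check = names(checks),
    pass = unname(vapply(checks, `[[`, logical(1), "pass")),
    first_fail = unname(vapply(checks, `[[`, integer(1), "first_fail")),
    detail = unname(vapply(checks, `[[`, character(1), "detail"))
  )
}

#' Triplet inventory of a sequence
#'
#' The distinct ordered triples occurring in the stream, in order of first
#' appearance.
#'
#' @param seq a `tone_sequence`.
#' @return A list of integer vectors of length 3.
#' @export
triplet_inventory <- function(seq) {
  tones <- seq$tone
  trip <- matrix(tones, nrow = 3)
  keys <- apply(trip, 2, paste, collapse = ",")
  lapply(strsplit(unique(keys), ","), as.integer)
}
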