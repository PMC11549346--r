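test_that("stimulus-scale high-regularity stream meets every construction rule", {
  s <- generate_sequence("high", 800, seed = 7)
  expect_equal(nrow(s), 2400)
  expect_equal(max(s$triplet_id), 800)
  counts <- table(s$tone)
  expect_length(counts, 12)
  expect_true(all(counts == 200))
  expect_length(triplet_inventory(s), 4)
  report <- validate_sequence(s)
  expect_true(all(report$pass))
})

test_that("low-regularity stream balances counts while resampling triplets", {
  s <- generate_sequence("low", 800, seed = 7)
  expect_true(all(table(s$tone) == 200))
  expect_true(all(validate_sequence(s)$pass))
  # triplets change constantly: far more distinct triples than the 4 types
  expect_gt(length(triplet_inventory(s)), 50)
})

test_that("generation is deterministic in (regularity, n_triplets, seed, variant)", {
  a <- generate_sequence("high", 80, seed = 11)
  b <- generate_sequence("high", 80, seed = 11)
  expect_identical(a$tone, b$tone)
  expect_identical(attr(a, "triplet_types"), attr(b, "triplet_types"))
  expect_false(identical(a$tone, generate_sequence("high", 80, seed = 12)$tone))
  v1 <- generate_sequence("high", 80, seed = 11, variant = 1)
  expect_false(identical(a$tone, v1$tone))
  expect_true(all(table(v1$tone) == 20))
})

test_that("transition matrix counts adjacent pairs and row-normalises", {
  cyc <- tibble::tibble(tone = c(0L, 1L, 2L, 0L, 1L, 2L, 0L))
  tm <- transition_matrix(cyc)
  expect_equal(tm$probabilities[1, 2], 1)
  expect_equal(tm$probabilities[2, 3], 1)
  expect_equal(tm$probabilities[3, 1], 1)
  expect_equal(sum(tm$counts), 6)
  expect_error(transition_matrix(tibble::tibble(tone = 0L)), "at least 2")
})

test_that("generated sequences never repeat a tone, so the count diagonal is zero", {
  for (sd in 1:3) {
    for (reg in c("high", "low")) {
      tm <- transition_matrix(generate_sequence(reg, 80, seed = sd))
      expect_true(all(diag(tm$counts) == 0))
    }
  }
})

test_that("high-regularity transitions stay inside the triplet grammar", {
  s <- generate_sequence("high", 200, seed = 3)
  inv <- attr(s, "triplet_types")
  # legal successors by enumeration: within a triple, tone k -> tone k+1;
  # a triple's last tone -> any other triple's first tone
  legal <- matrix(FALSE, 12, 12)
  firsts <- vapply(inv, `[`, integer(1), 1)
  for (g in seq_along(inv)) {
    tr <- inv[[g]]
    legal[tr[1] + 1, tr[2] + 1] <- TRUE
    legal[tr[2] + 1, tr[3] + 1] <- TRUE
    legal[tr[3] + 1, setdiff(firsts, firsts[g]) + 1] <- TRUE
  }
  tm <- transition_matrix(s)
  expect_true(all(tm$counts[!legal] == 0))
})

test_that("high-regularity streams have lower transition entropy than low", {
  for (sd in list(c(1, 1), c(2, 5), c(9, 3))) {
    h <- transition_entropy(transition_matrix(generate_sequence("high", 120, seed = sd[1])))
    l <- transition_entropy(transition_matrix(generate_sequence("low", 120, seed = sd[2])))
    expect_lt(h, l)
  }
})

test_that("validation pinpoints rule violations", {
  bad <- tibble::tibble(
    tone = c(5L, 5L, 3L, 0L, 1L, 2L),
    triplet_id = rep(1:2, each = 3)
  )
  rep <- validate_sequence(bad, tone_set())
  row <- rep[rep$check == "no_consecutive_tone_repeat", ]
  expect_false(row$pass)
  expect_equal(row$first_fail, 2L)

  # C4, D4, F#5 spans more than one octave (739.99 / 261.63 > 2)
  span_seq <- tibble::tibble(tone = c(0L, 1L, 9L), triplet_id = c(1L, 1L, 1L))
  rep2 <- validate_sequence(span_seq, tone_set())
  expect_false(rep2$pass[rep2$check == "octave_span_within_triplet"])
  expect_gt(octave_span(c(0L, 1L, 9L)), 2)
})

test_that("a tiny low-regularity stream on a 3-tone alphabet satisfies all invariants", {
  s <- generate_sequence("low", 4, seed = 0, toneset = toneset3())
  tones <- s$tone
  expect_length(tones, 12)
  # exhaustive adjacent-pair scan
  for (i in seq_len(length(tones) - 1)) expect_false(tones[i] == tones[i + 1])
  expect_true(all(table(tones) == 4))
  expect_true(all(validate_sequence(s, toneset3())$pass))
})

test_that("argument errors are raised for infeasible requests", {
  expect_error(generate_sequence("high", 7, seed = 1), "divisible")
  expect_error(generate_sequence("high", 0, seed = 1), "integer")
  # alphabet spanning > 1 octave everywhere cannot form any triple
  wide <- tibble::tibble(tone = 0:2, freq_hz = c(100, 300, 900))
  expect_error(generate_sequence("low", 4, seed = 1, toneset = wide, max_restarts = 3))
})

test_that("sequence TSV round trip preserves tones and metadata", {
  s <- generate_sequence("high", 8, seed = 4)
  path <- file.path(withr::local_tempdir(), "seq.tsv")
  write_sequence(s, path)
  r <- read_sequence(path)
  expect_equal(r$tone, s$tone)
  expect_equal(attr(r, "regularity"), "high")
  expect_equal(attr(r, "triplet_types"), attr(s, "triplet_types"))
})
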