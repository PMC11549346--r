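#' Pseudo-anatomical parcel atlas
#'
#' Builds a 72-parcel atlas with two mirrored hemispheric clusters of
#' centroids (arbitrary spatial units), standing in for a source-space
#' cortical parcellation. Centroids are reproducible per seed and pairwise
#' distinct.
#'
#' @param seed integer seed.
#' @param n_parcels number of parcels (even; default 72).
#' @return A tibble with `parcel` (1-based id), `label`, `hemisphere`
#'   ("L"/"R") and centroid coordinates `x`, `y`, `z` (arbitrary units,
#'   roughly a 140-unit-wide head).
#' @examples
#' make_atlas(seed = 1)
#' @export
make_atlas <- function(seed = 1, n_parcels = 72) {
  if (n_parcels %% 2 != 0) rlang::abort("`n_parcels` must be even (mirrored hemispheres)")
  half <- n_parcels %/% 2L
  withr::with_seed(seed, {
    # right-hemisphere cloud; x > 0, jittered shells so no two points collide
    x <- stats::runif(half, 8, 70)
    y <- stats::runif(half, -80, 80)
    z <- stats::runif(half, -40, 60)
    tibble::tibble(
      parcel = seq_len(n_parcels),
      label = c(sprintf("L%02d", seq_len(half)), sprintf("R%02d", seq_len(half))),
      hemisphere = rep(c("L", "R"), each = half),
      x = c(-x, x),
      y = c(y, y),
      z = c(z, z)
    )
  })
}

#' Spatial nearest neighbours of each parcel
#'
#' For searchlight analyses each parcel is grouped with its `k` nearest
#' other parcels by Euclidean centroid distance; the searchlight feature
#' set is the parcel plus these k neighbours. Distance ties are broken by
#' parcel id (with a warning when exact ties occur).
#'
#' @param atlas atlas tibble from [make_atlas()].
#' @param k number of neighbours (default 5, giving 6-parcel searchlights).
#' @return A tibble with `parcel` and a list-column `neighbors` of k parcel
#'   ids.
#' @export
parcel_neighbors <- function(atlas, k = 5) {
  n <- nrow(atlas)
  if (k >= n) rlang::abort("`k` must be smaller than the number of parcels")
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  diag(dm) <- Inf
  if (any(dm[upper.tri(dm)] == 0)) {
    rlang::warn("duplicate centroids; neighbour ties broken by parcel id")
  }
  nb <- lapply(seq_len(n), function(i) {
    ord <- order(dm[i, ], seq_len(n))
    atlas$parcel[ord[seq_len(k)]]
  })
  tibble::tibble(parcel = atlas$parcel, neighbors = nb)
}

#' Configuration of the synthetic source-level generator
#'
#' Parameters of the statistical structure planted into synthetic
#' source-parcel epochs. Defaults match the study conditions: 2400 tones
#' per sequence, 200 Hz sampling over -50..330 ms, 24 virtual subjects,
#' and planted effects at the latencies reported for the real data
#' (evoked kernel peaking 100 ms, learning morph in a 110-130 ms band,
#' prediction-error gain in designated encoder parcels, one synergistic
#' parcel pair).
#'
#' @param n_trials trials (tones) per condition.
#' @param sfreq_hz sampling rate.
#' @param epoch_window_s epoch limits in seconds (start, end).
#' @param pattern_snr amplitude of tone-specific patterns relative to unit
#'   noise.
#' @param evoked_amp amplitude of the tone-independent evoked component
#'   common to all parcels (the mean event-related field on which the
#'   tone-specific patterns ride).
#' @param gamma_max within-triplet convergence strength reached in the last
#'   block (high-regularity condition only), in [0, 1].
#' @param beta_pe trial-wise response-gain coupling to the standardised
#'   prediction-error trajectory in the encoder parcels; the default is
#'   sized so the planted encoding patch is reliably the searchlight map
#'   maximum at the desk-scale group size.
#' @param encoder_parcels centres of the prediction-error encoding patches;
#'   the first entry is the designated primary encoder. When
#'   `encoder_patch` is `TRUE` each centre is expanded to itself plus its 5
#'   spatial nearest neighbours, emulating a spatially extended encoding
#'   region the size of one searchlight.
#' @param encoder_patch expand encoder centres to searchlight-sized patches
#'   (default `TRUE`).
#' @param synergy_pair list with `i`, `j` (parcel ids), `shared_sd`
#'   (amplitude of the common masking noise) and `coupling` (PE loading on
#'   parcel `i` only); the pair carries information about the PE jointly
#'   but little individually.
#' @param noise_spatial_scale length scale (same units as the atlas) of the
#'   exponential spatial noise covariance.
#' @param ar1 temporal AR(1) coefficient of the noise (0 = white).
#' @param n_subjects number of virtual subjects (subject s uses
#'   `seed + s - 1`).
#' @param seed base seed.
#' @return A list of class `gen_config`.
#' @export
sim_config <- function(n_trials = 2400, sfreq_hz = 200,
                       epoch_window_s = c(-0.05, 0.33),
                       pattern_snr = 0.8, evoked_amp = 1,
                       gamma_max = 0.6, beta_pe = 0.6,
                       encoder_parcels = 41, encoder_patch = TRUE,
                       synergy_pair = list(i = 20, j = 56, shared_sd = 4, coupling = 1),
                       noise_spatial_scale = 30, ar1 = 0,
                       n_subjects = 24, seed = 1) {
  cfg <- list(
    n_trials = n_trials, sfreq_hz = sfreq_hz, epoch_window_s = epoch_window_s,
    pattern_snr = pattern_snr, evoked_amp = evoked_amp,
    gamma_max = gamma_max, beta_pe = beta_pe,
    encoder_parcels = encoder_parcels, encoder_patch = encoder_patch,
    synergy_pair = synergy_pair,
    noise_spatial_scale = noise_spatial_scale, ar1 = ar1,
    n_subjects = n_subjects, seed = seed
  )
  stopifnot(
    pattern_snr >= 0, gamma_max >= 0, gamma_max <= 1, beta_pe >= 0,
    synergy_pair$shared_sd >= 0, noise_spatial_scale > 0
  )
  if (epoch_window_s[1] > -0.05 || epoch_window_s[2] < 0.12) {
    rlang::abort("epoch window must contain the -50-0 ms baseline and the 90-120 ms analysis windows")
  }
  structure(cfg, class = "gen_config")
}

epoch_times <- function(cfg) {
  step <- 1 / cfg$sfreq_hz
  seq(cfg$epoch_window_s[1], cfg$epoch_window_s[2], by = step)
}

#' Generate synthetic source-parcel epochs
#'
#' Simulates trials x parcels x time source-level responses carrying the
#' statistical structure the analysis pipeline assumes:
#' \itemize{
#'   \item tone-specific multivariate patterns under a Gaussian evoked
#'     kernel centred at 100 ms (sd 20 ms);
#'   \item a learning morph: in a 110-130 ms band, each tone's pattern is
#'     pulled toward its triplet's mean pattern by a coefficient growing
#'     linearly from 0 to `gamma_max` across the 5 blocks (high-regularity
#'     condition only), so within-triplet representational distances shrink
#'     over learning;
#'   \item trial-wise gain `1 + beta_pe * z(pe)` in the encoder parcels,
#'     coupling response amplitude to the observer's prediction-error
#'     trajectory;
#'   \item a planted synergistic pair: parcel `i` carries
#'     `shared + coupling * z(pe)` and parcel `j` carries `shared`, both
#'     gated by the evoked kernel, so the PE is readable from their
#'     difference but masked in each alone by the common noise;
#'   \item spatially correlated Gaussian noise with exponential covariance
#'     over centroid distance (optional AR(1) in time).
#' }
#' The epoch of tone t carries the prediction error elicited by tone t
#' (i.e. the error of the transition t-1 -> t); the first epoch has no
#' prediction error and its `pe` is `NA`.
#'
#' @param seq a `tone_sequence` whose first `n_trials` tones are simulated.
#' @param trace the matching [run_observer()] trace.
#' @param atlas parcel atlas from [make_atlas()].
#' @param cfg generator configuration from [sim_config()].
#' @param subject virtual subject number (offsets the seed; patterns are
#'   shared across subjects, noise and trial effects are not).
#' @return An object of class `epoch_array`: list with `data`
#'   (trials x parcels x time array), `meta` (tibble: `trial`, `tone`,
#'   `triplet_id`, `block`, `condition`, `pe`), `time` (seconds), `atlas`,
#'   `cfg`, `subject`.
#' @export
generate_epochs <- function(seq, trace, atlas, cfg = sim_config(), subject = 1) {
  tones <- seq$tone
  n_trials <- min(cfg$n_trials, length(tones))
  if (nrow(trace$steps) != length(tones) - 1L) {
    rlang::abort("`trace` does not match `seq` (length mismatch)")
  }
  condition <- attr(seq, "regularity") %||% "low"
  time <- epoch_times(cfg)
  n_time <- length(time)
  n_parcels <- nrow(atlas)
  n_tones <- trace$n_tones

  pe_all <- c(NA_real_, trace$steps$pe)[seq_len(n_trials)]
  pe_z <- pe_all
  pe_z[!is.na(pe_z)] <- as.numeric(scale(pe_all[!is.na(pe_all)]))
  pe_z[is.na(pe_z)] <- 0

  blocks <- block_ids(n_trials, 5L)

  # kernel and morph band on the time axis
  kernel <- exp(-0.5 * ((time - 0.100) / 0.020)^2)
  band <- time >= 0.110 & time <= 0.130

  # triplet membership of each tone under the high-regularity inventory
  inventory <- attr(seq, "triplet_types")
  tone2trip <- rep(NA_integer_, n_tones)
  if (condition == "high" && length(inventory) > 0) {
    for (g in seq_along(inventory)) tone2trip[inventory[[g]] + 1L] <- g
  }

  withr::with_seed(cfg$seed, {
    # tone patterns shared by all subjects (drawn from the base seed)
    patterns <- matrix(stats::rnorm(n_tones * n_parcels, sd = cfg$pattern_snr),
                       n_tones, n_parcels)
  })

  # triplet-mean patterns, the morph targets
  trip_mean <- patterns
  if (condition == "high" && !anyNA(tone2trip)) {
    for (g in unique(tone2trip)) {
      rows <- which(tone2trip == g)
      trip_mean[rows, ] <- matrix(colMeans(patterns[rows, , drop = FALSE]),
                                  length(rows), n_parcels, byrow = TRUE)
    }
  }

  # spatial noise factor
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  K <- exp(-dm / cfg$noise_spatial_scale)
  L <- chol(K + diag(1e-8, n_parcels))

  sp <- cfg$synergy_pair
  enc <- encoder_set(atlas, cfg)

  data <- withr::with_seed(cfg$seed + subject - 1L + 1000L, {
    arr <- array(0, dim = c(n_trials, n_parcels, n_time))
    # noise: trials x parcels x time, spatially correlated, optionally AR(1)
    for (tt in seq_len(n_time)) {
      eps <- matrix(stats::rnorm(n_trials * n_parcels), n_trials, n_parcels) %*% L
      if (cfg$ar1 > 0 && tt > 1) {
        arr[, , tt] <- cfg$ar1 * arr[, , tt - 1] + sqrt(1 - cfg$ar1^2) * eps
      } else {
        arr[, , tt] <- eps
      }
    }
    shared <- stats::rnorm(n_trials, sd = sp$shared_sd)
    gamma_blk <- if (condition == "high") cfg$gamma_max * (blocks - 1) / 4 else numeric(n_trials)

    gain <- rep(1, n_trials)
    if (length(enc) > 0) gain <- 1 + cfg$beta_pe * pe_z

    for (tr in seq_len(n_trials)) {
      tone <- tones[tr] + 1L
      base <- cfg$evoked_amp + patterns[tone, ]
      morphed <- cfg$evoked_amp +
        (1 - gamma_blk[tr]) * patterns[tone, ] + gamma_blk[tr] * trip_mean[tone, ]
      sig_out <- outer(base, kernel)
      if (any(band)) {
        sig_out[, band] <- outer(morphed, kernel[band])
      }
      if (length(enc) > 0) sig_out[enc, ] <- sig_out[enc, ] * gain[tr]
      # synergistic pair riding on the kernel
      syn_i <- (shared[tr] + sp$coupling * pe_z[tr]) * kernel
      syn_j <- shared[tr] * kernel
      sig_out[sp$i, ] <- sig_out[sp$i, ] + syn_i
      sig_out[sp$j, ] <- sig_out[sp$j, ] + syn_j
      arr[tr, , ] <- arr[tr, , ] + sig_out
    }
    arr
  })

  meta <- tibble::tibble(
    trial = seq_len(n_trials),
    tone = tones[seq_len(n_trials)],
    triplet_id = seq$triplet_id[seq_len(n_trials)],
    block = blocks,
    condition = condition,
    pe = pe_all
  )
  structure(
    list(data = data, meta = meta, time = time, atlas = atlas,
         cfg = cfg, subject = subject),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_array> ", d[1], " trials x ", d[2], " parcels x ", d[3],
      " samples (", x$meta$condition[1], ", subject ", x$subject, ")\n", sep = "")
  invisible(x)
}

# contiguous equal blocks 1..n_blocks (remainder absorbed by the last block)
block_ids <- function(n_trials, n_blocks) {
  size <- n_trials %/% n_blocks
  b <- pmin(((seq_len(n_trials) - 1L) %/% size) + 1L, n_blocks)
  as.integer(b)
}

#' Label epochs with learning blocks
#'
#' Partitions trials in presentation order into `n_blocks` contiguous,
#' equally sized blocks (the last block absorbs any remainder, with a
#' warning).
#'
#' @param epochs an `epoch_array`.
#' @param n_blocks number of blocks (default 5).
#' @return The `epoch_array` with `meta$block` relabelled.
#' @export
split_blocks <- function(epochs, n_blocks = 5) {
  n <- nrow(epochs$meta)
  if (n_blocks > n) rlang::abort("more blocks than trials")
  if (n %% n_blocks != 0) {
    rlang::warn("trials not divisible by blocks; last block absorbs the remainder")
  }
  epochs$meta$block <- block_ids(n, as.integer(n_blocks))
  epochs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parcels that receive the planted prediction-error gain
#'
#' Expands the configured encoder centres to searchlight-sized patches
#' (when `encoder_patch` is set) and removes the synergy-pair parcels,
#' which are a separate planted structure.
#'
#' @param atlas parcel atlas.
#' @param cfg a [sim_config()].
#' @return Sorted parcel ids of the planted encoders.
#' @export
encoder_set <- function(atlas, cfg) {
  enc <- intersect(cfg$encoder_parcels, atlas$parcel)
  if (isTRUE(cfg$encoder_patch) && length(enc) > 0) {
    nb <- parcel_neighbors(atlas, k = 5)
    enc <- sort(unique(c(enc, unlist(nb$neighbors[match(enc, nb$parcel)]))))
  }
  setdiff(enc, c(cfg$synergy_pair$i, cfg$synergy_pair$j))
}
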