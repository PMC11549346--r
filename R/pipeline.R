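#' Study configuration
#'
#' Bundles every parameter of the end-to-end synthetic study: sequence
#' construction, observer settings, generator configuration, analysis
#' windows (RSA 110-120 ms, PID 90-120 ms, GCMI searchlight 90-120 ms,
#' baseline -50-0 ms), cross-validation folds, permutation counts and
#' seeds. The default is a desk-scale study (400 triplets, 8 virtual
#' subjects, 1000 permutations); `n_triplets = 800` and `n_subjects = 24`
#' reproduce the stimulus-scale conditions.
#'
#' @param n_triplets triplets per sequence.
#' @param n_subjects virtual subjects.
#' @param pe_mode observer prediction-error scalarisation.
#' @param gamma_max_high,gamma_max_low learning-morph strengths per
#'   condition (the representational shift is planted only in the
#'   high-regularity stream).
#' @param beta_pe encoder-gain coupling (both conditions).
#' @param rsa_window,gcmi_window,pid_window,baseline analysis windows (s).
#' @param folds crossnobis cross-validation folds.
#' @param n_perm permutations for group statistics.
#' @param alpha significance level.
#' @param seed base seed for every stage.
#' @param shift_metric which slope defines the per-subject
#'   "representational shift": `"model_rho"` (cluster-averaged model-RSA
#'   block slope, default) or `"within"` (negative within-triplet slope).
#' @param out_dir optional directory; when given, [run_study()] writes
#'   per-stage CSV/JSON outputs there.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_triplets = 400, n_subjects = 8,
                         pe_mode = "entropy_weighted_norm",
                         gamma_max_high = 0.6, gamma_max_low = 0,
                         beta_pe = 0.6,
                         rsa_window = c(0.110, 0.120),
                         gcmi_window = c(0.090, 0.120),
                         pid_window = c(0.090, 0.120),
                         baseline = c(-0.05, 0),
                         folds = 10, n_perm = 1000, alpha = 0.05,
                         seed = 1, shift_metric = c("model_rho", "within"),
                         out_dir = NULL) {
  shift_metric <- match.arg(shift_metric)
  structure(
    list(
      n_triplets = n_triplets, n_subjects = n_subjects, pe_mode = pe_mode,
      gamma_max_high = gamma_max_high, gamma_max_low = gamma_max_low,
      beta_pe = beta_pe, rsa_window = rsa_window, gcmi_window = gcmi_window,
      pid_window = pid_window, baseline = baseline, folds = folds,
      n_perm = n_perm, alpha = alpha, seed = seed,
      shift_metric = shift_metric, out_dir = out_dir
    ),
    class = "study_config"
  )
}

#' Run the full synthetic study
#'
#' Orchestrates the complete chain for both regularity conditions:
#' sequence generation, ideal-observer prediction errors, synthetic
#' source-parcel epochs per virtual subject, whole-brain and searchlight
#' crossnobis RSA across learning blocks, searchlight GCMI encoding of the
#' prediction error, PID redundancy/synergy networks with centrality, and
#' the group statistics linking representational shift to prediction-error
#' encoding.
#'
#' @param config a [study_config()].
#' @return A list of class `run_report`: per-stage tibbles (`subjects`,
#'   `rsa_slopes`, `searchlight_gcmi`, `pid_global`, `centrality`) and
#'   `headline` (tibble of headline indicators with values and p-values),
#'   plus `config`, the high-regularity `inventory`, the selected
#'   `cluster_parcels`, and the subject-averaged PID matrices
#'   (`group_synergy`, `group_redundancy`, one per condition).
#' @export
run_study <- function(config = study_config()) {
  cfgs <- config
  # the parcellation is a fixed template (one anatomy for all studies);
  # study seeds vary sequences, noise and subjects, not the atlas
  atlas <- make_atlas(seed = 1)
  nbt <- parcel_neighbors(atlas, k = 5)

  seqs <- list(
    high = generate_sequence("high", cfgs$n_triplets, seed = cfgs$seed),
    low = generate_sequence("low", cfgs$n_triplets, seed = cfgs$seed + 1L)
  )
  traces <- lapply(seqs, run_observer, pe_mode = cfgs$pe_mode)
  inventory <- attr(seqs$high, "triplet_types")

  decay <- fit_decay_models(traces$high$steps$pe, n_restarts = 100, seed = cfgs$seed)

  gamma <- c(high = cfgs$gamma_max_high, low = cfgs$gamma_max_low)
  n_trials <- 3L * cfgs$n_triplets
  encoder_parcels <- encoder_set(atlas, sim_config(n_trials = n_trials,
                                                   beta_pe = cfgs$beta_pe))

  per_subject <- list()
  sl_maps <- list()
  rsa_sl <- list()
  syn_sum <- red_sum <- list(high = NULL, low = NULL)
  for (s in seq_len(cfgs$n_subjects)) {
    for (cond in c("high", "low")) {
      gen <- sim_config(
        n_trials = n_trials, gamma_max = gamma[[cond]], beta_pe = cfgs$beta_pe,
        n_subjects = cfgs$n_subjects,
        seed = cfgs$seed + 100L * match(cond, c("high", "low"))
      )
      ep <- generate_epochs(seqs[[cond]], traces[[cond]], atlas, gen, subject = s)
      bs <- rsa_block_summary(ep, inventory, window = cfgs$rsa_window, folds = cfgs$folds)
      sl <- attr(bs, "slopes")
      slg <- searchlight_gcmi(ep, window = cfgs$gcmi_window,
                              baseline = cfgs$baseline, k = 5)
      net <- pid_network(ep, window = cfgs$pid_window, baseline = cfgs$baseline)
      slr <- searchlight_rsa(ep, inventory, window = cfgs$rsa_window, folds = cfgs$folds)

      per_subject[[length(per_subject) + 1L]] <- tibble::tibble(
        subject = s, condition = cond,
        within_slope = sl[["within"]], between_slope = sl[["between"]],
        model_slope = sl[["model_rho"]],
        global_redundancy = net$global$global_mean[1],
        global_synergy = net$global$global_mean[2],
        syn_max_from = which(net$synergy == max(net$synergy), arr.ind = TRUE)[1, 1],
        syn_max_to = which(net$synergy == max(net$synergy), arr.ind = TRUE)[1, 2]
      )
      syn_sum[[cond]] <- if (is.null(syn_sum[[cond]])) net$synergy else syn_sum[[cond]] + net$synergy
      red_sum[[cond]] <- if (is.null(red_sum[[cond]])) net$redundancy else red_sum[[cond]] + net$redundancy
      sl_maps[[length(sl_maps) + 1L]] <- dplyr::mutate(slg, subject = s, condition = cond)
      rsa_sl[[length(rsa_sl) + 1L]] <- dplyr::mutate(slr, subject = s, condition = cond)
      cent <- dplyr::mutate(net$centrality, subject = s, condition = cond)
      per_subject[[length(per_subject)]]$centrality <- list(cent)
    }
  }
  subjects <- dplyr::bind_rows(per_subject)
  sl_maps <- dplyr::bind_rows(sl_maps)
  rsa_sl <- dplyr::bind_rows(rsa_sl)
  centrality <- dplyr::bind_rows(subjects$centrality)
  subjects$centrality <- NULL

  # group contrasts: HR vs LR slopes
  hi <- dplyr::filter(subjects, .data$condition == "high")
  lo <- dplyr::filter(subjects, .data$condition == "low")
  t_within <- stats::t.test(hi$within_slope, lo$within_slope, paired = TRUE,
                            alternative = "less")
  t_model <- stats::t.test(hi$model_slope, lo$model_slope, paired = TRUE,
                           alternative = "greater")
  t_syn <- stats::t.test(hi$global_synergy, hi$global_redundancy, paired = TRUE,
                         alternative = "greater")

  # group searchlight GCMI map (HR): planted-encoder localisation
  gmap <- sl_maps |>
    dplyr::filter(.data$condition == "high") |>
    dplyr::group_by(.data$parcel) |>
    dplyr::summarise(mi = mean(.data$mi_corrected), .groups = "drop")
  peak_parcel <- gmap$parcel[which.max(gmap$mi)]

  # cluster of parcels with stronger model-slope shift for HR (first step of
  # the cluster test: contiguous parcels above the uncorrected threshold)
  model_mat <- function(cond) {
    m <- rsa_sl |>
      dplyr::filter(.data$condition == cond) |>
      dplyr::select("subject", "parcel", "model_slope") |>
      tidyr::pivot_wider(names_from = "parcel", values_from = "model_slope") |>
      dplyr::arrange(.data$subject)
    as.matrix(m[, -1])
  }
  mh <- model_mat("high")
  ml <- model_mat("low")
  adj <- spatial_adjacency(atlas, quantile = 0.1)
  cluster_parcels <- first_step_cluster(mh, ml, adj, alpha = cfgs$alpha)

  if (length(cluster_parcels) > 0) {
    shift <- representational_shift(rsa_sl, cluster_parcels,
                                    metric = cfgs$shift_metric, condition = "high")

    # per-subject encoding strength in the same cluster (HR searchlight GCMI)
    enc_strength <- sl_maps |>
      dplyr::filter(.data$condition == "high", .data$parcel %in% cluster_parcels) |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(value = mean(.data$mi_corrected), .groups = "drop")
    syn_centrality <- centrality |>
      dplyr::filter(.data$condition == "high", .data$component == "synergy",
                    .data$parcel %in% cluster_parcels) |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(value = mean(.data$betweenness), .groups = "drop")

    cor_enc <- correlate_bonferroni(shift$shift, enc_strength$value, m_tests = 2)
    cor_syn <- correlate_bonferroni(shift$shift, syn_centrality$value, m_tests = 2)
  } else {
    # nothing survives the first-step threshold (e.g. a null configuration)
    shift <- tibble::tibble(subject = integer(), shift = numeric())
    cor_enc <- cor_syn <- tibble::tibble(r = NA_real_, p = NA_real_,
                                         p_corrected = NA_real_)
  }

  headline <- tibble::tibble(
    indicator = c(
      "within_slope_contrast", "model_slope_contrast",
      "global_synergy_minus_redundancy_high",
      "pe_encoding_peak_parcel", "decay_exp_bic", "decay_lin_bic",
      "shift_vs_encoding_r", "shift_vs_synergy_centrality_r"
    ),
    value = c(
      mean(hi$within_slope - lo$within_slope),
      mean(hi$model_slope - lo$model_slope),
      mean(hi$global_synergy - hi$global_redundancy),
      peak_parcel, decay$exp_bic, decay$lin_bic,
      cor_enc$r, cor_syn$r
    ),
    p_value = c(
      t_within$p.value, t_model$p.value, t_syn$p.value,
      NA, NA, NA, cor_enc$p_corrected, cor_syn$p_corrected
    )
  )

  report <- structure(
    list(
      subjects = subjects, rsa_slopes = rsa_sl, searchlight_gcmi = sl_maps,
      centrality = centrality, headline = headline, decay = decay,
      shift = shift, cluster_parcels = cluster_parcels,
      peak_parcel = peak_parcel, encoder_parcels = encoder_parcels,
      inventory = inventory, config = cfgs,
      atlas = atlas,
      group_synergy = lapply(syn_sum, function(m) m / cfgs$n_subjects),
      group_redundancy = lapply(red_sum, function(m) m / cfgs$n_subjects)
    ),
    class = "run_report"
  )
  if (!is.null(cfgs$out_dir)) write_report(report, cfgs$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$config$n_subjects, " subjects x 2 conditions, ",
      x$config$n_triplets, " triplets\n", sep = "")
  print(x$headline)
  invisible(x)
}

# first step of the cluster-based test: contiguous parcels whose paired t
# exceeds the uncorrected two-tailed threshold; returns the cluster
# containing the peak t (empty integer vector when none survive)
first_step_cluster <- function(a, b, adjacency, alpha = 0.05) {
  s <- nrow(a)
  d <- a - b
  sds <- apply(d, 2, stats::sd)
  tv <- colMeans(d) / (sds / sqrt(s))
  tv[!is.finite(tv)] <- 0
  tcrit <- stats::qt(1 - alpha / 2, df = s - 1)
  cl <- supra_clusters(tv > tcrit, adjacency)
  if (length(cl) == 0) return(integer(0))
  peak <- which.max(tv)
  for (ix in cl) if (peak %in% ix) return(sort(ix))
  sort(cl[[which.max(vapply(cl, function(ix) sum(tv[ix]), numeric(1)))]])
}

#' Per-subject representational shift
#'
#' The scalar entering the shift-vs-encoding correlations: for each
#' subject, the block slope of the chosen searchlight RSA metric in the
#' high-regularity condition, averaged over the parcels of the selected
#' cluster. With `metric = "model_rho"` larger values mean a stronger
#' shift; with `metric = "within"` the sign is flipped (more negative
#' within-slope = stronger shift) so that larger always means stronger.
#'
#' @param rsa_sl tidy searchlight-RSA slopes with columns `subject`,
#'   `condition`, `parcel`, `within_slope`, `model_slope`.
#' @param cluster_parcels parcel ids of the selected cluster (non-empty).
#' @param metric `"model_rho"` or `"within"`.
#' @param condition which condition to summarise (default high).
#' @return A tibble with `subject` and `shift`.
#' @export
representational_shift <- function(rsa_sl, cluster_parcels,
                                   metric = c("model_rho", "within"),
                                   condition = "high") {
  metric <- match.arg(metric)
  if (length(cluster_parcels) == 0) rlang::abort("empty parcel cluster")
  col <- if (metric == "model_rho") "model_slope" else "within_slope"
  sgn <- if (metric == "model_rho") 1 else -1
  rsa_sl |>
    dplyr::filter(.data$condition == .env$condition,
                  .data$parcel %in% cluster_parcels) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(shift = sgn * mean(.data[[col]]), .groups = "drop")
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$subjects, file.path(out_dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(report$rsa_slopes, file.path(out_dir, "rsa_searchlight_slopes.csv"), row.names = FALSE)
  utils::write.csv(report$searchlight_gcmi, file.path(out_dir, "gcmi_searchlight.csv"), row.names = FALSE)
  utils::write.csv(report$centrality, file.path(out_dir, "pid_centrality.csv"), row.names = FALSE)
  utils::write.csv(report$headline, file.path(out_dir, "headline.csv"), row.names = FALSE)
  cfg <- report$config
  cfg$out_dir <- NULL
  jsonlite::write_json(
    list(config = unclass(cfg), cluster_parcels = report$cluster_parcels,
         peak_parcel = report$peak_parcel),
    file.path(out_dir, "run.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
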