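#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tone sequence excerpt
#'
#' Piano-roll style view of the first triplets of a stream, tones arranged
#' by frequency with triplet boundaries marked.
#'
#' @param object a `tone_sequence`.
#' @param n_triplets how many triplets to show (default 12).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tone_sequence
#' @export
autoplot.tone_sequence <- function(object, n_triplets = 12, ...) {
  d <- dplyr::filter(object, .data$triplet_id <= n_triplets)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$onset_s, y = .data$freq_hz)) +
    ggplot2::geom_vline(
      xintercept = unique((d$triplet_id - 1) * 0.999) - 0.0165,
      colour = "grey80", linetype = 2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10(breaks = unique(d$freq_hz), labels = unique(d$label)) +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = paste0(attr(object, "regularity"), "-regularity sequence")
    ) +
    ggplot2::theme_minimal()
}

#' Plot the observer's prediction-error and accuracy trajectories
#'
#' @param object an `observer_trace`.
#' @param ... unused.
#' @return A ggplot object with PE and running accuracy facets.
#' @method autoplot observer_trace
#' @export
autoplot.observer_trace <- function(object, ...) {
  d <- object$steps |>
    dplyr::select("transition", "pe", "accuracy") |>
    tidyr::pivot_longer(-"transition", names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$transition, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "transition", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a transition matrix or RDM
#'
#' @param m a square matrix (transition probabilities or dissimilarities).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_matrix <- function(m, title = NULL) {
  d <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Plot the redundancy and synergy networks
#'
#' @param object an `info_network`.
#' @param ... unused.
#' @return A ggplot object (tiles, both components side by side).
#' @method autoplot info_network
#' @export
autoplot.info_network <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("redundancy", "synergy"), names_to = "component")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$from, y = .data$to, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "parcel", y = "parcel", fill = "bits") +
    ggplot2::theme_minimal()
}

#' Time course of the within/between-triplet geometry per block
#'
#' @param object an `rdm_series`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rdm_series
#' @export
autoplot.rdm_series <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(c("within", "between", "model_rho"), names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = factor(.data$block))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (s)", colour = "block") +
    ggplot2::theme_minimal()
}
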