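#' Write / read a tone sequence as TSV with a JSON sidecar
#'
#' The TSV holds one row per tone (`position`, `tone_index`, `note_label`,
#' `freq_hz`, `triplet_id`, `onset_s`); the sidecar (`<path>.json`) records
#' regularity, seed, variant, triplet inventory and the tone alphabet so
#' the sequence can be reconstructed exactly.
#'
#' @param seq a `tone_sequence`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  out <- data.frame(
    position = seq$position, tone_index = seq$tone, note_label = seq$label,
    freq_hz = seq$freq_hz, triplet_id = seq$triplet_id, onset_s = seq$onset_s
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(
    regularity = attr(seq, "regularity"), seed = attr(seq, "seed"),
    variant = attr(seq, "variant"),
    triplet_types = attr(seq, "triplet_types"),
    toneset = as.data.frame(attr(seq, "toneset"))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  tab <- utils::read.delim(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- tibble::tibble(
    position = tab$position, tone = tab$tone_index, label = tab$note_label,
    freq_hz = tab$freq_hz, triplet_id = tab$triplet_id, onset_s = tab$onset_s
  )
  tt <- side$triplet_types
  if (is.matrix(tt)) {
    tt <- lapply(seq_len(nrow(tt)), function(i) as.integer(tt[i, ]))
  } else if (is.list(tt)) {
    tt <- lapply(tt, as.integer)
  }
  structure(out,
    class = c("tone_sequence", class(out)),
    regularity = side$regularity, seed = side$seed, variant = side$variant,
    triplet_types = tt,
    toneset = tibble::as_tibble(side$toneset)
  )
}

#' Write an observer trace as TSV (steps) and CSV (final weights)
#'
#' @param trace an `observer_trace`.
#' @param path output TSV path for the step table; the final weight matrix
#'   goes to `<path>.weights.csv`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace$steps), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(trace$W_final, paste0(path, ".weights.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
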