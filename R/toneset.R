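#' The 12-tone stimulus alphabet
#'
#' Pure-tone alphabet used to build the triplet sequences: the musical notes
#' C, D, E, F#, G# and A# from the 4th and 5th octaves, i.e. twelve sinusoids
#' between 261.63 and 932.33 Hz. Tones are indexed 0-11 in ascending
#' frequency.
#'
#' @return A tibble with columns `tone` (integer index 0-11), `label`
#'   (note name) and `freq_hz` (fundamental frequency in Hz).
#' @examples
#' tone_set()
#' @export
tone_set <- function() {
  tibble::tibble(
    tone = 0:11,
    label = c(
      "C4", "D4", "E4", "F#4", "G#4", "A#4",
      "C5", "D5", "E5", "F#5", "G#5", "A#5"
    ),
    freq_hz = c(
      261.63, 293.66, 329.63, 369.99, 415.30, 466.16,
      523.25, 587.33, 659.26, 739.99, 830.61, 932.33
    )
  )
}

validate_toneset <- function(toneset) {
  stopifnot(is.data.frame(toneset), all(c("tone", "freq_hz") %in% names(toneset)))
  if (nrow(toneset) < 3) {
    rlang::abort("a tone set needs at least 3 tones")
  }
  if (any(diff(toneset$freq_hz) <= 0)) {
    rlang::abort("tone frequencies must be strictly increasing")
  }
  if (any(toneset$freq_hz <= 0)) {
    rlang::abort("tone frequencies must be positive")
  }
  invisible(toneset)
}

#' Frequency span of a tone triple
#'
#' Ratio of the highest to the lowest frequency among the given tone indices.
#' Triplets in the stimulus sequences are constrained to span at most one
#' octave (ratio 2).
#'
#' @param tones integer tone indices (0-based).
#' @param toneset tone alphabet, see [tone_set()].
#' @return The max/min frequency ratio, a single number.
#' @export
octave_span <- function(tones, toneset = tone_set()) {
  f <- toneset$freq_hz[tones + 1L]
  max(f) / min(f)
}
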