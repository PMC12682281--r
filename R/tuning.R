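#' Equal-division tuning systems
#'
#' A tuning system divides a frequency span (an octave, 2:1, or a tritave,
#' 3:1) into a fixed number of logarithmically equal steps. Standard Western
#' tuning is `tuning_system(12, 2)` (12-EDO); dividing a tritave into twelve
#' equal steps yields an unfamiliar system whose steps are wider than
#' semitones but support the same 12-fold pitch-class arithmetic.
#'
#' @param divisions integer >= 2, number of equal steps per span.
#' @param span_ratio frequency ratio of the span (> 1); 2 for an octave,
#'   3 for a tritave.
#' @param base_frequency frequency in Hz assigned to step 0 (> 0).
#' @return an object of class `tuning_system`.
#' @examples
#' edo <- tuning_system(12, 2, 220)
#' step_frequency(edo, 12)  # 440 Hz, one octave up
#' ut <- tuning_system(12, 3, 220)
#' step_frequency(ut, 12)   # 660 Hz, one tritave up
#' @export
tuning_system <- function(divisions, span_ratio = 2, base_frequency = 220) {
  if (!is.numeric(divisions) || length(divisions) != 1L ||
      divisions != round(divisions) || divisions < 2) {
    abort("`divisions` must be a single integer >= 2")
  }
  if (!is.numeric(span_ratio) || length(span_ratio) != 1L || span_ratio <= 1) {
    abort("`span_ratio` must be a single number > 1")
  }
  if (!is.numeric(base_frequency) || length(base_frequency) != 1L ||
      base_frequency <= 0) {
    abort("`base_frequency` must be a single positive number (Hz)")
  }
  structure(
    list(divisions = as.integer(divisions),
         span_ratio = as.double(span_ratio),
         base_frequency = as.double(base_frequency)),
    class = "tuning_system"
  )
}

#' 12 equal divisions of the octave
#'
#' @param base_frequency Hz anchor for step 0.
#' @return a `tuning_system`.
#' @export
edo12 <- function(base_frequency = 220) tuning_system(12L, 2, base_frequency)

#' 12 equal divisions of the tritave (unfamiliar tuning, "UT")
#'
#' @param base_frequency Hz anchor for step 0.
#' @return a `tuning_system`.
#' @export
ut12 <- function(base_frequency = 220) tuning_system(12L, 3, base_frequency)

#' Frequency of a tuning step
#'
#' `base_frequency * span_ratio^(step / divisions)`; steps may be any
#' integer (negative or beyond one span), so that
#' `step_frequency(t, s + divisions) == span_ratio * step_frequency(t, s)`.
#'
#' @param tuning a `tuning_system`.
#' @param step integer step index (vectorized).
#' @return frequency in Hz.
#' @export
step_frequency <- function(tuning, step) {
  stopifnot(inherits(tuning, "tuning_system"))
  tuning$base_frequency * tuning$span_ratio^(step / tuning$divisions)
}

#' @export
print.tuning_system <- function(x, ...) {
  cat(sprintf("<tuning_system> %d equal divisions of span %.6g (step 0 = %.6g Hz)\n",
              x$divisions, x$span_ratio, x$base_frequency))
  invisible(x)
}

#' Read a tuning system from a JSON config
#'
#' Expects fields `divisions`, `span_ratio`, `base_frequency`.
#'
#' @param path path to a JSON file.
#' @return a `tuning_system`.
#' @export
read_tuning <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tuning_system(cfg$divisions, cfg$span_ratio %||% 2,
                cfg$base_frequency %||% 220)
}
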