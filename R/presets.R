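# Experiment presets: the four designs used throughout the package.
#
# exp1: pentatonic vs chromatic, octave 12-EDO, melody lengths 8/12/16
#       (three cohorts), 6 blocks x 20 trials split across the two sets.
# exp2: all 66 five-note transpositional classes, length 12; each
#       participant receives 6 sets, one block (20 trials) per set.
# exp3: the two perfectly even sets {0,3,6,9} and {0,2,4,6,8,10},
#       lengths 12/16.
# exp4: tritave tuning (12 equal divisions of 3:1); pentatonic {0,2,4,7,9}
#       vs the low-evenness control {0,1,2,4,8}, length 12.

#' Experiment preset configurations
#'
#' Returns the design bundle for one of the four standard experiments:
#' tuning, condition sets, melody lengths, and session layout.
#'
#' @param preset one of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`.
#' @return a list with `name`, `tuning`, `conditions` (named list of
#'   `pc_set`; `NULL` for exp2, which uses all 66 classes), `melody_lengths`,
#'   `n_blocks`, `trials_per_block`, `one_set_per_block`,
#'   `sets_per_participant`, `trials_per_set`.
#' @export
preset_config <- function(preset = c("exp1", "exp2", "exp3", "exp4")) {
  preset <- match.arg(preset)
  base <- list(name = preset, n_blocks = 6L, trials_per_block = 20L,
               one_set_per_block = FALSE, sets_per_participant = NULL,
               trials_per_set = NULL)
  switch(preset,
    exp1 = utils::modifyList(base, list(
      tuning = edo12(),
      conditions = list(pentatonic = pc_set(c(0, 2, 4, 7, 9)),
                        chromatic = pc_set(0:11)),
      melody_lengths = c(8L, 12L, 16L)
    )),
    exp2 = utils::modifyList(base, list(
      tuning = edo12(),
      conditions = NULL,  # all 66 five-note classes
      melody_lengths = 12L,
      one_set_per_block = TRUE,
      sets_per_participant = 6L,
      trials_per_set = 20L
    )),
    exp3 = utils::modifyList(base, list(
      tuning = edo12(),
      conditions = list(diminished7 = pc_set(c(0, 3, 6, 9)),
                        whole_tone = pc_set(c(0, 2, 4, 6, 8, 10))),
      melody_lengths = c(12L, 16L)
    )),
    exp4 = utils::modifyList(base, list(
      tuning = ut12(),
      conditions = list(pentatonic = pc_set(c(0, 2, 4, 7, 9)),
                        control = pc_set(c(0, 1, 2, 4, 8))),
      melody_lengths = 12L
    ))
  )
}

#' Conditions of a preset as set classes with ids
#'
#' @param config a [preset_config()] result.
#' @return a named list of `pc_set` objects (canonical representatives);
#'   for exp2, all 66 five-note class representatives keyed by set id.
#' @export
preset_conditions <- function(config) {
  if (!is.null(config$conditions)) {
    lapply(config$conditions, canonical_form)
  } else {
    classes <- enumerate_set_classes(config$tuning$divisions, 5L)
    setNames(lapply(classes, `[[`, "representative"),
             vapply(classes, `[[`, character(1), "set_id"))
  }
}
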