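# End-to-end pipeline: stimuli -> synthetic cohort -> analysis, with a
# manifest recording config, seeds and versions for reproducibility.

#' Run the full pipeline for an experiment preset
#'
#' Generates one example session plan per melody length, simulates a
#' synthetic cohort over the preset's sets, applies exclusions, computes
#' condition bias summaries and the group-test report, and — for the
#' many-sets design (exp2) — the evenness correlation and the
#' interval-vector ridge regression. All outputs are written under
#' `out_dir` together with a `manifest.json`; one global seed fans out to
#' per-stage seeds via [derive_seed()].
#'
#' @param preset one of `"exp1"`..`"exp4"` or a [preset_config()] list.
#' @param seed global integer seed.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param n_participants synthetic cohort size per melody length.
#' @param n_perm permutations for the ridge analysis (exp2 only).
#' @param model a [response_model()]; default [response_model()].
#' @return (invisibly) a list with `session_plans`, `responses`,
#'   `summaries`, `tests`, and for exp2 `scores`, `evenness_cor`, `ridge`;
#'   plus `manifest`.
#' @export
run_pipeline <- function(preset, seed = 1L, out_dir = NULL,
                         n_participants = 40L, n_perm = 1000L,
                         model = response_model()) {
  config <- if (is.character(preset)) preset_config(preset) else preset
  conditions <- preset_conditions(config)
  features <- set_class_features(conditions, config$tuning$divisions)

  stim_seed <- derive_seed(seed, "stimuli")
  sim_seed <- derive_seed(seed, "simulate")
  perm_seed <- derive_seed(seed, "permutation")

  # one example session plan per melody length (exp2 sessions would need a
  # per-participant set draw; the example plan uses the first 6 classes)
  session_conditions <- if (length(conditions) > config$n_blocks) {
    conditions[seq_len(config$n_blocks)]
  } else conditions
  session_plans <- lapply(config$melody_lengths, function(len) {
    build_session(session_conditions, melody_length = len,
                  tuning = config$tuning, n_blocks = config$n_blocks,
                  trials_per_block = config$trials_per_block,
                  one_set_per_block = config$one_set_per_block,
                  seed = derive_seed(stim_seed, paste0("len", len)))
  })
  names(session_plans) <- paste0("length_", config$melody_lengths)

  sets_pp <- config$sets_per_participant %||% length(conditions)
  trials_ps <- config$trials_per_set %||%
    (config$n_blocks * config$trials_per_block / length(conditions))
  responses <- do.call(rbind, lapply(seq_along(config$melody_lengths),
    function(i) {
      len <- config$melody_lengths[i]
      design <- cohort_design(features, sets_per_participant = sets_pp,
                              trials_per_set = trials_ps,
                              melody_length = len)
      simulate_cohort(model, design, n_participants,
                      seed = derive_seed(sim_seed, paste0("len", len)),
                      cohort = paste0(config$name, "_len", len))
    }))
  # participant ids must be unique across cohorts
  responses$participant_id <- paste(responses$cohort,
                                    responses$participant_id, sep = "_")

  kept <- apply_exclusions(responses)
  summaries <- compute_bias(kept)
  tests <- group_tests(summaries,
                       between = if (length(config$melody_lengths) > 1L)
                         "melody_length" else NULL)

  result <- list(config = config, session_plans = session_plans,
                 responses = responses, summaries = summaries,
                 tests = tests,
                 exclusions = attr(kept, "exclusions"))

  if (length(conditions) >= 10L) {  # many-sets design: geometry analyses
    scores <- set_scores(summaries, features)
    result$scores <- scores
    result$evenness_cor <- evenness_correlation(scores)
    result$ridge <- ridge_interval_regression(scores, penalty = 1.0,
                                              n_perm = n_perm,
                                              seed = perm_seed)
  }

  result$manifest <- list(
    package = "scalegeom",
    version = as.character(utils::packageVersion("scalegeom")),
    preset = config$name, seed = seed,
    stage_seeds = list(stimuli = stim_seed, simulate = sim_seed,
                       permutation = perm_seed),
    n_participants = n_participants, n_perm = n_perm,
    r_version = as.character(getRversion())
  )

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

set_class_features <- function(conditions, divisions) {
  rows <- lapply(names(conditions), function(nm) {
    s <- conditions[[nm]]
    iv <- interval_vector(s)
    ev <- evenness(s)
    c(list(set_id = nm, representative = set_string(canonical_form(s)),
           cardinality = length(s$steps)),
      as.list(iv),
      list(sd_deviation = ev$sd_deviation, evenness = ev$evenness))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_responses(result$responses, p("responses.csv"),
                  seed = result$manifest$seed)
  write.csv(result$summaries, p("bias_summaries.csv"), row.names = FALSE)
  write.csv(result$tests$t_tests, p("t_tests.csv"), row.names = FALSE)
  if (!is.null(result$tests$anova)) {
    write.csv(result$tests$anova, p("anova.csv"), row.names = FALSE)
  }
  excl <- result$exclusions
  if (nrow(excl$participants) > 0L || nrow(excl$conditions) > 0L) {
    jsonlite::write_json(excl, p("exclusions.json"), dataframe = "rows")
  }
  if (!is.null(result$scores)) {
    write.csv(result$scores, p("set_scores.csv"), row.names = FALSE)
    ev <- result$evenness_cor
    rg <- result$ridge
    jsonlite::write_json(
      list(evenness_correlation = ev,
           ridge = list(coefficients = as.list(rg$coefficients),
                        R = rg$R, p_model = rg$p_model,
                        p = as.list(rg$p),
                        ci = list(lower = as.list(rg$ci["lower", ]),
                                  upper = as.list(rg$ci["upper", ])),
                        penalty = rg$penalty, n_perm = rg$n_perm,
                        ci_method = rg$ci_method)),
      p("regression.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
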