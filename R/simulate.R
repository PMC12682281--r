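# Synthetic-participant generator: produces per-trial forced-choice response
# tables with the statistical structure the analysis pipeline assumes, so the
# full pipeline can be exercised and validated without any human data.

#' Generative response model for synthetic participants
#'
#' On each trial a synthetic participant either reports "no difference"
#' (probability `nodiff_rate`), lapses and picks note/contour uniformly
#' (probability `lapse`), or chooses the note deviant with probability
#' `plogis(eta)` where
#'
#' `eta = intercept + u_i + beta_evenness * evenness +
#'        sum(beta_ic * ic_counts) + beta_length * (length - 8)`
#'
#' and `u_i ~ N(0, sigma_u)` is a participant random intercept. Features
#' enter raw (interval-class counts 0..6, evenness in step units) so that
#' planted coefficients are directly comparable to the raw-predictor
#' regression in the analysis stage.
#'
#' The defaults encode a world in which sensitivity to note deviations
#' rises with set evenness, IC3 and IC5 content and melody length, and
#' falls with IC1 and IC6 content — the qualitative structure the analysis
#' stage is designed to detect. Magnitudes were sized once, at design time,
#' against the noiseless limit of the analysis pipeline: because evenness
#' and the interval-class counts are collinear across the 66 five-note
#' classes (the counts sum to 10), the population-level ridge coefficients
#' differ from the structural plants, and the defaults were chosen so that
#' the population ridge signs for IC1/IC3/IC5/IC6 are unambiguous while
#' set-level mean biases span roughly 0.05 to 0.45 and per-count effects on
#' the response-bias scale stay in the 0.01-0.05 band (see the package
#' vignette for the sizing rationale).
#'
#' @param intercept baseline log-odds of choosing the note deviant.
#' @param beta_evenness log-odds per unit evenness (evenness is negative,
#'   in step units; less even = more negative).
#' @param beta_ic numeric length-6: log-odds per count of IC1..IC6.
#' @param beta_length log-odds per melody note beyond 8.
#' @param sigma_u SD of the participant random intercept (log-odds).
#' @param lapse probability of a uniformly random note/contour choice.
#' @param nodiff_rate probability of reporting no difference.
#' @return an object of class `response_model`.
#' @export
response_model <- function(intercept = 0.6,
                           beta_evenness = 0.20,
                           beta_ic = c(-0.06, 0, 0.06, 0, 0.08, -0.12),
                           beta_length = 0.02,
                           sigma_u = 0.5,
                           lapse = 0.05,
                           nodiff_rate = 0.10) {
  if (length(beta_ic) != 6L) abort("`beta_ic` must have length 6")
  if (lapse < 0 || lapse >= 1 || nodiff_rate < 0 || nodiff_rate >= 1 ||
      lapse + nodiff_rate >= 1) {
    abort("`lapse` and `nodiff_rate` must lie in [0,1) with sum < 1")
  }
  if (sigma_u < 0) abort("`sigma_u` must be non-negative")
  structure(
    list(intercept = intercept, beta_evenness = beta_evenness,
         beta_ic = as.double(beta_ic), beta_length = beta_length,
         sigma_u = sigma_u, lapse = lapse, nodiff_rate = nodiff_rate),
    class = "response_model"
  )
}

#' Null response model
#'
#' All structural coefficients zero: choices are an even coin (up to lapse
#' and no-difference behavior). Used for null-calibration checks.
#'
#' @param ... overrides passed to [response_model()].
#' @return a `response_model`.
#' @export
null_response_model <- function(...) {
  response_model(intercept = 0, beta_evenness = 0,
                 beta_ic = rep(0, 6), beta_length = 0, ...)
}

#' Design for a simulated cohort
#'
#' Names the sets (rows of a [set_class_table()]) and session layout a
#' cohort is exposed to. In the many-sets design each participant receives
#' `sets_per_participant` of the listed sets (dealt from successive random
#' permutations of the set list, so all sets get near-equal coverage while
#' the participant-set pairing stays random), one block per set.
#'
#' @param features a [set_class_table()] (must include `set_id`,
#'   `ic1`..`ic6`, `evenness`).
#' @param set_ids which sets to administer; default all rows.
#' @param sets_per_participant conditions per participant (default 6).
#' @param trials_per_set trials per (participant, set) condition
#'   (default 20).
#' @param melody_length notes per melody (default 12).
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(features, set_ids = features$set_id,
                          sets_per_participant = 6L, trials_per_set = 20L,
                          melody_length = 12L) {
  need <- c("set_id", paste0("ic", 1:6), "evenness")
  if (!all(need %in% names(features))) {
    abort("`features` must contain set_id, ic1..ic6 and evenness columns")
  }
  missing <- setdiff(set_ids, features$set_id)
  if (length(missing) > 0L) {
    abort(sprintf("unknown set id(s): %s", paste(missing, collapse = ", ")))
  }
  sets_per_participant <- min(sets_per_participant, length(set_ids))
  structure(
    list(features = features, set_ids = set_ids,
         sets_per_participant = as.integer(sets_per_participant),
         trials_per_set = as.integer(trials_per_set),
         melody_length = as.integer(melody_length)),
    class = "cohort_design"
  )
}

model_eta <- function(model, features_row, melody_length) {
  ics <- as.numeric(features_row[paste0("ic", 1:6)])
  model$intercept + model$beta_evenness * features_row$evenness +
    sum(model$beta_ic * ics) + model$beta_length * (melody_length - 8)
}

#' Simulate a cohort of synthetic participants
#'
#' Produces a per-trial response table in the schema the analysis stage
#' consumes. Comprehension ratings default to 4 or 5 (all participants
#' understand the task); years of musical training are drawn from a
#' right-skewed distribution with a point mass at zero. Deterministic
#' given `seed`.
#'
#' @param model a [response_model()].
#' @param design a [cohort_design()].
#' @param n_participants number of synthetic participants.
#' @param seed integer seed.
#' @param cohort label recorded in the `cohort` column.
#' @return a data.frame with one row per trial: `participant_id`, `cohort`,
#'   `set_id`, `melody_length`, `block`, `trial`, `choice` (one of
#'   `"note"`, `"contour"`, `"no_difference"`), `comprehension_rating`,
#'   `years_training`, `plays_instrument`.
#' @export
simulate_cohort <- function(model, design, n_participants, seed = 1L,
                            cohort = "synthetic") {
  stopifnot(inherits(model, "response_model"),
            inherits(design, "cohort_design"))
  set.seed(seed)
  n_sets <- length(design$set_ids)
  spp <- design$sets_per_participant
  tps <- design$trials_per_set

  # Balanced random assignment: deal sets from successive random
  # permutations of the set list. Coverage stays near-equal while the
  # participant-set pairing is random, so participant-level heterogeneity
  # hits random set pairs and the set means stay exchangeable (a
  # deterministic consecutive-block assignment would induce a banded
  # correlation structure across sets and bias permutation inference).
  assign_idx <- if (n_sets %% spp == 0L) {
    rounds <- ceiling(n_participants * spp / n_sets)
    dealt <- unlist(lapply(seq_len(rounds), function(r) sample.int(n_sets)))
    matrix(dealt[seq_len(n_participants * spp)], nrow = spp)
  } else {
    vapply(seq_len(n_participants), function(i) sample.int(n_sets, spp),
           integer(spp))
  }
  feat <- design$features[match(design$set_ids, design$features$set_id), ]
  eta_set <- vapply(seq_len(n_sets), function(j)
    model_eta(model, feat[j, ], design$melody_length), numeric(1))

  u <- rnorm(n_participants, 0, model$sigma_u)
  comprehension <- sample(4:5, n_participants, replace = TRUE,
                          prob = c(0.3, 0.7))
  years <- ifelse(runif(n_participants) < 0.4, 0,
                  round(pmin(rexp(n_participants, 1 / 4), 20), 1))
  plays <- years > 0

  pid <- rep(seq_len(n_participants), each = spp * tps)
  set_idx <- rep(as.vector(assign_idx), each = tps)
  block <- rep(rep(seq_len(spp), each = tps), times = n_participants)
  trial <- rep(seq_len(tps), times = spp * n_participants)

  p_note <- stats::plogis(eta_set[set_idx] + u[pid])
  r <- runif(length(pid))
  choice <- character(length(pid))
  nodiff <- r < model$nodiff_rate
  lapse <- !nodiff & r < model$nodiff_rate + model$lapse
  rest <- !nodiff & !lapse
  choice[nodiff] <- "no_difference"
  choice[lapse] <- ifelse(runif(sum(lapse)) < 0.5, "note", "contour")
  choice[rest] <- ifelse(runif(sum(rest)) < p_note[rest], "note", "contour")

  data.frame(
    participant_id = pid,
    cohort = cohort,
    set_id = design$set_ids[set_idx],
    melody_length = design$melody_length,
    block = block,
    trial = trial,
    choice = choice,
    comprehension_rating = comprehension[pid],
    years_training = years[pid],
    plays_instrument = plays[pid],
    stringsAsFactors = FALSE
  )
}

#' Inject exclusion-triggering features into a response table
#'
#' Marks a fraction of participants as low-comprehension (rating drawn from
#' 1..3) and degrades a fraction of (participant, set) conditions so their
#' usable (note + contour) response count falls below a target, by flipping
#' trials to "no_difference". Exercises the downstream exclusion logic.
#'
#' @param table a response table from [simulate_cohort()].
#' @param low_comprehension_fraction fraction of participants set to a
#'   rating of 3 or less.
#' @param sparse_fraction fraction of (participant, set) conditions reduced
#'   to `sparse_usable` usable responses.
#' @param sparse_usable usable responses left in degraded conditions
#'   (default 14, one below the standard threshold of 15).
#' @param seed integer seed.
#' @return the modified response table.
#' @export
simulate_exclusion_features <- function(table,
                                        low_comprehension_fraction = 0,
                                        sparse_fraction = 0,
                                        sparse_usable = 14L,
                                        seed = 1L) {
  if (low_comprehension_fraction < 0 || low_comprehension_fraction > 1 ||
      sparse_fraction < 0 || sparse_fraction > 1) {
    abort("fractions must lie in [0, 1]")
  }
  set.seed(seed)
  ids <- unique(table$participant_id)
  n_low <- round(low_comprehension_fraction * length(ids))
  if (n_low > 0L) {
    low <- sample(ids, n_low)
    table$comprehension_rating[table$participant_id %in% low] <-
      sample(1:3, sum(table$participant_id %in% low), replace = TRUE)
  }
  conds <- unique(table[, c("participant_id", "set_id")])
  n_sparse <- round(sparse_fraction * nrow(conds))
  if (n_sparse > 0L) {
    pick <- conds[sample(nrow(conds), n_sparse), , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      rows <- which(table$participant_id == pick$participant_id[i] &
                      table$set_id == pick$set_id[i])
      usable <- rows[table$choice[rows] != "no_difference"]
      excess <- length(usable) - sparse_usable
      if (excess > 0L) {
        flip <- sample(usable, excess)
        table$choice[flip] <- "no_difference"
      }
    }
  }
  table
}

#' Write a response table to CSV with a seed header comment
#'
#' @param table response table.
#' @param path destination file.
#' @param seed seed recorded in a `#`-comment header line.
#' @return `path`, invisibly.
#' @export
write_responses <- function(table, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scalegeom response table; seed=%s", seed), con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a response table CSV (skipping comment header lines)
#'
#' @param path CSV written by [write_responses()] (or matching its schema).
#' @return a data.frame.
#' @export
read_responses <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
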