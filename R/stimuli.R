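# Stimulus generation: probe melodies by constrained pseudo-random walk over
# the members of a musical set, plus the two test melodies used in the
# forced-choice task (a note deviant and a contour deviant).

NOTE_DURATION_MS <- 250
NOTE_GAP_MS <- 83
INTER_MELODY_MS <- 1000

#' Melody generation specification
#'
#' Parameters of the constrained random walk that generates probe melodies:
#' the melody is confined to one span of the tuning (steps 0..divisions,
#' endpoints included; step `divisions` is the span note, equivalent to step
#' 0 modulo the span), consecutive notes never repeat, leaps never exceed
#' `leap_limit` steps (a leap of exactly `leap_limit` is legal), and every
#' pitch class belongs to one fixed mode of the set class, drawn uniformly
#' at random per melody.
#'
#' @param set a `pc_set` (the set class is realized through its modes).
#' @param length number of notes (8, 12 or 16 in the standard designs).
#' @param tuning a `tuning_system`.
#' @param leap_limit maximum absolute step difference between consecutive
#'   notes (default 6, inclusive).
#' @param range_steps inclusive pitch range, default `c(0, divisions)`.
#' @return an object of class `melody_spec`.
#' @export
melody_spec <- function(set, length = 12L, tuning = edo12(),
                        leap_limit = 6L, range_steps = NULL) {
  stopifnot(inherits(set, "pc_set"), inherits(tuning, "tuning_system"))
  if (set$divisions != tuning$divisions) {
    abort("set and tuning must agree on the number of divisions")
  }
  if (length < 4L) abort("`length` must be at least 4")
  if (leap_limit < 1L) abort("`leap_limit` must be at least 1")
  range_steps <- range_steps %||% c(0L, tuning$divisions)
  structure(
    list(set = set, length = as.integer(length), tuning = tuning,
         leap_limit = as.integer(leap_limit),
         range_steps = as.integer(range_steps)),
    class = "melody_spec"
  )
}

melody <- function(steps, spec, mode, role = "probe", transposition = NULL) {
  structure(
    list(steps = as.integer(steps), spec = spec, mode = mode, role = role,
         transposition = transposition,
         duration_ms = NOTE_DURATION_MS, gap_ms = NOTE_GAP_MS),
    class = "melody"
  )
}

#' @export
print.melody <- function(x, ...) {
  cat(sprintf("<melody> [%s] %s%s\n", x$role,
              paste(x$steps, collapse = " "),
              if (is.null(x$transposition)) "" else
                sprintf(" (transposed to base %d)", x$transposition)))
  invisible(x)
}

allowed_pitches <- function(spec, mode) {
  p <- spec$range_steps[1]:spec$range_steps[2]
  p[(p %% spec$tuning$divisions) %in% mode$steps]
}

#' Generate a probe melody
#'
#' Pseudo-random walk over the allowed pitches of one mode of the set,
#' restarting from scratch if the walk dead-ends (rare; bounded by
#' `max_retries`). Uses R's RNG: call `set.seed()` (or go through
#' [build_session()]) for reproducibility.
#'
#' @param spec a `melody_spec`.
#' @param mode optionally, a fixed mode (`pc_set`); by default one mode of
#'   `spec$set` is drawn uniformly at random and fixed for the melody.
#' @param max_retries restarts allowed before erroring.
#' @return a `melody`.
#' @export
generate_probe <- function(spec, mode = NULL, max_retries = 1000L) {
  stopifnot(inherits(spec, "melody_spec"))
  if (is.null(mode)) {
    ms <- modes(spec$set)
    mode <- ms[[sample.int(length(ms), 1L)]]
  }
  pool <- allowed_pitches(spec, mode)
  if (length(pool) < 2L) abort("mode admits fewer than 2 pitches in range")
  for (attempt in seq_len(max_retries)) {
    steps <- integer(spec$length)
    steps[1L] <- pool[sample.int(length(pool), 1L)]
    ok <- TRUE
    for (i in 2L:spec$length) {
      cand <- pool[abs(pool - steps[i - 1L]) <= spec$leap_limit &
                     pool != steps[i - 1L]]
      if (length(cand) == 0L) { ok <- FALSE; break }
      steps[i] <- cand[sample.int(length(cand), 1L)]
    }
    if (ok) return(melody(steps, spec, mode))
  }
  abort(sprintf("random walk failed after %d restarts", max_retries))
}

middle_positions <- function(n) {
  # the two exchanged/shifted positions, 1-based: 4/5, 6/7, 8/9 for
  # lengths 8/12/16; generalized to (n/2, n/2 + 1) for other even lengths
  if (n %% 2L != 0L) abort("middle positions undefined for odd length")
  c(n %/% 2L, n %/% 2L + 1L)
}

#' Contour-deviant test melody
#'
#' Identical to the probe except that the two middle notes are exchanged:
#' the pitch collection is preserved but the contour changes. The deviant is
#' exempt from the walk constraints (the swap may create a repetition).
#'
#' @param probe a probe `melody`.
#' @param middle optional explicit 1-based pair of positions to exchange.
#' @return a `melody` with role `"contour_deviant"`.
#' @export
make_contour_deviant <- function(probe, middle = NULL) {
  stopifnot(inherits(probe, "melody"))
  middle <- middle %||% middle_positions(length(probe$steps))
  steps <- probe$steps
  stopifnot(steps[middle[1]] != steps[middle[2]])  # walk forbids repeats
  steps[middle] <- steps[rev(middle)]
  out <- melody(steps, probe$spec, probe$mode, role = "contour_deviant",
                transposition = probe$transposition)
  out$middle <- middle
  out
}

#' Note-deviant test melody
#'
#' One of the two middle notes is shifted up or down by one tuning step.
#' The shifted pitch must not occur anywhere in the probe and must stay in
#' range; if neither middle position admits a legal shift in the requested
#' direction the construction fails (returns `NULL`) and the caller
#' regenerates the whole triplet.
#'
#' @param probe a probe `melody`.
#' @param direction +1 or -1 step.
#' @param middle optional explicit 1-based candidate positions.
#' @return a `melody` with role `"note_deviant"` and fields
#'   `deviant_position` / `shift_direction`, or `NULL` on failure.
#' @export
make_note_deviant <- function(probe, direction, middle = NULL) {
  stopifnot(inherits(probe, "melody"), direction %in% c(-1L, 1L))
  middle <- middle %||% middle_positions(length(probe$steps))
  rng <- probe$spec$range_steps
  shifted <- probe$steps[middle] + direction
  legal <- shifted >= rng[1] & shifted <= rng[2] &
    !(shifted %in% probe$steps)
  if (!any(legal)) return(NULL)
  pos <- middle[legal][sample.int(sum(legal), 1L)]
  steps <- probe$steps
  steps[pos] <- steps[pos] + direction
  out <- melody(steps, probe$spec, probe$mode, role = "note_deviant",
                transposition = probe$transposition)
  out$deviant_position <- pos
  out$shift_direction <- as.integer(direction)
  out
}

#' Generate a probe plus its two test melodies
#'
#' Probe, note deviant and contour deviant are generated together; if the
#' note deviant cannot be constructed (both candidate shifted pitches occur
#' in the probe or fall out of range) the probe is regenerated recursively
#' until all constraints are satisfied, up to `max_retries`.
#'
#' @param spec a `melody_spec`.
#' @param direction shift direction for the note deviant (+1 or -1).
#' @param presentation_order `"note_first"` or `"contour_first"`.
#' @param max_retries cap on probe regenerations.
#' @return an object of class `trial_triplet`: list with `probe`,
#'   `note_deviant`, `contour_deviant`, `deviant_position`,
#'   `shift_direction`, `presentation_order`, `n_regenerations`.
#' @export
generate_triplet <- function(spec, direction,
                             presentation_order = "note_first",
                             max_retries = 1000L) {
  for (attempt in seq_len(max_retries)) {
    probe <- generate_probe(spec, max_retries = max_retries)
    nd <- make_note_deviant(probe, direction)
    if (is.null(nd)) next
    cd <- make_contour_deviant(probe)
    return(structure(
      list(probe = probe, note_deviant = nd, contour_deviant = cd,
           deviant_position = nd$deviant_position,
           shift_direction = nd$shift_direction,
           presentation_order = presentation_order,
           n_regenerations = attempt - 1L),
      class = "trial_triplet"
    ))
  }
  abort(sprintf("triplet generation failed after %d attempts", max_retries))
}

#' Apply a common transposition to a triplet
#'
#' One integer base offset is applied to probe and both test melodies. For
#' octave 12-EDO the offset is the MIDI note of melody step 0 and must lie
#' in 54..66 (F#3..F#4), so that the full one-octave melody range spans
#' F#3..F#5 across the admissible transpositions. For other tunings the
#' offset is a step offset relative to the tuning's base frequency.
#'
#' @param triplet a `trial_triplet`.
#' @param offset integer base offset.
#' @return the triplet with `transposition` set on all three melodies.
#' @export
assign_transposition <- function(triplet, offset) {
  stopifnot(inherits(triplet, "trial_triplet"))
  offset <- as.integer(offset)
  tun <- triplet$probe$spec$tuning
  if (is_octave_edo12(tun) && (offset < 54L || offset > 66L)) {
    abort("for octave 12-EDO the transposition base must lie in MIDI 54..66")
  }
  for (role in c("probe", "note_deviant", "contour_deviant")) {
    triplet[[role]]$transposition <- offset
  }
  triplet$transposition <- offset
  triplet
}

is_octave_edo12 <- function(tuning) {
  tuning$divisions == 12L && isTRUE(all.equal(tuning$span_ratio, 2))
}

transposition_band <- function(tuning) {
  if (is_octave_edo12(tuning)) 54:66 else 0:tuning$divisions
}

#' Build a full experimental session
#'
#' Lays out `n_blocks` blocks of `trials_per_block` trials split evenly
#' across conditions. Within each block, shift direction and deviant
#' presentation order are exactly counterbalanced within each condition;
#' the transposition base is counterbalanced across the whole session by
#' dealing a shuffled balanced pool of admissible offsets to trials
#' block by block. Trial order within a block is randomized. Fully
#' deterministic given `seed`.
#'
#' @param conditions named list of `pc_set` objects, one per condition.
#' @param melody_length notes per melody.
#' @param tuning a `tuning_system`.
#' @param n_blocks number of blocks (default 6).
#' @param trials_per_block trials per block (default 20), divisible by the
#'   number of conditions.
#' @param one_set_per_block if `TRUE` (the many-sets design), each block
#'   presents a single condition, cycling through `conditions`.
#' @param seed integer seed.
#' @return an object of class `session_plan`: list with `trials` (list of
#'   trial records), `config`.
#' @export
build_session <- function(conditions, melody_length = 12L, tuning = edo12(),
                          n_blocks = 6L, trials_per_block = 20L,
                          one_set_per_block = FALSE, seed = 1L) {
  if (length(conditions) < 1L) abort("need at least one condition")
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    abort("`conditions` must be a named list of pc_set objects")
  }
  if (one_set_per_block) {
    if (length(conditions) > n_blocks) {
      abort("more conditions than blocks in one-set-per-block layout")
    }
  } else if (trials_per_block %% length(conditions) != 0L) {
    abort("`trials_per_block` must be divisible by the number of conditions")
  }
  set.seed(seed)
  specs <- lapply(conditions, melody_spec, length = melody_length,
                  tuning = tuning)
  n_trials <- n_blocks * trials_per_block
  band <- transposition_band(tuning)
  offsets <- sample(rep(band, length.out = n_trials))

  balanced <- function(vals, n) sample(rep(vals, length.out = n))
  trials <- list()
  t_global <- 0L
  for (b in seq_len(n_blocks)) {
    if (one_set_per_block) {
      block_conditions <- rep(names(conditions)[(b - 1L) %%
                                                  length(conditions) + 1L],
                              trials_per_block)
    } else {
      per <- trials_per_block %/% length(conditions)
      block_conditions <- rep(names(conditions), each = per)
    }
    # counterbalance within block, separately per condition
    dirs <- ords <- vector("list", length(conditions))
    names(dirs) <- names(ords) <- names(conditions)
    for (cn in unique(block_conditions)) {
      n_c <- sum(block_conditions == cn)
      dirs[[cn]] <- balanced(c(1L, -1L), n_c)
      ords[[cn]] <- balanced(c("note_first", "contour_first"), n_c)
    }
    idx <- sample(seq_len(trials_per_block))  # randomize order in block
    block_conditions <- block_conditions[idx]
    counters <- setNames(integer(length(conditions)), names(conditions))
    for (k in seq_len(trials_per_block)) {
      cn <- block_conditions[k]
      counters[cn] <- counters[cn] + 1L
      t_global <- t_global + 1L
      trip <- generate_triplet(specs[[cn]],
                               direction = dirs[[cn]][counters[cn]],
                               presentation_order = ords[[cn]][counters[cn]])
      trip <- assign_transposition(trip, offsets[t_global])
      trials[[t_global]] <- list(block = b, trial = k, trial_id = t_global,
                                 condition = cn, triplet = trip)
    }
  }
  structure(
    list(trials = trials,
         config = list(conditions = conditions,
                       melody_length = as.integer(melody_length),
                       tuning = tuning, n_blocks = as.integer(n_blocks),
                       trials_per_block = as.integer(trials_per_block),
                       one_set_per_block = one_set_per_block,
                       seed = as.integer(seed))),
    class = "session_plan"
  )
}

#' @export
print.session_plan <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<session_plan> %d trials (%d blocks x %d), %d condition(s), length %d\n",
              length(x$trials), cfg$n_blocks, cfg$trials_per_block,
              length(cfg$conditions), cfg$melody_length))
  invisible(x)
}

melody_frequency <- function(mel) {
  tun <- mel$spec$tuning
  base <- mel$transposition %||% 0L
  if (is_octave_edo12(tun)) {
    440 * 2^((base + mel$steps - 69) / 12)  # MIDI anchoring
  } else {
    step_frequency(tun, base + mel$steps)
  }
}

melody_timeline <- function(mel, t0 = 0, trial_id = NA_integer_) {
  n <- length(mel$steps)
  onset <- t0 + (seq_len(n) - 1L) * (mel$duration_ms + mel$gap_ms)
  data.frame(trial_id = trial_id, melody_role = mel$role,
             note_index = seq_len(n), onset_ms = onset,
             duration_ms = mel$duration_ms, step = mel$steps,
             frequency_hz = melody_frequency(mel))
}

triplet_roles_in_order <- function(trip) {
  if (identical(trip$presentation_order, "note_first")) {
    c("probe", "note_deviant", "contour_deviant")
  } else {
    c("probe", "contour_deviant", "note_deviant")
  }
}

#' Frequency timeline for a session plan or triplet
#'
#' One row per note event. Within a trial the probe and the two test
#' melodies are laid out in presentation order, separated by a 1000 ms
#' inter-melody interval; note spacing is 333 ms (250 ms tone + 83 ms gap).
#' `step` is the untransposed melody step; `frequency_hz` includes the
#' transposition.
#'
#' @param x a `session_plan` or a `trial_triplet`.
#' @return a data.frame with columns `trial_id`, `melody_role`,
#'   `note_index`, `onset_ms`, `duration_ms`, `step`, `frequency_hz`.
#' @export
export_timeline <- function(x) {
  if (inherits(x, "trial_triplet")) {
    trips <- list(list(trial_id = 1L, triplet = x))
  } else if (inherits(x, "session_plan")) {
    trips <- lapply(x$trials, function(tr)
      list(trial_id = tr$trial_id, triplet = tr$triplet))
  } else {
    abort("`x` must be a session_plan or trial_triplet")
  }
  out <- lapply(trips, function(tr) {
    t0 <- 0
    pieces <- lapply(triplet_roles_in_order(tr$triplet), function(role) {
      mel <- tr$triplet[[role]]
      tl <- melody_timeline(mel, t0, tr$trial_id)
      t0 <<- max(tl$onset_ms) + mel$duration_ms + INTER_MELODY_MS
      tl
    })
    do.call(rbind, pieces)
  })
  do.call(rbind, out)
}

#' Write a timeline to CSV
#'
#' @param timeline output of [export_timeline()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  write.csv(timeline, path, row.names = FALSE)
  invisible(path)
}

#' Re-import a timeline CSV as melody step sequences
#'
#' Round-trip companion to [export_timeline()]: returns, per trial and
#' melody role, the ordered step sequence.
#'
#' @param path CSV written by [write_timeline()].
#' @return a data.frame (trial_id, melody_role, note_index, step, ...).
#' @export
read_timeline <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# --- Standard MIDI File (format 0) export ------------------------------

midi_varint <- function(value) {
  bytes <- value %% 128L
  value <- value %/% 128L
  while (value > 0L) {
    bytes <- c(value %% 128L + 128L, bytes)
    value <- value %/% 128L
  }
  as.raw(bytes)
}

#' Write session stimuli as a Standard MIDI File
#'
#' Format 0, one track, fixed program and velocity; 480 ticks per quarter
#' at 120 bpm so 1 ms = 0.96 ticks. Only meaningful for octave 12-EDO
#' stimuli (MIDI is equal-tempered octave-based); for any other tuning the
#' export is refused and a frequency timeline should be written instead.
#'
#' @param x a `session_plan` or `trial_triplet`.
#' @param path destination `.mid` file.
#' @param velocity note-on velocity (1..127).
#' @return `path`, invisibly.
#' @export
write_midi <- function(x, path, velocity = 80L) {
  tun <- if (inherits(x, "session_plan")) x$config$tuning else
    x$probe$spec$tuning
  if (!is_octave_edo12(tun)) {
    abort(paste("MIDI export is only defined for octave 12-EDO stimuli;",
                "use write_timeline() for a frequency timeline instead"),
          class = "scalegeom_midi_error")
  }
  tl <- export_timeline(x)
  ticks_per_ms <- 480 / 500  # 480 ticks/quarter at 500000 us/quarter
  ev <- data.frame(
    tick = round(c(tl$onset_ms, tl$onset_ms + tl$duration_ms) * ticks_per_ms),
    on = rep(c(TRUE, FALSE), each = nrow(tl)),
    # step is untransposed; recover the MIDI note from the frequency
    note = rep(round(69 + 12 * log2(tl$frequency_hz / 440)), 2L)
  )
  ev <- ev[order(ev$tick, ev$on), ]  # offs before ons at equal ticks
  body <- raw(0)
  # tempo meta event: 500000 microseconds per quarter note
  body <- c(body, as.raw(c(0x00, 0xFF, 0x51, 0x03, 0x07, 0xA1, 0x20)))
  last <- 0
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last
    last <- ev$tick[i]
    status <- if (ev$on[i]) 0x90 else 0x80
    body <- c(body, midi_varint(delta),
              as.raw(c(status, ev$note[i], if (ev$on[i]) velocity else 0L)))
  }
  body <- c(body, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))  # end of track
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MThd"), con)
  writeBin(c(6L), con, size = 4, endian = "big")
  writeBin(c(0L, 1L, 480L), con, size = 2, endian = "big")
  writeBin(charToRaw("MTrk"), con)
  writeBin(length(body), con, size = 4, endian = "big")
  writeBin(body, con)
  invisible(path)
}

#' Check all walk invariants of a melody
#'
#' Used by the test suite and by downstream consumers that want a hard
#' guarantee: range, no immediate repetition, leap limit, and set
#' membership of every pitch class in the melody's mode.
#'
#' @param mel a `melody`.
#' @return `TRUE` or a character vector of violation messages.
#' @export
validate_melody <- function(mel) {
  spec <- mel$spec
  bad <- character(0)
  if (any(mel$steps < spec$range_steps[1] | mel$steps > spec$range_steps[2]))
    bad <- c(bad, "step out of range")
  if (any(diff(mel$steps) == 0L))
    bad <- c(bad, "immediate pitch repetition")
  if (any(abs(diff(mel$steps)) > spec$leap_limit))
    bad <- c(bad, "leap above limit")
  if (!all((mel$steps %% spec$tuning$divisions) %in% mel$mode$steps))
    bad <- c(bad, "pitch class outside the melody's mode")
  if (length(bad) == 0L) TRUE else bad
}
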