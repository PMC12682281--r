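#' Pitch-class sets
#'
#' A pitch-class set is a subset of the step positions of an equal-division
#' tuning system, identified modulo the span: step positions live in
#' `[0, divisions)`. What matters for the analyses in this package is the
#' set's relational structure, not the identity of its notes, so sets are
#' usually reduced to their transpositional (cyclic-rotation) class via
#' [canonical_form()] and [enumerate_set_classes()].
#'
#' @param steps strictly increasing integer vector of step positions in
#'   `[0, divisions)`.
#' @param divisions number of steps per span (default 12).
#' @return an object of class `pc_set`.
#' @examples
#' pentatonic <- pc_set(c(0, 2, 4, 7, 9))
#' interval_vector(pentatonic)
#' evenness(pentatonic)
#' @export
pc_set <- function(steps, divisions = 12L) {
  if (length(steps) == 0L) abort("a pitch-class set must be non-empty")
  if (!is.numeric(steps) || any(steps != round(steps))) {
    abort("`steps` must be integers")
  }
  steps <- as.integer(steps)
  if (anyDuplicated(steps)) abort("`steps` must be distinct")
  if (any(steps < 0L) || any(steps >= divisions)) {
    abort(sprintf("`steps` must lie in [0, %d)", divisions))
  }
  structure(list(steps = sort(steps), divisions = as.integer(divisions)),
            class = "pc_set")
}

#' @export
print.pc_set <- function(x, ...) {
  cat(sprintf("<pc_set> {%s} in %d divisions (\"%s\")\n",
              paste(x$steps, collapse = ","), x$divisions, set_string(x)))
  invisible(x)
}

#' @export
format.pc_set <- function(x, ...) set_string(x)

#' Compact string for a set
#'
#' Steps 10 and 11 print as "T" and "E" (the usual tokens for 12 divisions,
#' e.g. the pentatonic mode "0257T"); for systems with more than 12 divisions
#' steps are comma-separated instead.
#'
#' @param set a `pc_set`.
#' @return a character scalar.
#' @export
set_string <- function(set) {
  stopifnot(inherits(set, "pc_set"))
  if (set$divisions > 12L) return(paste(set$steps, collapse = ","))
  tok <- c(as.character(0:9), "T", "E")
  paste(tok[set$steps + 1L], collapse = "")
}

#' Parse a compact set string
#'
#' Inverse of [set_string()] for systems with at most 12 divisions.
#'
#' @param s string such as `"02479"` or `"0257T"`.
#' @param divisions steps per span.
#' @return a `pc_set`.
#' @export
parse_set_string <- function(s, divisions = 12L) {
  chars <- strsplit(s, "")[[1]]
  tok <- c(as.character(0:9), "T", "E")
  idx <- match(chars, tok)
  if (anyNA(idx)) abort(sprintf("cannot parse set string '%s'", s))
  pc_set(idx - 1L, divisions)
}

rotate_to_zero <- function(steps, divisions, i) {
  # rotation starting at the i-th element, re-anchored at 0
  k <- length(steps)
  rot <- steps[c(i:k, if (i > 1L) 1:(i - 1L))] - steps[i]
  sort(rot %% divisions)
}

#' Modes of a set
#'
#' The rotations of a set re-anchored so each begins at 0. A set with
#' rotational symmetry of order `m` has `cardinality / m` distinct modes:
#' the pentatonic `{0,2,4,7,9}` has five, the fully diminished set
#' `{0,3,6,9}` only one.
#'
#' @param set a `pc_set`.
#' @return a list of `pc_set` objects, distinct, in order of starting note.
#' @export
modes <- function(set) {
  stopifnot(inherits(set, "pc_set"))
  k <- length(set$steps)
  rots <- lapply(seq_len(k), function(i)
    rotate_to_zero(set$steps, set$divisions, i))
  rots <- unique(rots)
  lapply(rots, pc_set, divisions = set$divisions)
}

#' Canonical (normal-order) representative of a transpositional class
#'
#' The lexicographically least rotation of the set re-anchored at 0; for the
#' pentatonic class this is `{0,2,4,7,9}` ("02479").
#'
#' @param set a `pc_set`.
#' @return a `pc_set` containing 0.
#' @export
canonical_form <- function(set) {
  stopifnot(inherits(set, "pc_set"))
  k <- length(set$steps)
  best <- NULL
  for (i in seq_len(k)) {
    rot <- rotate_to_zero(set$steps, set$divisions, i)
    if (is.null(best) || lex_less(rot, best)) best <- rot
  }
  pc_set(best, set$divisions)
}

lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1L]] < 0L
}

#' Interval-class vector
#'
#' Counts every unordered pair of set members once at its interval class:
#' the circular distance `min(d, divisions - d)` between the two pitch
#' classes. For 12 divisions the classes are IC1..IC6. The vector is
#' invariant under transposition, and its entries sum to `choose(k, 2)`.
#'
#' @param set a `pc_set` with at least 2 elements.
#' @return integer vector of length `floor(divisions / 2)`, named `ic1`, ...
#' @examples
#' interval_vector(pc_set(c(0, 1, 4, 6, 9)))  # 1 1 3 2 2 1
#' @export
interval_vector <- function(set) {
  stopifnot(inherits(set, "pc_set"))
  k <- length(set$steps)
  if (k < 2L) abort("interval_vector needs at least 2 notes")
  n <- set$divisions
  m <- n %/% 2L
  d <- abs(rep(set$steps, times = k) - rep(set$steps, each = k))
  d <- pmin(d, n - d)
  counts <- tabulate(d[d > 0L], nbins = m) / 2L
  setNames(as.integer(counts), paste0("ic", seq_len(m)))
}

#' Evenness of a set
#'
#' How closely the set's step positions approach a perfectly even template
#' with the same cardinality: template positions are
#' `i * divisions / cardinality` for `i = 0..k-1`. Each rotation of the set
#' is re-anchored at 0 and differenced element-wise against the template;
#' `sd_deviation` is the minimum over rotations of the population standard
#' deviation of those differences (in step units). In fact the SD is the
#' same for every rotation — re-anchoring a rotation permutes the difference
#' vector and shifts it by a constant — so the minimum is a formality that
#' makes mode-invariance explicit. `evenness = -sd_deviation`, so larger
#' means more even; it is 0 exactly for perfectly even sets (possible only
#' when the cardinality divides the number of divisions).
#'
#' @param set a `pc_set` with at least 2 elements.
#' @return a list with `sd_deviation` and `evenness`.
#' @examples
#' evenness(pc_set(c(0, 2, 4, 6, 8, 10)))$sd_deviation  # 0: perfectly even
#' evenness(pc_set(c(0, 2, 4, 7, 9)))$evenness           # close to even
#' @export
evenness <- function(set) {
  stopifnot(inherits(set, "pc_set"))
  k <- length(set$steps)
  if (k < 2L) abort("evenness needs at least 2 notes")
  template <- (seq_len(k) - 1L) * set$divisions / k
  sds <- vapply(seq_len(k), function(i) {
    rot <- rotate_to_zero(set$steps, set$divisions, i)
    dif <- rot - template
    sqrt(mean((dif - mean(dif))^2))  # population SD
  }, numeric(1))
  sd_dev <- min(sds)
  list(sd_deviation = sd_dev, evenness = -sd_dev)
}

#' Enumerate all subsets of a given cardinality
#'
#' All `choose(divisions, cardinality)` pitch-class sets, in lexicographic
#' order. In standard tuning there are 792 five-note subsets.
#'
#' @param divisions steps per span.
#' @param cardinality number of notes per set.
#' @return a list of `pc_set` objects.
#' @export
enumerate_subsets <- function(divisions, cardinality) {
  divisions <- as.integer(divisions)
  if (cardinality < 1L || cardinality > divisions) {
    abort("`cardinality` must be in [1, divisions]")
  }
  combs <- combn(0:(divisions - 1L), cardinality)
  lapply(seq_len(ncol(combs)), function(j) pc_set(combs[, j], divisions))
}

#' Enumerate transpositional set classes
#'
#' Partitions the subsets of the given cardinality into classes under
#' cyclic transposition and returns one canonical representative per class,
#' with the class members attached. The 792 five-note subsets of standard
#' tuning collapse to 66 classes.
#'
#' @param divisions steps per span.
#' @param cardinality number of notes per set.
#' @return a list of `set_class` objects, each a list with `representative`
#'   (a `pc_set` in canonical form containing 0), `members` (list of all
#'   distinct transpositions), `cardinality`, and `set_id`
#'   (the representative's [set_string()]).
#' @export
enumerate_set_classes <- function(divisions, cardinality) {
  subsets <- enumerate_subsets(divisions, cardinality)
  keys <- vapply(subsets, function(s) set_string(canonical_form(s)),
                 character(1))
  split_idx <- split(seq_along(subsets), keys)
  # order classes by canonical representative, lexicographically
  reps <- lapply(names(split_idx), parse_set_string, divisions = divisions)
  ord <- order(vapply(reps, function(r)
    paste(sprintf("%03d", r$steps), collapse = ""), character(1)))
  lapply(ord, function(o) {
    structure(
      list(representative = reps[[o]],
           members = subsets[split_idx[[o]]],
           cardinality = as.integer(cardinality),
           set_id = names(split_idx)[o]),
      class = "set_class"
    )
  })
}

#' @export
print.set_class <- function(x, ...) {
  cat(sprintf("<set_class> %s (cardinality %d, %d transpositions)\n",
              x$set_id, x$cardinality, length(x$members)))
  invisible(x)
}

#' Geometric feature table for set classes
#'
#' One row per transpositional class: identifier, canonical representative,
#' cardinality, interval-class counts, and evenness. This is the predictor
#' table consumed by the regression analyses.
#'
#' @param divisions steps per span.
#' @param cardinality number of notes per set.
#' @return a data.frame with columns `set_id`, `representative`,
#'   `cardinality`, `ic1`..`ic<m>`, `sd_deviation`, `evenness`.
#' @export
set_class_table <- function(divisions = 12L, cardinality = 5L) {
  classes <- enumerate_set_classes(divisions, cardinality)
  m <- as.integer(divisions) %/% 2L
  rows <- lapply(classes, function(cl) {
    iv <- interval_vector(cl$representative)
    ev <- evenness(cl$representative)
    c(list(set_id = cl$set_id,
           representative = set_string(cl$representative),
           cardinality = cl$cardinality),
      as.list(iv),
      list(sd_deviation = ev$sd_deviation, evenness = ev$evenness))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Write a set-class feature table to CSV
#'
#' @param table output of [set_class_table()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_set_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
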