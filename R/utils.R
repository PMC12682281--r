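#' @importFrom stats rnorm runif sd var cor pt qt setNames aggregate
#' @importFrom utils write.csv read.csv head combn
NULL

.datatable.aware <- TRUE

abort <- function(msg, class = "scalegeom_error", ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Derive a stage-specific seed from a global seed
#'
#' One global seed fans out to per-stage seeds so that independent pipeline
#' stages do not share RNG streams. The derived seed is a deterministic hash
#' of the global seed and a stage label, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. `"stimuli"`, `"simulate"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
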