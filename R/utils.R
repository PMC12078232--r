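# Internal helpers: classed errors and deterministic seed substreams.

ctv_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "ctvrecur_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Derive a deterministic substream seed
#'
#' All randomness in a pipeline run descends from one master seed; each stage
#' (and each patient within the cohort generator) draws from its own labelled
#' substream so results are reproducible regardless of evaluation order.
#'
#' @param master integer master seed.
#' @param label character stream label (e.g. `"cohort"`).
#' @param counter optional non-negative integer (e.g. patient index).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(17, "cohort", 3)
substream_seed <- function(master, label, counter = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double-integer range
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% m
  s <- (abs(master) %% m)
  s <- (s * 48271) %% m
  s <- (s + h) %% m
  s <- (s * 69621 + (counter %% m)) %% m
  as.integer(s)
}

# round-capable running of an expression under a fixed RNG seed without
# disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
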