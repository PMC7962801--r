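# Internal helpers: deterministic seed streams and small validators.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All stochastic stages (design, trials, fixations, fields) draw from
#' distinct streams derived from one master seed, so that a stage can be
#' re-run in isolation and still reproduce its output.
#'
#' @param seed master integer seed.
#' @param stream character label of the stream ("design", "trials", ...).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed), length(stream) == 1)
  codes <- utf8ToInt(as.character(stream))
  h <- sum(as.numeric(codes) * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, stream),
# restoring the caller's RNG state afterwards.
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}

# scalar validators used across constructors
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  x
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a %s number", name,
                 if (strict) "positive" else "nonnegative"), call. = FALSE)
  }
  x
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
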