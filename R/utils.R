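# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a pipeline seed and a stream name
#'
#' Child streams (one per library) are derived by stable string hashing so
#' that adding or reordering libraries does not perturb the samples drawn
#' for the others. The hash is plain 31-polynomial over the UTF-8 code
#' points, reduced modulo a prime below 2^31, so the result is a valid R
#' integer seed on every platform.
#'
#' @param seed integer pipeline-level seed.
#' @param name character scalar naming the stream (e.g. a library name).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629 # prime < 2^31; all arithmetic stays < 2^53, exact in doubles
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m + h * 7919) %% m)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# canonical row order for position tables
order_positions <- function(df) {
  df[order(df$reference, df$strand, df$pos), , drop = FALSE]
}

stop_input <- function(...) stop(..., call. = FALSE)
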