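# internal helpers shared across the pipeline

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic RNG seed from a base seed and a label
#'
#' Mixes the base seed with arbitrary string/integer tokens so that
#' independent simulation streams (per strain, batch, plate, ...) are
#' reproducible and distinct, while staying below 2^31.
#'
#' @param seed integer base seed.
#' @param ... strings or integers identifying the stream.
#' @return a single integer usable with [set.seed()].
#' @keywords internal
derive_seed <- function(seed, ...) {
  tokens <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed) %% 2147483647
  for (tok in tokens) {
    for (b in utf8ToInt(tok)) {
      h <- (h * 31 + b) %% 2147483647
    }
  }
  as.integer(h)
}

# stop() with a consistent prefix so callers can grep error classes
abort_input <- function(...) stop(sprintf(...), call. = FALSE)

# checks that x is a single finite number
check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input("`%s` must be a single finite number", name)
  }
  invisible(x)
}
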