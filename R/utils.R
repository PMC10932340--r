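# Internal helpers: classed conditions, seed derivation, small validators.

stop_validation <- function(msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c("vfipred_validation_error", "vfipred_error", "error", "condition")
  ))
}

stop_data <- function(msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c("vfipred_data_error", "vfipred_error", "error", "condition")
  ))
}

#' Derive a reproducible child seed from a master seed and a tag
#'
#' All randomness in the package flows from a single master seed; each
#' stochastic stage (per-repeat shuffles, per-model fits, samplers) gets its
#' own deterministic child seed so stages can be re-run independently.
#'
#' @param seed integer master seed.
#' @param tag character label of the consuming stage.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(tag) == 1)
  h <- digest::digest2int(paste0(tag, ":", format(seed, scientific = FALSE)))
  # digest2int returns a signed 32-bit value; fold into non-negative range
  s <- (as.double(h) + 2^31) %% (2^31 - 1)
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)

# Deterministic RNG scope: evaluates expr with the given seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
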