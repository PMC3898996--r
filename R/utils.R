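#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the pipeline receives its own seed derived from a
#' single master seed, so that a whole run is reproducible from one integer
#' while stages remain independently re-runnable. The splitting rule is a
#' fixed affine hash of the master seed and the stage key:
#' `(seed * 2654435 + H(key)) mod (2^31 - 1)`, where `H(key)` is the weighted
#' sum of the key's character codes. All arithmetic stays below 2^53 so the
#' result is exact in double precision.
#'
#' @param seed integer master seed.
#' @param key character stage name (e.g. `"cohort"`, `"images"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "cohort")
#' child_seed(1, "images")
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- sum(utf8ToInt(key) * seq_len(nchar(key)))
  as.integer((abs(seed) * 2654435 + h) %% 2147483646 + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
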