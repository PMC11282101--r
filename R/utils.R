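#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so library code never clobbers the user's stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream index; keeps every
# random draw traceable to one logged integer while avoiding stream overlap.
child_seed <- function(seed, stream) {
  # double arithmetic: intermediate products overflow 32-bit integers
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12289) %%
               2147483587)
}

#' Round half away from zero
#'
#' `base::round()` rounds half to even; clinical tables conventionally round
#' half up (38/126 -> 30.2).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

fmt_pct <- function(num, denom, digits = 1) {
  if (denom == 0) return("NA")
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * num / denom, digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}
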