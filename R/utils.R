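# internal helpers shared across the pipeline

#' Round half away from zero
#'
#' Rounding used for all reported percentages and estimates. Base R's
#' `round()` rounds half to even (IEC 60559), which would print 78.55 as 78.5;
#' spontaneous-report tabulations conventionally round half up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(78.55, 1) # 78.6
#' round_half_up(0.125, 2) # 0.13
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a class so callers can distinguish configuration errors
config_error <- function(msg, field = NULL) {
  stop(structure(
    class = c("pvsignal_config_error", "error", "condition"),
    list(message = if (is.null(field)) msg else sprintf("%s (field: %s)", msg, field),
         call = sys.call(-1))
  ))
}

format_error <- function(msg) {
  stop(structure(
    class = c("pvsignal_format_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
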