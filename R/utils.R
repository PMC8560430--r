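#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (so 0.705 -> 0.71),
#' matching how lifetime tables are conventionally printed. Base R's
#' `round()` rounds half to even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a deterministic sub-stream seed
#'
#' Maps a top-level integer seed and a component label to a new seed, so
#' that each synthetic-data generator draws from its own reproducible
#' stream and adding a generator never perturbs the others.
#'
#' @param seed integer top-level seed.
#' @param label character scalar naming the component.
#' @return integer seed, strictly below 2^31.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(label))
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 100003
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2039 + h)
}

# internal: stop unless all values are finite and strictly positive
check_positive <- function(x, what) {
  if (!all(is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and strictly positive", what), call. = FALSE)
  }
  invisible(x)
}
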