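#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' One user-facing integer seed fans out to independent, named RNG streams
#' (meiosis, phenotype noise, read sampling, null simulation, ...) so a stage
#' can be regenerated without replaying the ones before it.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return an integer seed < 2^31, deterministic in (seed, stage).
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003L) * 1009L + h %% 1000003L)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (0.5 -> 1), the convention
#' used when reporting interval widths, rather than base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
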