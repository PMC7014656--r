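#' @importFrom rlang .data abort warn
#' @importFrom stats cor quantile rbeta rbinom runif sd var setNames aggregate
#' @importFrom utils head tail
NULL

#' Round half away from zero to a fixed number of decimals
#'
#' Presentation rounding for count ratios and percentages. Base [round()] uses
#' banker's rounding; published summary tables conventionally round 0.5 up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(1.465, 2.345), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic child seed from a top-level seed and a stage label.
# Keeps every stage's RNG stream independent while a single integer seed
# reproduces the full run. Result stays below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Sort order contract for sites: chromosome lexicographic (C locale), then
# position ascending. Used everywhere a total stable order is required.
site_order <- function(chrom, pos) {
  order(chrom, pos, method = "radix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
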