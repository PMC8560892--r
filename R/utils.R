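#' Round half away from zero
#'
#' Reported statistics follow the half-up rounding convention of the
#' clinical literature (2.745 prints as 2.75), not R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Percentage at one decimal, half-up, as a number (85.1 means 85.1%).
pct1 <- function(count, total) {
  if (total == 0) return(0)
  round_half_up(100 * count / total, 1)
}

# Quartiles by weighted-average linear interpolation between order
# statistics (quantile type 6), the convention of the mainstream clinical
# statistics packages whose tables these summaries mirror.
summary_quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 6, names = FALSE)
}

describe_continuous <- function(x) {
  q <- summary_quartiles(x)
  list(mean = mean(x), sd = stats::sd(x), median = q[2], p25 = q[1],
       p75 = q[3])
}
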