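#' Largest-remainder integer allocation
#'
#' Allocates `total` units across strata proportionally to `p`, rounding
#' fractional targets so the result sums exactly to `total`. Remainder ties
#' are broken by lexicographic stratum name, so the allocation is
#' deterministic and reproducible.
#'
#' @param p Named non-negative numeric vector of proportions (normalised
#'   internally).
#' @param total Integer total to distribute.
#' @return Named integer vector summing to `total`.
#' @export
#' @examples
#' largest_remainder(c(a = 1, b = 1, c = 1), 10)
largest_remainder <- function(p, total) {
  stopifnot(length(p) > 0, all(p >= 0), sum(p) > 0, total >= 0)
  if (is.null(names(p))) names(p) <- as.character(seq_along(p))
  p <- p / sum(p)
  target <- p * total
  base <- floor(target)
  rem <- target - base
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    ord <- order(-rem, names(p))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(p)
  out
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval on the percentage scale, truncated to
#' \[0, 100\].
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with numerator, denominator, proportion (percent),
#'   ci_low, ci_high and method columns.
#' @export
wald_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  p <- x / n
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(p * (1 - p) / n)
  data.frame(
    numerator = x, denominator = n,
    proportion = 100 * p,
    ci_low = 100 * max(0, p - z * se),
    ci_high = 100 * min(1, p + z * se),
    method = "wald",
    stringsAsFactors = FALSE
  )
}

# internal: stable normalisation key for scientific names
.squash <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
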