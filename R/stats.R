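#' Two-proportion Z-test (pooled)
#'
#' The classic two-tailed Z-test for equality of two proportions:
#' `z = (p1 - p2) / sqrt(p(1-p) (1/n1 + 1/n2))` with the pooled estimate
#' `p = (x1 + x2) / (n1 + n2)`; the p-value comes from the standard
#' normal. No continuity correction.
#'
#' @param x1,n1,x2,n2 Successes and trials of the two groups (`n1`,
#'   `n2` > 0).
#' @return List with `z`, `p_value`, the two proportions, and `degenerate`
#'   (`TRUE`, with `z = NA`, when the pooled proportion is 0 or 1 and the
#'   statistic is undefined).
#' @examples
#' z_test_two_proportions(50, 100, 30, 100)  # z ~ 2.857
#' @export
z_test_two_proportions <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    return(list(z = NA_real_, p_value = NA_real_, p1 = p1, p2 = p2,
                degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2,
       degenerate = FALSE)
}
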