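# Mendelian segregation testing for the binary branching contrast.

#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' Tests observed class counts against an expected segregation ratio
#' (default 3:1, dominant : recessive). Expected counts are kept unrounded
#' and no continuity correction is applied. The recessive-class proportion
#' is summarized with a Wilson score confidence interval.
#'
#' @param observed Integer vector of length 2: counts of the dominant and
#'   recessive class.
#' @param ratio Expected ratio, same length and order as `observed`.
#' @param conf_level Confidence level for the recessive-proportion interval.
#' @return An object of class `segregation_result`: observed and expected
#'   counts, `chi_square`, `df`, `p_value`, and the recessive `proportion`
#'   with `conf_int`.
#' @export
#' @examples
#' chisq_goodness_of_fit(c(451, 175))
chisq_goodness_of_fit <- function(observed, ratio = c(3, 1),
                                  conf_level = 0.95) {
  stopifnot(length(observed) == 2, length(ratio) == 2,
            all(observed >= 0), all(ratio > 0))
  total <- sum(observed)
  if (total == 0) stop("total count is zero", call. = FALSE)
  ct <- stats::chisq.test(observed, p = ratio / sum(ratio))
  prop <- proportion_with_ci(observed[2], total, conf_level)
  structure(
    list(observed = observed,
         expected = unname(ct$expected),
         ratio = ratio,
         chi_square = unname(ct$statistic),
         df = as.integer(ct$parameter),
         p_value = unname(ct$p.value),
         proportion = prop$estimate,
         conf_int = prop$conf_int,
         conf_level = conf_level),
    class = "segregation_result")
}

#' Binomial proportion with a Wilson score interval
#'
#' Point estimate `successes / total` with the Wilson score interval
#' (the score-test inversion, without continuity correction), which keeps
#' sensible coverage at moderate sample sizes and near the boundaries.
#'
#' @param successes,total Counts with `0 <= successes <= total`, `total > 0`.
#' @param conf_level Confidence level.
#' @return A list with `estimate` and `conf_int` (length-2 vector).
#' @export
proportion_with_ci <- function(successes, total, conf_level = 0.95) {
  stopifnot(total > 0, successes >= 0, successes <= total)
  ci <- stats::prop.test(successes, total, conf.level = conf_level,
                         correct = FALSE)$conf.int
  list(estimate = successes / total, conf_int = as.numeric(ci))
}

#' @method print segregation_result
#' @export
print.segregation_result <- function(x, ...) {
  cat("Segregation test against", paste(x$ratio, collapse = ":"), "ratio\n")
  cat(sprintf("  observed: %d / %d   expected: %.1f / %.1f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.4f\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("  recessive proportion = %.2f%% (%d%% CI %.1f%%-%.1f%%)\n",
              100 * x$proportion, round(100 * x$conf_level),
              100 * x$conf_int[1], 100 * x$conf_int[2]))
  invisible(x)
}
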