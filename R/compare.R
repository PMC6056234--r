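#' Two-group comparison of motility statistics
#'
#' Thin dispatch to the standard two-sample procedures used for motility
#' data: Student's t (equal variances), Welch's t, or the Mann-Whitney
#' (Wilcoxon rank-sum) test. Comparisons of run lengths should be run on the
#' raw values, never on fitted decay scales.
#'
#' @param groupA,groupB Numeric vectors (>= 2 values each).
#' @param test `"welch"` (default), `"student"` or `"mann_whitney"`.
#' @return A list with `test`, `statistic`, `p_value`, `estimate` (difference
#'   in means, or location shift for Mann-Whitney), and the group sizes.
#' @examples
#' compare_conditions(rnorm(10), rnorm(10) + 1)
#' @export
compare_conditions <- function(groupA, groupB,
                               test = c("welch", "student", "mann_whitney")) {
  test <- match.arg(test)
  a <- as.numeric(groupA); b <- as.numeric(groupB)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("insufficient data: each group needs at least 2 finite values",
         call. = FALSE)
  res <- switch(test,
    welch = stats::t.test(a, b, var.equal = FALSE),
    student = stats::t.test(a, b, var.equal = TRUE),
    mann_whitney = stats::wilcox.test(a, b, exact = FALSE))
  est <- if (test == "mann_whitney") stats::median(a) - stats::median(b)
         else unname(res$estimate[1] - res$estimate[2])
  list(test = test, statistic = unname(res$statistic),
       p_value = res$p.value, estimate = est,
       n_A = length(a), n_B = length(b))
}
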