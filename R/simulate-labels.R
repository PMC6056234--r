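#' Dual-colour detection counts
#'
#' Tallies of motile complexes by detected dye content: both colours, colour A
#' only, colour B only, or neither (undetected complexes exist but are
#' invisible in the assay; the count is retained for simulations where it is
#' known). Observed fractions are always computed conditional on detection.
#'
#' @param n_dual,n_A_only,n_B_only,n_undetected Nonnegative counts.
#' @param condition Optional condition label.
#' @return An object of class `dual_colour_counts`.
#' @export
dual_colour_counts <- function(n_dual, n_A_only, n_B_only,
                               n_undetected = NA_integer_,
                               condition = NA_character_) {
  for (f in c("n_dual", "n_A_only", "n_B_only")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      stop_config(f, "must be a single nonnegative count")
  }
  if (!is.na(n_undetected) && (n_undetected < 0 ||
                               n_undetected != round(n_undetected)))
    stop_config("n_undetected", "must be a nonnegative count or NA")
  x <- list(n_dual = as.integer(n_dual), n_A_only = as.integer(n_A_only),
            n_B_only = as.integer(n_B_only),
            n_undetected = as.integer(n_undetected),
            condition = condition)
  class(x) <- "dual_colour_counts"
  x
}

#' @export
print.dual_colour_counts <- function(x, ...) {
  n_obs <- x$n_dual + x$n_A_only + x$n_B_only
  cat(sprintf("<dual_colour_counts>%s dual %d / A-only %d / B-only %d",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$n_dual, x$n_A_only, x$n_B_only))
  if (!is.na(x$n_undetected)) cat(sprintf(" / undetected %d", x$n_undetected))
  if (n_obs > 0)
    cat(sprintf("  (dual fraction among detected: %.3f)", x$n_dual / n_obs))
  cat("\n")
  invisible(x)
}

#' Observed category fractions conditional on detection
#'
#' @param x A `dual_colour_counts` object.
#' @return Named numeric vector `(dual, A_only, B_only)` summing to 1, or
#'   all-`NA` if nothing was detected.
#' @export
detected_fractions <- function(x) {
  stopifnot(inherits(x, "dual_colour_counts"))
  n <- x$n_dual + x$n_A_only + x$n_B_only
  if (n == 0) return(c(dual = NA_real_, A_only = NA_real_, B_only = NA_real_))
  c(dual = x$n_dual, A_only = x$n_A_only, B_only = x$n_B_only) / n
}

#' Simulate dual-dye SNAP labelling of 1- or 2-copy protein complexes
#'
#' Each complex contains two polypeptides with probability `two_copy_fraction`
#' and one otherwise. Every polypeptide independently carries a dye with
#' probability `model$p_label`; a labelled polypeptide carries dye A with
#' probability `model$q_dyeA`, otherwise dye B. A complex is scored "dual" if
#' it carries at least one dye of each colour.
#'
#' @param n_complexes Number of complexes to simulate.
#' @param two_copy_fraction Probability that a complex holds two polypeptides.
#' @param model A [labeling_model()] with `mode = "binomial_snap"`.
#' @param seed Integer seed.
#' @return A [dual_colour_counts()] object; the four counts always sum to
#'   `n_complexes`.
#' @examples
#' m <- labeling_model("binomial_snap", p_label = 0.9, q_dyeA = 0.5)
#' simulate_dual_labels(10000, two_copy_fraction = 1, model = m, seed = 1)
#' @export
simulate_dual_labels <- function(n_complexes, two_copy_fraction, model,
                                 seed = 1L) {
  n_complexes <- check_count(n_complexes, "n_complexes", min = 1L)
  check_probability(two_copy_fraction, "two_copy_fraction")
  stopifnot(inherits(model, "labeling_model"))
  if (model$mode != "binomial_snap")
    stop("model mode mismatch: simulate_dual_labels requires a 'binomial_snap' model",
         call. = FALSE)
  set.seed(check_count(seed, "seed"))
  k <- 1L + stats::rbinom(n_complexes, 1L, two_copy_fraction)
  n_lab <- stats::rbinom(n_complexes, k, model$p_label)
  n_A <- stats::rbinom(n_complexes, n_lab, model$q_dyeA)
  n_B <- n_lab - n_A
  tally_dual(n_A, n_B, n_complexes)
}

#' Simulate dual-colour body-labelled RNA in 1- or 2-RNA RNPs
#'
#' Each RNP holds two RNA molecules with probability `two_rna_fraction` and
#' one otherwise. Each RNA comes from the colour-A preparation with
#' probability `model$colourA_fraction` (else colour B) and carries a
#' Poisson(`model$poisson_mean`) number of dyes of its preparation's colour;
#' an RNA is detected iff it carries at least one dye.
#'
#' @param n_rnps Number of RNPs to simulate.
#' @param two_rna_fraction Probability that an RNP holds two RNA molecules.
#' @param model A [labeling_model()] with `mode = "poisson_body"`.
#' @param seed Integer seed.
#' @return A [dual_colour_counts()] object; counts sum to `n_rnps`.
#' @examples
#' m <- labeling_model("poisson_body", poisson_mean = 3)
#' simulate_rna_labels(10000, two_rna_fraction = 0.3, model = m, seed = 1)
#' @export
simulate_rna_labels <- function(n_rnps, two_rna_fraction, model, seed = 1L) {
  n_rnps <- check_count(n_rnps, "n_rnps", min = 1L)
  check_probability(two_rna_fraction, "two_rna_fraction")
  stopifnot(inherits(model, "labeling_model"))
  if (model$mode != "poisson_body")
    stop("model mode mismatch: simulate_rna_labels requires a 'poisson_body' model",
         call. = FALSE)
  set.seed(check_count(seed, "seed"))
  k <- 1L + stats::rbinom(n_rnps, 1L, two_rna_fraction)
  # first RNA of every RNP, second only where k == 2
  det1 <- stats::rpois(n_rnps, model$poisson_mean) > 0
  colA1 <- stats::runif(n_rnps) < model$colourA_fraction
  det2 <- stats::rpois(n_rnps, model$poisson_mean) > 0 & k == 2L
  colA2 <- stats::runif(n_rnps) < model$colourA_fraction
  n_A <- (det1 & colA1) + (det2 & colA2)
  n_B <- (det1 & !colA1) + (det2 & !colA2)
  tally_dual(n_A, n_B, n_rnps)
}

tally_dual <- function(n_A, n_B, n) {
  dual <- n_A > 0 & n_B > 0
  a_only <- n_A > 0 & n_B == 0
  b_only <- n_B > 0 & n_A == 0
  dual_colour_counts(sum(dual), sum(a_only), sum(b_only),
                     n_undetected = n - sum(dual) - sum(a_only) - sum(b_only))
}
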