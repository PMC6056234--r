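#' Dual-dye outcome distribution for a k-copy complex under binomial labelling
#'
#' A complex contains `k` identical polypeptides. Each polypeptide
#' independently carries a dye with probability `p_label`; a dye is species A
#' with probability `q_dyeA`, else species B. The per-polypeptide outcome
#' probabilities are therefore `p_label * q_dyeA` (dye A),
#' `p_label * (1 - q_dyeA)` (dye B) and `1 - p_label` (no dye), and the
#' complex-level category probabilities follow by independence:
#' \deqn{P(\mathrm{dual}) = 1 - (1 - p q)^k - (1 - p(1-q))^k + (1 - p)^k}
#' with the single-colour and undetected categories given by the
#' corresponding inclusion–exclusion terms. For an obligate dimer (`k = 2`)
#' with full labelling and an equal dye split this yields the familiar
#' 50/25/25 split; at 90% labelling the dual category drops to 0.405.
#'
#' @param k Number of polypeptide copies per complex (integer >= 1).
#' @param p_label Per-polypeptide labelling probability.
#' @param q_dyeA Probability that a dye is species A.
#' @return Named numeric vector `(dual, A_only, B_only, undetected)`,
#'   summing to 1.
#' @examples
#' dual_label_distribution(2, 1, 0.5)    # 0.50 / 0.25 / 0.25 / 0
#' dual_label_distribution(2, 0.9, 0.5)  # 0.405 / 0.2925 / 0.2925 / 0.01
#' @export
dual_label_distribution <- function(k, p_label, q_dyeA) {
  k <- check_count(k, "k")
  if (k < 1L) stop("k must be >= 1: a complex has at least one copy",
                   call. = FALSE)
  check_probability(p_label, "p_label")
  check_probability(q_dyeA, "q_dyeA")
  pA <- p_label * q_dyeA
  pB <- p_label * (1 - q_dyeA)
  no_A <- (1 - pA)^k       # no A dye on any copy
  no_B <- (1 - pB)^k
  none <- (1 - p_label)^k  # no dye at all
  c(dual = 1 - no_A - no_B + none,
    A_only = no_B - none,
    B_only = no_A - none,
    undetected = none)
}

#' Expected dual-colour fraction of a k-copy complex
#'
#' Convenience wrapper around [dual_label_distribution()]. The unconditional
#' value is the probability that a complex carries both dye species; the
#' conditional value divides by the detection probability (at least one dye),
#' which is what a fluorescence assay can observe.
#'
#' @inheritParams dual_label_distribution
#' @param conditional_on_detection If `TRUE`, return
#'   `dual / (1 - undetected)`.
#' @return A probability, or `NA` (with a warning) when conditioning on
#'   detection is undefined because nothing can be detected.
#' @examples
#' expected_dual_fraction(2, 0.9, 0.5)        # 0.405, i.e. 40%
#' expected_dual_fraction(2, 0.9, 0.5, TRUE)  # 0.409
#' @export
expected_dual_fraction <- function(k, p_label, q_dyeA,
                                   conditional_on_detection = FALSE) {
  d <- dual_label_distribution(k, p_label, q_dyeA)
  if (!conditional_on_detection) return(unname(d["dual"]))
  det <- 1 - d[["undetected"]]
  if (det <= 0) {
    warning("detection probability is zero; conditional dual fraction undefined")
    return(NA_real_)
  }
  unname(d["dual"] / det)
}

#' Probability that every copy of a k-copy complex carries a dye
#'
#' @inheritParams dual_label_distribution
#' @return `p_label^k`. For a dimer at 90% labelling efficiency this is 81%.
#' @examples
#' both_labeled_fraction(2, 0.9)  # 0.81
#' @export
both_labeled_fraction <- function(k, p_label) {
  k <- check_count(k, "k")
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  check_probability(p_label, "p_label")
  p_label^k
}

#' Copy-number mixture estimate
#'
#' @param two_copy_fraction Estimated fraction of 2-copy complexes.
#' @param ci Length-2 numeric confidence interval on that fraction.
#' @param out_of_model Flag: the observed dual fraction exceeded the
#'   theoretical maximum of the model and was clipped.
#' @param model Description of the labelling model used.
#' @param n_obs Number of detected complexes behind the estimate.
#' @param ci_method Label of the interval method.
#' @return An object of class `copy_number_estimate`.
#' @keywords internal
copy_number_estimate <- function(two_copy_fraction, ci, out_of_model,
                                 model, n_obs, ci_method) {
  x <- list(two_copy_fraction = two_copy_fraction,
            one_copy_fraction = 1 - two_copy_fraction,
            ci_low = ci[1], ci_high = ci[2],
            out_of_model = out_of_model, model = model,
            n_obs = n_obs, ci_method = ci_method)
  class(x) <- "copy_number_estimate"
  x
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("<copy_number_estimate> two-copy %.1f%% / one-copy %.1f%%  (95%% CI %.1f-%.1f%%, %s, n = %d)\n",
              100 * x$two_copy_fraction, 100 * x$one_copy_fraction,
              100 * x$ci_low, 100 * x$ci_high, x$ci_method, x$n_obs))
  if (isTRUE(x$out_of_model))
    cat("  warning: observed dual fraction exceeds the model maximum; estimate clipped\n")
  invisible(x)
}

#' Infer the two-copy fraction of protein complexes from dual-colour counts
#'
#' Inverts the binomial labelling model: a mixture with weight `phi` of
#' two-copy complexes (and `1 - phi` one-copy) yields an observed
#' detected-conditional dual fraction
#' \deqn{d = \phi \, \mathrm{dual}_2 / (\phi \, \mathrm{det}_2 +
#'   (1-\phi)\, \mathrm{det}_1)}
#' where `dual_2` and `det_k` come from [dual_label_distribution()] (a
#' one-copy complex can never be dual). Solving for `phi` is linear; the
#' estimate is clipped to \[0, 1\] and the confidence interval on the raw
#' dual fraction is propagated through the (monotone) inversion.
#'
#' @param counts A [dual_colour_counts()] object (detected categories used).
#' @param p_label,q_dyeA Labelling-model parameters, see
#'   [dual_label_distribution()].
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param ci_method `"bootstrap"` (nonparametric, over detected complexes) or
#'   `"wilson"` (Wilson score interval on the dual fraction).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A `copy_number_estimate`.
#' @examples
#' # 39% of detected motile complexes dual-labelled, 90% labelling, even split
#' cts <- dual_colour_counts(390, 305, 305)
#' infer_two_copy_fraction(cts, p_label = 0.9, q_dyeA = 0.5)
#' @export
infer_two_copy_fraction <- function(counts, p_label, q_dyeA = 0.5,
                                    conf_level = 0.95,
                                    ci_method = c("bootstrap", "wilson"),
                                    n_boot = 1000, seed = 1L) {
  stopifnot(inherits(counts, "dual_colour_counts"))
  ci_method <- match.arg(ci_method)
  dist2 <- dual_label_distribution(2L, p_label, q_dyeA)
  det1 <- p_label                       # 1 - (1 - p)
  det2 <- 1 - dist2[["undetected"]]
  dual2 <- dist2[["dual"]]
  invert <- function(d) {
    denom <- dual2 - d * (det2 - det1)
    if (denom <= 0) return(1)
    min(max(d * det1 / denom, 0), 1)
  }
  d_max <- dual2 / det2                 # dual fraction at phi = 1
  estimate_mixture(counts, invert, d_max, conf_level, ci_method, n_boot, seed,
                   model = sprintf("binomial_snap(p = %.3g, q = %.3g)",
                                   p_label, q_dyeA))
}

#' Detection probability of a Poisson body-labelled RNA molecule
#'
#' An RNA carrying a Poisson-distributed number of dyes (mean `poisson_mean`)
#' is detectable iff it carries at least one, so the detection probability is
#' `1 - exp(-poisson_mean)`; about 0.95 at the typical ~3 dyes per molecule.
#'
#' @param poisson_mean Mean number of dyes per RNA molecule (>= 0).
#' @return A probability.
#' @examples
#' poisson_detection_probability(3)  # 0.9502
#' @export
poisson_detection_probability <- function(poisson_mean) {
  check_number(poisson_mean, "poisson_mean", lower = 0)
  -expm1(-poisson_mean)
}

#' Forward model: dual-colour fraction of detected RNPs
#'
#' For RNPs holding one or two body-labelled RNA molecules, with each RNA
#' drawn from the colour-A preparation with probability `colourA_fraction`
#' and detected with probability `L = 1 - exp(-poisson_mean)`, the expected
#' fraction of *detected* RNPs showing both colours is
#' \deqn{d = \frac{f_2 \cdot 2a(1-a)L^2}{(1-f_2)L + f_2(1-(1-L)^2)}}
#' where `f_2` is the two-RNA fraction and `a` the colour-A fraction. Only
#' two-RNA RNPs with differently coloured, doubly detected RNAs appear dual;
#' two same-colour RNAs are scored single-colour.
#'
#' @param two_rna_fraction Fraction of RNPs holding two RNA molecules.
#' @param poisson_mean Mean dyes per RNA molecule.
#' @param colourA_fraction Fraction of RNA molecules from the colour-A
#'   preparation (default 0.5, equimolar).
#' @return Expected dual fraction among detected RNPs; `NA` with a warning if
#'   `poisson_mean` is 0 (nothing detected).
#' @examples
#' rna_dual_fraction(0.3, 3)  # 0.1404, i.e. 14%
#' @export
rna_dual_fraction <- function(two_rna_fraction, poisson_mean,
                              colourA_fraction = 0.5) {
  check_probability(two_rna_fraction, "two_rna_fraction")
  check_number(poisson_mean, "poisson_mean", lower = 0)
  check_probability(colourA_fraction, "colourA_fraction")
  L <- poisson_detection_probability(poisson_mean)
  if (L <= 0) {
    warning("poisson_mean = 0: no RNA is detectable; dual fraction undefined")
    return(NA_real_)
  }
  f2 <- two_rna_fraction
  a <- colourA_fraction
  num <- f2 * 2 * a * (1 - a) * L^2
  den <- (1 - f2) * L + f2 * (1 - (1 - L)^2)
  num / den
}

#' Infer the two-RNA fraction of RNPs from dual-colour counts
#'
#' Closed-form inversion of [rna_dual_fraction()]: with
#' `A = 2a(1-a)L^2`, `B = L` and `C = 1 - (1-L)^2`,
#' \deqn{f_2 = \frac{dB}{A - d(C - B)}}
#' for an observed detected-conditional dual fraction `d`. The estimate is
#' clipped to \[0, 1\]; a dual fraction above the `f2 = 1` maximum `A / C`
#' sets the out-of-model flag. Confidence intervals on `d` are propagated
#' through the inversion as in [infer_two_copy_fraction()].
#'
#' @param counts A [dual_colour_counts()] object.
#' @param poisson_mean,colourA_fraction See [rna_dual_fraction()].
#' @inheritParams infer_two_copy_fraction
#' @return A `copy_number_estimate` (two-RNA vs one-RNA fractions).
#' @examples
#' # 14% of detected motile RNPs dual-coloured at ~3 dyes per RNA
#' cts <- dual_colour_counts(140, 430, 430)
#' infer_rna_mixture(cts, poisson_mean = 3)
#' @export
infer_rna_mixture <- function(counts, poisson_mean, colourA_fraction = 0.5,
                              conf_level = 0.95,
                              ci_method = c("bootstrap", "wilson"),
                              n_boot = 1000, seed = 1L) {
  stopifnot(inherits(counts, "dual_colour_counts"))
  ci_method <- match.arg(ci_method)
  check_number(poisson_mean, "poisson_mean", lower = 0,
               allow_zero_lower = FALSE)
  L <- poisson_detection_probability(poisson_mean)
  a <- colourA_fraction
  A <- 2 * a * (1 - a) * L^2
  B <- L
  C <- 1 - (1 - L)^2
  invert <- function(d) {
    denom <- A - d * (C - B)
    if (denom <= 0) return(1)
    min(max(d * B / denom, 0), 1)
  }
  estimate_mixture(counts, invert, d_max = A / C, conf_level, ci_method,
                   n_boot, seed,
                   model = sprintf("poisson_body(mean = %.3g, a = %.3g)",
                                   poisson_mean, a))
}

# shared inversion/CI machinery for both copy-number estimators
estimate_mixture <- function(counts, invert, d_max, conf_level, ci_method,
                             n_boot, seed, model) {
  n_obs <- counts$n_dual + counts$n_A_only + counts$n_B_only
  if (n_obs < 1L)
    stop("no detected complexes in `counts`", call. = FALSE)
  d <- counts$n_dual / n_obs
  out_of_model <- d > d_max + 1e-12
  if (out_of_model)
    warning(sprintf("observed dual fraction %.3f exceeds model maximum %.3f; estimate clipped to 1",
                    d, d_max))
  est <- invert(d)
  ci_d <- if (ci_method == "wilson") {
    wilson_interval(counts$n_dual, n_obs, conf_level)
  } else {
    set.seed(seed)
    db <- stats::rbinom(n_boot, n_obs, d) / n_obs
    stats::quantile(db, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                    names = FALSE)
  }
  ci <- sort(vapply(ci_d, invert, numeric(1)))
  ci <- c(min(ci[1], est), max(ci[2], est))
  copy_number_estimate(est, ci, out_of_model, model, n_obs, ci_method)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level.
#' @return Length-2 numeric vector (lower, upper).
#' @export
wilson_interval <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}
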