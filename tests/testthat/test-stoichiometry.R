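test_that("dual-label distribution matches exhaustive enumeration and known splits", {
  # closed form vs brute-force enumeration over per-polypeptide outcomes
  for (k in 1:3) {
    for (p in c(0.3, 0.9, 1)) {
      for (q in c(0.2, 0.5)) {
        expect_equal(dual_label_distribution(k, p, q),
                     enumerate_dual_distribution(k, p, q),
                     tolerance = 1e-12)
      }
    }
  }
  # idealised obligate dimer, full labelling, even split: 50/25/25
  expect_equal(unname(dual_label_distribution(2, 1, 0.5)),
               c(0.50, 0.25, 0.25, 0), tolerance = 1e-12)
  # dimer at 90% labelling: 0.405 / 0.2925 / 0.2925 / 0.01
  expect_equal(unname(dual_label_distribution(2, 0.9, 0.5)),
               c(0.405, 0.2925, 0.2925, 0.01), tolerance = 1e-12)
  # a single copy can never carry both dyes
  expect_equal(dual_label_distribution(1, 0.7, 0.3)[["dual"]], 0)
  expect_error(dual_label_distribution(0, 0.9, 0.5), "k")
})

test_that("dual-label distribution: conservation, A/B symmetry, monotonicity", {
  grid <- expand.grid(k = 1:4, p = seq(0, 1, by = 0.25),
                      q = seq(0, 1, by = 0.25))
  for (r in seq_len(nrow(grid))) {
    d <- dual_label_distribution(grid$k[r], grid$p[r], grid$q[r])
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= -1e-15))
    dm <- dual_label_distribution(grid$k[r], grid$p[r], 1 - grid$q[r])
    expect_equal(d[["dual"]], dm[["dual"]], tolerance = 1e-12)
    expect_equal(d[["A_only"]], dm[["B_only"]], tolerance = 1e-12)
  }
  # dual fraction increases with labelling efficiency, peaks at even split
  p_grid <- seq(0.05, 1, by = 0.05)
  duals <- vapply(p_grid, function(p)
    dual_label_distribution(2, p, 0.5)[["dual"]], numeric(1))
  expect_true(all(diff(duals) > 0))
  q_grid <- seq(0.05, 0.95, by = 0.05)
  dq <- vapply(q_grid, function(q)
    dual_label_distribution(2, 0.9, q)[["dual"]], numeric(1))
  expect_equal(q_grid[which.max(dq)], 0.5)
})

test_that("expected dual and both-labelled fractions reproduce the calibration numbers", {
  expect_equal(expected_dual_fraction(2, 0.9, 0.5), 0.405, tolerance = 1e-12)
  expect_equal(round(100 * expected_dual_fraction(2, 0.9, 0.5)), 40)
  expect_equal(expected_dual_fraction(2, 0.9, 0.5, TRUE), 0.405 / 0.99,
               tolerance = 1e-12)
  expect_equal(expected_dual_fraction(2, 1, 1), 0)
  expect_warning(out <- expected_dual_fraction(2, 0, 0.5, TRUE), "undefined")
  expect_true(is.na(out))
  expect_equal(both_labeled_fraction(2, 0.9), 0.81, tolerance = 1e-12)
  expect_equal(both_labeled_fraction(2, 1), 1)
  expect_equal(both_labeled_fraction(3, 0.5), 0.125, tolerance = 1e-12)
})

test_that("two-copy mixture inversion solves the forward model", {
  # forward model for a phi-mixture of 1- and 2-copy complexes
  forward <- function(phi, p, q) {
    d2 <- dual_label_distribution(2, p, q)
    det1 <- p; det2 <- 1 - d2[["undetected"]]
    phi * d2[["dual"]] / (phi * det2 + (1 - phi) * det1)
  }
  # observed dual fractions from the dual-labelled motility experiments
  cts <- dual_colour_counts(3900, 3050, 3050)   # d = 0.39
  est <- infer_two_copy_fraction(cts, 0.9, 0.5)
  expect_equal(est$two_copy_fraction, 0.949, tolerance = 1e-3)
  cts2 <- dual_colour_counts(3700, 3150, 3150)  # d = 0.37
  est2 <- infer_two_copy_fraction(cts2, 0.9, 0.5)
  expect_equal(est2$two_copy_fraction, 0.896, tolerance = 1e-3)
  expect_true(est$ci_low <= est$two_copy_fraction &&
                est$two_copy_fraction <= est$ci_high)
  # zero dual -> no two-copy complexes
  est0 <- infer_two_copy_fraction(dual_colour_counts(0, 50, 50), 0.9, 0.5)
  expect_equal(est0$two_copy_fraction, 0)
  # forward(inverse) identity across the admissible range
  for (p in c(0.5, 0.9)) {
    d_max <- forward(1, p, 0.5)
    for (d in seq(0.01, d_max - 0.01, length.out = 8)) {
      n <- 1e6
      cts <- dual_colour_counts(round(d * n), round((n - round(d * n)) / 2),
                                n - round(d * n) - round((n - round(d * n)) / 2))
      phi <- infer_two_copy_fraction(cts, p, 0.5, ci_method = "wilson")$two_copy_fraction
      expect_equal(forward(phi, p, 0.5), cts$n_dual / n, tolerance = 1e-9)
    }
  }
  # dual fraction above the dimer maximum: clipped with a warning
  expect_warning(
    est1 <- infer_two_copy_fraction(dual_colour_counts(90, 5, 5), 0.9, 0.5),
    "exceeds")
  expect_equal(est1$two_copy_fraction, 1)
  expect_true(est1$out_of_model)
})

test_that("RNA forward model and inversion reproduce the 14% <-> 30% correspondence", {
  expect_equal(rna_dual_fraction(0.3, 3), 0.1404, tolerance = 1e-3)
  expect_equal(round(100 * rna_dual_fraction(0.3, 3)), 14)
  expect_equal(rna_dual_fraction(0, 3), 0)
  # saturating labelling, all two-RNA: colours independent -> 1/2
  expect_equal(rna_dual_fraction(1, 50), 0.5, tolerance = 1e-12)
  expect_warning(out <- rna_dual_fraction(0.3, 0), "undefined")
  expect_true(is.na(out))

  est <- infer_rna_mixture(dual_colour_counts(1400, 4300, 4300), 3)
  expect_equal(est$two_copy_fraction, 0.299, tolerance = 1e-3)
  expect_equal(round(100 * est$two_copy_fraction), 30)
  expect_equal(round(100 * est$one_copy_fraction), 70)
  est0 <- infer_rna_mixture(dual_colour_counts(0, 100, 100), 3)
  expect_equal(est0$two_copy_fraction, 0)

  # round trip on a grid of admissible dual fractions
  L <- poisson_detection_probability(3)
  d_max <- 2 * 0.25 * L^2 / (1 - (1 - L)^2)
  for (d in seq(0.005, d_max - 0.005, length.out = 10)) {
    n <- 1e6; nd <- round(d * n)
    cts <- dual_colour_counts(nd, floor((n - nd) / 2),
                              n - nd - floor((n - nd) / 2))
    f2 <- infer_rna_mixture(cts, 3, ci_method = "wilson")$two_copy_fraction
    expect_equal(rna_dual_fraction(f2, 3), nd / n, tolerance = 1e-12)
  }
})

test_that("Poisson detection probability is 1 - exp(-mean)", {
  expect_equal(poisson_detection_probability(3), 1 - exp(-3),
               tolerance = 1e-15)
  expect_equal(round(poisson_detection_probability(3), 4), 0.9502)
  expect_equal(poisson_detection_probability(0), 0)
  expect_equal(poisson_detection_probability(1e6), 1)
})

test_that("copy-number estimator recovers a known mixture with calibrated intervals", {
  phi_true <- 0.9
  model <- labeling_model("binomial_snap", p_label = 0.9, q_dyeA = 0.5)
  est <- covered <- numeric(50)
  for (s in 1:50) {
    cts <- simulate_dual_labels(300, phi_true, model, seed = 1000 + s)
    # small samples can exceed the phi = 1 ceiling; the clip is expected
    e <- suppressWarnings(infer_two_copy_fraction(cts, 0.9, 0.5, seed = s))
    est[s] <- e$two_copy_fraction
    covered[s] <- (e$ci_low <= phi_true) && (phi_true <= e$ci_high)
  }
  expect_lt(abs(mean(est) - phi_true), 0.03)
  expect_gte(mean(covered), 0.90)
})
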