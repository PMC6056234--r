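test_that("configuration validation names the offending field", {
  expect_error(sim_config(class_probs = c(0.5, 0.5, 0.5)), "class_probs")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(run_length_mean = -1), "run_length_mean")
  expect_error(sim_config(pixel_size = -0.1), "pixel_size")
  expect_error(sim_config(diffusion_coeff = NaN), "diffusion_coeff")
})

test_that("track simulation is deterministic and respects geometry", {
  cfg <- sim_config(n_microtubules = 4, seed = 11)
  ts1 <- simulate_trackset(cfg)
  ts2 <- simulate_trackset(cfg)
  expect_identical(ts1$tracks, ts2$tracks)
  expect_identical(ts1$ground_truth, ts2$ground_truth)
  # every track references an existing microtubule, positions on the lattice
  expect_true(all(ts1$tracks$mt_id %in% ts1$microtubules$mt_id))
  lens <- ts1$microtubules$length_um[
    match(ts1$tracks$mt_id, ts1$microtubules$mt_id)]
  expect_true(all(ts1$tracks$position_um >= 0 &
                    ts1$tracks$position_um <= lens))
  # times strictly increasing within every track
  ok <- vapply(split(ts1$tracks$time_s, ts1$tracks$track_id),
               function(t) !is.unsorted(t, strictly = TRUE), logical(1))
  expect_true(all(ok))
})

test_that("degenerate static-only configuration yields zero displacement", {
  cfg <- sim_config(n_microtubules = 3, class_probs = c(1, 0, 0),
                    localisation_sd = 0, seed = 2)
  ts <- simulate_trackset(cfg)
  rng <- vapply(split(ts$tracks$position_um, ts$tracks$track_id),
                function(x) diff(range(x)), numeric(1))
  expect_true(all(rng == 0))
  expect_true(all(ts$ground_truth$class == "static"))
})

test_that("ground-truth run lengths are exponential with the configured mean", {
  cfg <- sim_config(n_microtubules = 25, tracks_per_mt_mean = 20,
                    class_probs = c(0, 0, 1), run_length_mean = 5, seed = 3)
  ts <- simulate_trackset(cfg)
  r <- ts$ground_truth$run_length_true_um
  expect_gte(length(r), 400)
  se <- 5 / sqrt(length(r))
  expect_lt(abs(mean(r) - 5), 3 * se)
})

test_that("labelling simulators conserve counts and match the closed forms", {
  model <- labeling_model("binomial_snap", p_label = 0.9, q_dyeA = 0.5)
  # full labelling of pure dimers: the idealised 50/25/25 outcome
  ideal <- simulate_dual_labels(
    50000, 1, labeling_model("binomial_snap", 1, 0.5), seed = 4)
  fr <- detected_fractions(ideal)
  expect_equal(unname(fr), c(0.5, 0.25, 0.25), tolerance = 0.02)
  expect_identical(ideal$n_undetected, 0L)
  # a single polypeptide can never carry both dyes
  mono <- simulate_dual_labels(2000, 0, model, seed = 5)
  expect_identical(mono$n_dual, 0L)
  # dual fraction of 90%-labelled dimers: 2 p^2 q (1-q) = 0.405
  dim90 <- simulate_dual_labels(100000, 1, model, seed = 6)
  p_hat <- dim90$n_dual / 100000
  expect_lt(abs(p_hat - 0.405), 3 * sqrt(0.405 * 0.595 / 100000))

  # Monte-Carlo vs analytic category probabilities across a grid
  for (p in c(0.5, 0.9)) for (q in c(0.3, 0.5)) for (f2 in c(0.2, 0.8)) {
    m <- labeling_model("binomial_snap", p, q)
    cts <- simulate_dual_labels(10000, f2, m, seed = 7)
    expect_identical(cts$n_dual + cts$n_A_only + cts$n_B_only +
                       cts$n_undetected, 10000L)
    exp_p <- f2 * dual_label_distribution(2, p, q) +
      (1 - f2) * dual_label_distribution(1, p, q)
    obs <- c(cts$n_dual, cts$n_A_only, cts$n_B_only, cts$n_undetected) / 10000
    se <- sqrt(exp_p * (1 - exp_p) / 10000)
    expect_true(all(abs(obs - exp_p) <= 4 * pmax(se, 1e-4)))
  }
  # mode mismatch
  expect_error(simulate_dual_labels(10, 0.5, labeling_model("poisson_body")),
               "mode mismatch")
})

test_that("RNA labelling simulator matches the Poisson-detection forward model", {
  m <- labeling_model("poisson_body", poisson_mean = 3, colourA_fraction = 0.5)
  # no two-RNA particles: never dual
  one <- simulate_rna_labels(2000, 0, m, seed = 8)
  expect_identical(one$n_dual, 0L)
  # saturating labelling: dual fraction -> 1/2
  sat <- simulate_rna_labels(
    50000, 1, labeling_model("poisson_body", poisson_mean = 30), seed = 9)
  expect_lt(abs(detected_fractions(sat)[["dual"]] - 0.5),
            3 * sqrt(0.25 / 50000))
  # forward model at f2 = 0.3, mean 3 dyes
  cts <- simulate_rna_labels(100000, 0.3, m, seed = 10)
  expect_identical(cts$n_dual + cts$n_A_only + cts$n_B_only +
                     cts$n_undetected, 100000L)
  d_hat <- detected_fractions(cts)[["dual"]]
  n_det <- cts$n_dual + cts$n_A_only + cts$n_B_only
  expect_lt(abs(d_hat - 0.1404), 3 * sqrt(0.1404 * (1 - 0.1404) / n_det))
  expect_error(simulate_rna_labels(10, 0.5, labeling_model("binomial_snap")),
               "mode mismatch")
})

test_that("kymograph rendering places stripes where the tracks are", {
  cfg <- sim_config(n_microtubules = 1, tracks_per_mt_mean = 0, seed = 12)
  ts <- simulate_trackset(cfg)
  img <- render_kymograph(ts, "mt01",
                          intensity_params = list(background = 0))
  expect_true(all(img == 0))   # empty set -> background only
  expect_error(render_kymograph(ts, "mt99"), "unknown")

  # one noiseless static track -> a constant-position vertical stripe
  L <- ts$microtubules$length_um[1]
  x0 <- 0.47 * L
  n_fr <- nrow(img)
  ts$tracks <- make_track(t = (0:(n_fr - 1)) * cfg$frame_interval,
                          x = rep(x0, n_fr))
  img2 <- render_kymograph(ts, "mt01",
                           intensity_params = list(background = 0,
                                                   psf_sigma = 0.05))
  peak_col <- apply(img2, 1, which.max)
  expect_true(all(peak_col == ceiling(x0 / cfg$pixel_size)))

  # a 1 um/s run: stripe slope of 1/pixel_size columns per second
  t <- (0:(n_fr - 1)) * cfg$frame_interval
  x <- pmax(0.9 * L - 1.0 * t, 0.5)
  moving <- which(0.9 * L - 1.0 * t > 0.5)
  ts$tracks <- make_track(t = t, x = x)
  img3 <- render_kymograph(ts, "mt01",
                           intensity_params = list(background = 0,
                                                   psf_sigma = 0.05))
  peaks <- apply(img3[moving, ], 1, which.max)
  slope <- unname(stats::coef(stats::lm(peaks ~ t[moving]))[2])
  expect_equal(abs(slope), 1 / cfg$pixel_size, tolerance = 0.05)
})
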