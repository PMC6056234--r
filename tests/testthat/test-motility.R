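test_that("classification applies the binding-event and processivity criteria", {
  mt <- mt_table(20)
  t10 <- seq(0, 4.5, by = 0.5)
  # constant position, no noise -> static
  ev <- classify_track(make_track(t10, rep(8, 10)), mt)
  expect_equal(ev$category, "static")
  # 10 frames at -1 um/s: net -4.5 um, straight -> processive
  ev <- classify_track(make_track(t10, 12 - t10), mt)
  expect_equal(ev$category, "processive")
  expect_equal(ev$run_length_um, 4.5, tolerance = 1e-12)
  expect_equal(ev$net_displacement_um, -4.5, tolerance = 1e-12)
  # two frames (1.0 s) is below the binding-event minimum -> rejected
  expect_null(classify_track(make_track(c(0, 0.5), c(5, 4.5)), mt))
  # plus-end-directed motion is not processive in this assay
  ev <- classify_track(make_track(t10, 8 + t10), mt)
  expect_equal(ev$category, "diffusive")
  # unordered times are an input error
  expect_error(classify_track(make_track(c(0, 1, 0.5), c(1, 2, 3)), mt),
               "strictly increasing")
})

test_that("an unbiased random walk with small net displacement is diffusive", {
  mt <- mt_table(40)
  seed <- 0
  repeat {  # resample until |net| < 0.5 um by construction
    seed <- seed + 1
    set.seed(seed)
    steps <- rnorm(49, 0, sqrt(2 * 0.05 * 0.5))
    x <- 20 + cumsum(c(0, steps))
    if (abs(x[50] - x[1]) < 0.5) break
  }
  ev <- classify_track(make_track(seq(0, by = 0.5, length.out = 50), x), mt)
  expect_equal(ev$category, "diffusive")
})

test_that("classification is invariant to time shifts and axis reflection", {
  set.seed(42)
  t <- seq(0, 9.5, by = 0.5)
  cases <- list(
    processive = 15 - 0.8 * t,
    static = rep(6, length(t)),
    diffusive = 10 + cumsum(c(0, rnorm(length(t) - 1, 0, 0.3))))
  for (nm in names(cases)) {
    x <- cases[[nm]]
    ev <- classify_track(make_track(t, x), mt_table(30))
    # uniform time shift
    ev_shift <- classify_track(make_track(t + 17.5, x), mt_table(30))
    expect_equal(ev_shift$category, ev$category)
    # reflect the axis and move the minus end to the far end
    ev_refl <- classify_track(make_track(t, 30 - x),
                              mt_table(30, minus_end = 30))
    expect_equal(ev_refl$category, ev$category)
  }
})

test_that("terminal minus-end dwell does not disguise a run as diffusive", {
  t <- seq(0, 29.5, by = 0.5)
  # runs 4 um to the minus end in 4 s, then sits at the end for 26 s
  x_true <- pmax(4 - 1.0 * t, 0)
  set.seed(7)
  x <- pmax(x_true + rnorm(length(t), 0, 0.05), 0)
  ev <- classify_track(make_track(t, x), mt_table(20))
  expect_equal(ev$category, "processive")
  expect_true(ev$arrived_minus_end)
  expect_true(ev$censored)
})

test_that("noiseless simulated tracks are classified to ground truth", {
  cfg <- sim_config(n_microtubules = 12, tracks_per_mt_mean = 15,
                    localisation_sd = 0, mt_length_mean = 25,
                    mt_length_sd = 3, seed = 21)
  ts <- simulate_trackset(cfg)
  mot <- classify_tracks(ts, params = classify_params(localisation_sd = 0),
                         segments = FALSE)
  m <- merge(mot$events, ts$ground_truth, by = "track_id")
  expect_gt(nrow(m), 80)
  # unambiguous cases must match exactly: truth consistent with the
  # operational thresholds (net displacement clear of the 0.5 um boundary)
  toward_minus <- -m$net_displacement_um
  amb <- abs(toward_minus - 0.5) < 0.1
  proc <- !amb & m$class == "processive" & toward_minus > 0.5 &
    m$directionality >= 0.75
  expect_true(all(m$category[proc] == "processive"))
  stat <- m$class == "static"
  expect_true(all(m$category[stat] == "static"))
  diff_ok <- !amb & m$class == "diffusive" &
    (toward_minus < 0.5 | m$directionality < 0.65)
  expect_true(all(m$category[diff_ok] == "diffusive"))
  # class counts partition the accepted events
  expect_identical(sum(table(m$category)), nrow(m))
})

test_that("piecewise-linear segmentation is exact on noiseless tracks", {
  t <- seq(0, 10, by = 0.5)
  # two constant-velocity stretches: -1 um/s then -2 um/s
  x <- ifelse(t <= 5, 10 - t, 5 - 2 * (t - 5))
  sg <- segment_velocities(data.frame(time_s = t, position_um = x))
  expect_identical(nrow(sg), 2L)
  expect_equal(sg$velocity_um_s, c(-1, -2), tolerance = 1e-9)
  # constant velocity -> exactly one segment
  sg1 <- segment_velocities(data.frame(time_s = t, position_um = 8 - 0.7 * t))
  expect_identical(nrow(sg1), 1L)
  expect_equal(sg1$velocity_um_s, -0.7, tolerance = 1e-9)
  # segments tile the track without overlap
  expect_equal(sg$t_start_s[1], t[1])
  expect_equal(sg$t_end_s[2], t[length(t)])
  expect_true(sg$t_start_s[2] > sg$t_end_s[1])
  # pauses are flagged but retained
  xp <- c(10 - t[t <= 5], rep(5, sum(t > 5)))
  sgp <- segment_velocities(data.frame(time_s = t, position_um = xp))
  expect_identical(nrow(sgp), 2L)
  expect_true(sgp$is_pause[2])
  # too few points: single-segment fallback
  sg2 <- segment_velocities(data.frame(time_s = t[1:4],
                                       position_um = 3 - t[1:4]))
  expect_identical(nrow(sg2), 1L)
})

test_that("segmentation agrees with the brute-force single-changepoint oracle", {
  set.seed(31)
  for (rep in 1:20) {
    bp <- sample(5:16, 1)
    v1 <- -runif(1, 0.4, 1.6); v2 <- -runif(1, 0.4, 1.6)
    if (abs(v1 - v2) < 0.3) v2 <- v1 - 0.5
    t <- seq(0, 10, by = 0.5); n <- length(t)
    x <- 14 + ifelse(seq_len(n) <= bp, v1 * t,
                     v1 * t[bp] + v2 * (t - t[bp]))
    sg <- segment_velocities(data.frame(time_s = t, position_um = x))
    oracle <- brute_force_changepoint(t, x)
    expect_identical(nrow(sg), 2L)
    # same optimum as the exhaustive search: identical residual cost; the
    # breakpoint may differ by one frame when the vertex sample lies exactly
    # on both lines (a genuine tie)
    split_dp <- which(t == sg$t_start_s[2])
    rss_dp <- brute_force_changepoint(t, x)$rss  # oracle cost at its split
    expect_lte(abs(split_dp - oracle$split), 1)
    fit1 <- stats::lm(x[1:(split_dp - 1)] ~ t[1:(split_dp - 1)])
    fit2 <- stats::lm(x[split_dp:n] ~ t[split_dp:n])
    expect_equal(sum(stats::resid(fit1)^2) + sum(stats::resid(fit2)^2),
                 oracle$rss, tolerance = 1e-9)
  }
})

test_that("changepoints of noisy two-segment tracks are recovered", {
  set.seed(55)
  hits <- 0; n_tracks <- 200
  for (i in seq_len(n_tracks)) {
    bp <- sample(5:15, 1)
    v1 <- -runif(1, 0.5, 1.5)
    v2 <- v1 + sample(c(-1, 1), 1) * runif(1, 0.4, 1.0)
    t <- seq(0, 10, by = 0.5)
    x <- 16 + ifelse(seq_along(t) <= bp, v1 * t,
                     v1 * t[bp] + v2 * (t - t[bp])) +
      rnorm(length(t), 0, 0.05)
    sg <- segment_velocities(data.frame(time_s = t, position_um = x))
    if (nrow(sg) >= 2) {
      est <- vapply(sg$t_start_s[-1], function(s) which(t == s), integer(1))
      if (any(abs(est - (bp + 1)) <= 2)) hits <- hits + 1
    }
  }
  expect_gte(hits / n_tracks, 0.90)
})

test_that("noiseless segmental velocities reproduce the generating slopes", {
  cfg <- sim_config(n_microtubules = 6, tracks_per_mt_mean = 8,
                    class_probs = c(0, 0, 1), localisation_sd = 0,
                    mt_length_mean = 30, segment_switch_rate = 0.15,
                    seed = 41)
  ts <- simulate_trackset(cfg)
  mot <- classify_tracks(ts)
  sg <- mot$segments
  ev <- mot$events
  expect_gt(nrow(sg), 20)
  # segment decomposition does not lose displacement: sum of |v| * duration
  # covers |net displacement| up to one transition frame per changepoint
  # (the frame straddling a velocity change mixes the two speeds)
  for (id in unique(sg$track_id)) {
    s <- sg[sg$track_id == id, ]
    e <- ev[ev$track_id == id, ]
    path_seg <- sum(abs(s$velocity_um_s) *
                      (s$t_end_s - s$t_start_s + cfg$frame_interval))
    allowance <- (nrow(s) - 1) * cfg$frame_interval *
      max(abs(s$velocity_um_s))
    expect_gte(path_seg + allowance + 1e-6, abs(e$net_displacement_um))
  }
  # single-segment ground-truth tracks: slope matches the drawn velocity
  gt <- ts$truth_segments
  one_seg <- names(which(table(gt$track_id) == 1))
  for (id in intersect(one_seg, unique(sg$track_id))) {
    s <- sg[sg$track_id == id, ]
    if (nrow(s) == 1)
      expect_equal(s$velocity_um_s,
                   gt$velocity_um_s[gt$track_id == id], tolerance = 1e-6)
  }
})

test_that("per-microtubule motility fractions sum to one and pool correctly", {
  cfg <- sim_config(n_microtubules = 8, seed = 51)
  mot <- classify_tracks(simulate_trackset(cfg), segments = FALSE)
  fr <- motility_fractions(mot)
  sums <- rowSums(fr$per_mt[, c("frac_static", "frac_diffusive",
                                "frac_processive")])
  expect_equal(unname(sums), rep(1, nrow(fr$per_mt)), tolerance = 1e-12)
  expect_equal(sum(fr$pooled), 1, tolerance = 1e-12)
  # all-processive events
  ev <- data.frame(mt_id = "mt01", category = rep("processive", 5))
  fr2 <- motility_fractions(ev)
  expect_equal(unname(fr2$pooled),
               c(0, 0, 1))
  # no events: absent, not zero
  fr0 <- motility_fractions(NULL)
  expect_true(all(is.na(fr0$pooled)))
  expect_identical(nrow(fr0$per_mt), 0L)
})
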