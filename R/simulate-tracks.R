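#' Simulate a synthetic single-molecule track set
#'
#' Generates per-particle trajectories along microtubules with known ground
#' truth. Each track belongs to one of three classes: *static* (localisation
#' noise only), *diffusive* (unbiased Gaussian random walk, reflected at the
#' microtubule ends) or *processive* (piecewise-constant velocity toward the
#' minus end at coordinate 0, with an exponentially distributed run length).
#' Particles attach at uniform random times and positions. Static and
#' diffusive particles detach after an exponential attachment duration;
#' processive particles detach when their drawn run length is exhausted or
#' arrest on reaching the minus end, where they persist for the remainder of
#' the movie. Every sampled position is corrupted with Gaussian localisation
#' noise and clipped to the microtubule.
#'
#' @param config A [sim_config()] object.
#' @param channel Channel label stored with every track (default `"ch1"`).
#' @return An object of class `track_set`: a list with elements
#'   \describe{
#'     \item{tracks}{data.frame with columns `mt_id`, `track_id`, `channel`,
#'       `frame_index`, `time_s`, `position_um` (one row per track and frame).}
#'     \item{microtubules}{data.frame with `mt_id`, `length_um`,
#'       `minus_end_position_um`.}
#'     \item{ground_truth}{data.frame with the true class, true run length
#'       (processive tracks), attachment time/position and arrest status of
#'       every track.}
#'     \item{truth_segments}{data.frame with the true constant-velocity
#'       segments (signed velocity, negative = minus-end-directed) of every
#'       processive track.}
#'     \item{config}{the generating configuration (seed included).}
#'   }
#' @examples
#' ts <- simulate_trackset(sim_config(n_microtubules = 2, seed = 7))
#' head(ts$tracks)
#' table(ts$ground_truth$class)
#' @export
simulate_trackset <- function(config, channel = "ch1") {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  set.seed(config$seed)
  dt <- config$frame_interval
  n_frames <- max(1L, floor(config$movie_duration / dt))
  frame_times <- (seq_len(n_frames) - 1L) * dt

  mt_len <- rtnorm_lower(config$n_microtubules, config$mt_length_mean,
                         config$mt_length_sd, lower = 1)
  mts <- data.frame(
    mt_id = sprintf("mt%02d", seq_len(config$n_microtubules)),
    length_um = mt_len,
    minus_end_position_um = 0,
    stringsAsFactors = FALSE)

  n_per_mt <- stats::rpois(config$n_microtubules, config$tracks_per_mt_mean)
  classes <- c("static", "diffusive", "processive")

  tracks <- vector("list", sum(n_per_mt))
  truth <- vector("list", sum(n_per_mt))
  tsegs <- list()
  idx <- 0L

  for (m in seq_len(config$n_microtubules)) {
    L <- mt_len[m]
    for (k in seq_len(n_per_mt[m])) {
      idx <- idx + 1L
      cls <- classes[sample.int(3L, 1L, prob = config$class_probs)]
      t0 <- stats::runif(1, 0, config$movie_duration)
      x0 <- stats::runif(1, 0, L)
      tid <- sprintf("trk%05d", idx)

      sim <- switch(cls,
        static = sim_static_track(t0, x0, config),
        diffusive = sim_diffusive_track(t0, x0, L, config),
        processive = sim_processive_track(t0, x0, config))

      f0 <- ceiling(t0 / dt)            # first frame at or after attachment
      fL <- min(floor(sim$t_obs_end / dt), n_frames - 1L)
      if (f0 > fL) { idx <- idx - 1L; next }  # never sampled
      fr <- f0:fL
      tq <- frame_times[fr + 1L]
      x <- sim$position(tq)
      if (config$localisation_sd > 0)
        x <- x + stats::rnorm(length(x), 0, config$localisation_sd)
      x <- pmin(pmax(x, 0), L)

      tracks[[idx]] <- data.frame(
        mt_id = mts$mt_id[m], track_id = tid, channel = channel,
        frame_index = as.integer(fr), time_s = tq, position_um = x,
        stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(
        track_id = tid, mt_id = mts$mt_id[m], class = cls,
        t_attach_s = t0, x_attach_um = x0,
        run_length_true_um = sim$run_length %||% NA_real_,
        arrested = isTRUE(sim$arrested),
        detach_time_s = sim$t_motion_end,
        stringsAsFactors = FALSE)
      if (!is.null(sim$segments) && nrow(sim$segments) > 0) {
        sg <- sim$segments
        sg$track_id <- tid
        tsegs[[length(tsegs) + 1L]] <- sg
      }
    }
  }

  tracks <- tracks[seq_len(idx)]
  truth <- truth[seq_len(idx)]
  out <- list(
    tracks = if (idx > 0) do.call(rbind, tracks) else empty_track_table(),
    microtubules = mts,
    ground_truth = if (idx > 0) do.call(rbind, truth) else NULL,
    truth_segments = if (length(tsegs)) do.call(rbind, tsegs) else NULL,
    config = config)
  rownames(out$tracks) <- NULL
  class(out) <- "track_set"
  out
}

sim_static_track <- function(t0, x0, config) {
  dur <- stats::rexp(1, 1 / config$attach_duration_mean)
  t_end <- min(t0 + dur, config$movie_duration)
  list(position = function(tq) rep(x0, length(tq)),
       t_obs_end = t_end, t_motion_end = t_end)
}

sim_diffusive_track <- function(t0, x0, L, config) {
  dur <- stats::rexp(1, 1 / config$attach_duration_mean)
  t_end <- min(t0 + dur, config$movie_duration)
  dt <- config$frame_interval
  # pre-draw the walk on the frame grid covering [t0, t_end]
  n_steps <- max(0L, ceiling((t_end - t0) / dt) + 1L)
  steps <- stats::rnorm(n_steps, 0, sqrt(2 * config$diffusion_coeff * dt))
  path <- reflect_interval(x0 + cumsum(c(0, steps)), L)
  list(position = function(tq) {
    i <- pmin(round((tq - t0) / dt), length(path) - 1L)
    path[i + 1L]
  }, t_obs_end = t_end, t_motion_end = t_end)
}

# fold a coordinate into [0, L] by mirror reflection
reflect_interval <- function(x, L) {
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

sim_processive_track <- function(t0, x0, config) {
  run <- stats::rexp(1, 1 / config$run_length_mean)
  avail <- config$movie_duration - t0
  stop_dist <- min(run, x0)          # detachment or minus-end arrest

  durs <- numeric(0); vels <- numeric(0)
  cum_t <- 0; cum_d <- 0
  repeat {
    d <- if (config$segment_switch_rate > 0)
      stats::rexp(1, config$segment_switch_rate) else Inf
    v <- rtnorm_lower(1, config$velocity_mean, config$velocity_sd, lower = 0)
    durs <- c(durs, d); vels <- c(vels, v)
    cum_t <- cum_t + min(d, avail)
    cum_d <- cum_d + v * min(d, avail)
    if (cum_d >= stop_dist || cum_t >= avail) break
  }

  knot_t <- c(0, cumsum(pmin(durs, avail)))
  knot_d <- c(0, cumsum(vels * pmin(durs, avail)))
  # time at which cumulative distance reaches stop_dist (Inf if not in movie)
  if (max(knot_d) >= stop_dist) {
    i <- which(knot_d >= stop_dist)[1] - 1L
    tau <- knot_t[i] + (stop_dist - knot_d[i]) / vels[i]
  } else tau <- Inf
  arrested <- is.finite(tau) && stop_dist == x0 && x0 <= run
  t_motion_end <- t0 + min(tau, avail)
  t_obs_end <- if (arrested) config$movie_duration else t_motion_end

  pos <- function(tq) {
    rel <- pmin(pmax(tq - t0, 0), min(tau, avail))
    s <- stats::approx(knot_t, knot_d, xout = rel, rule = 2,
                       ties = "ordered")$y
    pmax(x0 - s, 0)
  }

  n_seg <- if (is.finite(tau)) which(knot_t >= tau)[1] - 1L else length(vels)
  n_seg <- min(n_seg, length(vels))
  segs <- data.frame(
    t_start_s = t0 + knot_t[seq_len(n_seg)],
    t_end_s = t0 + pmin(knot_t[seq_len(n_seg) + 1L], min(tau, avail)),
    velocity_um_s = -vels[seq_len(n_seg)])
  list(position = pos, t_obs_end = min(t_obs_end, config$movie_duration),
       t_motion_end = t_motion_end, run_length = run,
       arrested = arrested, segments = segs)
}

empty_track_table <- function() {
  data.frame(mt_id = character(), track_id = character(),
             channel = character(), frame_index = integer(),
             time_s = numeric(), position_um = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.track_set <- function(x, ...) {
  nt <- length(unique(x$tracks$track_id))
  cat(sprintf("<track_set> %d tracks on %d microtubules (%d samples)\n",
              nt, nrow(x$microtubules), nrow(x$tracks)))
  if (!is.null(x$ground_truth))
    print(table(x$ground_truth$class))
  invisible(x)
}
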