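#' Classification parameters for motility events
#'
#' Thresholds implementing the event-scoring protocol of the assay: particles
#' are accepted as binding events only if present for at least `min_frames`
#' frames / `min_duration` seconds, and scored processive if they achieve a
#' predominantly minus-end-directed displacement exceeding
#' `processive_min_net` without significant diffusive behaviour. The latter is
#' operationalised by the directionality ratio |net| / path-length: a track is
#' \describe{
#'   \item{processive}{net minus-end displacement >= `processive_min_net` and
#'     directionality ratio >= `directionality_min`;}
#'   \item{static}{maximum excursion from its mean position <=
#'     `static_max_excursion` (default `2 * localisation_sd * sqrt(2)`);}
#'   \item{diffusive}{anything else.}
#' }
#' A terminal dwell at the minus end (sustained residence within
#' `minus_end_zone` of coordinate 0) is trimmed before computing net and path
#' length, so that end-arrested runs are not scored as diffusive merely
#' because localisation noise accumulates path length while the particle sits
#' at the end.
#'
#' @param min_frames Minimum frames for a binding event (default 3).
#' @param min_duration Minimum duration in seconds (default 1.5). Event
#'   duration is `n_frames * frame_interval`, so at 2 frames/s the two
#'   defaults coincide.
#' @param processive_min_net Minimum net minus-end displacement (um) for a
#'   processive call (default 0.5, i.e. five 105-nm pixels).
#' @param directionality_min Minimum |net displacement| / path-length ratio
#'   for a processive call (default 0.7).
#' @param localisation_sd Localisation noise SD (um) used for the default
#'   static excursion threshold.
#' @param static_max_excursion Maximum excursion from the mean position (um)
#'   for a static call.
#' @param changepoint_penalty Unitless multiplier of the segmentation penalty
#'   `penalty * sigma^2 * log(n)`; see [segment_velocities()].
#' @param min_segment_frames Minimum frames per velocity segment (default 3).
#' @param velocity_merge_tol Adjacent segments whose velocities differ by less
#'   than this (um/s) are merged (default 0.1).
#' @param pause_velocity_max Segments with |velocity| below this (um/s) are
#'   flagged as pauses and excluded from segmental-velocity distributions
#'   (default 0.05); they still count toward run length.
#' @param minus_end_zone Distance from the minus end (um) within which a
#'   particle counts as end-arrested (default 0.2).
#' @return An object of class `classify_params`.
#' @export
classify_params <- function(min_frames = 3L,
                            min_duration = 1.5,
                            processive_min_net = 0.5,
                            directionality_min = 0.7,
                            localisation_sd = 0.05,
                            static_max_excursion = 2 * localisation_sd * sqrt(2),
                            changepoint_penalty = 10,
                            min_segment_frames = 3L,
                            velocity_merge_tol = 0.1,
                            pause_velocity_max = 0.05,
                            minus_end_zone = 0.2) {
  check_count(min_frames, "min_frames", min = 1L)
  check_number(min_duration, "min_duration", lower = 0)
  check_number(processive_min_net, "processive_min_net", lower = 0,
               allow_zero_lower = FALSE)
  check_probability(directionality_min, "directionality_min")
  check_number(localisation_sd, "localisation_sd", lower = 0)
  check_number(static_max_excursion, "static_max_excursion", lower = 0)
  check_number(changepoint_penalty, "changepoint_penalty", lower = 0)
  check_count(min_segment_frames, "min_segment_frames", min = 2L)
  check_number(velocity_merge_tol, "velocity_merge_tol", lower = 0)
  check_number(pause_velocity_max, "pause_velocity_max", lower = 0)
  check_number(minus_end_zone, "minus_end_zone", lower = 0)
  p <- list(min_frames = as.integer(min_frames), min_duration = min_duration,
            processive_min_net = processive_min_net,
            directionality_min = directionality_min,
            localisation_sd = localisation_sd,
            static_max_excursion = static_max_excursion,
            changepoint_penalty = changepoint_penalty,
            min_segment_frames = as.integer(min_segment_frames),
            velocity_merge_tol = velocity_merge_tol,
            pause_velocity_max = pause_velocity_max,
            minus_end_zone = minus_end_zone)
  class(p) <- "classify_params"
  p
}

#' Classify one track into a motility event
#'
#' Applies the binding-event and processivity criteria to a single track (see
#' [classify_params()] for the decision rule). Tracks that are too short to
#' count as binding events are rejected (returns `NULL`). Processive events
#' carry their run length, defined as the magnitude of total displacement of
#' the (dwell-trimmed) track regardless of velocity changes or pauses.
#'
#' @param track A data.frame with numeric columns `time_s` (strictly
#'   increasing) and `position_um`, and optionally `mt_id`, `track_id`,
#'   `channel`.
#' @param mt A one-row data.frame with `length_um` and
#'   `minus_end_position_um` (default 0); used to orient the minus end.
#' @param params A [classify_params()] object.
#' @param movie_duration Movie length (s) used to flag truncation at the
#'   movie end; `NULL` disables the flag (events are then conservatively
#'   treated as possibly truncated if they end at the last observed time).
#' @return A one-row data.frame (the motility event) or `NULL` if the track
#'   is rejected. Columns include `category`, `n_frames`, `duration_s`,
#'   signed `net_displacement_um` (negative = minus-end-directed),
#'   `path_length_um`, `directionality`, `run_length_um`, `censored`,
#'   `fully_observed` and start/end positions and times.
#' @export
classify_track <- function(track, mt = NULL, params = classify_params(),
                           movie_duration = NULL) {
  stopifnot(is.data.frame(track),
            all(c("time_s", "position_um") %in% names(track)))
  t <- track$time_s
  x <- track$position_um
  if (any(!is.finite(t)) || any(!is.finite(x)))
    stop("track contains non-finite times or positions", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("track times must be strictly increasing", call. = FALSE)

  minus_pos <- if (!is.null(mt)) mt$minus_end_position_um[1] else 0
  mt_len <- if (!is.null(mt)) mt$length_um[1] else NA_real_
  dist_minus <- abs(x - minus_pos)

  dt <- if (length(t) > 1) stats::median(diff(t)) else NA_real_

  # trim a terminal dwell at the minus end: the particle entered the
  # minus-end zone and never left it again
  arrived_minus <- FALSE
  n <- length(x)
  if (n >= 2 && dist_minus[1] > params$minus_end_zone &&
      dist_minus[n] <= params$minus_end_zone) {
    in_zone_to_end <- rev(cumprod(rev(dist_minus <= params$minus_end_zone)))
    j <- which(in_zone_to_end == 1)[1]
    arrived_minus <- TRUE
    keep <- seq_len(j)   # keep the arrival frame
    t_full_end <- t[n]
    t <- t[keep]; x <- x[keep]; dist_minus <- dist_minus[keep]
    n <- length(x)
  } else {
    t_full_end <- t[n]
    arrived_minus <- dist_minus[n] <= params$minus_end_zone
  }

  duration <- if (is.na(dt)) 0 else n * dt
  if (n < params$min_frames || duration < params$min_duration - 1e-9)
    return(NULL)

  toward_minus <- dist_minus[1] - dist_minus[n]   # >0 = moved minus-ward
  net <- -toward_minus                            # signed convention
  path <- sum(abs(diff(x)))
  directionality <- if (path > 0) abs(net) / path else 1
  excursion <- max(abs(x - mean(x)))

  category <- if (toward_minus >= params$processive_min_net &&
                  directionality >= params$directionality_min) {
    "processive"
  } else if (excursion <= params$static_max_excursion) {
    "static"
  } else "diffusive"

  starts_at_movie_start <- t[1] <= 1e-9   # present from the very first frame
  ends_at_movie_end <- if (is.null(movie_duration)) NA else
    t_full_end >= movie_duration - dt - 1e-9
  fully_observed <- !arrived_minus & !starts_at_movie_start &
    (if (is.na(ends_at_movie_end)) FALSE else !ends_at_movie_end)
  censored <- arrived_minus | starts_at_movie_start |
    isTRUE(ends_at_movie_end)

  data.frame(
    track_id = track$track_id[1] %||% NA_character_,
    mt_id = track$mt_id[1] %||% NA_character_,
    channel = track$channel[1] %||% NA_character_,
    category = category,
    n_frames = n, duration_s = duration,
    t_start_s = t[1], t_end_s = t[n],
    start_position_um = x[1], end_position_um = x[n],
    start_dist_minus_um = dist_minus[1],
    net_displacement_um = net, path_length_um = path,
    directionality = directionality,
    run_length_um = if (category == "processive") abs(net) else NA_real_,
    censored = censored, fully_observed = fully_observed,
    arrived_minus_end = arrived_minus,
    stringsAsFactors = FALSE)
}

#' Classify every track of a track set
#'
#' @param x A `track_set` (from [simulate_trackset()] or [read_tracks()]) or
#'   a track table data.frame.
#' @param microtubules Microtubule table (required when `x` is a bare
#'   data.frame).
#' @param params A [classify_params()] object.
#' @param movie_duration Movie length (s); taken from the simulation config
#'   when `x` is a simulated `track_set`.
#' @param segments If `TRUE` (default) run [segment_velocities()] on every
#'   processive event.
#' @return A list of class `motility_result` with elements `events` (one row
#'   per accepted binding event), `segments` (velocity segments of processive
#'   events), and `rejected` (track ids failing the binding-event criteria).
#' @export
classify_tracks <- function(x, microtubules = NULL,
                            params = classify_params(),
                            movie_duration = NULL, segments = TRUE) {
  if (inherits(x, "track_set")) {
    microtubules <- microtubules %||% x$microtubules
    movie_duration <- movie_duration %||% x$config$movie_duration
    tracks <- x$tracks
  } else tracks <- x
  stopifnot(is.data.frame(tracks))
  if (is.null(microtubules))
    stop("`microtubules` table required", call. = FALSE)

  split_key <- interaction(tracks$track_id, tracks$channel, drop = TRUE)
  per_track <- split(tracks, split_key)
  events <- vector("list", length(per_track))
  segs <- list()
  rejected <- character(0)
  for (i in seq_along(per_track)) {
    tr <- per_track[[i]]
    tr <- tr[order(tr$time_s), , drop = FALSE]
    mt <- microtubules[microtubules$mt_id == tr$mt_id[1], , drop = FALSE]
    if (nrow(mt) == 0)
      stop(sprintf("track %s references unknown microtubule %s",
                   tr$track_id[1], tr$mt_id[1]), call. = FALSE)
    ev <- classify_track(tr, mt, params, movie_duration)
    if (is.null(ev)) {
      rejected <- c(rejected, tr$track_id[1])
      next
    }
    events[[i]] <- ev
    if (segments && ev$category == "processive") {
      sg <- segment_velocities(tr, params)
      sg$track_id <- tr$track_id[1]
      segs[[length(segs) + 1L]] <- sg
    }
  }
  events <- events[!vapply(events, is.null, logical(1))]
  out <- list(
    events = if (length(events)) do.call(rbind, events) else NULL,
    segments = if (length(segs)) do.call(rbind, segs) else NULL,
    rejected = rejected,
    params = params)
  if (!is.null(out$events)) rownames(out$events) <- NULL
  class(out) <- "motility_result"
  out
}

#' @export
print.motility_result <- function(x, ...) {
  ne <- if (is.null(x$events)) 0L else nrow(x$events)
  cat(sprintf("<motility_result> %d binding events (%d tracks rejected)\n",
              ne, length(x$rejected)))
  if (ne > 0) print(table(x$events$category))
  invisible(x)
}

#' Per-microtubule and pooled motility-class fractions
#'
#' @param events Events data.frame from [classify_tracks()] (or a
#'   `motility_result`).
#' @return A list with `per_mt` (one row per microtubule with >= 1 event;
#'   fractions sum to 1 within each row) and `pooled` (named fractions over
#'   all events). With no events, `per_mt` is empty and `pooled` is `NA`.
#' @export
motility_fractions <- function(events) {
  if (inherits(events, "motility_result")) events <- events$events
  cats <- c("static", "diffusive", "processive")
  if (is.null(events) || nrow(events) == 0) {
    return(list(per_mt = data.frame(), pooled =
                  stats::setNames(rep(NA_real_, 3), cats)))
  }
  tab <- table(factor(events$mt_id), factor(events$category, levels = cats))
  per_mt <- data.frame(mt_id = rownames(tab),
                       n_events = as.integer(rowSums(tab)),
                       stringsAsFactors = FALSE)
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  colnames(frac) <- paste0("frac_", cats)
  per_mt <- cbind(per_mt, as.data.frame(frac, stringsAsFactors = FALSE))
  rownames(per_mt) <- NULL
  pooled <- colSums(tab) / sum(tab)
  list(per_mt = per_mt, pooled = stats::setNames(as.numeric(pooled), cats))
}
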