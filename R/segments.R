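#' Piecewise-constant velocity segmentation of a track
#'
#' Motile complexes frequently change velocity mid-run, so velocities are
#' reported per constant-velocity segment. Segmentation minimises the
#' penalised cost
#' \deqn{\sum_{s} \mathrm{RSS}(s) + \beta \cdot \#\mathrm{segments}}
#' over all partitions of the track into segments of at least
#' `min_segment_frames` points, where RSS is the residual sum of squares of a
#' per-segment least-squares line and
#' `beta = changepoint_penalty * sigma^2 * log(n)`. The noise scale `sigma`
#' is estimated robustly from second differences of the positions (which
#' annihilate any piecewise-linear trend). An infinitesimal floor on `beta`
#' makes the fit of a noiseless piecewise-linear track resolve ties toward
#' the fewest segments, so such tracks are segmented exactly. Adjacent
#' segments whose fitted velocities differ by less than `velocity_merge_tol`
#' are merged and refitted.
#'
#' Dynamic programming guarantees the global optimum (exhaustive over all
#' admissible changepoint sets), so for single-changepoint tracks the result
#' coincides with a brute-force single-breakpoint search.
#'
#' @param track Data.frame with `time_s` and `position_um`.
#' @param params A [classify_params()] object (fields `changepoint_penalty`,
#'   `min_segment_frames`, `velocity_merge_tol`, `pause_velocity_max`).
#' @return Data.frame with one row per segment: `seg_index`, `t_start_s`,
#'   `t_end_s` (segments tile the track; each sample belongs to exactly one
#'   segment), `n_frames`, `velocity_um_s` (signed least-squares slope) and
#'   `is_pause` (|velocity| <= `pause_velocity_max`; pauses are excluded from
#'   segmental-velocity distributions but retained in run lengths).
#' @examples
#' t <- seq(0, 10, by = 0.5)
#' x <- ifelse(t <= 5, 10 - t, 5 - 2 * (t - 5))
#' segment_velocities(data.frame(time_s = t, position_um = x))
#' @export
segment_velocities <- function(track, params = classify_params()) {
  stopifnot(is.data.frame(track),
            all(c("time_s", "position_um") %in% names(track)))
  t <- track$time_s
  x <- track$position_um
  if (is.unsorted(t, strictly = TRUE))
    stop("track times must be strictly increasing", call. = FALSE)
  n <- length(t)
  mlen <- params$min_segment_frames

  if (n < 2 * mlen) {                       # single-segment fallback
    v <- if (n >= 2) ls_slope(t, x) else 0
    return(segment_table(t, breaks = integer(0), velocities = v, params))
  }

  # O(1) RSS of a least-squares line on points i..j via cumulative sums
  ct <- cumsum(t); cx <- cumsum(x); ctt <- cumsum(t * t)
  ctx <- cumsum(t * x); cxx <- cumsum(x * x)
  seg_stats <- function(i, j) {
    m <- j - i + 1
    st <- ct[j] - if (i > 1) ct[i - 1] else 0
    sx <- cx[j] - if (i > 1) cx[i - 1] else 0
    stt <- ctt[j] - if (i > 1) ctt[i - 1] else 0
    stx <- ctx[j] - if (i > 1) ctx[i - 1] else 0
    sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
    vtt <- stt - st * st / m
    vtx <- stx - st * sx / m
    vxx <- sxx - sx * sx / m
    slope <- if (vtt > 0) vtx / vtt else 0
    rss <- max(vxx - if (vtt > 0) vtx * vtx / vtt else 0, 0)
    c(rss = rss, slope = slope)
  }

  d2 <- diff(x, differences = 2)
  sigma <- stats::mad(d2, center = 0) / sqrt(6)
  beta <- params$changepoint_penalty * sigma^2 * log(n) + 1e-12

  # F[j+1]: minimal cost of segmenting points 1..j (F[1] = 0 for j = 0)
  F <- rep(Inf, n + 1L)
  F[1] <- -beta                     # first segment's beta cancels
  prev <- integer(n + 1L)
  for (j in mlen:n) {
    best <- Inf; arg <- 0L
    for (i in seq.int(1L, j - mlen + 1L)) {
      if (is.finite(F[i])) {
        cost <- F[i] + seg_stats(i, j)[["rss"]] + beta
        if (cost < best) { best <- cost; arg <- i }
      }
    }
    F[j + 1L] <- best
    prev[j + 1L] <- arg
  }

  # backtrack segment start indices
  starts <- integer(0)
  j <- n
  while (j >= 1) {
    i <- prev[j + 1L]
    starts <- c(i, starts)
    j <- i - 1L
  }

  # merge adjacent segments with near-identical velocities, then refit
  repeat {
    bounds <- c(starts, n + 1L)
    vels <- vapply(seq_len(length(starts)), function(s) {
      seg_stats(bounds[s], bounds[s + 1L] - 1L)[["slope"]]
    }, numeric(1))
    if (length(starts) < 2) break
    dv <- abs(diff(vels))
    if (all(dv >= params$velocity_merge_tol)) break
    drop <- which.min(dv) + 1L
    starts <- starts[-drop]
  }

  segment_table(t, breaks = starts[-1], velocities = vels, params)
}

ls_slope <- function(t, x) {
  vt <- t - mean(t)
  s <- sum(vt^2)
  if (s <= 0) return(0)
  sum(vt * (x - mean(x))) / s
}

segment_table <- function(t, breaks, velocities, params) {
  starts <- c(1L, breaks)
  ends <- c(breaks - 1L, length(t))
  data.frame(
    seg_index = seq_along(starts),
    t_start_s = t[starts],
    t_end_s = t[ends],
    n_frames = ends - starts + 1L,
    velocity_um_s = velocities,
    is_pause = abs(velocities) <= params$pause_velocity_max)
}
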