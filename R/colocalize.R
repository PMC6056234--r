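#' Two-channel co-localisation of tracks on shared microtubules
#'
#' Two tracks from different channels on the same microtubule are scored as
#' co-localised (co-transport) if, over the frames where both are present,
#' their positions agree within `max_gap` for at least
#' `min_overlap_fraction` of the shorter track's frames. Frames are matched
#' by `frame_index`.
#'
#' @param tracks_A,tracks_B Track tables (columns `mt_id`, `track_id`,
#'   `channel`, `frame_index`, `position_um`) for the two channels; both must
#'   be mapped to the same microtubule coordinate frame. Supplying the same
#'   channel twice is an error.
#' @param max_gap Maximum positional gap (um) to count a frame as
#'   co-localised (default 0.21, i.e. two 105-nm pixels).
#' @param min_overlap_fraction Minimum fraction of the shorter track's frames
#'   that must agree (default 0.5).
#' @return A list with `pairs` (one row per co-localised A/B track pair, with
#'   the overlap fraction), `per_mt` (per-microtubule co-localised fractions
#'   of each channel's tracks) and `pooled` (named overall fractions
#'   `frac_A_coloc`, `frac_B_coloc`).
#' @export
colocalize <- function(tracks_A, tracks_B, max_gap = 0.21,
                       min_overlap_fraction = 0.5) {
  for (nm in c("tracks_A", "tracks_B")) {
    tr <- get(nm)
    if (!is.data.frame(tr) ||
        !all(c("mt_id", "track_id", "frame_index", "position_um") %in%
             names(tr)))
      stop(sprintf("`%s` must be a track table", nm), call. = FALSE)
  }
  chA <- unique(tracks_A$channel %||% "A")
  chB <- unique(tracks_B$channel %||% "B")
  if (length(chA) == 1 && length(chB) == 1 && identical(chA, chB))
    stop("the two inputs carry the identical channel label; co-localisation needs two distinct channels",
         call. = FALSE)
  check_number(max_gap, "max_gap", lower = 0)
  check_probability(min_overlap_fraction, "min_overlap_fraction")

  a_ids <- unique(tracks_A$track_id)
  b_ids <- unique(tracks_B$track_id)
  a_by_id <- split(tracks_A[c("mt_id", "frame_index", "position_um")],
                   tracks_A$track_id)
  b_by_id <- split(tracks_B[c("mt_id", "frame_index", "position_um")],
                   tracks_B$track_id)
  a_mt <- vapply(a_by_id, function(d) d$mt_id[1], character(1))
  b_mt <- vapply(b_by_id, function(d) d$mt_id[1], character(1))

  pairs <- list()
  for (ai in a_ids) {
    da <- a_by_id[[ai]]
    for (bi in b_ids[b_mt[b_ids] == a_mt[[ai]]]) {
      db <- b_by_id[[bi]]
      common <- intersect(da$frame_index, db$frame_index)
      if (length(common) == 0) next
      pa <- da$position_um[match(common, da$frame_index)]
      pb <- db$position_um[match(common, db$frame_index)]
      n_short <- min(nrow(da), nrow(db))
      overlap <- sum(abs(pa - pb) <= max_gap) / n_short
      if (overlap >= min_overlap_fraction)
        pairs[[length(pairs) + 1L]] <- data.frame(
          mt_id = a_mt[[ai]], track_A = ai, track_B = bi,
          n_common_frames = length(common), overlap_fraction = overlap,
          stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(mt_id = character(), track_A = character(),
               track_B = character(), n_common_frames = integer(),
               overlap_fraction = numeric(), stringsAsFactors = FALSE)

  mt_ids <- sort(unique(c(a_mt, b_mt)))
  per_mt <- do.call(rbind, lapply(mt_ids, function(m) {
    a_here <- names(a_mt)[a_mt == m]
    b_here <- names(b_mt)[b_mt == m]
    data.frame(
      mt_id = m, n_A = length(a_here), n_B = length(b_here),
      frac_A_coloc = if (length(a_here))
        mean(a_here %in% pairs$track_A) else NA_real_,
      frac_B_coloc = if (length(b_here))
        mean(b_here %in% pairs$track_B) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  pooled <- c(frac_A_coloc = mean(a_ids %in% pairs$track_A),
              frac_B_coloc = mean(b_ids %in% pairs$track_B))
  list(pairs = pairs, per_mt = per_mt, pooled = pooled)
}
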