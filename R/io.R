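# Delimited-text serialisation of track sets. One canonical schema:
# tracks:        mt_id  track_id  channel  frame_index  time_s  position_um
# microtubules:  mt_id  length_um  minus_end_position_um
# ground truth (optional sibling), keyed by track_id.
# All tables TSV; positions/times written at full double precision (%.17g).

track_columns <- c("mt_id", "track_id", "channel", "frame_index",
                   "time_s", "position_um")

write_tsv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a track set to delimited-text tables
#'
#' Writes the track table to `path` and, alongside it, the microtubule table
#' (`<stem>_microtubules.tsv`) and, if present, the ground-truth tables
#' (`<stem>_ground_truth.tsv`, `<stem>_truth_segments.tsv`). Numeric columns
#' are written at full double precision so that a write/read round trip is
#' lossless.
#'
#' @param trackset A `track_set`.
#' @param path Path of the track table (e.g. `"tracks.tsv"`).
#' @return The track-table path, invisibly.
#' @export
write_tracks <- function(trackset, path) {
  stopifnot(inherits(trackset, "track_set"))
  stem <- sub("\\.tsv$", "", path)
  write_tsv_full(trackset$tracks[track_columns], path)
  write_tsv_full(trackset$microtubules, paste0(stem, "_microtubules.tsv"))
  if (!is.null(trackset$ground_truth))
    write_tsv_full(trackset$ground_truth, paste0(stem, "_ground_truth.tsv"))
  if (!is.null(trackset$truth_segments))
    write_tsv_full(trackset$truth_segments,
                   paste0(stem, "_truth_segments.tsv"))
  invisible(path)
}

#' Read a track set from delimited-text tables
#'
#' Reads the track table at `path` and the sibling microtubule (and, if
#' present, ground-truth) tables written by [write_tracks()]. The schema is
#' validated: required columns, strictly increasing times within each track,
#' no duplicated (track_id, channel, frame_index) rows, and every `mt_id`
#' present in the microtubule table. Violations raise errors naming the
#' offending rows; an empty (header-only) file yields an empty track set
#' with a warning.
#'
#' @param path Path of the track table.
#' @param microtubules_path Optional explicit path of the microtubule table;
#'   defaults to the `write_tracks()` sibling convention.
#' @return A `track_set`.
#' @export
read_tracks <- function(path, microtubules_path = NULL) {
  tracks <- read_tsv(path)
  missing_cols <- setdiff(track_columns, names(tracks))
  if (length(missing_cols))
    stop(sprintf("track table %s is missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  stem <- sub("\\.tsv$", "", path)
  mt_path <- microtubules_path %||% paste0(stem, "_microtubules.tsv")
  mts <- if (file.exists(mt_path)) read_tsv(mt_path) else NULL

  if (nrow(tracks) == 0) {
    warning(sprintf("track table %s contains a header only; empty track set",
                    path))
  } else {
    key <- paste(tracks$track_id, tracks$channel, tracks$frame_index)
    dup <- which(duplicated(key))
    if (length(dup))
      stop(sprintf("duplicated (track_id, frame_index) rows in %s: row %s",
                   path, paste(dup + 1L, collapse = ", ")), call. = FALSE)
    ord <- order(tracks$track_id, tracks$channel, tracks$frame_index)
    bad <- unlist(lapply(
      split(seq_len(nrow(tracks))[ord],
            paste(tracks$track_id, tracks$channel)[ord]),
      function(i) if (is.unsorted(tracks$time_s[i], strictly = TRUE))
        i[1] else NULL))
    if (length(bad))
      stop(sprintf("non-monotonic time within track(s): %s",
                   paste(unique(tracks$track_id[bad]), collapse = ", ")),
           call. = FALSE)
    if (!is.null(mts)) {
      unknown <- setdiff(unique(tracks$mt_id), mts$mt_id)
      if (length(unknown))
        stop(sprintf("track table references unknown mt_id(s): %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(mts)) {
    # reconstruct a minimal geometry from the data
    mts <- do.call(rbind, lapply(split(tracks, tracks$mt_id), function(d) {
      data.frame(mt_id = d$mt_id[1],
                 length_um = max(d$position_um, 1),
                 minus_end_position_um = 0, stringsAsFactors = FALSE)
    }))
    rownames(mts) <- NULL
  }
  gt_path <- paste0(stem, "_ground_truth.tsv")
  ts_path <- paste0(stem, "_truth_segments.tsv")
  out <- list(tracks = tracks, microtubules = mts,
              ground_truth = if (file.exists(gt_path)) read_tsv(gt_path),
              truth_segments = if (file.exists(ts_path)) read_tsv(ts_path),
              config = NULL)
  class(out) <- "track_set"
  out
}

#' Read a dual-colour counts table
#'
#' Expects columns `n_dual`, `n_A_only`, `n_B_only` and optionally
#' `n_undetected` and `condition`; one row per condition. Counts in multiple
#' rows of the same condition (e.g. per microtubule) are summed.
#'
#' @param path TSV file path.
#' @return A list of [dual_colour_counts()] objects, one per condition.
#' @export
read_dual_counts <- function(path) {
  d <- read_tsv(path)
  need <- c("n_dual", "n_A_only", "n_B_only")
  if (!all(need %in% names(d)))
    stop(sprintf("counts table %s must contain columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (is.null(d$condition)) d$condition <- "all"
  lapply(split(d, d$condition), function(g) {
    dual_colour_counts(sum(g$n_dual), sum(g$n_A_only), sum(g$n_B_only),
                       n_undetected = if (!is.null(g$n_undetected))
                         sum(g$n_undetected) else NA_integer_,
                       condition = g$condition[1])
  })
}
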