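#' Render a synthetic kymograph for one microtubule
#'
#' Builds a time-versus-position intensity image from the tracks of one
#' microtubule: each sampled particle position contributes a Gaussian
#' intensity profile across the position axis of its frame's row, on top of a
#' constant background. Rows span the full movie; columns discretise the
#' microtubule at the configured pixel size.
#'
#' @param trackset A `track_set`.
#' @param mt_id Microtubule identifier present in the set.
#' @param intensity_params List with `amplitude` (peak counts per particle,
#'   default 100), `psf_sigma` (Gaussian spot SD in um, default 0.13),
#'   `background` (counts, default 10) and `max_value` (clip ceiling,
#'   default 255).
#' @return A numeric matrix (frames x pixels) of class `kymograph`, with
#'   nonnegative values clipped at `max_value`; pixel size and frame interval
#'   stored as attributes.
#' @seealso [write_kymograph()]
#' @export
render_kymograph <- function(trackset, mt_id,
                             intensity_params = list()) {
  stopifnot(inherits(trackset, "track_set"))
  ip <- utils::modifyList(list(amplitude = 100, psf_sigma = 0.13,
                               background = 10, max_value = 255),
                          intensity_params)
  mts <- trackset$microtubules
  if (!mt_id %in% mts$mt_id)
    stop(sprintf("unknown microtubule id '%s'", mt_id), call. = FALSE)
  cfg <- trackset$config
  px <- cfg$pixel_size
  dt <- cfg$frame_interval
  L <- mts$length_um[mts$mt_id == mt_id]
  n_cols <- max(1L, ceiling(L / px))
  n_rows <- max(1L, floor(cfg$movie_duration / dt))
  img <- matrix(ip$background, nrow = n_rows, ncol = n_cols)
  centres <- (seq_len(n_cols) - 0.5) * px

  tr <- trackset$tracks[trackset$tracks$mt_id == mt_id, , drop = FALSE]
  if (nrow(tr) > 0) {
    rows <- tr$frame_index + 1L
    ok <- rows >= 1L & rows <= n_rows
    for (i in which(ok)) {
      prof <- ip$amplitude *
        exp(-(centres - tr$position_um[i])^2 / (2 * ip$psf_sigma^2))
      img[rows[i], ] <- img[rows[i], ] + prof
    }
  }
  img <- pmin(pmax(img, 0), ip$max_value)
  attr(img, "pixel_size_um") <- px
  attr(img, "frame_interval_s") <- dt
  attr(img, "mt_id") <- mt_id
  class(img) <- c("kymograph", class(img))
  img
}

#' Write a kymograph as a single-channel TIFF
#'
#' @param kymo A `kymograph` matrix from [render_kymograph()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- unclass(kymo)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 16L)
  invisible(path)
}
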