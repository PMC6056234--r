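#' Background-corrected per-microtubule event counts
#'
#' Binding to the coverslip glass inflates per-microtubule event counts.
#' Background is quantified from kymographs of microtubule-free regions of
#' length equal to the median microtubule length; the mean background count
#' is scaled linearly to each microtubule's length and subtracted, flooring
#' at zero.
#'
#' @param events Events data.frame from [classify_tracks()] (or a
#'   `motility_result`).
#' @param microtubules Microtubule table with `mt_id` and `length_um`.
#' @param background Background event counts from microtubule-free regions
#'   sampled at the median microtubule length: either a numeric vector of
#'   binding-event counts per region, or a data.frame with columns
#'   `n_binding` and optionally `n_processive`. `NULL` skips the correction
#'   with a warning.
#' @return Data.frame with one row per microtubule: raw binding and
#'   processive counts, the expected background for that length, and the
#'   floored corrected counts. Microtubules with no events get zero raw
#'   counts.
#' @export
count_events <- function(events, microtubules, background = NULL) {
  if (inherits(events, "motility_result")) events <- events$events
  stopifnot(is.data.frame(microtubules),
            all(c("mt_id", "length_um") %in% names(microtubules)))
  mts <- microtubules
  n_bind <- n_proc <- stats::setNames(rep(0L, nrow(mts)), mts$mt_id)
  if (!is.null(events) && nrow(events) > 0) {
    tb <- table(events$mt_id)
    n_bind[names(tb)] <- as.integer(tb)
    tp <- table(events$mt_id[events$category == "processive"])
    n_proc[names(tp)] <- as.integer(tp)
  }
  out <- data.frame(mt_id = mts$mt_id, length_um = mts$length_um,
                    n_binding = as.integer(n_bind),
                    n_processive = as.integer(n_proc),
                    stringsAsFactors = FALSE)
  if (is.null(background)) {
    warning("no background regions supplied; returning uncorrected counts")
    out$bg_binding_expected <- 0
    out$bg_processive_expected <- 0
    out$n_binding_corrected <- out$n_binding
    out$n_processive_corrected <- out$n_processive
    return(out)
  }
  if (is.numeric(background))
    background <- data.frame(n_binding = background, n_processive = 0)
  stopifnot(is.data.frame(background), "n_binding" %in% names(background))
  if (is.null(background$n_processive)) background$n_processive <- 0
  med_len <- stats::median(mts$length_um)
  scale <- out$length_um / med_len
  out$bg_binding_expected <- mean(background$n_binding) * scale
  out$bg_processive_expected <- mean(background$n_processive) * scale
  out$n_binding_corrected <- pmax(out$n_binding - out$bg_binding_expected, 0)
  out$n_processive_corrected <-
    pmax(out$n_processive - out$bg_processive_expected, 0)
  out
}
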