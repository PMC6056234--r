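#' Extract eligible run lengths from processive events
#'
#' Run lengths (total displacement of a particle's run, regardless of
#' velocity changes or pauses) are kept only for events whose measurement is
#' not badly censored: either the entire run was observed (the particle
#' appeared after the movie started, disappeared before it ended, and did not
#' arrest at the minus end), or the run began more than `min_start_distance`
#' from the microtubule minus end.
#'
#' @param events Events data.frame from [classify_tracks()] (or a
#'   `motility_result`).
#' @param min_start_distance Minimum start distance from the minus end (um)
#'   for truncated runs to remain eligible (default 5).
#' @return Numeric vector of eligible run lengths (um); empty if none. The
#'   eligibility mask is attached as attribute `"eligible"` (indexed by the
#'   processive events).
#' @export
extract_run_lengths <- function(events, min_start_distance = 5) {
  if (inherits(events, "motility_result")) events <- events$events
  if (is.null(events) || nrow(events) == 0) return(numeric(0))
  pr <- events[events$category == "processive", , drop = FALSE]
  if (nrow(pr) == 0) return(numeric(0))
  eligible <- pr$fully_observed |
    (pr$start_dist_minus_um > min_start_distance)
  out <- pr$run_length_um[eligible]
  attr(out, "eligible") <- eligible
  out
}

#' One-phase exponential fit to the run-length survival curve
#'
#' Fits `1 - CDF(x) = exp(-x / scale)` to the empirical survival function of
#' the run lengths by least squares, mirroring the conventional presentation
#' of single-molecule run-length data. The fitted scale is a display
#' quantity: statistical comparisons between groups should use the raw run
#' lengths (e.g. via [compare_conditions()]), not fitted scales.
#'
#' @param run_lengths Numeric vector of run lengths (um), at least 10.
#' @return An object of class `decay_fit`: `scale` (um), `n_runs`,
#'   `fit_domain` (range of the data) and `poorly_conditioned` (degenerate
#'   input, e.g. all runs identical).
#' @examples
#' fit_decay(stats::rexp(200, 1 / 5))
#' @export
fit_decay <- function(run_lengths) {
  x <- as.numeric(run_lengths)
  if (any(!is.finite(x)) || any(x < 0))
    stop("run lengths must be finite and nonnegative", call. = FALSE)
  n <- length(x)
  if (n < 10)
    stop(sprintf("insufficient data: %d runs supplied, >= 10 required", n),
         call. = FALSE)
  x <- sort(x)
  surv <- (n - seq_len(n)) / n          # P(run > x_(i))
  obj <- function(s) sum((surv - exp(-x / s))^2)
  upper <- max(mean(x), max(x)) * 100
  opt <- stats::optimize(obj, interval = c(1e-9, upper), tol = 1e-10)
  poorly <- length(unique(x)) < 3 || stats::sd(x) == 0
  if (poorly)
    warning("run-length distribution is degenerate; fit is poorly conditioned")
  out <- list(scale = opt$minimum, n_runs = n, fit_domain = range(x),
              poorly_conditioned = poorly)
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> 1-CDF ~ exp(-x / %.3g um), n = %d runs, domain %.2f-%.2f um%s\n",
              x$scale, x$n_runs, x$fit_domain[1], x$fit_domain[2],
              if (x$poorly_conditioned) " [poorly conditioned]" else ""))
  invisible(x)
}
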