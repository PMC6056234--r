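# internal helpers shared across modules

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a single finite number")
  lo_ok <- if (allow_zero_lower) x >= lower else x > lower
  if (!lo_ok || x > upper)
    stop_config(field, sprintf("must lie in %s%g, %g]",
                               if (allow_zero_lower) "[" else "(", lower, upper))
  invisible(x)
}

check_probability <- function(x, field) check_number(x, field, 0, 1)

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x))
    stop_config(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# inverse-CDF truncated normal, lower bound only (vectorised)
rtnorm_lower <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  p0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
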