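# Independent oracles used to freeze expected values.

# Exhaustive enumeration of dye outcomes for a k-copy complex: each
# polypeptide is A / B / unlabelled with probs (p*q, p*(1-q), 1-p).
enumerate_dual_distribution <- function(k, p, q) {
  probs <- c(A = p * q, B = p * (1 - q), none = 1 - p)
  grid <- expand.grid(rep(list(1:3), k))
  out <- c(dual = 0, A_only = 0, B_only = 0, undetected = 0)
  for (r in seq_len(nrow(grid))) {
    states <- as.integer(grid[r, ])
    pr <- prod(probs[states])
    nA <- sum(states == 1L); nB <- sum(states == 2L)
    cat_ <- if (nA > 0 && nB > 0) "dual" else if (nA > 0) "A_only" else
      if (nB > 0) "B_only" else "undetected"
    out[cat_] <- out[cat_] + pr
  }
  out
}

# Brute-force single-changepoint least-squares segmentation: best split of
# points into two runs of >= mlen, by total RSS; returns the index of the
# first point of the second segment (or NA if one segment is better
# than every split by margin `penalty`).
brute_force_changepoint <- function(t, x, mlen = 3) {
  n <- length(t)
  rss_lm <- function(i, j) {
    if (j - i + 1 < 2) return(0)
    sum(stats::resid(stats::lm(x[i:j] ~ t[i:j]))^2)
  }
  best <- Inf; arg <- NA_integer_
  for (s in seq.int(mlen + 1L, n - mlen + 1L)) {
    r <- rss_lm(1L, s - 1L) + rss_lm(s, n)
    if (r < best) { best <- r; arg <- s }
  }
  list(split = arg, rss = best, rss_single = rss_lm(1L, n))
}

# Closed-form mean of eligible observed run lengths for starts ~ U(0, L),
# true runs ~ Exp(mu), observed = min(run, start), no movie truncation.
# Eligible = fully observed (run < start) OR start > d_min.
censored_run_oracle <- function(L, mu, d_min) {
  # E[R 1(R < x)] = mu - (mu + x) exp(-x/mu); P(R < x) = 1 - exp(-x/mu)
  contrib_full <- stats::integrate(function(x)
    (mu - (mu + x) * exp(-x / mu)) / L, 0, d_min)$value
  contrib_far <- stats::integrate(function(x)
    mu * (1 - exp(-x / mu)) / L, d_min, L)$value
  p_elig <- stats::integrate(function(x)
    (1 - exp(-x / mu)) / L, 0, d_min)$value + (L - d_min) / L
  mean_all <- stats::integrate(function(x)
    mu * (1 - exp(-x / mu)) / L, 0, L)$value
  list(mean_eligible = (contrib_full + contrib_far) / p_elig,
       mean_all = mean_all)
}

# deterministic piecewise-linear test track
make_track <- function(t, x, mt_id = "mt01", track_id = "trk1",
                       channel = "ch1") {
  data.frame(mt_id = mt_id, track_id = track_id, channel = channel,
             frame_index = seq_along(t) - 1L, time_s = t, position_um = x,
             stringsAsFactors = FALSE)
}

mt_table <- function(length_um = 20, mt_id = "mt01", minus_end = 0) {
  data.frame(mt_id = mt_id, length_um = length_um,
             minus_end_position_um = minus_end, stringsAsFactors = FALSE)
}
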