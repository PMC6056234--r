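#!/usr/bin/env Rscript
# Step 3 — two-colour co-transport. Emulates the two-channel experiment in
# which most processive particles of one channel travel together with a
# particle of the other channel: 75% of channel-2 tracks are duplicates of
# channel-1 tracks (50 nm registration jitter), the rest move independently.
# The co-localisation scorer should recover the planted fraction.

library(rnptransport)

out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(7)
n <- 200
planted <- 0.75

mk_track <- function(i, ch, vel) {
  t0 <- sample(0:80, 1) * 0.5
  tt <- t0 + seq(0, 4.5, by = 0.5)
  x0 <- runif(1, 6, 18)
  data.frame(mt_id = sprintf("mt%02d", (i %% 6) + 1),
             track_id = sprintf("%s_%03d", ch, i), channel = ch,
             frame_index = as.integer(tt / 0.5),
             time_s = tt,
             position_um = x0 + vel * (tt - t0) + rnorm(length(tt), 0, 0.02))
}

ch1 <- lapply(seq_len(n), mk_track, ch = "ch1", vel = -1)
ch2 <- lapply(seq_len(n), function(i) {
  if (i <= planted * n) {
    d <- ch1[[i]]
    d$position_um <- d$position_um + rnorm(nrow(d), 0, 0.05)
    d$track_id <- sprintf("ch2_%03d", i)
    d$channel <- "ch2"
    d
  } else mk_track(i + 1000, ch = "ch2", vel = 1)  # independent traffic
})

cl <- colocalize(do.call(rbind, ch1), do.call(rbind, ch2),
                 max_gap = 0.21, min_overlap_fraction = 0.5)
utils::write.table(cl$per_mt, file.path(out, "demo_coloc_per_mt.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("planted co-transport fraction: %.2f", planted))
message(sprintf("recovered: %.3f of channel-2 tracks co-localise with channel 1 (%d pairs)",
                cl$pooled["frac_B_coloc"], nrow(cl$pairs)))
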