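#' Simulation configuration for synthetic track sets
#'
#' Bundles and validates the parameters of the trajectory generator. Defaults
#' mirror a typical reconstituted minus-end transport assay imaged by TIRF
#' microscopy at ~2 frames per second with 105 nm pixels: a field of
#' microtubules, a mixture of static, diffusive and processive particles,
#' exponential run lengths for the processive class and Gaussian localisation
#' noise on every sampled position. The minus end of every microtubule sits at
#' coordinate 0 and processive particles move toward it (decreasing
#' coordinate).
#'
#' @param n_microtubules Number of microtubules in the field.
#' @param mt_length_mean,mt_length_sd Mean and SD of microtubule length (um);
#'   lengths are drawn from a normal truncated below at 1 um.
#' @param tracks_per_mt_mean Mean number of tracks per microtubule (Poisson).
#' @param class_probs Probabilities of the (static, diffusive, processive)
#'   classes; must be nonnegative and sum to 1.
#' @param velocity_mean,velocity_sd Mean and SD of per-segment speed
#'   (um/s, toward the minus end); speeds are drawn from a normal truncated
#'   below at 0.
#' @param segment_switch_rate Rate (events/s) at which a processive particle
#'   switches to a freshly drawn segment speed.
#' @param run_length_mean Mean of the exponential run-length distribution (um)
#'   governing processive detachment.
#' @param diffusion_coeff Diffusion coefficient of the diffusive class
#'   (um^2/s).
#' @param attach_duration_mean Mean attachment duration (s, exponential) of
#'   static and diffusive particles. Processive particles detach via their run
#'   length (or arrest at the minus end) instead.
#' @param frame_interval Sampling interval (s). Default 0.5 s.
#' @param pixel_size Pixel size (um). Default 0.105 um.
#' @param localisation_sd Gaussian localisation noise SD (um) added to every
#'   sampled position.
#' @param movie_duration Movie length (s).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_trackset()]
#' @export
sim_config <- function(n_microtubules = 10,
                       mt_length_mean = 14,
                       mt_length_sd = 3,
                       tracks_per_mt_mean = 15,
                       class_probs = c(static = 0.35, diffusive = 0.25,
                                       processive = 0.40),
                       velocity_mean = 1.0,
                       velocity_sd = 0.25,
                       segment_switch_rate = 0.1,
                       run_length_mean = 5,
                       diffusion_coeff = 0.05,
                       attach_duration_mean = 6,
                       frame_interval = 0.5,
                       pixel_size = 0.105,
                       localisation_sd = 0.05,
                       movie_duration = 60,
                       seed = 1L) {
  check_count(n_microtubules, "n_microtubules", min = 1L)
  check_number(mt_length_mean, "mt_length_mean", lower = 0,
               allow_zero_lower = FALSE)
  check_number(mt_length_sd, "mt_length_sd", lower = 0)
  check_number(tracks_per_mt_mean, "tracks_per_mt_mean", lower = 0)
  if (!is.numeric(class_probs) || length(class_probs) != 3L ||
      any(!is.finite(class_probs)) || any(class_probs < 0))
    stop_config("class_probs", "must be 3 nonnegative finite probabilities")
  if (abs(sum(class_probs) - 1) > 1e-12)
    stop_config("class_probs", "must sum to 1 (within 1e-12)")
  check_number(velocity_mean, "velocity_mean", lower = 0)
  check_number(velocity_sd, "velocity_sd", lower = 0)
  check_number(segment_switch_rate, "segment_switch_rate", lower = 0)
  check_number(run_length_mean, "run_length_mean", lower = 0,
               allow_zero_lower = FALSE)
  check_number(diffusion_coeff, "diffusion_coeff", lower = 0)
  check_number(attach_duration_mean, "attach_duration_mean", lower = 0,
               allow_zero_lower = FALSE)
  check_number(frame_interval, "frame_interval", lower = 0,
               allow_zero_lower = FALSE)
  check_number(pixel_size, "pixel_size", lower = 0, allow_zero_lower = FALSE)
  check_number(localisation_sd, "localisation_sd", lower = 0)
  check_number(movie_duration, "movie_duration", lower = 0,
               allow_zero_lower = FALSE)
  seed <- check_count(seed, "seed")

  names(class_probs) <- c("static", "diffusive", "processive")
  cfg <- list(
    n_microtubules = as.integer(n_microtubules),
    mt_length_mean = mt_length_mean, mt_length_sd = mt_length_sd,
    tracks_per_mt_mean = tracks_per_mt_mean,
    class_probs = class_probs,
    velocity_mean = velocity_mean, velocity_sd = velocity_sd,
    segment_switch_rate = segment_switch_rate,
    run_length_mean = run_length_mean,
    diffusion_coeff = diffusion_coeff,
    attach_duration_mean = attach_duration_mean,
    frame_interval = frame_interval, pixel_size = pixel_size,
    localisation_sd = localisation_sd,
    movie_duration = movie_duration, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d microtubules (length %.1f +/- %.1f um), ~%.0f tracks each\n",
              x$n_microtubules, x$mt_length_mean, x$mt_length_sd,
              x$tracks_per_mt_mean))
  cat(sprintf("  class probs: static %.2f / diffusive %.2f / processive %.2f\n",
              x$class_probs[1], x$class_probs[2], x$class_probs[3]))
  cat(sprintf("  movie %.0f s @ %.2f s/frame, noise %.3f um, seed %d\n",
              x$movie_duration, x$frame_interval, x$localisation_sd, x$seed))
  invisible(x)
}

#' Stochastic dye-assignment model for dual-colour labelling
#'
#' Describes how fluorophores are attached to the molecules of a complex.
#' Two modes are supported. `"binomial_snap"`: each polypeptide of a complex
#' independently carries a dye with probability `p_label` (the SNAP-tag
#' labelling efficiency) and a labelled polypeptide carries dye A with
#' probability `q_dyeA`, otherwise dye B. `"poisson_body"`: each RNA molecule
#' originates from the colour-A preparation with probability
#' `colourA_fraction` and carries a Poisson(`poisson_mean`) number of dyes of
#' its preparation's colour; it is detectable iff it carries at least one dye.
#'
#' @param mode `"binomial_snap"` or `"poisson_body"`.
#' @param p_label Per-polypeptide labelling probability (binomial mode).
#' @param q_dyeA Probability that a label is dye A (binomial mode).
#' @param poisson_mean Mean dyes per RNA molecule (poisson mode).
#' @param colourA_fraction Fraction of RNA molecules from the colour-A
#'   preparation (poisson mode).
#' @return An object of class `labeling_model`.
#' @examples
#' labeling_model("binomial_snap", p_label = 0.9, q_dyeA = 0.5)
#' labeling_model("poisson_body", poisson_mean = 3)
#' @export
labeling_model <- function(mode = c("binomial_snap", "poisson_body"),
                           p_label = 0.9, q_dyeA = 0.5,
                           poisson_mean = 3, colourA_fraction = 0.5) {
  mode <- match.arg(mode)
  check_probability(p_label, "p_label")
  check_probability(q_dyeA, "q_dyeA")
  check_number(poisson_mean, "poisson_mean", lower = 0)
  check_probability(colourA_fraction, "colourA_fraction")
  m <- list(mode = mode, p_label = p_label, q_dyeA = q_dyeA,
            poisson_mean = poisson_mean,
            colourA_fraction = colourA_fraction)
  class(m) <- "labeling_model"
  m
}

#' @export
print.labeling_model <- function(x, ...) {
  if (x$mode == "binomial_snap")
    cat(sprintf("<labeling_model> binomial SNAP: p_label = %.3g, q_dyeA = %.3g\n",
                x$p_label, x$q_dyeA))
  else
    cat(sprintf("<labeling_model> Poisson body-labelled RNA: mean %.3g dyes, colour-A fraction %.3g\n",
                x$poisson_mean, x$colourA_fraction))
  invisible(x)
}
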