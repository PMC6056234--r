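#' End-to-end pipeline configuration
#'
#' Collects everything one run needs: either a simulation configuration or
#' paths to existing track tables (exactly one input source), classification
#' parameters, optional stoichiometry inputs, an output directory and a seed.
#' Can also be loaded from a YAML or JSON document via [load_run_config()].
#'
#' @param out_dir Directory for intermediate tables and the report.
#' @param seed Integer seed applied to every stochastic stage.
#' @param sim A [sim_config()] to simulate input tracks, or `NULL`.
#' @param tracks_path Path to an existing track table, or `NULL`. Exactly one
#'   of `sim` / `tracks_path` must be given for the motility stages; both
#'   `NULL` is allowed when only the stoichiometry stage runs.
#' @param params A [classify_params()] object.
#' @param classify,kinetics Logical stage flags (classification; velocity /
#'   run-length kinetics).
#' @param coloc `NULL`, or a list with a second channel's simulation or path
#'   (`sim` or `tracks_path`) to run co-localisation against.
#' @param stoich `NULL`, or a list with `model` (a [labeling_model()]),
#'   `counts` (a [dual_colour_counts()] or path to a counts table) and
#'   optionally `q_dyeA`, `p_label`, `poisson_mean` overrides.
#' @param write_intermediates Write stage outputs as TSV under `out_dir`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("rnprun"), seed = 1L,
                       sim = sim_config(), tracks_path = NULL,
                       params = classify_params(),
                       classify = TRUE, kinetics = TRUE,
                       coloc = NULL, stoich = NULL,
                       write_intermediates = TRUE) {
  if (!is.null(sim) && !is.null(tracks_path))
    stop_config("sim/tracks_path",
                "exactly one input source per stage: supply either a simulation config or a tracks path, not both")
  if (is.null(sim) && is.null(tracks_path) && (classify || kinetics))
    stop_config("sim/tracks_path",
                "motility stages need an input source (simulation config or tracks path)")
  if (!is.null(tracks_path) && !file.exists(tracks_path))
    stop_config("tracks_path", sprintf("file '%s' not found", tracks_path))
  seed <- check_count(seed, "seed")
  cfg <- list(out_dir = out_dir, seed = seed, sim = sim,
              tracks_path = tracks_path, params = params,
              classify = isTRUE(classify), kinetics = isTRUE(kinetics),
              coloc = coloc, stoich = stoich,
              write_intermediates = isTRUE(write_intermediates))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' The document may contain `seed`, `out_dir`, nested `sim` (fields of
#' [sim_config()]), `params` (fields of [classify_params()]), `tracks_path`,
#' stage flags, and a `stoich` block (`mode`, `p_label`, `q_dyeA`,
#' `poisson_mean`, `counts_path`).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list(...)
  take <- function(nm) args[[nm]] %||% doc[[nm]]
  stoich <- take("stoich")
  if (!is.null(stoich) && is.null(stoich$model))
    stoich$model <- labeling_model(
      mode = stoich$mode %||% "binomial_snap",
      p_label = stoich$p_label %||% 0.9,
      q_dyeA = stoich$q_dyeA %||% 0.5,
      poisson_mean = stoich$poisson_mean %||% 3)
  run_config(
    out_dir = take("out_dir") %||% tempfile("rnprun"),
    seed = take("seed") %||% 1L,
    sim = if (!is.null(doc$sim) || !is.null(args$sim))
      do.call(sim_config, as.list(take("sim"))) else
        if (is.null(take("tracks_path"))) sim_config() else NULL,
    tracks_path = take("tracks_path"),
    params = if (!is.null(doc$params) || !is.null(args$params))
      do.call(classify_params, as.list(take("params"))) else
        classify_params(),
    classify = take("classify") %||% TRUE,
    kinetics = take("kinetics") %||% TRUE,
    coloc = take("coloc"),
    stoich = stoich,
    write_intermediates = take("write_intermediates") %||% TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or read) tracks, classify binding events,
#' kinetics (segmental velocities, event counts, run-length extraction and
#' survival fit), optional two-channel co-localisation, optional
#' copy-number stoichiometry. All intermediates are written as TSV under
#' `config$out_dir` (unless disabled) and the per-stage tables are collected
#' into a report with a provenance block. The run is fully deterministic
#' given the configuration and seed.
#'
#' @param config A [run_config()] (or a path accepted by
#'   [load_run_config()]).
#' @return An object of class `rnp_report`: a list of stage tables plus
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (config$write_intermediates && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list()
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] records in: %d, out: %d", stage, n_in, n_out))
  }

  # --- input stage -------------------------------------------------------
  trackset <- NULL
  if (config$classify || config$kinetics) {
    trackset <- run_stage("input", {
      if (!is.null(config$sim)) {
        sim <- config$sim
        sim$seed <- config$seed
        ts <- simulate_trackset(sim)
        if (config$write_intermediates)
          write_tracks(ts, file.path(out_dir, "tracks.tsv"))
        ts
      } else read_tracks(config$tracks_path)
    })
    log_stage("input", 0L, nrow(trackset$tracks))
  }

  movie_dur <- if (!is.null(trackset$config))
    trackset$config$movie_duration else NULL

  # --- classification ----------------------------------------------------
  mot <- NULL
  if (config$classify) {
    mot <- run_stage("classify", classify_tracks(
      trackset, params = config$params, movie_duration = movie_dur))
    log_stage("classify", length(unique(trackset$tracks$track_id)),
              if (is.null(mot$events)) 0L else nrow(mot$events))
    report$events <- mot$events
    report$segments <- mot$segments
    fr <- motility_fractions(mot)
    report$fractions_per_mt <- fr$per_mt
    report$fractions_pooled <- fr$pooled
    report$counts <- run_stage("counts", suppressWarnings(
      count_events(mot, trackset$microtubules)))
    if (config$write_intermediates) {
      if (!is.null(mot$events))
        write_tsv_full(mot$events, file.path(out_dir, "events.tsv"))
      if (!is.null(mot$segments))
        write_tsv_full(mot$segments, file.path(out_dir, "segments.tsv"))
      write_tsv_full(report$counts, file.path(out_dir, "counts_per_mt.tsv"))
    }
  }

  # --- kinetics ----------------------------------------------------------
  if (config$kinetics && !is.null(mot)) {
    runs <- run_stage("kinetics", extract_run_lengths(mot))
    log_stage("kinetics",
              if (is.null(mot$events)) 0L else
                sum(mot$events$category == "processive"),
              length(runs))
    report$run_lengths <- as.numeric(runs)
    report$decay_fit <- if (length(runs) >= 10) fit_decay(runs) else NULL
    if (!is.null(mot$segments)) {
      vseg <- mot$segments[!mot$segments$is_pause, , drop = FALSE]
      report$velocity_summary <- data.frame(
        n_segments = nrow(vseg),
        mean_speed_um_s = mean(abs(vseg$velocity_um_s)),
        sd_speed_um_s = stats::sd(abs(vseg$velocity_um_s)))
    }
  }

  # --- co-localisation ---------------------------------------------------
  if (!is.null(config$coloc)) {
    second <- run_stage("coloc", {
      if (!is.null(config$coloc$sim)) {
        sim2 <- config$coloc$sim
        sim2$seed <- config$seed + 1L
        simulate_trackset(sim2, channel = "ch2")
      } else read_tracks(config$coloc$tracks_path)
    })
    cl <- run_stage("coloc", colocalize(trackset$tracks, second$tracks))
    log_stage("coloc", nrow(cl$per_mt), nrow(cl$pairs))
    report$coloc_pairs <- cl$pairs
    report$coloc_per_mt <- cl$per_mt
    report$coloc_pooled <- cl$pooled
  }

  # --- stoichiometry -----------------------------------------------------
  if (!is.null(config$stoich)) {
    st <- config$stoich
    counts <- st$counts
    if (is.character(counts)) counts <- read_dual_counts(counts)[[1]]
    model <- st$model %||% labeling_model()
    est <- run_stage("stoich", {
      if (model$mode == "binomial_snap")
        infer_two_copy_fraction(counts, p_label = model$p_label,
                                q_dyeA = model$q_dyeA, seed = config$seed)
      else
        infer_rna_mixture(counts, poisson_mean = model$poisson_mean,
                          colourA_fraction = model$colourA_fraction,
                          seed = config$seed)
    })
    log_stage("stoich", counts$n_dual + counts$n_A_only + counts$n_B_only, 1L)
    report$copy_number <- est
    report$copy_number_table <- data.frame(
      model = est$model, n_obs = est$n_obs,
      two_copy_fraction = est$two_copy_fraction,
      one_copy_fraction = est$one_copy_fraction,
      ci_low = est$ci_low, ci_high = est$ci_high,
      out_of_model = est$out_of_model)
    if (config$write_intermediates)
      write_tsv_full(report$copy_number_table,
                     file.path(out_dir, "copy_number.tsv"))
  }

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("rnptransport")),
    seed = config$seed,
    config_json = config_fingerprint(config))
  class(report) <- "rnp_report"
  report
}

# run one stage, naming it on failure but keeping earlier outputs on disk
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

# canonical JSON of the configuration; uniquely identifies a run's inputs
# (output location is not an input and is excluded)
config_fingerprint <- function(config) {
  config$out_dir <- NULL
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  as.character(jsonlite::toJSON(strip(unclass(config)), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

#' @export
print.rnp_report <- function(x, ...) {
  cat("<rnp_report>\n")
  if (!is.null(x$events))
    cat(sprintf("  %d binding events; pooled fractions: %s\n",
                nrow(x$events),
                paste(sprintf("%s %.2f", names(x$fractions_pooled),
                              x$fractions_pooled), collapse = ", ")))
  if (!is.null(x$decay_fit))
    cat(sprintf("  run-length decay scale: %.2f um (n = %d)\n",
                x$decay_fit$scale, x$decay_fit$n_runs))
  if (!is.null(x$coloc_pooled))
    cat(sprintf("  co-localised fractions: A %.2f / B %.2f\n",
                x$coloc_pooled[1], x$coloc_pooled[2]))
  if (!is.null(x$copy_number)) print(x$copy_number)
  cat(sprintf("  seed %d, rnptransport %s\n", x$provenance$seed,
              x$provenance$package_version))
  invisible(x)
}
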