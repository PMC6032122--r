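# End-to-end orchestration: synth -> preprocess -> detect -> fit -> resample
# -> drift -> gain model, with TSV outputs and a JSON run manifest.

# polynomial rolling hash of a character scalar (no external digest
# dependency; doubles hold the 31-bit state exactly)
str_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  cfg <- config
  cfg$template <- unclass(cfg$template)
  str_hash(paste(utils::capture.output(utils::str(unclass(cfg), digits.d = 12)),
                 collapse = "\n"))
}

#' Run the full analysis chain on a synthetic session
#'
#' Generates a seeded synthetic session, renders a trace segment for
#' detection-based stages, detects microsaccades, attaches latencies, runs
#' the global psychometric fit, the sensitivity timecourse, the suppression
#' and facilitation window CSFs, the orientation partition, the drift
#' timecourse, and the gain-model delay sweep. All tables are written as TSV
#' under `out_dir` with a JSON manifest; reruns with the same config and seed
#' reproduce identical outputs.
#'
#' @param config a [synth_config()]; `config$seed` drives all randomness.
#' @param out_dir output directory (created); NULL skips writing.
#' @param trace_duration seconds of 500-Hz trace rendered for the
#'   detection/drift stages (a separate, shorter segment than the full trial
#'   session), default 300.
#' @param timecourse_step sliding-bin step for the sensitivity timecourse,
#'   seconds; the default 0.01 is coarser than the 0.002 used for figures, to
#'   keep routine runs fast.
#' @param n_match subject-matched baseline replicates.
#' @return list with all stage outputs plus `manifest`.
#' @export
run_all <- function(config, out_dir = NULL, trace_duration = 300,
                    timecourse_step = 0.01, n_match = 50) {
  stopifnot(inherits(config, "synth_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  # --- synth: trial session (ground-truth events) + detection trace segment
  sess <- simulate_session(config)
  log_stage("synth", "%d trials, %d ground-truth microsaccades",
            nrow(sess$trials), nrow(sess$events))
  cfg_trace <- config
  cfg_trace$seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  cfg_trace$session_duration <- trace_duration
  tr <- generate_trace(cfg_trace)

  # --- preprocess + detect on the trace segment
  trace <- mask_blinks(tr$trace)
  detected <- detect_microsaccades(trace)
  log_stage("detect", "%d events detected (%d true)", nrow(detected),
            nrow(tr$events))
  ms <- if (nrow(detected) >= 3) main_sequence(detected) else NULL
  dirs <- if (nrow(detected) >= 1) direction_histogram(detected) else NULL

  # --- trials: blink exclusion, then latency from the ground-truth events
  blink_samples <- if (nrow(sess$blinks) > 0)
    unlist(lapply(seq_len(nrow(sess$blinks)), function(i)
      seq(sess$blinks$onset_s[i], sess$blinks$offset_s[i], by = 0.002)))
  else numeric(0)
  excl <- exclude_blink_trials(sess$trials, blink_samples)
  log_stage("preprocess", "blink exclusion removed %.1f%% of trials",
            100 * excl$fraction_removed)
  trials <- attach_latency(excl$trials, sess$events)
  lat_hist <- latency_histogram(trials)

  # --- psychometric pipeline
  frozen <- global_fit(trials)
  log_stage("fit", "lapse %.3f", frozen$lapse)
  tc <- sensitivity_timecourse(trials, frozen, step = timecourse_step,
                               n_match = n_match, rng = config$seed)
  csf_supp <- window_csf(trials, frozen, c(-0.1, 0.05), n_match = n_match,
                         rng = config$seed)
  csf_fac <- window_csf(trials, frozen, c(0.05, 0.2), n_match = n_match,
                        rng = config$seed)
  supp_trials <- trials[trials$tau_s >= -0.1 & trials$tau_s < 0.05 &
                          !is.na(trials$event_direction_deg), , drop = FALSE]
  orient <- if (nrow(supp_trials) >= 50)
    orientation_partition(supp_trials, frozen) else NULL

  # --- drift on the trace segment
  drift <- if (nrow(detected) >= 5) drift_timecourse(trace, detected) else NULL

  # --- gain model
  sweep <- sweep_delay(gain_params())

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fixsens")),
    n_trials = nrow(trials),
    blink_exclusion_fraction = excl$fraction_removed,
    n_true_events = nrow(sess$events),
    n_detected_events = nrow(detected),
    trace_duration_s = trace_duration,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = character(0)
  )

  out <- list(trials = trials, events = sess$events, detected = detected,
              main_sequence = ms, direction_histogram = dirs,
              latency_histogram = lat_hist, frozen = frozen,
              timecourse = tc, csf_suppression = csf_supp,
              csf_facilitation = csf_fac, orientation = orient,
              drift = drift, gain_sweep = sweep, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name) {
      if (is.null(x)) return(invisible(NULL))
      p <- file.path(out_dir, name)
      write_tsv(x, p)
      manifest$outputs <<- c(manifest$outputs, name)
    }
    w(trials, "trials.tsv")
    w(sess$events, "events_true.tsv")
    w(detected, "events_detected.tsv")
    w(lat_hist, "latency_histogram.tsv")
    w(dirs, "direction_histogram.tsv")
    w(tc, "sensitivity_timecourse.tsv")
    w(csf_supp, "csf_suppression.tsv")
    w(csf_fac, "csf_facilitation.tsv")
    w(orient, "orientation_partition.tsv")
    if (!is.null(drift)) {
      w(drift$velocity, "drift_velocity.tsv")
      w(drift$boxcount, "drift_boxcount.tsv")
    }
    gm <- do.call(rbind, lapply(sweep, function(s) {
      data.frame(t_delay = s$t_delay, a_scaled = s$a_scaled,
                 peak_time = s$peak_time, peak_sf = s$peak_sf,
                 peak_sr = s$peak_sr)
    }))
    w(gm, "gain_model_sweep.tsv")
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Histogram of trial counts by microsaccade latency
#'
#' @param trials trial table with `tau_s`.
#' @param breaks bin edges, seconds.
#' @return data frame `bin_center_s`, `n_trials`.
#' @export
latency_histogram <- function(trials, breaks = seq(-0.5, 0.5, by = 0.05)) {
  tau <- trials$tau_s[is.finite(trials$tau_s)]
  tau <- tau[tau >= breaks[1] & tau <= breaks[length(breaks)]]
  nb <- length(breaks) - 1L
  counts <- tabulate(pmin(findInterval(tau, breaks), nb), nb)
  data.frame(bin_center_s = (breaks[-1] + breaks[-length(breaks)]) / 2,
             n_trials = counts)
}
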