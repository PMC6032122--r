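# Seeded synthetic fixation sessions: drift + main-sequence microsaccades +
# blinks rendered into binocular 500-Hz traces, and interleaved 1-up-3-down
# staircases driving a simulated observer whose log threshold is perturbed
# around microsaccades by a suppression/facilitation template.

#' Suppression/facilitation sensitivity template
#'
#' Ground-truth analogue of the microsaccade-locked log sensitivity-ratio
#' surface: per spatial frequency, a negative suppression Gaussian centred
#' just after microsaccade onset plus a positive facilitation Gaussian in the
#' post-movement period. Units are log10 sensitivity ratio.
#'
#' Default depths are the third-order polynomial of the gain model evaluated
#' at the five study frequencies (strongest suppression at 0.1 cycles/deg);
#' default facilitation peaks at 2 cycles/deg, centred 0.125 s after onset.
#'
#' @param sfs spatial frequencies, cycles/deg.
#' @param suppression_depth log10 units, one per sf, all `<= 0`.
#' @param suppression_center,suppression_width seconds.
#' @param facilitation_amp log10 units, one per sf, all `>= 0`.
#' @param facilitation_center,facilitation_width seconds.
#' @return object of class `sensitivity_template`.
#' @export
sensitivity_template <- function(
    sfs = FIXSENS_SFS,
    suppression_depth = sf_profile(log10(sfs)),
    suppression_center = 0.02, suppression_width = 0.067,
    facilitation_amp = c(0, 0, 0.04, 0.08, 0.03),
    facilitation_center = 0.125, facilitation_width = 0.05) {
  stopifnot(length(suppression_depth) == length(sfs),
            length(facilitation_amp) == length(sfs),
            all(suppression_depth <= 0), all(facilitation_amp >= 0),
            suppression_width > 0, facilitation_width > 0)
  structure(list(sfs = sfs,
                 suppression_depth = suppression_depth,
                 suppression_center = suppression_center,
                 suppression_width = suppression_width,
                 facilitation_amp = facilitation_amp,
                 facilitation_center = facilitation_center,
                 facilitation_width = facilitation_width),
            class = "sensitivity_template")
}

#' All-zero (null observer) template
#' @export
null_template <- function(sfs = FIXSENS_SFS) {
  sensitivity_template(sfs, suppression_depth = rep(0, length(sfs)),
                       facilitation_amp = rep(0, length(sfs)))
}

#' Evaluate the template log sensitivity ratio
#'
#' @param tau latency `t_stim - t_onset` in seconds (vectorised).
#' @param sf single spatial frequency, must be one of `template$sfs`.
#' @param template a [sensitivity_template()].
#' @return log10 sensitivity ratio (negative = suppression).
#' @export
template_sr <- function(tau, sf, template) {
  k <- match(sf, template$sfs)
  if (is.na(k)) stop("unknown spatial frequency: ", sf)
  supp <- template$suppression_depth[k] *
    exp(-((tau - template$suppression_center) / template$suppression_width)^2)
  fac <- template$facilitation_amp[k] *
    exp(-((tau - template$facilitation_center) / template$facilitation_width)^2)
  out <- supp + fac
  out[is.infinite(tau)] <- 0
  out
}

#' Synthetic-session configuration
#'
#' Defaults describe the study conditions: 500-Hz binocular recording,
#' microsaccades at 1.3/s (within the observed 0.3-2.3/s range) with
#' log-normal amplitudes bounded to 3-60 arcmin and a power-law main sequence,
#' Brownian drift, sparse blinks, inter-trial intervals uniform on 0.8-4.0 s,
#' five interleaved 1-up-3-down staircases stepping 0.05 log10 contrast, and a
#' logistic observer with the global-fit slope/lapse values.
#'
#' @param sampling_rate Hz.
#' @param session_duration seconds (ignored when `n_trials` is given).
#' @param n_trials optional exact trial count; the session grows to fit.
#' @param ms_rate microsaccades per second.
#' @param ms_refractory minimum onset-to-onset gap, seconds.
#' @param amplitude_meanlog,amplitude_sdlog log-normal amplitude parameters
#'   (natural log of arcmin), truncated to `amplitude_bounds`.
#' @param amplitude_bounds arcmin, default `c(3, 60)`.
#' @param ms_k,ms_b,ms_noise_sd main sequence `v_peak = k * A_deg^b *
#'   exp(N(0, noise_sd))`, v in deg/s.
#' @param drift_diffusion 2D diffusion coefficient, deg^2/s
#'   (`E|dr|^2 = D dt`).
#' @param eye_noise_sd per-eye, per-axis positional measurement noise, deg.
#' @param blink_rate,blink_duration events/s and seconds.
#' @param direction_kappa von Mises concentration of the horizontal
#'   (0/180 deg) direction mixture.
#' @param iti_range response-to-stimulus interval, seconds, uniform.
#' @param response_latency fixed simulated response time, seconds.
#' @param stair_start,stair_step initial log10 contrast and up/down step
#'   (log10 units) of the 1-up-3-down staircases.
#' @param sfs spatial frequencies, cycles/deg.
#' @param observer_mu,observer_s baseline log10-contrast thresholds and slopes
#'   per sf.
#' @param observer_lapse lapse rate.
#' @param template a [sensitivity_template()]; `null_template()` for a
#'   latency-independent observer.
#' @param seed integer or NULL.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(
    sampling_rate = 500, session_duration = 60, n_trials = NULL,
    ms_rate = 1.3, ms_refractory = 0.15,
    amplitude_meanlog = log(15), amplitude_sdlog = 0.55,
    amplitude_bounds = c(3, 60),
    ms_k = 100, ms_b = 1, ms_noise_sd = 0.15,
    drift_diffusion = 0.005, eye_noise_sd = 0.005,
    blink_rate = 0.1, blink_duration = 0.3,
    direction_kappa = 4,
    iti_range = c(0.8, 4.0), response_latency = 0.5,
    stair_start = -0.8, stair_step = 0.05,
    sfs = FIXSENS_SFS,
    observer_mu = c(-1.30, -1.70, -2.00, -1.92, -1.40),
    observer_s = c(0.105, 0.072, 0.094, 0.089, 0.144),
    observer_lapse = 0.055,
    template = sensitivity_template(sfs),
    seed = NULL) {
  if (sampling_rate <= 0) stop("invalid config: sampling_rate must be > 0")
  if (session_duration <= 0) stop("invalid config: session_duration must be > 0")
  if (ms_rate < 0) stop("invalid config: ms_rate must be >= 0")
  if (ms_rate > 0 && ms_refractory >= 1 / ms_rate)
    stop("invalid config: refractory period incompatible with ms_rate")
  stopifnot(amplitude_bounds[1] >= 3, amplitude_bounds[2] <= 60,
            stair_step > 0, length(observer_mu) == length(sfs),
            length(observer_s) == length(sfs))
  structure(as.list(environment()), class = "synth_config")
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy rejection scheme)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

# truncated log-normal amplitudes (arcmin), rejection sampling
r_amplitude <- function(n, meanlog, sdlog, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 8, meanlog, sdlog)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  out[seq_len(n)]
}

# ground-truth microsaccade event stream over [0, duration]
gen_events <- function(config, duration) {
  if (config$ms_rate <= 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), amplitude_arcmin = numeric(0),
                      peak_velocity_dps = numeric(0),
                      direction_deg = numeric(0)))
  # refractory-plus-exponential gaps with mean 1/rate
  exp_rate <- 1 / (1 / config$ms_rate - config$ms_refractory)
  n_guess <- ceiling(duration * config$ms_rate * 1.5) + 20
  gaps <- config$ms_refractory + stats::rexp(n_guess, exp_rate)
  onsets <- cumsum(gaps)
  while (sum(gaps) < duration) {
    g2 <- config$ms_refractory + stats::rexp(n_guess, exp_rate)
    gaps <- c(gaps, g2)
    onsets <- cumsum(gaps)
  }
  onsets <- onsets[onsets < duration - 0.1]
  n <- length(onsets)
  if (n == 0) return(gen_events(within_rate_zero(config), duration))
  amp <- r_amplitude(n, config$amplitude_meanlog, config$amplitude_sdlog,
                     config$amplitude_bounds)
  amp_deg <- amp / 60
  vpk <- config$ms_k * amp_deg^config$ms_b *
    exp(stats::rnorm(n, 0, config$ms_noise_sd))
  dur <- 2 * amp_deg / vpk           # raised-cosine profile: A = vpk * dur / 2
  horiz <- stats::runif(n) < 0.5
  dirs <- rvonmises(n, 0, config$direction_kappa)
  dirs[!horiz] <- (dirs[!horiz] + pi) %% (2 * pi)
  data.frame(onset_s = onsets, offset_s = onsets + dur, duration_s = dur,
             amplitude_arcmin = amp, peak_velocity_dps = vpk,
             direction_deg = dirs * 180 / pi)
}

within_rate_zero <- function(config) { config$ms_rate <- 0; config }

# raised-cosine displacement profile: s(u)/A for u = t/dur in [0,1]
raised_cosine_disp <- function(u) u - sin(2 * pi * u) / (2 * pi)

#' Render a binocular gaze trace with ground-truth microsaccades
#'
#' One generative event stream (Brownian drift plus raised-cosine
#' microsaccades) is rendered into both eyes with independent per-sample
#' positional noise; blinks zero the pupil channel and blank positions.
#'
#' @param config a [synth_config()]; `config$seed` (if non-NULL) makes the
#'   trace reproducible.
#' @param duration seconds; defaults to `config$session_duration`.
#' @param events optional pre-generated event table (e.g. from
#'   [simulate_session()]) to render instead of drawing a fresh stream.
#' @return list with `trace` (data frame `time_s, xL_deg, yL_deg, pupilL,
#'   xR_deg, yR_deg, pupilR`) and `events` (ground-truth microsaccade table).
#' @export
generate_trace <- function(config, duration = config$session_duration,
                           events = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (duration <= 0) stop("invalid config: non-positive duration")
  if (!is.null(config$seed)) set.seed(config$seed)
  dt <- 1 / config$sampling_rate
  n <- floor(duration / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  if (is.null(events)) events <- gen_events(config, duration)

  # Brownian drift, shared across eyes (per-axis variance D/2 per second)
  sd_step <- sqrt(config$drift_diffusion / 2 * dt)
  x <- cumsum(c(0, stats::rnorm(n - 1L, 0, sd_step)))
  y <- cumsum(c(0, stats::rnorm(n - 1L, 0, sd_step)))

  # add each microsaccade's displacement profile
  if (nrow(events) > 0) {
    th <- events$direction_deg * pi / 180
    for (i in seq_len(nrow(events))) {
      i0 <- findInterval(events$onset_s[i], tt)
      i1 <- min(findInterval(events$offset_s[i], tt) + 1L, n)
      if (i1 <= i0) next
      u <- pmin(pmax((tt[i0:i1] - events$onset_s[i]) / events$duration_s[i], 0), 1)
      disp <- events$amplitude_arcmin[i] / 60 * raised_cosine_disp(u)
      x[i0:i1] <- x[i0:i1] + disp * cos(th[i])
      y[i0:i1] <- y[i0:i1] + disp * sin(th[i])
      if (i1 < n) {
        A <- events$amplitude_arcmin[i] / 60
        x[(i1 + 1L):n] <- x[(i1 + 1L):n] + A * cos(th[i])
        y[(i1 + 1L):n] <- y[(i1 + 1L):n] + A * sin(th[i])
      }
    }
  }

  pupil <- rep(1, n)
  if (config$blink_rate > 0) {
    nb <- stats::rpois(1, config$blink_rate * duration)
    if (nb > 0) {
      b0 <- sort(stats::runif(nb, 0, duration - config$blink_duration))
      for (b in b0) pupil[tt >= b & tt < b + config$blink_duration] <- 0
    }
  }

  noise <- function() stats::rnorm(n, 0, config$eye_noise_sd)
  xL <- x + noise(); yL <- y + noise()
  xR <- x + noise(); yR <- y + noise()
  blink <- pupil == 0
  xL[blink] <- NA; yL[blink] <- NA; xR[blink] <- NA; yR[blink] <- NA
  trace <- data.frame(time_s = tt, xL_deg = xL, yL_deg = yL, pupilL = pupil,
                      xR_deg = xR, yR_deg = yR, pupilR = pupil)
  list(trace = trace, events = events)
}

# 1-up-3-down update: returns new state list(contrast, n_correct)
staircase_update <- function(state, correct, step) {
  if (correct) {
    state$n_correct <- state$n_correct + 1L
    if (state$n_correct >= 3L) {
      state$contrast <- state$contrast - step
      state$n_correct <- 0L
    }
  } else {
    state$contrast <- state$contrast + step
    state$n_correct <- 0L
  }
  state
}

#' Simulate a full psychophysical session
#'
#' Runs five interleaved 1-up-3-down staircases (one per spatial frequency)
#' against a logistic observer whose log10 threshold at each trial is shifted
#' by `-template_sr(tau)` where `tau` is the latency from the nearest
#' ground-truth microsaccade onset to stimulus onset. Trial correctness is
#' Bernoulli under the logistic psychometric on log10 contrast.
#'
#' @param config a [synth_config()]. With `config$n_trials` set the session
#'   runs exactly that many trials; otherwise it fills
#'   `config$session_duration`.
#' @param render_trace also render the 500-Hz binocular trace (memory-heavy
#'   for long sessions; the trial table and ground-truth events never require
#'   it).
#' @param subject subject label for the trial table.
#' @return list: `trials` (data frame `subject, t_stim_s, sf_cpd, contrast`
#'   (log10), `stim_orientation_deg, correct, tau_true_s`), `events`
#'   (ground truth), `blinks` (onset/offset intervals), and `trace` (or NULL).
#' @export
simulate_session <- function(config, render_trace = FALSE, subject = "s01") {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  mean_step <- config$response_latency + mean(config$iti_range)
  if (is.null(config$n_trials)) {
    duration <- config$session_duration
    n_max <- floor(duration / (config$response_latency + config$iti_range[1]))
    if (n_max < length(config$sfs))
      stop("session too short for at least one trial per staircase")
  } else {
    duration <- config$n_trials * mean_step * 1.15 + 10
    n_max <- config$n_trials
  }
  events <- gen_events(config, duration)
  onsets <- events$onset_s
  nb <- if (config$blink_rate > 0) stats::rpois(1, config$blink_rate * duration) else 0
  blinks <- data.frame(onset_s = if (nb > 0)
    sort(stats::runif(nb, 0, duration)) else numeric(0))
  blinks$offset_s <- blinks$onset_s + config$blink_duration

  nsf <- length(config$sfs)
  stair <- lapply(seq_len(nsf), function(i)
    list(contrast = config$stair_start, n_correct = 0L))
  # interleave in shuffled blocks so staircase counts stay balanced
  order_pool <- integer(0)

  res <- vector("list", n_max)
  t_stim <- config$response_latency + stats::runif(1, config$iti_range[1],
                                                   config$iti_range[2])
  i <- 0L
  while (i < n_max && t_stim < duration) {
    i <- i + 1L
    if (length(order_pool) == 0) order_pool <- sample.int(nsf)
    k <- order_pool[1]; order_pool <- order_pool[-1]
    cc <- stair[[k]]$contrast
    if (length(onsets) > 0) {
      j <- nearest_event_index(t_stim, onsets)
      tau <- t_stim - onsets[j]
      ev_dir <- events$direction_deg[j]
    } else {
      tau <- Inf
      ev_dir <- NA_real_
    }
    sr <- template_sr(tau, config$sfs[k], config$template)
    mu_eff <- config$observer_mu[k] - sr
    p <- psy_predict(cc, mu_eff, config$observer_s[k], config$observer_lapse)
    correct <- stats::runif(1) < p
    res[[i]] <- list(t_stim_s = t_stim, sf_cpd = config$sfs[k], contrast = cc,
                     stim_orientation_deg = sample(c(-45, 45), 1),
                     correct = correct, tau_true_s = tau,
                     event_direction_deg = ev_dir)
    stair[[k]] <- staircase_update(stair[[k]], correct, config$stair_step)
    t_stim <- t_stim + config$response_latency +
      stats::runif(1, config$iti_range[1], config$iti_range[2])
  }
  res <- res[seq_len(i)]
  if (!is.null(config$n_trials) && i < config$n_trials)
    stop("session too short for requested n_trials")
  trials <- data.frame(
    subject = subject,
    t_stim_s = vapply(res, `[[`, numeric(1), "t_stim_s"),
    sf_cpd = vapply(res, `[[`, numeric(1), "sf_cpd"),
    contrast = vapply(res, `[[`, numeric(1), "contrast"),
    stim_orientation_deg = vapply(res, `[[`, numeric(1), "stim_orientation_deg"),
    correct = vapply(res, `[[`, logical(1), "correct"),
    tau_true_s = vapply(res, `[[`, numeric(1), "tau_true_s"),
    event_direction_deg = vapply(res, `[[`, numeric(1), "event_direction_deg")
  )
  trace <- NULL
  if (render_trace) {
    cfg2 <- config; cfg2$seed <- NULL   # keep the RNG stream continuous
    trace <- generate_trace(cfg2, duration = duration, events = events)$trace
  }
  list(trials = trials, events = events, blinks = blinks, trace = trace)
}

#' Write/read the delimited-text session formats
#'
#' Gaze traces: `time_s, xL_deg, yL_deg, pupilL, xR_deg, yR_deg, pupilR`.
#' Trials: `subject, t_stim_s, sf_cpd, contrast, stim_orientation_deg,
#' correct` (+ any extra columns present). Events: `onset_s, offset_s,
#' duration_s, amplitude_arcmin, peak_velocity_dps, direction_deg`.
#' All tab-separated with a header line.
#'
#' @param x data frame to write.
#' @param path file path.
#' @name session_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
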