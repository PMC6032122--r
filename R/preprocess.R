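# Gaze-trace cleaning (blink masking, velocity computation) and trial-level
# microsaccade-latency metadata.

#' Mask blink samples with a surrounding buffer
#'
#' Invalidates every sample with pupil = 0 in either eye together with all
#' samples within `buffer` seconds before and after; no interpolation is
#' performed. Adds/overwrites a logical `valid` column. Overlapping buffers
#' union into contiguous invalid runs, and re-masking an already-masked trace
#' is a no-op.
#'
#' @param trace gaze trace data frame (uniform time grid) with `time_s`,
#'   `pupilL`, `pupilR`.
#' @param buffer seconds, default 0.2.
#' @return the trace with a `valid` column.
#' @export
mask_blinks <- function(trace, buffer = 0.2) {
  blink <- trace$pupilL == 0 | trace$pupilR == 0
  valid <- if (is.null(trace$valid)) rep(TRUE, nrow(trace)) else trace$valid
  if (any(blink)) {
    dt <- stats::median(diff(trace$time_s))
    w <- ceiling(buffer / dt)
    idx <- which(blink)
    bad <- unique(unlist(lapply(idx, function(i)
      max(1L, i - w):min(nrow(trace), i + w))))
    valid[bad] <- FALSE
  }
  trace$valid <- valid
  if (!any(trace$valid)) warning("entirely invalid trace")
  trace
}

# contiguous runs of TRUE in a logical vector -> matrix [start, end]
logical_runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# 5-sample moving-window differentiator on one component within one run
diff5 <- function(p, dt) {
  n <- length(p)
  v <- rep(NA_real_, n)
  if (n >= 5)
    v[3:(n - 2)] <- (p[5:n] + p[4:(n - 1)] - p[2:(n - 3)] - p[1:(n - 4)]) /
      (6 * dt)
  v
}

#' Compute eye velocities
#'
#' Per eye and component, the 5-sample moving-window differentiator
#' \eqn{v_n = (p_{n+2} + p_{n+1} - p_{n-1} - p_{n-2}) / (6\Delta t)}, applied
#' within each contiguous valid run (velocities are undefined at run edges and
#' across masked gaps). Radial velocity \eqn{\sqrt{v_x^2 + v_y^2}} is also
#' returned, together with a 5-point moving-average smoothed copy used by the
#' drift analyses.
#'
#' @param trace gaze trace with a `valid` column (see [mask_blinks()]).
#' @return data frame `time_s, vxL, vyL, vrL, vxR, vyR, vrR, vrL_smooth,
#'   vrR_smooth, valid`.
#' @export
compute_velocity <- function(trace) {
  if (is.null(trace$valid)) trace$valid <- TRUE
  dt <- stats::median(diff(trace$time_s))
  n <- nrow(trace)
  ok <- trace$valid & !is.na(trace$xL_deg) & !is.na(trace$xR_deg)
  out <- data.frame(time_s = trace$time_s,
                    vxL = NA_real_, vyL = NA_real_, vrL = NA_real_,
                    vxR = NA_real_, vyR = NA_real_, vrR = NA_real_,
                    vrL_smooth = NA_real_, vrR_smooth = NA_real_,
                    valid = ok)
  runs <- logical_runs(ok)
  smooth5 <- function(v) stats::filter(v, rep(1 / 5, 5), sides = 2)
  if (nrow(runs) > 0) for (r in seq_len(nrow(runs))) {
    i <- runs[r, "start"]:runs[r, "end"]
    if (length(i) < 5) next
    out$vxL[i] <- diff5(trace$xL_deg[i], dt)
    out$vyL[i] <- diff5(trace$yL_deg[i], dt)
    out$vxR[i] <- diff5(trace$xR_deg[i], dt)
    out$vyR[i] <- diff5(trace$yR_deg[i], dt)
    out$vrL[i] <- sqrt(out$vxL[i]^2 + out$vyL[i]^2)
    out$vrR[i] <- sqrt(out$vxR[i]^2 + out$vyR[i]^2)
    out$vrL_smooth[i] <- as.numeric(smooth5(out$vrL[i]))
    out$vrR_smooth[i] <- as.numeric(smooth5(out$vrR[i]))
  }
  out
}

# Index of the event onset nearest each time in `t` (onsets must be sorted).
# Ties in |t - onset| (to within `tol`) resolve toward the later event.
nearest_event_index <- function(t, onsets, tol = 1e-9) {
  if (length(onsets) == 0) return(rep(NA_integer_, length(t)))
  jlo <- findInterval(t, onsets)
  jhi <- pmin(jlo + 1L, length(onsets))
  jlo <- pmax(jlo, 1L)
  dlo <- abs(t - onsets[jlo])
  dhi <- abs(t - onsets[jhi])
  as.integer(ifelse(dhi <= dlo + tol, jhi, jlo))  # prefer later on ties
}

# Latency tau = t - nearest onset; +Inf when there are no events.
nearest_tau <- function(t, onsets, tol = 1e-9) {
  if (length(onsets) == 0) return(rep(Inf, length(t)))
  onsets <- sort(onsets)
  j <- nearest_event_index(t, onsets, tol)
  t - onsets[j]
}

#' Attach microsaccade latency to trials
#'
#' For each trial, `tau = t_stim - onset` of the microsaccade whose onset is
#' nearest in absolute time; positive tau means the stimulus followed the
#' microsaccade. Equidistant events resolve toward the later event (negative
#' tau). Sessions without any event yield `tau = +Inf` (baseline-eligible).
#' The nearest event's direction is attached as `event_direction_deg`.
#'
#' @param trials trial table with `t_stim_s`.
#' @param events microsaccade table with `onset_s` (any order) and optionally
#'   `direction_deg`.
#' @return trials with `tau_s` (and `event_direction_deg`) columns.
#' @export
attach_latency <- function(trials, events) {
  onsets <- sort(events$onset_s)
  trials$tau_s <- nearest_tau(trials$t_stim_s, onsets)
  if (!is.null(events$direction_deg) && nrow(events) > 0) {
    dirs <- events$direction_deg[order(events$onset_s)]
    idx <- nearest_event_index(trials$t_stim_s, onsets)
    trials$event_direction_deg <- dirs[idx]
  } else if (nrow(events) == 0) {
    trials$event_direction_deg <- NA_real_
  }
  trials
}

#' Discard trials with a blink near the stimulus
#'
#' Removes trials with any blink sample within `window` seconds of stimulus
#' onset and reports the fraction removed.
#'
#' @param trials trial table with `t_stim_s`.
#' @param blink_times numeric vector of blink sample times (seconds), e.g.
#'   `trace$time_s[trace$pupilL == 0]`.
#' @param window seconds, default 0.1.
#' @return list: `trials` (kept rows), `fraction_removed`.
#' @export
exclude_blink_trials <- function(trials, blink_times, window = 0.1) {
  if (length(blink_times) == 0)
    return(list(trials = trials, fraction_removed = 0))
  blink_times <- sort(blink_times)
  bad <- vapply(trials$t_stim_s, function(ts) {
    j <- findInterval(ts, blink_times)
    near <- c(if (j >= 1) blink_times[j], if (j < length(blink_times)) blink_times[j + 1])
    any(abs(near - ts) <= window)
  }, logical(1))
  list(trials = trials[!bad, , drop = FALSE], fraction_removed = mean(bad))
}
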