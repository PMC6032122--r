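# Median-based velocity-threshold microsaccade detection with duration,
# amplitude, merge and binocular-overlap filters; main-sequence and direction
# statistics.

# median-based SD estimator: robust to heavy-tailed velocity samples
median_sd <- function(v) {
  v <- v[!is.na(v)]
  sqrt(stats::median(v^2) - stats::median(v)^2)
}

#' Detect candidate microsaccades in one eye
#'
#' Component-wise detection thresholds are `multiplier` times a median-based
#' standard deviation of the velocity, `sigma = sqrt(median(v^2) -
#' median(v)^2)`, computed over all valid samples. A candidate is a maximal
#' run of samples exceeding the elliptic criterion
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` with `eta_i = multiplier * sigma_i`.
#'
#' @param time numeric sample times (seconds).
#' @param vx,vy component velocities (deg/s), NA where invalid.
#' @param multiplier threshold multiplier, default 6.
#' @param min_samples minimum run length in samples, default 3.
#' @return data frame `onset_s, offset_s, onset_idx, offset_idx`.
#' @export
detect_candidates <- function(time, vx, vy, multiplier = 6, min_samples = 3L) {
  ok <- !is.na(vx) & !is.na(vy)
  sx <- median_sd(vx[ok]); sy <- median_sd(vy[ok])
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    stop("degenerate velocity trace: median-based sigma is zero")
  ex <- multiplier * sx; ey <- multiplier * sy
  crit <- ok & ((vx / ex)^2 + (vy / ey)^2 > 1)
  crit[is.na(crit)] <- FALSE
  runs <- logical_runs(crit)
  if (nrow(runs) > 0) {
    keep <- (runs[, "end"] - runs[, "start"] + 1L) >= min_samples
    runs <- runs[keep, , drop = FALSE]
  }
  data.frame(onset_s = time[runs[, "start"]], offset_s = time[runs[, "end"]],
             onset_idx = as.integer(runs[, "start"]),
             offset_idx = as.integer(runs[, "end"]))
}

# amplitude (net onset->offset displacement, arcmin), peak radial velocity and
# direction for a candidate interval
event_params <- function(cand, time, x, y, vr) {
  n <- nrow(cand)
  amp <- dir <- vpk <- numeric(n)
  for (i in seq_len(n)) {
    i0 <- cand$onset_idx[i]; i1 <- cand$offset_idx[i]
    dx <- x[i1] - x[i0]; dy <- y[i1] - y[i0]
    amp[i] <- sqrt(dx^2 + dy^2) * 60
    dir[i] <- (atan2(dy, dx) * 180 / pi) %% 360
    vpk[i] <- max(vr[i0:i1], na.rm = TRUE)
  }
  cbind(amplitude_arcmin = amp, peak_velocity_dps = vpk, direction_deg = dir)
}

#' Merge nearby candidates and apply duration/amplitude filters
#'
#' Same-eye candidates whose offset-to-onset gap is below `merge_gap` are
#' merged (transitively) into one event spanning the first onset to the last
#' offset, fusing overshoots misclassified as separate saccades; amplitude,
#' peak velocity and direction are recomputed on the merged interval. Events
#' with duration below `min_duration` or amplitude outside `amp_bounds` are
#' then discarded.
#'
#' @param cand candidate table from [detect_candidates()], sorted by onset.
#' @param time,x,y,vr sample times, positions (deg) and radial velocity of the
#'   same eye.
#' @param merge_gap seconds, default 0.05.
#' @param min_duration seconds, default 0.006.
#' @param amp_bounds arcmin, default `c(3, 60)`.
#' @return microsaccade table `onset_s, offset_s, duration_s,
#'   amplitude_arcmin, peak_velocity_dps, direction_deg`.
#' @export
filter_and_merge <- function(cand, time, x, y, vr, merge_gap = 0.05,
                             min_duration = 0.006, amp_bounds = c(3, 60)) {
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), amplitude_arcmin = numeric(0),
                      peak_velocity_dps = numeric(0), direction_deg = numeric(0))
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(cand$onset_s), , drop = FALSE]
  # transitive merge of offset-to-onset gaps < merge_gap
  gaps <- cand$onset_s[-1] - cand$offset_s[-nrow(cand)]
  grp <- cumsum(c(1L, as.integer(gaps >= merge_gap)))
  merged <- do.call(rbind, lapply(split(seq_len(nrow(cand)), grp), function(i)
    data.frame(onset_s = cand$onset_s[i[1]],
               offset_s = cand$offset_s[i[length(i)]],
               onset_idx = cand$onset_idx[i[1]],
               offset_idx = cand$offset_idx[i[length(i)]])))
  pars <- event_params(merged, time, x, y, vr)
  ev <- data.frame(onset_s = merged$onset_s, offset_s = merged$offset_s,
                   duration_s = merged$offset_s - merged$onset_s,
                   amplitude_arcmin = pars[, "amplitude_arcmin"],
                   peak_velocity_dps = pars[, "peak_velocity_dps"],
                   direction_deg = pars[, "direction_deg"])
  keep <- ev$duration_s >= min_duration &
    ev$amplitude_arcmin >= amp_bounds[1] & ev$amplitude_arcmin <= amp_bounds[2]
  rownames(ev) <- NULL
  ev[keep, , drop = FALSE]
}

#' Binocular overlap filter
#'
#' Retains left-eye events whose `[onset, offset]` interval intersects at
#' least one right-eye event (any overlap, including a single shared sample,
#' suffices); the retained events carry the left-eye parameters.
#'
#' @param left,right per-eye microsaccade tables.
#' @return filtered left-eye table.
#' @export
binocular_filter <- function(left, right) {
  if (nrow(left) == 0 || nrow(right) == 0) return(left[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(left)), function(i)
    any(left$onset_s[i] <= right$offset_s & left$offset_s[i] >= right$onset_s),
    logical(1))
  out <- left[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full microsaccade detection pipeline for one trace
#'
#' Masks blinks, computes velocities, detects per-eye candidates with the
#' elliptic median-based velocity threshold, merges/filters them, and applies
#' the binocular-overlap requirement. Returned events carry left-eye
#' parameters.
#'
#' @param trace binocular gaze trace.
#' @param multiplier velocity-threshold multiplier, default 6.
#' @param merge_gap,min_duration,amp_bounds see [filter_and_merge()].
#' @param blink_buffer seconds, see [mask_blinks()].
#' @return microsaccade table.
#' @export
detect_microsaccades <- function(trace, multiplier = 6, merge_gap = 0.05,
                                 min_duration = 0.006, amp_bounds = c(3, 60),
                                 blink_buffer = 0.2) {
  trace <- mask_blinks(trace, blink_buffer)
  vel <- compute_velocity(trace)
  candL <- detect_candidates(vel$time_s, vel$vxL, vel$vyL, multiplier)
  candR <- detect_candidates(vel$time_s, vel$vxR, vel$vyR, multiplier)
  evL <- filter_and_merge(candL, trace$time_s, trace$xL_deg, trace$yL_deg,
                          vel$vrL, merge_gap, min_duration, amp_bounds)
  evR <- filter_and_merge(candR, trace$time_s, trace$xR_deg, trace$yR_deg,
                          vel$vrR, merge_gap, min_duration, amp_bounds)
  binocular_filter(evL, evR)
}

#' Main-sequence statistics
#'
#' Pearson correlation and least-squares slope of log10 peak velocity against
#' log10 amplitude across events.
#'
#' @param events microsaccade table with `amplitude_arcmin`,
#'   `peak_velocity_dps`.
#' @return list `r`, `slope`, `intercept`, `n`.
#' @export
main_sequence <- function(events) {
  if (nrow(events) < 3) stop("main sequence undefined for fewer than 3 events")
  la <- log10(events$amplitude_arcmin / 60)
  lv <- log10(events$peak_velocity_dps)
  fit <- stats::lm.fit(cbind(1, la), lv)
  list(r = stats::cor(la, lv), slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = nrow(events))
}

#' Direction histogram
#'
#' Proportion of events per angular bin; bins are centred on 0, 360/n_bins,
#' ... degrees (so a bin straddles 0 = rightward).
#'
#' @param events microsaccade table with `direction_deg`.
#' @param n_bins number of angular bins, default 16.
#' @return data frame `bin_center_deg`, `proportion` (sums to 1).
#' @export
direction_histogram <- function(events, n_bins = 16) {
  stopifnot(nrow(events) >= 1)
  w <- 360 / n_bins
  centers <- (seq_len(n_bins) - 1L) * w
  shifted <- (events$direction_deg + w / 2) %% 360
  bin <- floor(shifted / w) + 1L
  counts <- tabulate(bin, n_bins)
  data.frame(bin_center_deg = centers, proportion = counts / sum(counts))
}
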