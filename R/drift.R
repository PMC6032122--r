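# Post-microsaccadic drift: epoch-averaged radial velocity and box-count
# magnitude, normalized to a microsaccade-free baseline. Left-eye positions
# only.

#' Collate left-eye position epochs around microsaccade onsets
#'
#' Extracts a window (default 1 s before to 1 s after) of left-eye samples
#' around every onset and invalidates samples falling inside any detected
#' event's `[onset, offset]` interval (including neighbouring events).
#' Epochs truncated by the recording edge are flagged.
#'
#' @param trace gaze trace (with `valid` column if blinks were masked).
#' @param events microsaccade table (`onset_s`, `offset_s`).
#' @param window numeric length-2, seconds relative to onset.
#' @return list: `t_rel` (relative time grid), `x`, `y` (epoch-by-sample
#'   matrices, NA where invalid), `truncated` (logical per epoch).
#' @export
epoch_positions <- function(trace, events, window = c(-1, 1)) {
  dt <- stats::median(diff(trace$time_s))
  n <- nrow(trace)
  k0 <- round(window[1] / dt); k1 <- round(window[2] / dt)
  t_rel <- (k0:k1) * dt
  valid <- if (is.null(trace$valid)) rep(TRUE, n) else trace$valid
  # global mask of samples inside any event
  in_event <- rep(FALSE, n)
  for (i in seq_len(nrow(events))) {
    i0 <- findInterval(events$onset_s[i] - dt / 2, trace$time_s) + 1L
    i1 <- findInterval(events$offset_s[i] + dt / 2, trace$time_s)
    if (i1 >= i0) in_event[max(1L, i0):min(n, i1)] <- TRUE
  }
  x <- trace$xL_deg; y <- trace$yL_deg
  x[!valid | in_event] <- NA; y[!valid | in_event] <- NA
  m <- nrow(events)
  X <- matrix(NA_real_, m, length(t_rel))
  Y <- matrix(NA_real_, m, length(t_rel))
  truncated <- logical(m)
  for (i in seq_len(m)) {
    c_idx <- round(events$onset_s[i] / dt) + 1L
    idx <- c_idx + (k0:k1)
    inside <- idx >= 1L & idx <= n
    truncated[i] <- !all(inside)
    X[i, inside] <- x[idx[inside]]
    Y[i, inside] <- y[idx[inside]]
  }
  list(t_rel = t_rel, x = X, y = Y, truncated = truncated)
}

#' Box count of a trajectory segment
#'
#' Number of distinct square grid cells (edge `box` degrees, grid anchored at
#' the coordinate origin) containing at least one sample. NA samples are
#' ignored; an empty segment gives NA.
#'
#' @param x,y positions in degrees.
#' @param box cell edge, default 0.01 deg.
#' @return integer count (or NA).
#' @export
box_count <- function(x, y, box = 0.01) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_integer_)
  ix <- floor(x[ok] / box); iy <- floor(y[ok] / box)
  nrow(unique(cbind(ix, iy)))
}

#' Drift timecourse around microsaccade onset
#'
#' Per epoch sample: mean (across events) of the smoothed radial velocity;
#' per 50-ms bin: mean box count. Baseline values are computed from samples
#' more than 0.1 s before and 0.5 s after every microsaccade onset over the
#' whole recording, and used to normalize both metrics.
#'
#' @param trace gaze trace (blink-masked).
#' @param events microsaccade table.
#' @param window epoch window, seconds.
#' @param box_bin box-count bin width, seconds (default 0.05).
#' @param box cell edge, degrees (default 0.01).
#' @return list: `velocity` (data frame `t_rel_s, radial_vel, radial_vel_norm,
#'   se_vel`), `boxcount` (data frame `t_rel_s, boxcount, boxcount_norm,
#'   se_box`), `baseline_vel`, `baseline_box`.
#' @export
drift_timecourse <- function(trace, events, window = c(-1, 1),
                             box_bin = 0.05, box = 0.01) {
  vel <- compute_velocity(trace)
  dt <- stats::median(diff(trace$time_s))
  n <- nrow(trace)

  # baseline mask: outside (-0.1, +0.5) s around every onset
  tau <- nearest_tau(trace$time_s, events$onset_s)
  base_ok <- (tau <= -0.5 | tau >= 0.1) & !is.na(vel$vrL_smooth)
  baseline_vel <- mean(vel$vrL_smooth[base_ok], na.rm = TRUE)

  ep <- epoch_positions(trace, events, window)
  # epoch the smoothed radial velocity on the same grid
  k0 <- round(window[1] / dt); k1 <- round(window[2] / dt)
  m <- nrow(events)
  V <- matrix(NA_real_, m, length(ep$t_rel))
  for (i in seq_len(m)) {
    c_idx <- round(events$onset_s[i] / dt) + 1L
    idx <- c_idx + (k0:k1)
    inside <- idx >= 1L & idx <= n
    V[i, inside] <- vel$vrL_smooth[idx[inside]]
    V[i, inside][is.na(ep$x[i, inside])] <- NA  # drop in-event samples
  }
  mv <- colMeans(V, na.rm = TRUE)
  sev <- apply(V, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) NA_real_ else stats::sd(col) / sqrt(length(col))
  })
  velocity <- data.frame(t_rel_s = ep$t_rel, radial_vel = mv,
                         radial_vel_norm = mv / baseline_vel, se_vel = sev)

  # box counts in 50-ms bins per epoch
  nb <- floor((window[2] - window[1]) / box_bin)
  edges <- window[1] + (0:nb) * box_bin
  bin_of <- findInterval(ep$t_rel, edges, rightmost.closed = TRUE)
  B <- matrix(NA_real_, m, nb)
  for (i in seq_len(m))
    for (b in seq_len(nb)) {
      sel <- bin_of == b
      B[i, b] <- box_count(ep$x[i, sel], ep$y[i, sel], box)
    }
  # baseline box count: same bin width applied to baseline samples, chunked
  base_idx <- which(base_ok & !is.na(trace$xL_deg))
  bb <- c()
  if (length(base_idx) > 0) {
    chunk <- max(1L, round(box_bin / dt))
    runs <- logical_runs(seq_len(n) %in% base_idx)
    for (r in seq_len(nrow(runs))) {
      i <- runs[r, "start"]:runs[r, "end"]
      if (length(i) < chunk) next
      starts <- seq(1L, length(i) - chunk + 1L, by = chunk)
      for (s0 in starts) {
        j <- i[s0:(s0 + chunk - 1L)]
        bb <- c(bb, box_count(trace$xL_deg[j], trace$yL_deg[j], box))
      }
    }
  }
  baseline_box <- mean(bb, na.rm = TRUE)
  mb <- colMeans(B, na.rm = TRUE)
  seb <- apply(B, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) NA_real_ else stats::sd(col) / sqrt(length(col))
  })
  boxcount <- data.frame(t_rel_s = (edges[-1] + edges[-(nb + 1)]) / 2,
                         boxcount = mb, boxcount_norm = mb / baseline_box,
                         se_box = seb)
  list(velocity = velocity, boxcount = boxcount,
       baseline_vel = baseline_vel, baseline_box = baseline_box)
}

#' Normalize a drift metric by its baseline mean
#'
#' @param values numeric metric values.
#' @param baseline_mean baseline mean of the same metric; must be nonzero.
#' @return `values / baseline_mean`.
#' @export
normalize_drift <- function(values, baseline_mean) {
  if (!is.finite(baseline_mean) || baseline_mean == 0)
    stop("zero or undefined baseline mean")
  values / baseline_mean
}
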