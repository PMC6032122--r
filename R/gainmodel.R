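# Delayed normative gain model: a separable 2D suppression profile over
# (time since microsaccade onset, spatial frequency) is relaxed by divisive
# normalization against the mean channel activity at a delayed time point.
# All SR values are log10 sensitivity ratios (negative = suppression); the
# divisive operation on linear sensitivity ratios is mean subtraction in log
# space.

#' Gain-model parameters
#'
#' @param a peak relative suppression scale (1 before rescaling).
#' @param t_peak time of maximum suppression, seconds (default 0.02).
#' @param c_width suppression duration constant, seconds (default 0.067).
#' @param poly cubic coefficients `(p1, p2, p3, p4)` of the suppression
#'   profile over `x = log10(spatial frequency)`.
#' @param t_delay normalization delay, seconds; must sit on the time grid.
#' @param t_grid time grid: `c(start, stop, step)` seconds, default
#'   `c(-0.1, 0.4, 0.002)`.
#' @param sfs spatial-frequency channels, cycles/deg.
#' @return object of class `gain_params`.
#' @export
gain_params <- function(a = 1, t_peak = 0.02, c_width = 0.067,
                        poly = c(-0.0723, -0.09754, 0.07958, -0.0641),
                        t_delay = 0, t_grid = c(-0.1, 0.4, 0.002),
                        sfs = FIXSENS_SFS) {
  stopifnot(c_width > 0, t_delay >= 0, length(poly) == 4, length(sfs) > 0,
            t_grid[3] > 0, t_grid[2] > t_grid[1])
  steps <- t_delay / t_grid[3]
  if (abs(steps - round(steps)) > 1e-9)
    stop("t_delay must be an integer multiple of the time step")
  structure(list(a = a, t_peak = t_peak, c_width = c_width, poly = poly,
                 t_delay = t_delay, t_grid = t_grid, sfs = sfs),
            class = "gain_params")
}

#' Temporal suppression profile
#'
#' Gaussian relative-suppression profile
#' \eqn{a \exp(-((t - t_{peak})/c)^2)}, peaking at `a` at `t = t_peak` and
#' falling to `a/e` at `t_peak +- c_width`.
#'
#' @param t time, seconds (vectorised).
#' @param a,t_peak,c_width see [gain_params()].
#' @export
time_profile <- function(t, a = 1, t_peak = 0.02, c_width = 0.067) {
  a * exp(-((t - t_peak) / c_width)^2)
}

#' Spatial-frequency suppression profile
#'
#' Third-order polynomial over log10 spatial frequency giving the log10
#' sensitivity ratio at peak suppression:
#' \eqn{p_1 x^3 + p_2 x^2 + p_3 x + p_4}, `x = log10(sf)`.
#'
#' @param log10_sf log10 of spatial frequency (cycles/deg), vectorised.
#' @param poly coefficients `(p1, p2, p3, p4)`.
#' @export
sf_profile <- function(log10_sf,
                       poly = c(-0.0723, -0.09754, 0.07958, -0.0641)) {
  poly[1] * log10_sf^3 + poly[2] * log10_sf^2 + poly[3] * log10_sf + poly[4]
}

#' Build the separable initial suppression profile
#'
#' `SR(t, sf) = a * exp(-((t - t_peak)/c)^2) * sf_profile(log10 sf)`; with
#' `a = 1` the value at `(t_peak, sf)` equals `sf_profile(sf)` exactly.
#'
#' @param params a [gain_params()].
#' @return object of class `gain_state`: list with `sr` (time x sf matrix),
#'   `t` (grid), `sfs`, `stage = "initial"`, `params`.
#' @export
build_profile <- function(params) {
  stopifnot(inherits(params, "gain_params"))
  t <- seq(params$t_grid[1], params$t_grid[2], by = params$t_grid[3])
  tp <- time_profile(t, params$a, params$t_peak, params$c_width)
  sp <- sf_profile(log10(params$sfs), params$poly)
  sr <- outer(tp, sp)
  structure(list(sr = sr, t = t, sfs = params$sfs, stage = "initial",
                 params = params), class = "gain_state")
}

#' Delayed divisive normalization across spatial-frequency channels
#'
#' Iterates time bins in ascending order. At each bin the log sensitivity
#' ratio of every channel is divided (on the linear sensitivity-ratio scale,
#' i.e. mean-subtracted in log space) by the mean across channels of the
#' model state at `t - t_delay`. The state updates in place, so later bins
#' see already-normalized earlier bins; lookbacks preceding the grid use a
#' baseline (zero log ratio) normalization term.
#'
#' @param state a `gain_state` (stage "initial").
#' @param t_delay seconds; defaults to `state$params$t_delay`. Must be a
#'   multiple of the grid step.
#' @return normalized `gain_state` (stage "normalized").
#' @export
gain_normalize <- function(state, t_delay = state$params$t_delay) {
  stopifnot(inherits(state, "gain_state"))
  step <- state$params$t_grid[3]
  lag <- t_delay / step
  if (abs(lag - round(lag)) > 1e-9)
    stop("t_delay must be an integer multiple of the time step")
  lag <- as.integer(round(lag))
  sr <- state$sr
  for (i in seq_len(nrow(sr))) {
    norm_term <- if (i - lag >= 1) mean(sr[i - lag, ]) else 0
    sr[i, ] <- sr[i, ] - norm_term
  }
  state$sr <- sr
  state$stage <- "normalized"
  state$t_delay_used <- t_delay
  state
}

#' Two-pass rescaling of the suppression amplitude
#'
#' Pass 1 runs the model with `a = 1`; the amplitude is then rescaled by the
#' ratio of the initial-fit and model SR values at peak suppression
#' `(t_peak, lowest sf)`, the profile is rebuilt with the scaled `a`, and
#' pass 2 produces the final state. After pass 2 the model value at the
#' anchor equals the pass-1 initial fit's value there.
#'
#' @param params a [gain_params()] (its `a` is ignored; pass 1 uses 1).
#' @param t_delay seconds, defaults to `params$t_delay`.
#' @param anchor_sf anchor channel, default the lowest spatial frequency.
#' @return list: `a_scaled`, `state` (final normalized state), `initial`
#'   (pass-1 initial state).
#' @export
rescale_a <- function(params, t_delay = params$t_delay,
                      anchor_sf = min(params$sfs)) {
  p1 <- params; p1$a <- 1; p1$t_delay <- t_delay
  init <- build_profile(p1)
  it <- which.min(abs(init$t - params$t_peak))
  k <- match(anchor_sf, params$sfs)
  pass1 <- gain_normalize(init, t_delay)
  denom <- pass1$sr[it, k]
  if (!is.finite(denom) || denom == 0)
    stop("degenerate rescale: model SR at the anchor is zero")
  a_scaled <- init$sr[it, k] / denom
  p2 <- p1; p2$a <- a_scaled
  final <- gain_normalize(build_profile(p2), t_delay)
  list(a_scaled = a_scaled, state = final, initial = init)
}

#' Sweep the normalization delay
#'
#' Runs the two-pass rescaled model at each delay and summarizes the final
#' state: the mean-across-channel (net) SR curve, the location of the maximum
#' positive SR (the facilitation peak), and a spatial-tuning contrast of the
#' facilitation (max-to-mean ratio of positive channel SR at the peak time).
#'
#' @param params a [gain_params()].
#' @param delays seconds, default `c(0, 0.04, 0.06, 0.14)`.
#' @return list per delay: `t_delay`, `a_scaled`, `state`, `net_sr` (data
#'   frame `t, net_sr`), `peak_time`, `peak_sf`, `peak_sr`, `tuning_contrast`.
#' @export
sweep_delay <- function(params, delays = c(0, 0.04, 0.06, 0.14)) {
  lapply(delays, function(d) {
    res <- rescale_a(params, t_delay = d)
    sr <- res$state$sr
    net <- rowMeans(sr)
    imax <- which(sr == max(sr), arr.ind = TRUE)[1, ]
    row_at_peak <- sr[imax[1], ]
    pos <- row_at_peak[row_at_peak > 0]
    tuning <- if (length(pos) > 0 && mean(row_at_peak) != 0)
      max(row_at_peak) / mean(abs(row_at_peak)) else NA_real_
    list(t_delay = d, a_scaled = res$a_scaled, state = res$state,
         net_sr = data.frame(t = res$state$t, net_sr = net),
         peak_time = res$state$t[imax[1]], peak_sf = res$state$sfs[imax[2]],
         peak_sr = max(sr), tuning_contrast = tuning)
  })
}
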