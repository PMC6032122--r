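# Psychometric model and the time-resolved threshold pipeline.
#
# All fitting operates on the contrast scale of the `contrast` column handed
# in; the pipeline uses log10 contrast (staircases step in log units) and
# converts to linear contrast only when reporting thresholds.

#' Logistic psychometric function for a 2AFC detection task
#'
#' \deqn{p(correct) = 0.5 + 0.5 (1 - \lambda) / (1 + e^{(\mu - c)/s})}
#'
#' `mu` is the contrast detection threshold, the 75\%-correct point when
#' `lapse = 0`; `s` the slope; `lapse` the stimulus-independent lapse rate
#' capping asymptotic performance at `1 - lapse/2`.
#'
#' @param contrast numeric vector of stimulus contrasts (any monotone scale;
#'   the pipeline uses log10 contrast).
#' @param mu threshold, same scale as `contrast`.
#' @param s slope, `> 0`, same units as `contrast`.
#' @param lapse lapse rate in `[0, 1)`.
#' @return probability correct, in `[0.5, 1 - lapse/2]`.
#' @export
psy_predict <- function(contrast, mu, s, lapse = 0) {
  stopifnot(s > 0, lapse >= 0, lapse < 1)
  0.5 + 0.5 * (1 - lapse) / (1 + exp((mu - contrast) / s))
}

# Bernoulli log-likelihood of responses under the logistic model.
psy_loglik <- function(contrast, correct, mu, s, lapse) {
  p <- psy_predict(contrast, mu, s, lapse)
  # clamp away from exact 0/1 for numerical safety
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(ifelse(correct, log(p), log1p(-p)))
}

#' Maximum-likelihood psychometric fit
#'
#' Fits any subset of (`mu`, `s`, `lapse`) by maximising the Bernoulli
#' likelihood; the remaining parameters are held at the supplied values.
#' Optimisation is deterministic: a fixed multi-start grid over `mu` (and `s`,
#' `lapse` when free) followed by local refinement, so repeated calls on the
#' same data give identical estimates without any seed.
#'
#' @param trials data frame with columns `contrast` and `correct` (logical or
#'   0/1).
#' @param free character vector, subset of `c("mu", "s", "lapse")`.
#' @param mu,s,lapse fixed values (and starting values for free parameters).
#' @return list with `mu`, `s`, `lapse`, `loglik`, `converged`, `boundary`
#'   (TRUE when the data are all-correct or all-wrong and the threshold is
#'   only bounded, not identified).
#' @export
fit_ml <- function(trials, free = "mu", mu = NULL, s = NULL, lapse = NULL) {
  stopifnot(all(free %in% c("mu", "s", "lapse")), nrow(trials) > 0)
  x <- trials$contrast
  y <- as.logical(trials$correct)
  boundary <- all(y) || !any(y)

  if (is.null(mu)) mu <- stats::median(x)
  if (is.null(s)) s <- max(stats::sd(x), 0.05)
  if (is.null(lapse)) lapse <- 0.02

  lo <- min(x); hi <- max(x)
  span <- max(hi - lo, 1e-3)
  mu_lo <- lo - 0.5 * span; mu_hi <- hi + 0.5 * span

  if (identical(free, "mu")) {
    # 1-D problem: coarse grid then golden-section refinement
    grid <- seq(mu_lo, mu_hi, length.out = 41)
    ll <- vapply(grid, function(m) psy_loglik(x, y, m, s, lapse), numeric(1))
    m0 <- grid[which.max(ll)]
    step <- grid[2] - grid[1]
    opt <- stats::optimize(function(m) psy_loglik(x, y, m, s, lapse),
                           lower = max(mu_lo, m0 - 2 * step),
                           upper = min(mu_hi, m0 + 2 * step),
                           maximum = TRUE, tol = 1e-8)
    return(list(mu = opt$maximum, s = s, lapse = lapse,
                loglik = opt$objective, converged = TRUE,
                boundary = boundary))
  }

  # general case: optim over the free parameters with a fixed start grid
  par0 <- c(mu = mu, s = s, lapse = lapse)
  trans <- function(p) {     # unconstrained -> natural
    out <- par0
    for (nm in free) out[nm] <- p[nm]
    out["s"] <- if ("s" %in% free) exp(p["s"]) else s
    out["lapse"] <- if ("lapse" %in% free) stats::plogis(p["lapse"]) * 0.3 else lapse
    out
  }
  negll <- function(p) {
    q <- trans(p)
    -psy_loglik(x, y, q["mu"], q["s"], q["lapse"])
  }
  starts_mu <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  starts_s <- log(c(0.5, 1, 2) * s)
  best <- NULL
  for (m0 in if ("mu" %in% free) starts_mu else mu)
    for (s0 in if ("s" %in% free) starts_s else 0) {
      p0 <- c(mu = m0, s = s0, lapse = stats::qlogis(min(max(lapse / 0.3, 1e-3), 1 - 1e-3)))
      p0 <- p0[free]
      fit <- stats::optim(p0, function(p) {
        q <- p0; q[] <- p    # Brent drops names; assign by position
        negll(q)
      }, method = if (length(free) == 1L) "Brent" else "Nelder-Mead",
      lower = if (length(free) == 1L) -20 else -Inf,
      upper = if (length(free) == 1L) 20 else Inf,
      control = list(maxit = 2000))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  q <- trans(structure(best$par, names = free))
  list(mu = unname(q["mu"]), s = unname(q["s"]), lapse = unname(q["lapse"]),
       loglik = -best$value, converged = best$convergence == 0,
       boundary = boundary)
}

#' Global psychometric fit with a single shared lapse rate
#'
#' Jointly fits one lapse rate across all spatial frequencies while letting
#' threshold and slope vary per frequency; the returned lapse and slopes are
#' intended to be frozen for all subsequent time-binned threshold fits.
#' Implemented as a profile likelihood: for each candidate lapse the per-sf
#' (mu, s) fits are independent, and a 1-D deterministic search maximises the
#' summed log-likelihood over the lapse.
#'
#' @param trials data frame with `contrast`, `correct`, `sf_cpd`.
#' @param sfs the spatial-frequency levels that must all be present.
#' @return list with `lapse`, and a data frame `by_sf` (`sf_cpd`, `mu`, `s`),
#'   plus the joint `loglik`.
#' @export
global_fit <- function(trials, sfs = FIXSENS_SFS) {
  present <- sfs %in% unique(trials$sf_cpd)
  if (!all(present))
    stop("missing spatial-frequency level(s): ", paste(sfs[!present], collapse = ", "))
  split_tr <- lapply(sfs, function(f) trials[trials$sf_cpd == f, , drop = FALSE])

  profile_ll <- function(lam) {
    fits <- lapply(split_tr, function(tr)
      fit_ml(tr, free = c("mu", "s"), lapse = lam))
    list(ll = sum(vapply(fits, `[[`, numeric(1), "loglik")), fits = fits)
  }
  opt <- stats::optimize(function(l) profile_ll(l)$ll,
                         lower = 0, upper = 0.25, maximum = TRUE, tol = 1e-4)
  lam <- opt$maximum
  prof <- profile_ll(lam)
  by_sf <- data.frame(
    sf_cpd = sfs,
    mu = vapply(prof$fits, `[[`, numeric(1), "mu"),
    s = vapply(prof$fits, `[[`, numeric(1), "s")
  )
  list(lapse = lam, by_sf = by_sf, loglik = prof$ll)
}

#' Sliding latency bins
#'
#' Bins trials by microsaccade latency tau into overlapping windows of
#' `width` seconds whose centres advance in `step`-second increments; the bin
#' centred at `tc` holds trials with `tau` in `[tc - width/2, tc + width/2)`.
#'
#' @param trials data frame with a `tau_s` column.
#' @param width,step window width and centre step, seconds.
#' @param range numeric length-2: first and last bin centre.
#' @return list with `centers` and `index` (list of integer row indices).
#' @export
bin_by_latency <- function(trials, width = 0.1, step = 0.002,
                           range = c(-0.2, 0.3)) {
  if (range[2] < range[1]) return(list(centers = numeric(0), index = list()))
  centers <- seq(range[1], range[2], by = step)
  half <- width / 2
  index <- lapply(centers, function(tc)
    which(trials$tau_s >= tc - half & trials$tau_s < tc + half))
  list(centers = centers, index = index)
}

#' Baseline (microsaccade-free) trials
#'
#' Keeps trials with no microsaccade onset inside `(t_stim - 0.5, t_stim +
#' 0.1)` s, i.e. the stimulus occurred more than 0.1 s before or 0.5 s after
#' every microsaccade. Requires per-trial stimulus times and the event onsets;
#' trials whose session contains no event at all qualify.
#'
#' @param trials data frame with `t_stim_s` (and optionally `tau_s`).
#' @param onsets numeric vector of microsaccade onset times for the same
#'   session, or NULL to use the `tau_s`/`tau2_s` columns (nearest and
#'   second-nearest latency) attached by [attach_latency()].
#' @param before,after exclusion-zone half widths: an event with
#'   `t_stim - onset` in `(-after, +before)` disqualifies the trial.
#' @return logical vector, TRUE for baseline-eligible trials.
#' @export
baseline_trials <- function(trials, onsets = NULL, before = 0.1, after = 0.5) {
  if (!is.null(onsets)) {
    if (length(onsets) == 0) return(rep(TRUE, nrow(trials)))
    vapply(trials$t_stim_s, function(ts) {
      d <- ts - onsets
      !any(d > -after & d < before)
    }, logical(1))
  } else {
    # nearest-event latency is sufficient: any offending event is at least as
    # near as the nearest one, and the exclusion zone is an interval around 0
    tau <- trials$tau_s
    is.infinite(tau) | tau >= before | tau <= -after
  }
}

#' Time-resolved sensitivity timecourse
#'
#' For every (latency bin, spatial frequency) cell, refits the threshold with
#' slope and lapse frozen at the global-fit values, and expresses it as a log10
#' sensitivity ratio against a subject-matched baseline threshold:
#' `SR = -(log10 mu_bin - log10 mu_baseline)` on the log10-contrast fitting
#' scale, so negative SR is suppression.
#'
#' @param trials trial table with `tau_s`, `sf_cpd`, `contrast`, `correct`,
#'   `subject`, `t_stim_s`.
#' @param frozen list from [global_fit()] (elements `lapse`, `by_sf`).
#' @param width,step,range passed to [bin_by_latency()].
#' @param n_match subject-matched baseline replicates (see [subject_match()]).
#' @param min_n bins with fewer trials are flagged `low_n`.
#' @param rng optional integer seed for the matching subsamples.
#' @return data frame with `tau_s`, `sf_cpd`, `mu` (log10 contrast),
#'   `mu_baseline`, `sensitivity` (1/linear mu), `sr_log10`, `n_trials`,
#'   `low_n`.
#' @export
sensitivity_timecourse <- function(trials, frozen, width = 0.1, step = 0.002,
                                   range = c(-0.2, 0.3), n_match = 50,
                                   min_n = 30, rng = NULL) {
  base_ok <- baseline_trials(trials)
  base <- trials[base_ok, , drop = FALSE]
  out <- vector("list", length(FIXSENS_SFS))
  for (k in seq_along(frozen$by_sf$sf_cpd)) {
    f <- frozen$by_sf$sf_cpd[k]
    s_k <- frozen$by_sf$s[k]
    tr_f <- trials[trials$sf_cpd == f, , drop = FALSE]
    base_f <- base[base$sf_cpd == f, , drop = FALSE]
    bins <- bin_by_latency(tr_f, width, step, range)
    rows <- lapply(seq_along(bins$centers), function(i) {
      idx <- bins$index[[i]]
      n <- length(idx)
      if (n < 2)
        return(data.frame(tau_s = bins$centers[i], sf_cpd = f, mu = NA_real_,
                          mu_baseline = NA_real_, sensitivity = NA_real_,
                          sr_log10 = NA_real_, n_trials = n, low_n = TRUE))
      bin_tr <- tr_f[idx, , drop = FALSE]
      mu_bin <- fit_ml(bin_tr, "mu", s = s_k, lapse = frozen$lapse)$mu
      # named substream per (sf, bin) cell so reruns are reproducible
      rng_i <- if (is.null(rng)) NULL else (rng + 7919L * k + i) %% 2147483629L
      mb <- subject_match(base_f, bin_tr, n_reps = n_match,
                          s = s_k, lapse = frozen$lapse, rng = rng_i)
      data.frame(tau_s = bins$centers[i], sf_cpd = f, mu = mu_bin,
                 mu_baseline = mb$mu,
                 sensitivity = 10^(-mu_bin),
                 sr_log10 = -(mu_bin - mb$mu),
                 n_trials = n, low_n = n < min_n)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Per-window contrast sensitivity function
#'
#' Thresholds at each spatial frequency for trials whose latency falls inside
#' `window`, with subject-matched baseline thresholds; the classic windows are
#' the suppression period (-0.1 to +0.05 s) and the facilitation period
#' (+0.05 to +0.2 s).
#'
#' @param trials trial table with `tau_s` attached.
#' @param frozen output of [global_fit()].
#' @param window numeric length-2 `[tau_lo, tau_hi)` in seconds.
#' @inheritParams sensitivity_timecourse
#' @return data frame `sf_cpd`, `mu`, `mu_baseline`, `sensitivity`,
#'   `sensitivity_baseline`, `sr_log10`, `n_trials`.
#' @export
window_csf <- function(trials, frozen, window, n_match = 50, rng = NULL) {
  stopifnot(length(window) == 2, window[2] > window[1])
  base <- trials[baseline_trials(trials), , drop = FALSE]
  inwin <- trials$tau_s >= window[1] & trials$tau_s < window[2]
  rows <- lapply(seq_len(nrow(frozen$by_sf)), function(k) {
    f <- frozen$by_sf$sf_cpd[k]
    s_k <- frozen$by_sf$s[k]
    tr <- trials[inwin & trials$sf_cpd == f, , drop = FALSE]
    bf <- base[base$sf_cpd == f, , drop = FALSE]
    if (nrow(tr) < 2)
      return(data.frame(sf_cpd = f, mu = NA_real_, mu_baseline = NA_real_,
                        sensitivity = NA_real_, sensitivity_baseline = NA_real_,
                        sr_log10 = NA_real_, n_trials = nrow(tr)))
    mu <- fit_ml(tr, "mu", s = s_k, lapse = frozen$lapse)$mu
    mb <- subject_match(bf, tr, s = s_k, lapse = frozen$lapse, rng = rng)
    data.frame(sf_cpd = f, mu = mu, mu_baseline = mb$mu,
               sensitivity = 10^(-mu), sensitivity_baseline = 10^(-mb$mu),
               sr_log10 = -(mu - mb$mu), n_trials = nrow(tr))
  })
  do.call(rbind, rows)
}

#' Fold an orientation difference onto the axial range [0, 90]
#'
#' Both gratings and saccade directions are treated as axial (mod 180); the
#' returned angle is 0 for parallel and 90 for orthogonal.
#' @param stim_deg,event_deg orientations/directions in degrees.
#' @export
axial_difference <- function(stim_deg, event_deg) {
  d <- abs(stim_deg - event_deg) %% 180
  pmin(d, 180 - d)
}

#' Sensitivity by stimulus-microsaccade orientation difference
#'
#' Partitions suppression-window trials into 18-degree bins of the axial angle
#' between the stimulus orientation and the nearest microsaccade's direction,
#' and fits a threshold per bin (frozen slope/lapse), with a subject-matched
#' baseline per bin.
#'
#' @param trials suppression-window trials with `stim_orientation_deg`,
#'   `event_direction_deg`, `contrast`, `correct`, `subject`, `sf_cpd`.
#' @param frozen output of [global_fit()]; fits pool spatial frequencies using
#'   each trial's own frozen slope unless `sf` restricts to one frequency.
#' @param sf optional single spatial frequency to restrict to.
#' @param bin_width degrees, default 18 (five bins spanning 0-90).
#' @inheritParams sensitivity_timecourse
#' @return data frame `bin_center_deg`, `sf_cpd`, `mu`, `mu_baseline`,
#'   `sr_log10`, `n_trials`.
#' @export
orientation_partition <- function(trials, frozen, sf = NULL, bin_width = 18,
                                  n_match = 50, rng = NULL) {
  if (!is.null(sf)) trials <- trials[trials$sf_cpd == sf, , drop = FALSE]
  stopifnot(nrow(trials) > 0)
  delta <- axial_difference(trials$stim_orientation_deg,
                            trials$event_direction_deg)
  edges <- seq(0, 90, by = bin_width)
  bin <- findInterval(delta, edges, rightmost.closed = TRUE)
  sfs_here <- sort(unique(trials$sf_cpd))
  rows <- list()
  for (f in sfs_here) {
    s_k <- frozen$by_sf$s[match(f, frozen$by_sf$sf_cpd)]
    for (b in seq_len(length(edges) - 1)) {
      tr <- trials[bin == b & trials$sf_cpd == f, , drop = FALSE]
      if (nrow(tr) < 2) next
      mu <- fit_ml(tr, "mu", s = s_k, lapse = frozen$lapse)$mu
      rows[[length(rows) + 1L]] <- data.frame(
        bin_center_deg = (edges[b] + edges[b + 1]) / 2, sf_cpd = f,
        mu = mu, sensitivity = 10^(-mu), n_trials = nrow(tr))
    }
  }
  do.call(rbind, rows)
}
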