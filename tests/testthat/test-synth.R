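test_that("config validation rejects degenerate settings", {
  expect_error(synth_config(session_duration = 0), "session_duration")
  expect_error(synth_config(sampling_rate = -1), "sampling_rate")
  expect_error(synth_config(ms_rate = 2.3, ms_refractory = 0.5), "refractory")
  expect_error(synth_config(stair_step = 0))
})

test_that("identical seed and config give identical outputs", {
  cfg <- synth_config(seed = 11, session_duration = 20)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$events, b$events)
  ta <- generate_trace(cfg, duration = 5)
  tb <- generate_trace(cfg, duration = 5)
  expect_identical(ta$trace, tb$trace)
})

test_that("zero microsaccade rate yields a drift-only trace with no events", {
  cfg <- synth_config(seed = 3, ms_rate = 0, blink_rate = 0,
                      session_duration = 10)
  tr <- generate_trace(cfg)
  expect_equal(nrow(tr$events), 0)
  # no sample-to-sample jump larger than plausible drift + noise
  expect_lt(max(abs(diff(tr$trace$xL_deg))), 0.05)
})

test_that("noiseless events sit exactly on the main-sequence power law", {
  cfg <- synth_config(seed = 4, ms_noise_sd = 0, session_duration = 60)
  ev <- generate_trace(cfg)$events
  expect_gt(nrow(ev), 10)
  expect_equal(ev$peak_velocity_dps,
               cfg$ms_k * (ev$amplitude_arcmin / 60)^cfg$ms_b,
               tolerance = 1e-12)
})

test_that("event count falls in the Poisson 99% interval of rate x duration", {
  cfg <- synth_config(seed = 1, session_duration = 60)
  n <- nrow(generate_trace(cfg)$events)
  lambda <- cfg$ms_rate * 60
  expect_gte(n, qpois(0.005, lambda))
  expect_lte(n, qpois(0.995, lambda))
})

test_that("event amplitudes stay in bounds and onsets respect the refractory gap", {
  cfg <- synth_config(seed = 5, session_duration = 120)
  ev <- generate_trace(cfg)$events
  expect_true(all(ev$amplitude_arcmin >= 3 & ev$amplitude_arcmin <= 60))
  expect_true(all(diff(ev$onset_s) >= cfg$ms_refractory - 1e-12))
})

test_that("template evaluates suppression and facilitation Gaussians", {
  tpl <- sensitivity_template()
  expect_equal(template_sr(-1, 0.1, tpl), 0, tolerance = 1e-10)
  expect_equal(template_sr(Inf, 0.1, tpl), 0)
  tpl0 <- sensitivity_template(facilitation_amp = rep(0, 5))
  expect_equal(template_sr(0.02, 0.1, tpl0), tpl0$suppression_depth[1])
  expect_gt(template_sr(0.125, 2, tpl), 0)
  expect_error(template_sr(0.1, 0.7, tpl), "unknown")
})

test_that("staircases converge near the 1-up-3-down point of the psychometric", {
  cfg <- synth_config(seed = 6, n_trials = 10000, observer_lapse = 0,
                      template = null_template())
  sess <- simulate_session(cfg)
  # analytic convergence: p* = 0.5^(1/3); solving the logistic for c at p*
  # gives c* = mu - s*log(0.5/(p*-0.5) - 1)
  p_star <- 0.5^(1 / 3)
  for (k in seq_along(cfg$sfs)) {
    c_star <- cfg$observer_mu[k] -
      cfg$observer_s[k] * log(0.5 / (p_star - 0.5) - 1)
    tr <- sess$trials[sess$trials$sf_cpd == cfg$sfs[k], ]
    tail_c <- tr$contrast[(nrow(tr) %/% 2):nrow(tr)]
    expect_equal(mean(tail_c), c_star, tolerance = 0.04)
  }
})

test_that("null template makes correctness independent of latency", {
  cfg <- synth_config(seed = 7, n_trials = 10000, template = null_template())
  sess <- simulate_session(cfg)
  tr <- sess$trials[is.finite(sess$trials$tau_true_s) &
                      abs(sess$trials$tau_true_s) < 0.5, ]
  bin <- cut(tr$tau_true_s, seq(-0.5, 0.5, by = 0.1))
  p <- suppressWarnings(chisq.test(table(bin, tr$correct))$p.value)
  expect_gt(p, 0.01)
})

test_that("suppressed latencies lower accuracy relative to baseline trials", {
  tpl <- sensitivity_template(
    suppression_depth = c(-0.2, 0, 0, 0, 0),
    facilitation_amp = rep(0, 5))
  cfg <- synth_config(seed = 8, n_trials = 8000, template = tpl)
  sess <- simulate_session(cfg)
  tr <- sess$trials[sess$trials$sf_cpd == 0.1, ]
  inwin <- tr$tau_true_s >= -0.1 & tr$tau_true_s < 0.05
  base <- is.infinite(tr$tau_true_s) | tr$tau_true_s >= 0.1 |
    tr$tau_true_s <= -0.5
  expect_gt(sum(inwin), 100)
  expect_lt(mean(tr$correct[inwin]), mean(tr$correct[base]))
})
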