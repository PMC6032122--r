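test_that("the logistic psychometric has the stated identities and limits", {
  expect_equal(psy_predict(0.3, mu = 0.3, s = 0.1, lapse = 0), 0.75)
  expect_equal(psy_predict(1e6, mu = 0.3, s = 0.1, lapse = 0.1), 1 - 0.1 / 2)
  expect_equal(psy_predict(-1e6, mu = 0.3, s = 0.1, lapse = 0.1), 0.5)
  # monotone nondecreasing in contrast
  cc <- seq(-3, 1, length.out = 200)
  expect_true(all(diff(psy_predict(cc, -1, 0.1, 0.05)) >= 0))
})

test_that("threshold-only ML fit recovers the generating threshold", {
  cc <- rep(seq(0.02, 0.25, length.out = 8), each = 250)
  tr <- psy_trials(cc, mu = 0.1, s = 0.09, lapse = 0.055, seed = 5)
  fit <- fit_ml(tr, free = "mu", s = 0.09, lapse = 0.055)
  expect_equal(fit$mu, 0.1, tolerance = 0.05 * 0.1 / 0.1)  # within 5%
  expect_lt(abs(fit$mu - 0.1) / 0.1, 0.05)

  # duplicating every trial scales the likelihood but not the argmax
  fit2 <- fit_ml(rbind(tr, tr), free = "mu", s = 0.09, lapse = 0.055)
  expect_equal(fit2$mu, fit$mu, tolerance = 1e-6)
  expect_equal(fit2$loglik, 2 * fit$loglik, tolerance = 1e-6)
})

test_that("free lapse is recovered from the saturation level", {
  # performance ceiling at 0.95 implies lapse = 0.1
  tr <- psy_trials(rep(5, 4000), mu = 0.1, s = 0.09, lapse = 0.1, seed = 6)
  fit <- fit_ml(tr, free = "lapse", mu = 0.1, s = 0.09)
  expect_lt(abs(fit$lapse - 0.1), 0.02)   # ~3 binomial SDs at n = 4000
})

test_that("threshold-only fit matches a dense 1-D likelihood grid search", {
  tr <- psy_trials(rep(c(-2, -1.6), each = 300), mu = -1.8, s = 0.1,
                   lapse = 0.05, seed = 7)
  fit <- fit_ml(tr, free = "mu", s = 0.1, lapse = 0.05)
  grid <- seq(-2.5, -1.1, by = 1e-5)
  ll <- vapply(grid, function(m)
    sum(ifelse(tr$correct, log(psy_predict(tr$contrast, m, 0.1, 0.05)),
               log(1 - psy_predict(tr$contrast, m, 0.1, 0.05)))), numeric(1))
  expect_lt(abs(fit$mu - grid[which.max(ll)]), 1e-4)
})

test_that("boundary data are flagged", {
  tr <- data.frame(contrast = rep(0.5, 50), correct = TRUE)
  expect_true(fit_ml(tr, free = "mu", s = 0.1, lapse = 0)$boundary)
})

test_that("global fit recovers lapse and slopes from a staircase session", {
  cfg <- synth_config(seed = 3, n_trials = 15000, template = null_template())
  sess <- simulate_session(cfg)
  gf <- global_fit(sess$trials)
  expect_gt(gf$lapse, 0.03)
  expect_lt(gf$lapse, 0.08)
  expect_true(all(abs(gf$by_sf$s - cfg$observer_s) / cfg$observer_s < 0.2))
  expect_true(all(abs(gf$by_sf$mu - cfg$observer_mu) < 0.06))
  expect_error(global_fit(sess$trials[sess$trials$sf_cpd != 1, ]), "missing")
})

test_that("equal data at all frequencies give agreeing slope estimates", {
  cc <- rep(seq(-2.1, -1.5, length.out = 7), each = 300)
  one <- psy_trials(cc, mu = -1.8, s = 0.1, lapse = 0.05, seed = 8)
  trials <- do.call(rbind, lapply(FIXSENS_SFS, function(f)
    transform(one, sf_cpd = f)))
  gf <- global_fit(trials)
  expect_lt(diff(range(gf$by_sf$s)), 1e-6)
  expect_lt(diff(range(gf$by_sf$mu)), 1e-6)
})

test_that("sliding bins share trials according to the window arithmetic", {
  tr <- data.frame(tau_s = 0.049)
  bins <- bin_by_latency(tr, width = 0.1, step = 0.002, range = c(-0.2, 0.3))
  inbin <- vapply(bins$index, length, integer(1)) == 1
  expect_equal(range(bins$centers[inbin]), c(0.0, 0.098))

  empty <- bin_by_latency(tr, range = c(0.3, -0.2))
  expect_length(empty$centers, 0)

  set.seed(9)
  tru <- data.frame(tau_s = runif(1000, -0.5, 0.5))
  b <- bin_by_latency(tru, width = 0.1, step = 0.05, range = c(-0.3, 0.3))
  counts <- vapply(b$index, length, integer(1))
  expect_true(all(abs(counts - 100) < 40))   # expected = density x width = 100
})

test_that("baseline eligibility excludes the perisaccadic zone around every event", {
  trials <- data.frame(t_stim_s = c(10, 20, 30), tau_s = c(Inf, 0.05, NA))
  expect_true(baseline_trials(trials)[1])
  expect_false(baseline_trials(trials)[2])
  # explicit onsets: events at -0.6 and +0.2 relative to the stimulus are
  # both outside the exclusion zone
  t3 <- data.frame(t_stim_s = 10)
  expect_true(baseline_trials(t3, onsets = c(10.6, 9.8)))
  expect_false(baseline_trials(t3, onsets = c(10.6, 9.95)))
})

test_that("SR is invariant to a global contrast rescaling", {
  cfg <- synth_config(seed = 12, n_trials = 4000)
  sess <- simulate_session(cfg)
  trials <- attach_latency(sess$trials, sess$events)
  gf <- list(lapse = cfg$observer_lapse,
             by_sf = data.frame(sf_cpd = cfg$sfs, mu = cfg$observer_mu,
                                s = cfg$observer_s))
  w1 <- window_csf(trials, gf, c(-0.1, 0.05))
  shifted <- trials
  shifted$contrast <- shifted$contrast + 0.5   # x10 in linear contrast
  gf2 <- gf; gf2$by_sf$mu <- gf2$by_sf$mu + 0.5
  w2 <- window_csf(shifted, gf2, c(-0.1, 0.05))
  expect_equal(w2$sr_log10, w1$sr_log10, tolerance = 1e-6)
  expect_equal(w2$mu, w1$mu + 0.5, tolerance = 1e-6)
})

test_that("window CSFs recover the template's spatial tuning", {
  tpl <- sensitivity_template(facilitation_amp = rep(0, 5))  # suppression only
  cfg <- synth_config(seed = 13, n_trials = 12000, template = tpl)
  sess <- simulate_session(cfg)
  trials <- attach_latency(sess$trials, sess$events)
  gf <- global_fit(trials)
  w <- window_csf(trials, gf, c(-0.1, 0.05), rng = 13)
  expect_true(all(w$sr_log10 < 0))
  expect_equal(w$sf_cpd[which.min(w$sr_log10)], 0.1)

  # a window covering every latency dilutes to baseline
  wide <- window_csf(trials, gf, c(-20, 20), rng = 13)
  expect_true(all(abs(wide$sr_log10) < 0.05))
})

test_that("orientation differences fold axially into [0, 90]", {
  expect_equal(axial_difference(45, 45), 0)
  expect_equal(axial_difference(45, 135), 90)
  expect_equal(axial_difference(-45, 305), 10)
  expect_equal(axial_difference(0, 171), 9)
})
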