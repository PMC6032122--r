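test_that("pure noise below threshold yields no candidates", {
  set.seed(1)
  n <- 5000; tt <- (seq_len(n) - 1) / 500
  vx <- rnorm(n, 0, 0.5); vy <- rnorm(n, 0, 0.5)
  cand <- detect_candidates(tt, vx, vy)
  expect_equal(nrow(cand), 0)
})

test_that("an injected velocity excursion yields exactly one candidate", {
  set.seed(2)
  n <- 5000; tt <- (seq_len(n) - 1) / 500
  vx <- rnorm(n, 0, 0.5); vy <- rnorm(n, 0, 0.5)
  vx[2000:2010] <- vx[2000:2010] + 30
  cand <- detect_candidates(tt, vx, vy)
  expect_equal(nrow(cand), 1)
  expect_lte(cand$onset_s, tt[2010])
  expect_gte(cand$offset_s, tt[2000])
})

test_that("the median-based sigma is insensitive to a single extreme outlier", {
  set.seed(3)
  v <- rnorm(20000, 0, 0.5)
  s0 <- sqrt(median(v^2) - median(v)^2)
  v_out <- c(v, 500)
  s1 <- sqrt(median(v_out^2) - median(v_out)^2)
  expect_lt(abs(s1 - s0) / s0, 0.01)
  # in contrast, the plain SD moves substantially
  expect_gt(abs(sd(v_out) - sd(v)) / sd(v), 0.5)
})

test_that("nearby candidates merge transitively and filters apply after", {
  # synthetic positions: a 0.3-deg ramp from sample 300 to 344 carrying
  # three above-threshold bursts 30 ms apart
  rate <- 500; dt <- 1 / rate
  tt <- (0:999) * dt
  x <- numeric(1000); vr <- numeric(1000)
  x[300:344] <- 0.3 * (0:44) / 44
  x[345:1000] <- 0.3
  vr[c(300:304, 320:324, 340:344)] <- 40
  cand <- data.frame(onset_s = tt[c(300, 320, 340)],
                     offset_s = tt[c(304, 324, 344)],
                     onset_idx = c(300L, 320L, 340L),
                     offset_idx = c(304L, 324L, 344L))
  ev <- filter_and_merge(cand, tt, x, numeric(1000), vr)
  expect_equal(nrow(ev), 1)             # transitive merge
  expect_equal(ev$onset_s, tt[300])
  expect_equal(ev$offset_s, tt[344])
  expect_equal(ev$amplitude_arcmin, 0.3 * 60, tolerance = 1e-9)

  # sub-3-arcmin amplitude is discarded
  x2 <- numeric(1000); x2[300:1000] <- 0.02   # 1.2 arcmin
  ev2 <- filter_and_merge(cand[1, ], tt, x2, numeric(1000), vr)
  expect_equal(nrow(ev2), 0)

  # sub-6-ms duration is discarded
  cand3 <- data.frame(onset_s = tt[300], offset_s = tt[302],
                      onset_idx = 300L, offset_idx = 302L)
  ev3 <- filter_and_merge(cand3, tt, x, numeric(1000), vr)
  expect_equal(nrow(ev3), 0)
})

test_that("binocular filter requires temporal overlap in both eyes", {
  L <- data.frame(onset_s = c(1, 2, 3), offset_s = c(1.02, 2.02, 3.02),
                  duration_s = 0.02, amplitude_arcmin = 10,
                  peak_velocity_dps = 20, direction_deg = 0)
  expect_equal(nrow(binocular_filter(L, L)), 3)
  R <- L[2, ]
  expect_equal(binocular_filter(L, R)$onset_s, 2)
  # 1-sample partial overlap suffices
  R2 <- data.frame(onset_s = 1.02, offset_s = 1.05, duration_s = 0.03,
                   amplitude_arcmin = 10, peak_velocity_dps = 20,
                   direction_deg = 0)
  expect_equal(nrow(binocular_filter(L[1, ], R2)), 1)
  expect_equal(nrow(binocular_filter(L[1, ], R2[integer(0), ])), 0)
})

test_that("main sequence is exact for noiseless power-law events", {
  A <- seq(4, 50, length.out = 20)
  ev <- data.frame(amplitude_arcmin = A,
                   peak_velocity_dps = 80 * (A / 60)^1.3)
  ms <- main_sequence(ev)
  expect_equal(ms$r, 1, tolerance = 1e-12)
  expect_equal(ms$slope, 1.3, tolerance = 1e-9)
  expect_error(main_sequence(ev[1:2, ]), "fewer than 3")
})

test_that("shuffling the amplitude/velocity pairing destroys the correlation", {
  set.seed(4)
  A <- exp(rnorm(500, log(15), 0.5))
  ev <- data.frame(amplitude_arcmin = A,
                   peak_velocity_dps = 100 * (A / 60) * exp(rnorm(500, 0, 0.15)))
  expect_gt(main_sequence(ev)$r, 0.9)
  ev$peak_velocity_dps <- sample(ev$peak_velocity_dps)
  expect_lt(abs(main_sequence(ev)$r), 0.2)
})

test_that("direction histogram sums to 1 and localizes pure directions", {
  ev <- data.frame(direction_deg = rep(0, 10))
  h <- direction_histogram(ev, n_bins = 8)
  expect_equal(sum(h$proportion), 1)
  expect_equal(h$proportion[h$bin_center_deg == 0], 1)
})

test_that("detection recovers the synthetic ground truth", {
  cfg <- synth_config(seed = 21, session_duration = 420)
  tr <- generate_trace(cfg)
  trace <- mask_blinks(tr$trace)
  det <- detect_microsaccades(trace)
  expect_gt(nrow(tr$events), 500)
  # events fully hidden by the blink mask cannot be recovered; score the rest
  dt <- 1 / cfg$sampling_rate
  visible <- vapply(seq_len(nrow(tr$events)), function(i) {
    sel <- trace$time_s >= tr$events$onset_s[i] - 2 * dt &
      trace$time_s <= tr$events$offset_s[i] + 2 * dt
    all(trace$valid[sel])
  }, logical(1))
  sc <- event_overlap_counts(tr$events[visible, ], det)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.9)
  # retained events satisfy the microsaccade invariants exactly
  expect_true(all(det$offset_s > det$onset_s))
  expect_true(all(det$duration_s >= 0.006))
  expect_true(all(det$amplitude_arcmin >= 3 & det$amplitude_arcmin <= 60))
  expect_true(all(det$peak_velocity_dps > 0))
  # main sequence on detected events reaches the reported lower bound
  expect_gte(main_sequence(det)$r, 0.86)
  # horizontal dominance: bins straddling 0 and 180 jointly exceed 0.5
  h <- direction_histogram(det, n_bins = 8)
  expect_gt(sum(h$proportion[h$bin_center_deg %in% c(0, 180)]), 0.5)
})

test_that("shifting the trace in time shifts all onsets equally", {
  cfg <- synth_config(seed = 22, session_duration = 60, blink_rate = 0)
  tr <- generate_trace(cfg)
  det1 <- detect_microsaccades(tr$trace)
  shifted <- tr$trace
  shifted$time_s <- shifted$time_s + 5
  det2 <- detect_microsaccades(shifted)
  expect_equal(det2$onset_s, det1$onset_s + 5, tolerance = 1e-9)
})
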