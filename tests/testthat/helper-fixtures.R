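# Shared in-code fixtures for the test suite.

# flat binocular trace on a 500-Hz grid (constant position, pupil 1)
flat_trace <- function(duration = 2, rate = 500, x = 0, y = 0) {
  n <- duration * rate + 1
  tt <- (seq_len(n) - 1) / rate
  data.frame(time_s = tt, xL_deg = x, yL_deg = y, pupilL = 1,
             xR_deg = x, yR_deg = y, pupilR = 1)
}

# Bernoulli trials from the logistic psychometric at given contrasts
psy_trials <- function(contrast, mu, s, lapse = 0, seed = 1) {
  set.seed(seed)
  p <- psy_predict(contrast, mu, s, lapse)
  data.frame(contrast = contrast, correct = stats::runif(length(contrast)) < p)
}

# independent brute-force box-count oracle: enumerate cells sample by sample
box_count_oracle <- function(x, y, box = 0.01) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_integer_)
  cells <- character(0)
  for (i in which(ok)) {
    key <- paste(floor(x[i] / box), floor(y[i] / box), sep = ",")
    if (!(key %in% cells)) cells <- c(cells, key)
  }
  length(cells)
}

# interval-union oracle: total invalid mask from blink intervals +/- buffer
mask_oracle <- function(times, blink_times, buffer) {
  bad <- rep(FALSE, length(times))
  for (b in blink_times) bad <- bad | (times >= b - buffer & times <= b + buffer)
  bad
}

# match detected to true events by interval overlap
event_overlap_counts <- function(true_ev, det_ev) {
  rec <- vapply(seq_len(nrow(true_ev)), function(i)
    any(true_ev$onset_s[i] <= det_ev$offset_s &
          true_ev$offset_s[i] >= det_ev$onset_s), logical(1))
  prec <- vapply(seq_len(nrow(det_ev)), function(i)
    any(det_ev$onset_s[i] <= true_ev$offset_s &
          det_ev$offset_s[i] >= true_ev$onset_s), logical(1))
  list(recall = mean(rec), precision = mean(prec))
}
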