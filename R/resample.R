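# Subject-matched baselines, bootstrap CIs, permutation tests.

#' Largest-remainder apportionment of counts to proportions
#'
#' Distributes `n` integer counts across categories so that counts/n match
#' `prop` as closely as possible: each category gets the floor of its quota
#' and the remaining units go to the largest fractional remainders
#' (ties broken by category order, deterministically).
#'
#' @param prop nonnegative proportions (normalised internally).
#' @param n total count.
#' @return integer vector summing to `n`.
#' @export
largest_remainder <- function(prop, n) {
  stopifnot(all(prop >= 0), sum(prop) > 0, n >= 0)
  quota <- prop / sum(prop) * n
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Subject-matched baseline threshold
#'
#' Builds `n_reps` baseline subsamples whose per-subject trial proportions
#' match the composition of a target bin (largest-remainder rounding), fits a
#' threshold to each with slope/lapse frozen, and returns the mean across
#' replicates. Controls for subjects with high microsaccade rates dominating
#' perisaccadic bins while contributing little baseline data, and vice versa.
#'
#' @param baseline baseline-eligible trials (one spatial frequency) with
#'   `subject`, `contrast`, `correct`.
#' @param bin trials of the target bin (defines the subject composition).
#' @param n_reps number of matched subsamples, default 50.
#' @param s,lapse frozen slope and lapse for the threshold fits.
#' @param size subsample size; default is the largest size for which every
#'   subject's baseline pool can supply its quota without replacement, capped
#'   at the baseline size.
#' @param rng optional integer seed (local to this call).
#' @return list: `mu` (mean threshold), `mu_reps`, `counts` (per-subject
#'   counts used), `size`.
#' @export
subject_match <- function(baseline, bin, n_reps = 50, s, lapse,
                          size = NULL, rng = NULL) {
  if (!is.null(rng)) set.seed(rng)
  subs <- sort(unique(as.character(bin$subject)))
  prop <- as.numeric(table(factor(as.character(bin$subject), levels = subs)))
  prop <- prop / sum(prop)
  pools <- lapply(subs, function(sj)
    which(as.character(baseline$subject) == sj))
  npool <- vapply(pools, length, integer(1))
  if (any(npool == 0))
    stop("subject(s) with empty baseline pool: ",
         paste(subs[npool == 0], collapse = ", "))
  if (is.null(size)) {
    size <- min(floor(npool / prop), nrow(baseline))
    size <- max(size, length(subs))
  }
  counts <- largest_remainder(prop, size)
  # quotas cannot exceed pools by construction of `size`; guard anyway
  counts <- pmin(counts, npool)
  if (all(counts == npool)) {
    # every replicate would draw each subject's entire pool: one exact fit
    mu <- fit_ml(baseline, "mu", s = s, lapse = lapse)$mu
    return(list(mu = mu, mu_reps = rep(mu, n_reps), counts = counts,
                size = sum(counts)))
  }
  mu_reps <- vapply(seq_len(n_reps), function(r) {
    idx <- unlist(lapply(seq_along(pools), function(j) {
      if (counts[j] == 0) return(integer(0))
      pools[[j]][sample.int(npool[j], counts[j])]
    }))
    fit_ml(baseline[idx, , drop = FALSE], "mu", s = s, lapse = lapse)$mu
  }, numeric(1))
  list(mu = mean(mu_reps), mu_reps = mu_reps, counts = counts, size = sum(counts))
}

#' Nonparametric bootstrap confidence interval
#'
#' Resamples trials with replacement (before any binning the statistic
#' performs), recomputes the statistic on each resample, and returns
#' percentile intervals. Statistic failures (errors or NA) cause the resample
#' to be redrawn, up to 10 extra draws per replicate, with the redraw count
#' reported.
#'
#' @param trials data frame of trials.
#' @param statistic function(trials) -> numeric (scalar or fixed-length
#'   vector).
#' @param n_boot bootstrap replicates, default 1000.
#' @param level coverage, default 0.95.
#' @param rng optional integer seed.
#' @return list: `estimate` (statistic on the original data), `ci_lo`,
#'   `ci_hi`, `replicates` (matrix n_boot x k), `n_redrawn`.
#' @export
bootstrap_ci <- function(trials, statistic, n_boot = 1000, level = 0.95,
                         rng = NULL) {
  if (!is.null(rng)) set.seed(rng)
  est <- statistic(trials)
  k <- length(est)
  reps <- matrix(NA_real_, n_boot, k)
  n_redrawn <- 0L
  n <- nrow(trials)
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(11L)) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(trials[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (length(val) == k && !anyNA(val)) break
      n_redrawn <- n_redrawn + 1L
      val <- rep(NA_real_, k)
    }
    reps[b, ] <- val
  }
  a <- (1 - level) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  list(estimate = est, ci_lo = unname(qs[1, ]), ci_hi = unname(qs[2, ]),
       replicates = reps, n_redrawn = n_redrawn)
}

#' Permutation test for a threshold difference between two trial groups
#'
#' Pools the two groups, permutes group labels preserving group sizes, refits
#' both thresholds (slope/lapse frozen) per permutation, and compares the
#' observed `|delta log10 mu|` with the permutation distribution. Two-sided,
#' add-one corrected: `p = (1 + #(perm >= obs)) / (n_perm + 1)`.
#'
#' @param group1,group2 trial data frames with `contrast`, `correct`.
#' @param s,lapse frozen slope and lapse.
#' @param n_perm permutations, default 1000.
#' @param rng optional integer seed.
#' @return list: `p`, `observed` (|delta mu|), `mu1`, `mu2`, `perm_stats`.
#' @export
permutation_test <- function(group1, group2, s, lapse, n_perm = 1000,
                             rng = NULL) {
  stopifnot(nrow(group1) > 0, nrow(group2) > 0)
  if (!is.null(rng)) set.seed(rng)
  fit1 <- fit_ml(group1, "mu", s = s, lapse = lapse)$mu
  fit2 <- fit_ml(group2, "mu", s = s, lapse = lapse)$mu
  obs <- abs(fit1 - fit2)
  pool <- rbind(group1[, c("contrast", "correct")],
                group2[, c("contrast", "correct")])
  n1 <- nrow(group1); n <- nrow(pool)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n1)
    m1 <- fit_ml(pool[idx, , drop = FALSE], "mu", s = s, lapse = lapse)$mu
    m2 <- fit_ml(pool[-idx, , drop = FALSE], "mu", s = s, lapse = lapse)$mu
    abs(m1 - m2)
  }, numeric(1))
  p <- (1 + sum(perm_stats >= obs)) / (n_perm + 1)
  list(p = p, observed = obs, mu1 = fit1, mu2 = fit2, perm_stats = perm_stats)
}
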