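---
title: "Methods: microsaccade-locked contrast sensitivity and the delayed gain model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsaccade-locked contrast sensitivity and the delayed gain model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixsens)
```

## The scientific problem

During fixation the eyes make small involuntary saccades (microsaccades,
here 3–60 arcmin) once or twice per second, separated by slow ocular drift.
Contrast sensitivity is not constant around these movements: it is suppressed
just before and during a microsaccade — most strongly for low spatial
frequencies — and facilitated roughly 0.1–0.2 s after onset, most strongly
near 1–2 cycles/°. `fixsens` implements the full analysis chain needed to
measure these modulations from binocular gaze recordings and trial-by-trial
detection responses, and a normative gain model that links suppression and
facilitation through delayed divisive normalization between
spatial-frequency channels.

Because no human dataset ships with the package, every stage is driven and
validated by a synthetic-session generator with known ground truth. The
generator is first-class, tested code: its defaults *are* the study
conditions, and the test suite performs parameter recovery against them.

## The psychometric model

Performance in the two-alternative orientation task is modelled as a
logistic over contrast $c$:

$$p(\mathrm{correct}) = 0.5 + \frac{0.5\,(1-\lambda)}{1 + e^{(\mu - c)/s}}$$

with threshold $\mu$ (the 75%-correct point when $\lambda = 0$), slope $s$,
and lapse rate $\lambda$ capping asymptotic performance at $1-\lambda/2$.
Fitting operates on log10 contrast (the staircases step in log units);
thresholds convert to linear contrast only for reporting. The protocol is:
one *global* maximum-likelihood fit of the whole session with a single
shared $\lambda$ and per-frequency $(\mu, s)$; the lapse and slopes are then
frozen and only $\mu$ is refit in every time bin. The optimizer is a
deterministic multi-start grid plus local refinement, so fits are
reproducible without seeds.

All sensitivity comparisons are expressed as the log sensitivity ratio

$$SR = \log_{10}\frac{1/\mu_{\mathrm{bin}}}{1/\mu_{\mathrm{baseline}}},$$

negative under suppression and positive under facilitation. (Written as a
threshold ratio the same quantity is $-\log_{10}(\mu_{\mathrm{bin}}/
\mu_{\mathrm{baseline}})$; defining SR on sensitivities rather than
thresholds is what makes the suppression profile negative, consistent with
the gain model's polynomial and with the sign conventions used throughout.)

Latency bins are 100 ms wide and slide in small steps (2 ms for
figure-quality timecourses; coarser steps are used in routine tests purely
to reduce the number of refits). A trial is *baseline-eligible* when no
microsaccade onset falls in $(t_{\mathrm{stim}} - 0.5, t_{\mathrm{stim}} +
0.1)$ s — i.e. the stimulus occurred more than 0.1 s before or 0.5 s after
every microsaccade. Note the window averaging attenuates narrow features:
a Gaussian suppression of width 0.067 s averaged over a 0.1-s window keeps
roughly 84% of its peak depth, which is why point estimates of peak
suppression sit slightly above the generating depth while the bootstrap CI
still covers it.

## Eye-movement processing

*Blink handling.* Samples with pupil size 0, plus a 200-ms buffer before and
after, are invalidated (no interpolation); trials with a blink within 100 ms
of the stimulus are discarded. Velocities are computed only inside
contiguous valid runs with the 5-sample moving-window differentiator
$v_n = (p_{n+2}+p_{n+1}-p_{n-1}-p_{n-2})/(6\Delta t)$, which is exact for
linear signals; run edges are left undefined rather than estimated with a
shortened window, to avoid edge artifacts biasing detection. Blink masking
happens before differentiation.

*Microsaccade detection.* Per eye and component, the detection threshold is
6 times a median-based standard deviation,
$\sigma = \sqrt{\mathrm{median}(v^2) - \mathrm{median}(v)^2}$, and a
candidate is a maximal run exceeding the elliptic criterion
$(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$. Candidates separated by less than
50 ms merge into one event (fusing overshoots); events shorter than 6 ms or
with net onset→offset displacement outside 3–60 arcmin are discarded;
surviving events must overlap in time across the two eyes and are reported
with left-eye parameters. Amplitude is net displacement, not path length,
matching main-sequence conventions; direction is the atan2 of the net
displacement (0° = rightward).

*Latency.* Each trial's $\tau$ is the signed time from the onset of the
*nearest* microsaccade ($\tau > 0$: stimulus after onset). An exactly
equidistant pair resolves toward the later event — the conservative choice
for suppression-window assignment — deterministically.

*Drift.* Left-eye positions are collated in ±1-s epochs around each onset,
with all in-event samples removed. Drift magnitude is the number of 0.01°
grid cells the trajectory visits per 50-ms bin, with the grid anchored at
the coordinate origin (deterministic and comparable across bins; per-segment
anchoring would shift counts by ±1 cell unpredictably). Radial velocity is
smoothed with a 5-point moving average. Both metrics are divided by their
baseline means (samples outside $(-0.1, +0.5)$ s around every onset).

## Resampling inference

Baseline thresholds are *subject-matched*: for every (bin, frequency) cell,
50 baseline subsamples are drawn without replacement so that each subject's
share matches their share of the bin (largest-remainder rounding), and the
cell's baseline threshold is the mean of the 50 replicate fits. The
subsample size is the largest one every subject's pool can supply, capped at
the baseline size. With a single subject the procedure degenerates to one
exact fit of the full pool, which the implementation shortcuts.

Confidence intervals are nonparametric bootstrap percentiles, resampling
trials with replacement *before* binning (1,000 replicates for
figure-quality output; tests use 200). Group comparisons use two-sided
permutation tests on $|\Delta \log_{10}\mu|$ with frozen slope/lapse and the
add-one correction $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n+1)$.
No correction is applied across the overlapping sliding bins; raw p-values
are reported. When a *family* of per-cell CIs is checked against a null
(e.g. 45 overlapping cells of a null observer), the calibrated expectation
is nominal coverage, not zero violations; the suite therefore bounds the
violation count by the binomial 99.5th percentile rather than requiring
every CI to cover 0.

## The synthetic-session generator

The generator emulates the study conditions and provides ground truth:

* **Microsaccades** at 1.3/s by default (the observed range is 0.3–2.3/s),
  with a 150-ms refractory gap; log-normal amplitudes (median 15 arcmin,
  log-sd 0.55) truncated to 3–60 arcmin; power-law main sequence
  $v_{\mathrm{peak}} = k A^b$ with $k = 100$ (°/s per °), $b = 1$ and 15%
  multiplicative log-normal noise — parameters in the range typical of
  fixational saccades. The velocity profile is a raised cosine (smooth,
  zero at both endpoints, correct displacement integral); its duration
  follows as $2A/v_{\mathrm{peak}}$, giving 10–30 ms for typical events.
* **Directions** from a von Mises mixture centred at 0° and 180°. The
  concentration ($\kappa = 4$) was set so that the axial horizontal bins of
  an 8-bin histogram jointly hold a clear majority of events, the horizontal
  dominance reported for human microsaccades.
* **Drift** as a 2D Brownian walk with total diffusion 0.005 °²/s — the
  simplest process consistent with drift being roughly constant from
  ~0.05 s after a microsaccade; real drift is mildly self-avoiding, which
  the generator does not emulate.
* **Binocularity**: one generative event stream rendered into both eyes
  with independent 0.005° per-sample measurement noise, so the
  binocular-overlap filter is genuinely exercised.
* **Blinks** at 0.1/s, 300 ms, zeroing the pupil and blanking positions.
* **Trials**: five interleaved 1-up-3-down staircases (one per spatial
  frequency: 0.1, 0.33, 1, 2, 5 cycles/°) stepping 0.05 log10 contrast — a
  conventional step size; the study does not state one, so it is
  configurable. Response-to-stimulus intervals are uniform on 0.8–4.0 s
  with a fixed 0.5-s simulated response time.
* **Observer**: baseline log10 thresholds $(-1.30, -1.70, -2.00, -1.92,
  -1.40)$ — a standard inverted-U contrast sensitivity function peaking near
  1–2 cycles/° — with the global-fit slope and lapse values (0.105, 0.072,
  0.094, 0.089, 0.144; $\lambda = 0.055$) adopted as generating parameters.
  On each trial the effective log threshold is shifted by
  $-SR_{\mathrm{template}}(\tau, f)$, where the template is a negative
  suppression Gaussian (centre 0.02 s, width 0.067 s, depths given by the
  gain model's cubic at the five frequencies) plus a positive facilitation
  Gaussian (centre 0.125 s, width 0.05 s, amplitudes 0/0/0.04/0.08/0.03,
  largest at 2 cycles/°).

What the generator does *not* emulate: microsaccadic inhibition by stimulus
onset (reported to be weak under these near-threshold stimuli), retinal
smear or masking physics, oculomotor correlations between successive
saccade directions, and per-subject heterogeneity (sessions are
single-subject unless concatenated). Passing recovery tests therefore show
the *pipeline* is unbiased under the assumed generative structure, not that
the structure exhausts real data.

Long sessions (a 15,000-trial session spans ≈12 h of simulated fixation)
generate the trial table and ground-truth event stream directly; the 500-Hz
binocular trace is rendered on request and is exercised on shorter
(minutes-long) segments by the detection and drift stages.

## The delayed normative gain model

The model input is a separable suppression surface on a 2-ms time grid from
−0.1 to 0.4 s and the five frequency channels:

$$SR(t, f) = a\,e^{-\left(\frac{t - t_{\mathrm{peak}}}{c}\right)^2}
  \times \left(p_1 x^3 + p_2 x^2 + p_3 x + p_4\right), \quad x = \log_{10} f$$

with $t_{\mathrm{peak}} = 0.02$ s, $c = 0.067$ s and
$(p_1, p_2, p_3, p_4) = (-0.0723, -0.09754, 0.07958, -0.0641)$. Three
numerical readings deserve note, each forced by internal consistency:

* the Gaussian exponent carries a minus sign (a growing exponential could
  not describe a transient suppression);
* the polynomial argument is log10 frequency — on linear frequency the
  cubic term alone would reach magnitude ≈9 at 5 cycles/°, and the log10
  reading reproduces both the low-frequency dominance of suppression and
  the reference rescaled amplitudes;
* "division" of log sensitivity ratios is implemented as mean subtraction
  in log space, i.e. true division of the linear sensitivity ratios.
  Dividing the log values themselves would neither conserve a zero net SR
  at zero delay nor produce sensible rescaling factors.

Normalization iterates time bins in ascending order: the state at $(t, f)$
is reduced by the mean state across channels at $t - t_{\mathrm{delay}}$,
updates happening in place so later bins see normalized earlier bins.
Lookbacks before the grid use a zero (baseline) term. With
$t_{\mathrm{delay}} = 0$ the cross-channel mean is identically zero at
every time bin (machine precision); the low-frequency channels, suppressed
more than the mean, are pushed up less than the high-frequency ones, which
emerge *facilitated* — the model's central qualitative point. As the delay
grows the facilitation moves later and its spatial tuning broadens, and the
in-place recursion leaves a weak oscillation of the net SR after the
facilitation period.

The amplitude $a$ is set by a two-pass procedure: run once with $a = 1$,
rescale $a$ by the ratio of the initial to the normalized SR at the anchor
$(t_{\mathrm{peak}}, 0.1\ \mathrm{cycles/°})$, rebuild, run again. Because
the whole pipeline is linear in the input grid, the final model value at
the anchor equals the initial fit exactly. On the default grid the rescaled
amplitudes at delays $(0, 0.04, 0.06, 0.14)$ s evaluate to approximately
$(2.33, 1.40, 1.30, 1.00)$; the exact values depend at the few-percent
level on the time-grid extent and on whether the five discrete channels or
a denser frequency grid enter the normalization mean, which is why the
package's checks use an absolute ±0.15 band around the reference values
$(2.25, 1.38, 1.29, 1.01)$.

```{r gain-demo}
sw <- sweep_delay(gain_params())
data.frame(t_delay = sapply(sw, `[[`, "t_delay"),
           a_scaled = round(sapply(sw, `[[`, "a_scaled"), 3),
           peak_time = sapply(sw, `[[`, "peak_time"),
           peak_sf = sapply(sw, `[[`, "peak_sf"))
```

## Degenerate inputs and edge policies

Flat velocity traces (zero median-based $\sigma$) raise an error rather
than emitting spurious candidates. Sessions with no microsaccades flow
through the pipeline: all trials are baseline-eligible ($\tau = +\infty$),
timecourse cells are flagged `low_n` rather than erroring, and detection
returns an empty table. Bins with fewer than 30 trials are reported with a
flag, never suppressed — the CI width carries the information. Events at
recording edges yield truncated, flagged drift epochs. Bootstrap replicates
on which the statistic fails are redrawn (up to 10 times) and counted.

## Problem sizes used by the test suite

Module tests run on sessions of 4,000–15,000 trials and traces of 1–8
minutes; the end-to-end recovery checks use 15,000-trial sessions with 200
bootstrap replicates (scaled down from the 1,000 used for figure-quality
intervals), 999-permutation tests across 20 session seeds, and 200
small null sessions with 199-permutation tests for the type-I calibration,
where the p-value grid $\{1/200, \dots, 1\}$ is exact for a
Kolmogorov–Smirnov uniformity check. These sizes were chosen to keep
Monte-Carlo error comfortably below the tested tolerances.

## Known limitations

* No empirical human dataset ships with the package, so the sensitivity
  surfaces are validated by parameter recovery on synthetic sessions rather
  than by reproduction of empirical sensitivity figures.
* The reference best-fitting slopes are adopted as generator defaults on a
  log10-contrast scale; the original contrast units of the slope are not
  stated, so these values are treated as plausible defaults rather than
  numeric targets.
* The permutation scheme permutes trial labels between bin and baseline
  groups; schemes that permute subject-matched replicate labels instead
  would differ for strongly unbalanced multi-subject data.
* Box counting uses the single 0.01° cell size of the drift analysis; no
  multi-scale (fractal-dimension) extension is attempted.
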