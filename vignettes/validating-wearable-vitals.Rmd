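---
title: "Validating wearable vital-sign monitors against reference monitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable vital-sign monitors against reference monitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalagree)
```

## The problem

Postoperative patients on general wards are typically monitored by
intermittent spot checks, although deterioration announces itself in the
continuous vital-sign trace. Wrist-worn photoplethysmography (PPG) devices
can stream heart rate (HR, bpm) and respiratory rate (RR, rpm) continuously,
but before such a device can be trusted its agreement with the bedside
reference monitors (ECG-derived HR, capnography-derived RR) must be
quantified on the population of interest. `vitalagree` implements the full
statistical pipeline for that comparison on paired 1 Hz streams:
synchronization, quality filtering, coverage analytics, repeated-measures
Bland-Altman agreement with MOVER confidence intervals, within-threshold
agreement, and an error-grid classification of clinical risk.

Because clinical recordings of this kind are rarely shareable, the package
ships a synthetic cohort generator with the statistical structure the
analysis assumes, so every stage is exercised end to end and estimators can
be checked against closed-form expectations.

## Data model

A `vital_series` is one device's stream of one vital on a strict 1 Hz grid:
values (with `NA` for missing seconds) and a parallel quality vector.
Wearables report a quality index 0–4 of which only 4 counts as high quality;
reference monitors carry a 0/4 validity flag, a reproducible replacement for
the visual inspection with which reference artifacts are usually discarded.
Missing data have a single encoding: absent value *and* quality 0.

Files are plain delimited text (`t_s,value,quality`, one file per
patient/device/vital). `read_vitals_csv()` places rows on the 1 Hz grid
(absent seconds become missing; duplicate timestamps keep the last
occurrence); `regularize_1hz()` handles sources that are not natively 1 Hz —
sub-second samples are averaged within each second (keeping the worst
constituent quality), and channels slower than 1 Hz, such as a 0.1 Hz
ward-monitor RR feed, are forward-filled up to a hold window of 10 s (one
reporting interval). How a 250 Hz ECG-derived HR should be collapsed to 1 Hz
is not standardized; the mean-within-second rule is this package's choice.

## Synchronization

The two devices are started independently, so their clocks disagree by a
constant offset. `estimate_lag()` recovers it as the integer lag maximizing
the normalized cross-correlation of the mean-centered HR signals (missing
samples excluded pairwise), searched over ±300 s by default. Ties are broken
toward the smallest absolute lag, then toward the negative lag: devices
started near-simultaneously make small offsets the more plausible
explanation. The RR channel reuses its patient's HR lag — both streams share
one device clock, and HR is the better-conditioned signal for alignment.
Constant (zero-variance) signals are rejected as degenerate rather than
returning an arbitrary lag. Where a study would manually correct an
implausible alignment after visual inspection, `run_validation()` accepts an
explicit per-patient lag override instead, which is reproducible.

Drift (a time-varying lag) and sub-second alignment are out of scope.

## Quality filtering, pairing, coverage

`quality_mask()` keeps seconds with quality ≥ 4 and a present value.
Patients whose *reference* recording is absent or shorter than 15 minutes
are excluded per vital (`exclude_short_recordings()`; exactly 15 minutes is
retained). `make_pairs()` intersects the wearable and reference masks on the
aligned grid and reports three availability counts — good wearable, good
reference, both — all sharing the total overlap seconds as denominator,
while the agreement and error-grid statistics use the both-good pairs.

Coverage (`coverage_and_gaps()`) is computed on the wearable mask alone,
because the question it answers is device availability, not joint
availability. A gap is a maximal run of low-quality seconds, including
leading and trailing runs; a mask with no gaps reports 100% of gaps under a
minute by convention. `cohort_coverage_summary()` aggregates per-patient
coverage as median and interquartile range with R's default
linear-interpolation quartiles.

## Repeated-measures Bland-Altman with MOVER intervals

With many seconds per patient, differences $d_{ij}$ (wearable − reference;
the sign convention is declared, not universal) are correlated within
patient, and the classic limits of agreement $\bar d \pm 1.96\,s_d$ computed
on the pooled differences would be dominated by the patients with the
longest recordings and understate the between-patient spread. The package
uses the one-way random-effects decomposition for repeated measures with a
true value that varies over the recording:

$$d_{ij} = \mu + b_i + \varepsilon_{ij}, \qquad
  b_i \sim (0, \sigma_b^2), \quad \varepsilon_{ij} \sim (0, \sigma_w^2).$$

Estimates are method-of-moments: $\hat\mu$ is the unweighted mean of the
per-patient mean differences $\bar d_i$; $s_w^2$ pools the variance around
each patient's mean; and with $m_h$ the harmonic mean of the per-patient
counts (the correction for unbalanced designs),
$s_b^2 = \max\!\bigl(0,\; s_{\bar d}^2 - s_w^2/m_h\bigr)$, truncated at zero
as usual for moment estimators. The SD of a single difference is
$s_d = \sqrt{s_b^2 + s_w^2}$ and the limits of agreement are
$\hat\mu \pm z\,s_d$ with $z = 1.96$. When every patient contributes exactly
one observation this reduces *exactly* to the classic Bland-Altman formula,
and the test suite asserts that reduction at `1e-10`.

Confidence intervals for each limit use the Method Of Variance Estimates
Recovery (MOVER): a $t$-interval for $\mu$ (on $n$ patients) and
$\chi^2$-intervals for the two variance components of
$s_{\bar d}^2 + (1 - 1/m_h)\,s_w^2$ (degrees of freedom $n-1$ and $N-n$) are
recombined into an interval for $\hat\mu \pm z\,s_d$. One numerical choice
is worth stating: the recovered variance interval is centered on the
truncation-consistent total $s_b^2 + s_w^2$, so the interval always contains
the reported limit; whenever the truncation is inactive — in practice almost
always — this is identical to the untruncated construction. The empirical
95% coverage of the upper limit's interval is checked by a 1000-replicate
simulation (50 patients × 100 observations) and required to fall in
[92%, 98%].

Pearson's $r$ is computed over the *pooled* pairs, mixing between- and
within-patient variation — the convention used when a single overall
correlation is reported — and the within-threshold percentage counts
$|d| \le \tau$ inclusively, with the usual clinical thresholds
$\tau = 5$ bpm (HR) and $3$ rpm (RR).

Pairs enter per second without thinning. Autocorrelation within patients
does not bias the point estimates and is partly absorbed by the
between/within decomposition, but the within-patient effective sample size
is smaller than the pair count; MOVER intervals are accordingly anti-
conservative on strongly autocorrelated data. This caveat is documented
rather than corrected, matching second-to-second comparison practice.

## The error grid

The Clarke error grid classifies each (reference, measured) pair by the
clinical consequence of its error. The original glucose geometry is
polygonal; for HR and RR the zones are re-expressed through early-warning-
score thresholds — a low (bradycardia/bradypnea) cutoff, a high
(tachycardia/tachypnea) cutoff, a relative tolerance, and optional treatment
thresholds. Rules are evaluated first-match in the order A, E, D, C, B:

1. **A** — within 20% of the reference, or both values brady (a correctly
   identified bradycardia);
2. **E** — brady and tachy confused in either direction;
3. **D** — reference outside the normal band but the device inside it (a
   missed brady/tachy event), reported with a missed-low/missed-high
   breakdown;
4. **C** — reference normal but the device beyond a treatment threshold
   (unnecessary treatment);
5. **B** — residual benign disagreement.

The normal band is half-open, `[low, high)`: a value exactly at the high
threshold counts as tachy. Defaults are the common MEWS-style bands — HR
50/110 bpm, RR 9/21 rpm — but ward protocols differ, so all four thresholds
are mandatory configuration in any serious reanalysis. The classifier is
verified against an independently coded rule oracle over the full integer
grid (both vitals).

## The synthetic cohort generator

`synthetic_cohort_config()` encodes the study conditions the pipeline is
designed for; its defaults describe a 62-patient postoperative cohort with
recording lengths drawn from a truncated lognormal (median 72 min, range
16 min–10 h) and a per-patient wearable clock offset uniform on ±60 s.
Per vital, the generative model is:

* a latent mean-reverting AR(1) trajectory around a patient baseline
  (population 75 ± 10 bpm, 14 ± 3 rpm). The AR coefficient is 0.99 at 1 Hz
  with innovation SDs 1.0 bpm / 0.3 rpm, giving within-patient SDs of about
  7 bpm / 2.1 rpm and a decorrelation time of roughly 100 s — slow enough to
  be physiological, fast enough that the cross-correlation lag is
  identifiable. (At a coefficient of 0.999 adjacent lags differ by only
  ~0.1% in correlation and exact second-level synchronization becomes
  unreliable; that is a property of any near-unit-root signal, not of the
  estimator.)
* a reference observation: truth plus Gaussian noise (0.7 bpm / 0.8 rpm),
  with i.i.d. invalid samples at 2% (ECG HR) / 26% (capnography RR);
* a wearable observation: truth delayed by the clock offset, plus a
  patient-level bias $\delta_i \sim N(\mu_b, \sigma_b^2)$ (HR −0.15/0.8 bpm,
  RR 0.17/0.8 rpm) and *contaminated-normal* noise — SD 0.93 bpm with
  probability 0.97 and 6.5 bpm otherwise for HR; 0.81/9 rpm at rate 0.06 for
  RR. The contamination makes the difference distribution heavy-tailed, as
  wrist-PPG errors are: with these defaults the total difference SD is
  1.80 bpm / 2.60 rpm while only ~98% of HR pairs fall within 5 bpm and
  ~93% of RR pairs within 3 rpm, percentages a pure Gaussian with the same
  SD could not produce;
* bursty wearable quality dropout from a two-state Markov chain. Mean bad-
  burst lengths are 20 s (HR) and 36 s (RR), so about 96% / 81% of gaps are
  shorter than a minute, and per-patient good-state occupancy is drawn from
  Beta(14, 1) (HR) and Beta(0.9, 2.1) (RR), reproducing both the overall
  availability (~94% HR, ~34% RR) and its wide between-patient spread.
  Residual artifact noise is independent of the quality flag — quality
  indices are imperfect in exactly this way;
* about 13% of patients lack an RR reference (no usable capnography), and
  an optional arrhythmia-burst window forces wearable quality below 4.

`theoretical_agreement()` gives the closed-form expectations: once the lag
is corrected the latent trajectory cancels in the difference, so the bias is
$\mu_b$ and
$\mathrm{sd}_d = \sqrt{\sigma_b^2 + (1-\rho)\sigma_w^2 + \rho\sigma_a^2 +
\sigma_{ref}^2}$ with contamination rate $\rho$. Parameter-recovery tests
run the estimator against these values over 100 seeded cohorts.

Reproducibility follows a substream contract: each patient's record is a
deterministic function of `(seed, patient_index)`, so cohorts are identical
whether generated serially or patient-by-patient, and the generator never
touches the caller's RNG state.

What the generator does **not** emulate: waveform-level PPG/ECG content,
motion-artifact spectra, cardiorespiratory coupling (RR is independent of
HR), clock drift within a recording, and systematic rate-dependent device
error (the bias does not vary with the vital's level). Pipeline tests
passing on this model therefore demonstrate correctness of the statistics
under the stated assumptions, not device performance on real patients.

## Problem sizes and numerical choices

The shipped test suite uses deliberately modest sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances: 100 cohorts of
30 patients × 200 s for parameter recovery, 1000 replicates of
50 × 100 for MOVER coverage, 100 runs of a single 1800 s patient at 2 bpm
wearable noise for exact lag recovery (≥ 99 of 100 required), and the full
integer grid for the error-grid oracle. The acceptance script runs the
default 62-patient study scale.

Other fixed choices: display percentages round half-up (availability as
integers, zone percentages to one decimal, composite rows at or above 99.95
print as "100") and display rounding never feeds back into computation;
negative between-patient variance moments truncate to zero; `z` is 1.96
throughout; empty quality masks propagate as zero pairs and downstream
stages refuse empty inputs explicitly.

## A worked example

```{r example}
cfg <- synthetic_cohort_config(n_patients = 12, duration_s = 1800, seed = 42)
cohort <- simulate_cohort(cfg)
report <- run_validation(cohort$recordings, max_lag_s = 90)
report
```

The HR block reports the availability counts, the repeated-measures bias
and limits of agreement with their MOVER intervals, the pooled correlation
and within-5-bpm percentage, and the error-grid occupancy; `write_validation_report()`
writes the same content as `report.json`, `table2.csv` and plot-ready
Bland-Altman / error-grid point files.

```{r theory}
theoretical_agreement(cfg, "HR")
```

## Limitations

* Second-to-second pairs are autocorrelated; MOVER intervals are
  anti-conservative in proportion to that autocorrelation.
* The bias model is additive and level-independent; proportional error
  would call for a regression-based extension ("trending ability" analysis
  is deliberately out of scope).
* Error-grid defaults are *an* early-warning-score band, not a universal
  one; published grid adaptations must be reproduced by configuring the
  thresholds they state.
* The reference monitor is treated as gold standard plus noise; structured
  reference failure (e.g. capnography during speech) appears only as the
  i.i.d. validity flag.
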