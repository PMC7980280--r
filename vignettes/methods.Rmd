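---
title: "Methods: from two-channel photometry to cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from two-channel photometry to cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladderfp)
```

`ladderfp` analyzes cerebellar Purkinje-cell population calcium signals
(GCaMP6f fiber photometry) recorded while mice perform an adaptive
locomotor-learning task on an automated horizontal ladder. Each learning
session presents a sequence of ladder traversals ("trials"); on *paired*
trials a high-pitched tone (conditioned stimulus, CS) precedes a rising
obstacle (unconditioned stimulus, US) by a 250-ms interstimulus interval.
The package quantifies anticipatory Purkinje activity in the CS--US window,
links it to step-time adaptation, and compares cohorts that differ in
CS--US responsiveness -- a "responsive" (healthy-like) cohort versus an
"attenuated" (injured-like) cohort.

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic-data generator can show.

## The signal model and the isosbestic correction

Two excitation wavelengths give two simultaneous fluorescence channels:
the calcium-dependent GCaMP signal channel and the 410-nm isosbestic
control channel, whose fluorescence is calcium-independent. The
preprocessing assumes a multiplicative model:

$$
S(t) = B_S\,\beta(t)\,\bigl(1 + a(t) + m(t) + \varepsilon_S(t)\bigr), \qquad
C(t) = B_C\,\beta(t)\,\bigl(1 + m(t) + \varepsilon_C(t)\bigr),
$$

where $\beta(t)$ is a shared single-exponential photobleaching factor,
$a(t)$ the calcium-driven activity (present only in the signal channel),
$m(t)$ brief shared motion artifacts, and $\varepsilon$ independent
measurement noise. Under this model:

1. **Artifact removal** (`remove_artifacts()`): samples where *both*
   channels deviate by more than 8 robust deviations (MAD) from a 1-s
   rolling median are flagged and linearly interpolated. Requiring joint
   deviation is what preserves unilateral calcium transients; 8 MADs is
   deliberately conservative so that only gross fiber artifacts are
   touched. The exact artifact procedure is a package decision -- the
   upstream description of this step is not prescriptive.
2. **Bleach correction** (`correct_bleaching()`): least-squares fit of
   $a + b\,e^{-t/\tau}$, channel divided by the fitted curve so the output
   fluctuates around 1. The fit runs on a 5-s rolling-median version of the
   channel so that sparse positive transients do not bias $\tau$; for a
   transient-free exponential the median filter is the identity away from
   the edges. A non-convergent fit falls back to a linear detrend with a
   warning (short or nearly flat recordings, where $\tau$ is
   unidentifiable and a line is the honest model).
3. **Control filtering** (`filter_control()`): Savitzky--Golay, polynomial
   order 3, window 1.001 s rounded to an odd number of samples. The window
   is long enough to suppress high-frequency noise yet short enough to
   track the slow drift the dF/F regression must follow.
4. **dF/F** (`compute_dff()`): the filtered control is regressed onto the
   signal (scale + offset, OLS), and
   $\mathrm{dF/F} = (S - \hat C)/\hat C$. Because artifacts enter both
   channels proportionally, the fitted control tracks and cancels them;
   this is the entire point of the isosbestic channel. The subtraction is
   signal-minus-fitted-control: the opposite order would invert the sign
   of every CS response, contradicting the positive CS-locked responses
   the analysis is built to measure.
5. **z-scoring** (`zscore_trace()`): $(x - \bar x)/s$ with the sample SD
   ($n-1$ denominator) over the whole recording. Whole-recording
   normalization is used because windows are extracted *after* z-scoring;
   a per-session span is available by processing sessions separately.

## Trials, windows, metrics

Trials are segmented from the event stream by pairing each `trial_start`
with the next `trial_end` before any further start; unmatched markers are
dropped and reported, never repaired -- inferring a missing boundary would
silently fabricate a trial. A trial is `paired`, `cs_only`, `us_only` or
`unperturbed` by membership of CS/US onsets in its interval, with the first
occurrence of each kind canonical.

Analysis windows span 2 s with $t=0$ at the sample nearest the alignment
event: 0.5 s before and 1.5 s after. The 0.5/1.5 split is a package
decision (only the 2-s total and the $t=0$ anchor are prescribed
upstream); it leaves room for a pre-stimulus baseline while covering the
full transient decay. Windows use half-open sample intervals,
nearest-sample alignment and 0-based sample arithmetic, so they are
bit-reproducible. US-only trials align to US onset.

Per-trial metrics on the window:

- `z_mean_csus`: mean z over $[0, 0.25)$ s -- the anticipatory CS--US
  epoch (half-open, so exactly `round(0.25 * fs)` samples);
- `delta_z`: $z(0.25) - z(0)$ at the nearest samples, no interpolation;
- `slope`: OLS slope of z against time over $[0, 0.25)$, in z/s;
- `z_pre`, `z_post`: z-scored pre-/post-perturbation step times;
- `euclid_log2`:
  $\log_2\sqrt{(z_\mathrm{post}-z_\mathrm{pre})^2 + (z_\mathrm{US}-z_\mathrm{CS})^2}$,
  the combined behavior--physiology statistic. The printed source formula
  omits the square root while naming the quantity a Euclidean distance;
  since $\log_2(d^2) = 2\log_2 d$, the two readings differ only by a
  factor of 2 and preserve ranks and signs. The true distance is the
  default; `squared = TRUE` gives the literal form. Zero-distance trials
  are undefined under the log and are excluded with a message.

**Step-time z-score span.** The span over which step times are z-scored is
genuinely open. The default pools the whole analysis table (both cohorts
together): centering each cohort separately would force both cohorts to
mean zero and erase exactly the group difference the joint
physiology-behavior scatter is meant to display. `per_group`, `per_mouse`
and `per_session` spans are available for within-cohort questions.

Pooled responses average windows pointwise with a pointwise 95% t-interval
band; the upstream description says only "confidence intervals", and the
t-based pointwise band is the conventional reading.

## Statistics

- **ROUT outliers** (`rout_outliers()`, Q = 1%): robust fit (median, or an
  M-estimator line when a regressor is supplied), robust residual scale
  RSDR = 68.27th percentile of $|r|$ times $N/(N-K)$, two-sided t
  p-values, and an FDR-style outside-in step over at most 30% of the
  points at thresholds $Q\,i/N$. Screening is applied per group x session
  metric vector before testing.
- **Repeated-measures cohort contrast** (`compare_groups_repeated()`):
  mixed-effects model with subject (mouse) random intercept and trials as
  repeated observations, Satterthwaite denominator df; per-session group
  contrasts Sidak-adjusted across sessions. A Geisser--Greenhouse epsilon
  is computed from the pooled covariance of subject-by-session cell means
  and applied to the within-subject F tests (`p_gg`). The original
  commercial-software "mixed-effects analysis" is not fully specified, so
  this combination -- the standard mixed-model omnibus plus the classical
  sphericity correction on the session terms -- is an explicit
  approximation, not a numerical replica.
- **Two-sample tests**: Welch's t (Welch--Satterthwaite df) and
  Mann--Whitney, both two-sided; both are offered for the Euclidean
  statistic because the source material prescribes each in different
  places, and neither is privileged.
- **Slopes**: Kruskal--Wallis omnibus with hand-computed, tie-corrected
  Dunn pairwise z tests, Sidak family adjustment (matching the adjustment
  used for the other contrasts).
- **Departures**: Fisher's exact test on the 2x2 before-/after-cue by
  cohort table.
- **GLM**: Gaussian identity-link regression of window metrics on trial
  duration and velocity, with $R^2 = 1 - \text{dev}/\text{dev}_0$.

## What the generator emulates -- and what it does not

`sim_config()` + `simulate_cohort()` produce complete experiments: per
mouse and session a two-channel recording, an event stream and a behavior
table. The defaults are the study conditions: 3 sessions of 72 trials, a
250-ms ISI, GCaMP6f-like kinetics (double-exponential kernel, 50-ms rise,
400-ms decay), exponential bleaching, shared brief artifacts, and two
cohorts (CS amplitude 1.0 vs 0.1; post-perturbation step-time penalty
decaying across sessions at rate 0.8 vs 0.1 per session). Values the
source never states were fixed once at field-plausible levels and are
documented here as assumptions:

| parameter | default | rationale |
|---|---|---|
| `sample_rate_hz` | 1000 | typical photometry acquisition; tests use 50--100 Hz (the 250-ms window still holds 12--25 samples) |
| `trial_type_fractions` | 0.40/0.175/0.175/0.25 | unstated upstream; gives 18 paired trials per 72-trial session, so a 3-mouse cohort contributes 162 paired trials over 3 sessions, within the reported per-cohort range |
| `session_scale` | 0.6 to 1.0 | CS responses grow with learning across sessions |
| `noise_sd` | 0.3 | fractional units; matches the designed parameter-recovery contrast |
| `bleach_tau_s`, `bleach_fraction` | 500 s, 0.3 | slow, visible decay over a session |
| `artifact_rate_hz`, amplitude, duration | 0.02 Hz, 3.0, 50 ms | rare, large, brief fiber artifacts -- above the 8-MAD detection floor at the default noise |
| `pre_step_mean_ms`, `pre_step_sd_ms` | 250, 30 | ladder step times, cohort-independent before the perturbation |
| `penalty_ms` | 150 | session-1 post-perturbation slowdown |
| `coupling` | 0.5 | within-trial shrinkage of the penalty with the drawn CS amplitude, so strong anticipatory responses co-occur with better-adapted steps |

Per-mouse amplitude multipliers are log-normal with CV 0.1; all
per-mouse/per-session seeds derive from the master seed through a
documented counter scheme (`derive_seed()`), so any subset of an
experiment reproduces exactly.

The generator does **not** emulate: video tracking or rung-level gait,
biophysical calcium dynamics (the kernel is phenomenological), hemodynamic
or wavelength-dependent bleaching differences, inter-trial dependence of
responses, or the biology of the injury itself -- the "attenuated" label
is purely an amplitude/learning-rate contrast. Passing tests therefore
demonstrate that the *pipeline* recovers designed effects of this
structure from realistically noisy two-channel data; they cannot certify
performance on artifacts or kinetics outside this model family.

## Numerical choices and degenerate inputs

- Timestamps are seconds (double); sample indices 0-based in arithmetic,
  1-based only at R vector access; intervals half-open throughout.
- $t=0$ is the sample nearest the event; no interpolation anywhere.
- Zero-variance dF/F and constant step-time vectors are errors (a z-score
  is undefined), zero-variance *control* falls back to the constant
  control level as baseline with a warning.
- The bleach fit is bounded ($a, b \ge 0$, $\tau > 0$) and falls back to a
  linear detrend rather than failing the pipeline.
- Identical-data group comparisons return t = 0, p = 1 (and Sidak keeps
  p = 1); empty design cells are an error naming the cell.
- Simulation sizes in the test-suite power and calibration studies: 100
  replicates of the full two-cohort experiment (3 mice x 3 sessions x 72
  paired trials) at 50 Hz with 1-s inter-trial intervals, and 200-replicate
  null calibrations on directly generated metric tables. These sizes give
  stable rate estimates while keeping the default test run fast; the
  generator's scientific parameters are never changed for speed, only its
  resolution.

## Known limitations

- The mixed-model + Geisser--Greenhouse combination approximates, rather
  than reproduces, the original commercial software's repeated-measures
  output; exact F and p values will differ in the third decimal even on
  identical data.
- ROUT is implemented from its published construction; it is validated
  here by its operating characteristics (gross-outlier detection,
  false-flag rate at Q = 1%), not against the commercial implementation.
- With 3 subjects per cohort the subject-level denominator df are tiny
  (about 4); the group omnibus is honest but conservative confidence in
  the random-effect variance itself is impossible at that n.
- CSV is the only on-disk format; recordings of hours at kHz rates would
  warrant a binary container instead.
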