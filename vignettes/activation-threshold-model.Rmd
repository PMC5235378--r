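---
title: "Modelling partial response inhibition: activation thresholds versus a horse race"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling partial response inhibition: activation thresholds versus a horse race}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmrace)
```

## The scientific problem

Cancelling one component of a prepared multi-effector response — stopping
the right hand while still responding with the left — delays the executed
component by 80–100 ms, robustly, across paradigms. Two mechanistic
accounts of this *partial response inhibition* delay are implemented and
pitted against each other here.

In the **horse-race model (HRM)**, independent pools of neural activity —
a facilitatory *go* process and, after a stop cue, an inhibitory *stop*
process — race towards a single fixed decision threshold; whichever
arrives first determines whether a response is produced. In the
**activation threshold model (ATM)**, a response is initiated when
facilitatory input to the motoneuron pool exceeds an inhibition level:
tonic at rest, and raised *nonselectively* by a stop cue. A raised
threshold that the prepared drive can no longer reach forces a *secondary*
facilitatory process — a reprogrammed unimanual response — to be recruited
before the remaining component can be executed. The delay is then not a
sampling accident but a structural necessity.

Both models are fitted to distributions of neurophysiological and muscular
observables from an anticipatory response inhibition (ARI) task: motor
evoked potential (MEP) amplitudes at fixed stimulation times before the
response target, electromyographic (EMG) burst onset and offset times, and
EMG onset rates. All internal times are in seconds relative to the
response target (negative = before it); activation is in mV-equivalent
units commensurate with MEP amplitudes; the stop signal on partial trials
occurs at −0.250 s.

## Model components

**Drives.** Every facilitatory or inhibitory process is a Gaussian in
time, `a exp(-(t-b)² / 2c²)`: `a` captures spatiotemporal summation onto
the motoneuron pool, `b` the internally generated timing of the response,
`c` the speed of accumulation. Between-trial physiological variability is
modelled by drawing each parameter per trial from a normal distribution;
draws of amplitudes, widths and tonic levels are redrawn until positive
(clamping would pile probability mass at zero and distort the binned
distributions the objective compares).

**Onset of a curve.** Gaussians have infinite support, so a curve's
nominal onset is where it reaches a minimum activation of 0.1 (a rise
above resting corticomotor excitability):
`t0 = b − sqrt(−2c² ln(0.1/a))`. At the reference parameters this gives
−157 ms (ATM go drive), −159 ms (HRM go drive), −190 ms (HRM stop
process) and −55 ms (ATM secondary drive).

**Thresholds.** The HRM uses a fixed `DecisionThresh`. The ATM uses a
tonic level `Inhib_Go ~ N(mean, sd)` on go trials and, on stop-cued
trials, a step-elevated curve
`Inhib_GS(t) = Inhib_Go + k_inh (1 − e^{−(t + step_t)/τ_inh})`, clamped at
the baseline for `t ≤ −step_t` (inhibition is a rise triggered by the
stop signal; the raw exponential would dip below baseline before the
step, which has no physiological reading). With the reference
`step_t = 0.133` s, neural braking begins 117 ms after the stop signal.

**Predicted observables.** MEP amplitude is the difference between
facilitation and the rise of inhibition above baseline, floored at zero
(no resting-MEP offset is added; the models equate MEP with that
difference). EMG onset is the first upward crossing of drive through
threshold; EMG offset is, by default, the downward recrossing
(`offset_mode = "recross"`), with onset plus the empirical 107 ms burst
duration available as the documented alternative. The EMG onset *rate* is
the drive's slope at the crossing, mapped to mV/s by a single calibration
scalar chosen so the mean-parameter go-trial slope maps to the observed
5.6 mV/s; the same scalar applies to partial trials, making the
partial/go rate ratio a genuine model output (see *Known limitations*).

## Numerical choices

Crossings of a Gaussian with a constant (per-trial) threshold are
computed in closed form. Curve-versus-curve crossings (the ATM's partial
trials) are located on a 1 ms grid over [−400, +200] ms and refined by
linear interpolation; the residual error is far below the millisecond
scale of the reported quantities, and a property test holds the grid
crossing to within one grid step of the closed form over randomized
curves. Simulations default to 100,000 trials. Sampling is done one full
parameter vector at a time in a fixed order, so a shared seed yields
identical facilitation draws across trial types of the same model — the
basis of the matched-seed race comparisons. All simulators are
bit-reproducible under a fixed seed.

## Which parameters vary on stop-cued trials

A design question the model description leaves genuinely open is whether
the go-derived components (facilitation `a, b, c`; tonic `Inhib_Go`) are
*re-drawn per trial* on stop-cued trials, or enter as the fixed values
estimated from go trials, with only the partial-trial parameters
(`step_t`, the secondary peak time) varying. The geometry decides it: at
the reference parameters the combined drive's maximum (≈3.75) clears the
elevated threshold's asymptote (≈3.69) by less than one trial-SD of the
drawn width, so with re-drawn go parameters a large minority of partial
trials never cross, the crossed ones skew early (mean onset ≈ +6 ms), and
complete cancellation leaks (~7.5 × 10⁻⁴). With the go components fixed
at their fitted means, essentially every partial trial produces the
delayed response (mean onset ≈ +22 ms, ≈70 ms after the go-trial onset),
and complete-stop trials essentially never cross — the behaviour the
threshold-elevation account is *about*. `simulate_partial_atm()`
therefore defaults to `go_params = "mean"` and offers `"sampled"`; the
sampled mode is also the one in which a flat step (`k_inh = 0`) with no
secondary drive degenerates exactly to the go simulation at a shared
seed. The HRM's partial trials always re-draw facilitation: that model's
defining failure is precisely that its partial-trial onset distribution
*is* the go distribution.

Even under `"mean"`, complete cancellation retains a ~1.3 × 10⁻⁶-per-trial
leak from the slow tail of the stop-processing delay (`step_t` more than
~4.7 SD below its mean), where braking begins only after the go drive has
already crossed the tonic level — a failure to stop in time rather than a
threshold failure.

## Fitting

Each fitted variable (three MEP stimulation times; EMG onsets; EMG
offsets on go trials or EMG onset rates on partial trials) is partitioned
into lower/middle/upper thirds using edges at the observed data's 1/3 and
2/3 quantiles (linear-interpolation convention; outer bins open-ended).
Predictions from the simulator are counted in the same bins, scaled to
the observed trial count, and floored at 0.5 counts to keep sparse bins
from blowing up the Pearson statistic `Σ (o − p)²/p`, which is summed
over variables. The objective runs the simulator with a fixed seed at
every evaluation (common random numbers), making the stochastic surface
quasi-smooth for the Nelder-Mead simplex; an evaluation whose predictions
contain no threshold crossings while onset variables are fitted returns a
large penalty (10⁶) instead of an error. Multi-start perturbs each
coordinate of the starting vector up and down (10 ms for time-valued
coordinates, 20% otherwise); SD coordinates pass through `abs()` so the
optimizer stays unconstrained. The free-parameter counts are 7 (go HRM),
8 (go ATM), 6 (partial-trial modes, with go-fit components frozen) and 2
(SST peak-time distribution).

Model comparison uses the small-sample corrected
`AIC = χ² + 2p + 2p(p+1)/(N − p − 1)` with `N` the total bin count
(5 variables × 3 = 15). Published AIC values for this paradigm are not
reproducible by direct substitution into this formula under any reading
of `N` we could identify, so AIC values are reported as computed and
never used as external anchors.

Amplitude is only weakly identified from go-trial data: the fitted
stimulation times sample the rising tail of the facilitation curve, so
`a`, `c` and the tonic level trade off along a ridge. Parameter-recovery
tests reflect this — the median recovered amplitude error across
replicate synthetic datasets is ~8%, versus <1% for the width and
well under a millisecond for the peak time.

## The pseudo-empirical generators

`generate_observed_go()` / `generate_observed_gs()` build datasets with
the published summary distributions of the ARI study (go: MEP means
0.17/0.44/0.74 mV at −150/−125/−100 ms, onsets −50 ± 35 ms, burst
durations 107 ± 38 ms, n = 514; partial: MEP means 0.18/0.33/0.44 mV at
−75/−50/−25 ms, onsets +25 ± 46 ms, rates 6.8 ± 1.2 mV/s, n = 258). MEP
"±" values are treated as standard errors over 15 participants (trial
SD = SE·√15), per the source figures' captions; EMG "±" values as
trial-level SDs (they are far too large to be between-subject standard
errors given the task's known 20–30 ms go spread). Both interpretations
are switchable (`mep_spread_kind`). `generate_sst_rts()` draws
stop-signal-task reaction times from a right-skewed skew-normal whose
location and scale are solved analytically so the mean and SD equal
0.472 s and 0.049 s at the configured shape (default 4; only
"right-skewed" is pinned down by the source, so the shape is a choice).

These generators draw each variable *independently* from normal
distributions. Real MEP amplitudes are right-skewed and correlated with
onset times within a trial, and real trial-level distributions need not
match the model's predicted shapes even when the summary moments do.
Passing tests against these datasets therefore demonstrates that the
machinery — simulation, binning, optimisation, comparison — behaves as
specified, not that the models fit the original recordings.
`generate_from_model()` closes the loop properly for recovery studies:
it packages the simulator's own output as a dataset with the generating
model attached as ground truth.

## Known limitations

* **Rate gain.** The threshold-elevation account is described as
  producing a ~120% EMG onset-rate gain on partial trials. At the
  reference parameters the summed drive crosses the elevated threshold on
  a shallower slope (~12 units/s) than the go drive crosses the tonic
  level (~24 units/s), so under the go-anchored calibration the predicted
  partial-trial rates are *lower* than go rates, not higher. No reading
  of the drive/threshold geometry we examined reverses this at the
  reference parameters; the gain claim should be treated as outside what
  this re-implementation reproduces.
* **Chi-square scale.** Count-based tertile chi-squares at realistic
  trial counts are orders of magnitude larger than the published
  goodness-of-fit values, whose binning/scaling convention could not be
  reconstructed; comparisons within this package are internally
  consistent but not comparable to published chi-square magnitudes.
* Only the responding (nondominant) hand is modelled; unsuccessful stop
  trials, hand asymmetries and subject-level hierarchy are out of scope
  (the models are applied to aggregated group data).

## Problem sizes

The simulators default to 100,000 trials, matching the original
procedure; the package's own test suite runs the headline checks at that
size and uses 1,000–5,000-trial simulations for the optimisation-heavy
contracts, with 4,000-trial objective evaluations and ten replicate
datasets in the parameter-recovery study — sizes at which the
Monte-Carlo error is comfortably below every tolerance tested.
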