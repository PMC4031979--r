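---
title: "Models and methods behind oxyloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oxyloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyloop)
```

oxyloop simulates and evaluates automated titration of the inspired oxygen
fraction (FiO2) against a pulse-oximetry (SpO2) target band in mechanically
ventilated adults. This vignette is the package's own account of its models:
what is assumed, what each tunable means, why the defaults are what they are,
and what the simulations can and cannot tell you about real patients.

## The controller

The controller holds SpO2 inside a target band (default 92–96%) by
regulating toward the band midpoint, 94%. Its decision cycle, every
`decision_interval_s = 30` s, applies four rules in strict priority order:

1. **Rescue.** A *valid* sample with SpO2 strictly below `rescue_spo2 = 85`%
   proposes `rescue_fio2 = 1.0` immediately. Rescue bypasses the lockout and
   is evaluated on every 1-s sample, not only on decision ticks. Exit from
   rescue is via the ordinary table steps once SpO2 ≥ 85% — there is no
   special weaning rule.
2. **Signal-quality fall-back.** A sample with no signal, or with signal
   quality index (SIQ) strictly below `siq_min = 0.30`, holds the last valid
   FiO2. This also blocks rescue: a reading of 70% with SIQ 0.1 is far more
   likely an artifact than an emergency, and acting on it would let motion
   artifacts drive oxygen delivery.
3. **Lockout.** After any FiO2 change, `lockout_s = 30` s must pass before
   the next non-rescue change.
4. **Dampened PI step.** The error e = SpO2 − 94 is looked up in the active
   deviation-to-step table (the proportional term), an integral term
   `ki = 0.002` FiO2-fraction per %·tick accumulates e with clamping
   anti-windup (cap 25 %·ticks, reset on rescue and inside the band), and a
   derivative term is available but off by default (`kd = 0`) since the 30-s
   tick plus the oximeter's 2-s averaging already low-pass the signal. The
   whole correction is multiplied by the dampening factor
   `max(0, 1 − |FiO2_current − FiO2_effective| / 0.2)`, where the
   *effective FiO2 estimate* relaxes toward the current setting with time
   constant `tau_effective_s = 60` s: while a previous change has not yet
   plausibly reached the alveoli, further corrections shrink, which is what
   prevents staircase overshoot at a 30-s cadence.

Deviations inside the band never step (a patient at SpO2 92 or 96 is in
range; nudging them would trade stability for nothing). SpO2 readings are
integer percent, so deviations are integers and the tables are inclusive
integer bins.

### The two step tables

The dual-profile design encodes one physiological fact: the higher the
intrapulmonary shunt, the flatter the SpO2 response to FiO2, so severely
hypoxemic patients need larger steps. The defaults:

| deviation (SpO2 − 94) | SH step | MH step |
|---|---|---|
| ≤ −9 | +0.30 | +0.15 |
| −8, −7 | +0.20 | +0.10 |
| −6 … −4 | +0.10 | +0.05 |
| −3 | +0.05 | +0.02 |
| −2 … +2 | 0 | 0 |
| +3 | −0.03 | −0.02 |
| ≥ +4 | −0.05 | −0.04 |

These tables satisfy the published constraints on the controller —
sign convention, zero across the band, magnitude non-decreasing with
deviation, and per-bin dominance |SH| ≥ |MH| — but the prototype's actual
table entries, PID constants, dampening law and effective-FiO2 estimator
were never published; everything here is configurable
(`controller_config()`, `profile()`, YAML via `load_config()`) and none of
it is claimed as faithful to the device. Down-steps are deliberately smaller
than up-steps: hypoxemia is the acute hazard, so the controller climbs fast
and descends cautiously.

Profile selection uses the classic 200 mm Hg PaO2/FiO2 threshold
(`select_profile()`): below it SH, at or above it MH. Exactly 200 takes MH
— with a near-threshold patient either profile is defensible, and MH is the
gentler choice.

## The virtual patient

A single-compartment lung with a fixed venous-admixture (shunt) fraction:

* **Alveolar wash-in.** Delivered FiO2 relaxes toward the set value with
  first-order time constant `tau_alveolar = 45` s — mid-range of published
  nitrogen wash-in/wash-out times at ICU ventilation settings.
* **Alveolar gas equation.** PAO2 = FiO2·(Pb − 47) − PaCO2/R with
  Pb = 760 mm Hg, PaCO2 = 40 mm Hg, R = 0.8 by default.
* **Dissociation curve.** The Severinghaus closed form
  S(P) = 1/(1 + 23400/(P³ + 150P)) — accurate to about ±0.3% saturation
  over the clinical range, has the correct P50 (26.8 mm Hg), and is exactly
  invertible by root-finding, which the model needs at every step.
* **Oxygen content.** C = 1.34·Hb·S + 0.003·P ml O2/dl, with
  `hb = 12` g/dl (a mid-range ICU hemoglobin).
* **Shunt admixture.** Berggren mass balance
  CaO2 = Cc′O2 − s·Δav/(1 − s) with `av_o2_diff = 5` ml/dl. This single
  equation carries the entire severity story: at s = 0.25 an extra 1.67
  ml/dl of content is lost to venous blood, and because the gain from extra
  FiO2 above ~150 mm Hg PAO2 is mostly dissolved oxygen (0.003 ml/dl per
  mm Hg), high-shunt patients respond weakly to FiO2. Setting the arterial
  content equal to the achievable maximum shows that SpO2 ≥ 92% becomes
  unreachable even at FiO2 1.0 once total shunt exceeds roughly 0.38 at
  these defaults — a property the disturbance analysis below relies on.
* **Transport delay.** The arterial point reaches the oximeter probe after
  a pure delay `circ_delay = 15` s (a FIFO line, distinct from the alveolar
  lag), giving the visibly dampened measurement dynamics a finger probe
  shows.

Arterial PaO2 is recovered from content by inverting
C(P) = 1.34·Hb·S(P) + 0.003·P, a strictly increasing function, bracketed in
[1, 700] mm Hg. The user-facing inversion (`pao2_from_sao2()`) uses Brent's
method at 1e-9 tolerance; the per-tick simulation path uses a warm-started
Newton iteration with the analytic derivative, guarded by the same bracket
(it falls back to Brent if an iterate leaves it). At a 1-Hz tick the warm
start converges in 2–3 iterations.

### Severity strata

The crossover cohort draws severe patients with shunt ~ U(0.20, 0.30) and
moderate patients with shunt ~ U(0.05, 0.15). With the content defaults
above, a severe patient at FiO2 0.40 sits near PaO2/FiO2 ≈ 145–190 mm Hg,
matching the severe stratum's clinical anchor (~160). The moderate stratum
is the model's honest compromise: a single shunt compartment with s ≤ 0.15
yields PaO2/FiO2 ≈ 260–380 at FiO2 0.30, above the ~239 clinical anchor,
because real moderate hypoxemia also involves V/Q heterogeneity that a
one-compartment model cannot express. Both strata fall on the correct sides
of the 200 mm Hg selection threshold, which is what profile selection
needs; the strata are a stand-in, not a calibrated patient population.

Severe patients start episodes at FiO2 0.40 and moderate at 0.30, mirroring
the typical baseline ventilator settings of the two groups (severe: FiO2
~40%, SpO2 ~93–94%; moderate: FiO2 ~30%, SpO2 ~97%).

## The oximeter model

1-Hz sampling of the probe-delayed true saturation with: a 2-s trailing
average (the monitor's configured averaging interval), additive Gaussian
noise (`noise_sd = 0.5`% SpO2), rounding to integer percent, clamping to
[0, 100], and two Poisson event processes — signal dropouts (default 0.5/h,
30 s each) and low-SIQ episodes (0.5/h, 20 s each, during which SIQ < 0.30
and the displayed value may be garbage). The defaults produce the small
no-signal and low-SIQ fractions (a few tenths of a percent of recorded
time) reported for this class of monitor in ICU conditions; they are set to
those aggregates, not fit to any waveform data. Motion-artifact waveforms
and SpO2-vs-SaO2 calibration bias are out of scope; the model treats probe
SaO2 as the truth the oximeter perturbs.

## Scenarios and the crossover harness

`run_episode()` wires patient, sensor and policy together at 1 Hz. All
stochastic inputs — disturbance schedules, sensor noise, event timing — are
drawn up-front from the episode seed, so an episode is a pure function of
(patient, policy, plan, seed) and bit-reproducible.

* **Suctioning** (default 2 per 3-h period): the clinician takes over and
  forces FiO2 = 1.0 (preoxygenation + suctioning, 180 s), after which
  control returns to the policy — the controller tracks the actually set
  FiO2, so it weans down from 100% through its ordinary down-steps. Profile
  comparisons exclude a 15-minute window from each suction onset
  (`suction_mask()`), matching the clinical protocol.
* **Desaturation events**: Poisson arrivals (~1/h), each transiently raising
  the shunt fraction by U(0.10, 0.25) for 2–10 min. Overlapping events
  elevate the shunt to the largest active magnitude rather than the sum
  (one diseased compartment, not stacking pathologies).
* **Usual care** (`usual_care_policy()`): a deliberate caricature for the
  baseline comparison — raise FiO2 by 0.10 on a low-SpO2 alarm (at most
  once a minute), lower by 0.05 only at 30-min checks when SpO2 ≥ 98%. It
  reproduces the qualitative signature of manual management (long
  hyperoxemic plateaus, slow weaning); it is not fitted to any real cohort,
  and outputs label it as a caricature.

`run_crossover()` draws the two-stratum cohort, allocates each patient a
random profile order (the seeded RNG standing in for the sealed envelope),
runs both 3-h periods with independent disturbance realizations, masks
suction windows, and summarizes each patient × period. `tidy()` returns the
per-episode table, `glance()` the cohort means, and `compare_profiles()`
the within-stratum paired Wilcoxon contrast.

## Outcome metrics

`time_in_ranges()` reports percentages of *recorded* time (excluded
intervals leave both numerator and denominator): hypoxemia (rounded SpO2 ≤
91), normoxemia (92–96), hyperoxemia (≥ 97), with no-signal and low-SIQ
(SIQ ≤ 0.3) time as separate categories. The five categories partition
recorded time exactly, which the test suite asserts to 1e-9. Each sample
holds until the next one (the last holds one median inter-sample gap), so
irregular audit logs — e.g. historical systems recording every 1–2 min —
are weighted by time, not by sample count; whether the original clinical
percentages were sample- or time-weighted is unstated, and time-weighting
is the choice consistent with "percentage of recorded time".

Audit mode adds `filter_aberrant()` (remove SpO2 strictly below 80%,
recording the removals as an exclusion mask — artifact readings in
historical logs, never applied to controller traces) and
`extract_windows()` (6-h windows at admission, +24 h, day 7).
`compare_groups()` is a thin wrapper over `stats::wilcox.test()` /
`stats::t.test()` — paired signed-rank within crossover strata,
Mann-Whitney for unpaired baselines, Welch's t for study-vs-historical.

## What the simulations do and do not show

The test suite verifies, among other properties: the dissociation-curve
round-trip to 1e-6 mm Hg; steady-state SaO2 monotone in FiO2 over random
patients; the shunt mass balance against brute-force venous mixing; the
quantified sensitivity ordering (∂SaO2/∂FiO2 falls with shunt at a fixed
operating point); rescue dominance, lockout spacing, and FiO2 frozen under
sustained low SIQ; and that the noiseless static closed loop enters the
band within 15 min from any admissible start, stays there, and shows zero
FiO2 sign reversals after settling.

Under the *disturbed* study conditions (hourly desaturation events of the
magnitudes above), the simulated crossover cohort's mean time-in-target —
recomputed by `scripts/acceptance.R` — lands in the mid/high 80s percent
rather than above 95%. The decomposition is structural, not a tuning
artifact: events pushing total shunt beyond ~0.38 make SpO2 ≥ 92%
physically unreachable at any FiO2 (the controller correctly saturates at
1.0 and waits), and every rescue excursion is followed by several minutes
of hyperoxemic weaning, because the design has no down-titration inside the
band, down-steps of at most 0.05 per 30 s, and dampening after each change.
A clinical cohort whose patients rarely desaturate below 85% during the
study periods does not pay either cost; the simulator's disturbance
schedule deliberately includes such events, so its cohort does. Readers
should treat the undisturbed closed-loop results as the controller's
intrinsic performance and the disturbed-cohort number as a statement about
the disturbance model as much as about the controller.

Problem sizes: unit and property tests run on episodes of 3–45 simulated
minutes; the crossover tests and the acceptance script run the full
20-patient × 2 × 3-h cohort (432,000 simulated seconds, under a minute of
wall time).

## Known limitations

* One shunt compartment: no V/Q heterogeneity, so moderate-severity
  PaO2/FiO2 ratios are overestimated (see strata note above).
* No CO2 kinetics, hemodynamics, oxygen-consumption variation, or
  PEEP-recruitment effects; `av_o2_diff` is fixed even during desaturation
  events, where cardiac output would normally compensate.
* The oximeter model does not bias SpO2 relative to SaO2.
* The usual-care policy is a caricature; comparisons against it bound the
  plausible benefit from above, they do not estimate it.
* Alarm escalation and PEEP management are explicitly out of scope.
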