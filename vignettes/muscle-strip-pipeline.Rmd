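---
title: "Simulating and analyzing isometric muscle-strip recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing isometric muscle-strip recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotrace)
```

`myotrace` analyzes synchronized isometric-force and fura-2 ratio recordings
from paced muscle strips, and ships a calibrated forward model of healthy
(CONT) and monocrotaline-treated (MCT) rat right-atrial strips so the whole
pipeline can be exercised, tested and benchmarked without external data.
This vignette is the package's account of the underlying model, the
measurement conventions, the calibration, and the limits of what the
synthetic cohorts can show.

## The forward model

**Within-beat Ca transient.** Each beat's cytosolic Ca signal (in F/F0
units) is the two-exponential waveform

$$\mathrm{Ca}(t) = d\cdot m_\mathrm{dia} +
  A\left(e^{-t/\tau_d} - e^{-t/\tau_r}\right),\qquad \tau_r < \tau_d,$$

scaled so the peak above the diastolic level $d$ equals
`ca_amp` times the beat's amplitude multiplier. Its peak time has the closed
form $t^\* = \frac{\tau_r\tau_d}{\tau_d-\tau_r}\ln\frac{\tau_d}{\tau_r}$
(exported as `cat_peak_time()`), which anchors several oracle tests. The
family was chosen because it matches the monotone, bump-free decay of atrial
Ca transients and is analytically tractable; it is *not* a flux model. One
hard geometric consequence matters for calibration: the ratio of the decay
half-time ($T_{50}$, peak to 50% amplitude) to the time-to-peak is bounded
below by ≈ 1.68 over the whole family, so very "square" transient shapes are
not representable (see *Calibration*).

**Force.** Total force is passive plus active,
$F = P(L) + s(L)\,F_\mathrm{ref}\,A(t)$, with a first-order activation state

$$\frac{dA}{dt} = k_\mathrm{act}\,H(\mathrm{Ca})\,(1-A) - k_\mathrm{rel}\,A,
\qquad
H(\mathrm{Ca}) = \frac{x^n}{1+x^n},\;
x = \frac{(\mathrm{Ca}-d)_+}{K/m_\mathrm{sens}}.$$

$H$ is an *effective* Hill coupling — $n$ is a phenomenological
cooperativity, not a binding stoichiometry. The preload maps are
$s(L)$, linear from `min_scale` (0.35) at 75% $L_\mathrm{MAX}$ to 1 at
100% (the definition of $L_\mathrm{MAX}$), and
$P(L) = \alpha(e^{\beta(L/L_\mathrm{max}-\ell_0)}-1)$ with $\beta = 12$,
$\ell_0 = 0.70$ and $\alpha$ set during calibration so that resting tension
exceeds peak active tension at 95% and 100% $L_\mathrm{MAX}$, as observed in
atrial strips. The generator's Ca transient is deliberately
preload-independent: the Frank–Starling behavior enters only through
$s(L)$, which keeps the simulated F–L runs exactly interpretable (the
noise-free active curve *is* $s(L)$, a property the tests assert).

The ODE is integrated with an exponential one-step scheme using
midpoint-averaged drive. The scheme is unconditionally stable; a guard
rejects grids where max-rate × Δt > 1.5 because the *drive's time course*
would be unresolved, not because the integrator blows up.

**Slow envelopes.** Protocol-scale dynamics act as per-beat multipliers on
the beat generator:

* SFR, time $t$ from stretch end:
  amplitude $1+g_\mathrm{ca}(1-e^{-t/\tau})$, sensitivity
  $1+g_\mathrm{sens}(1-e^{-t/\tau})$, diastolic
  $1+g_\mathrm{dia}(1-e^{-t/\tau})$, shared $\tau$ = 40 s so the response
  plateaus within the 3-min record.
* PRP, post-pause beat $k$: the first-beat amplitude multiplier is
  $M_0 = 1 + g_\mathrm{load}(1-e^{-t_\mathrm{rest}/\tau_\mathrm{load}})$
  ($\tau_\mathrm{load}$ = 25 s), then geometric return
  $1+(M_0-1)r^k$ with recirculation fraction $r$ = 0.75. The diastolic
  envelope dips 2% below baseline for the first three beats, then relaxes to
  +1% (time constant 6 beats) — magnitudes chosen small, since only the
  qualitative dip-then-overshoot shape is established.

The SFR force rise is carried mainly by slow *sensitization* rather than by
Ca amplitude: in the healthy group the Ca amplitude ends *below* its
post-stretch value (gain −0.095) while force rises to ~117%, which pure
amplitude coupling cannot produce. The decomposition is a modeling device,
not a mechanistic claim.

**Cohorts, noise, determinism.** `make_cohort()` multiplies parameters by
lognormal draws with mean exactly 1: `cv_inter_muscle` (default 0.02) on the
slow-response gains and the force scale, `cv_kinetics` (default 0.02) on
time/rate constants. Measurement noise is additive white Gaussian per
channel (force 4×10⁻⁴ mN, fluorescence 4×10⁻³ a.u. on each of F340/F380).
All randomness flows through the `seed` argument; identical inputs give
bit-identical recordings, and the caller's RNG state is untouched.

On dispersion: with the steep effective Hill coupling, per-muscle endpoint
SDs scale roughly 10–25× the gain CV. Reproducing the observed *group means*
at n = 12/11 within a few percentage points requires per-muscle endpoint SDs
of only a few points, which is why the default CV is small; simulated cohort
SDs are consequently 2–4× tighter than typical experimental ones. Treat the
cohorts as a means-calibrated reference, not as a model of biological
scatter.

## Measurement conventions

* **Beat windows** span 50 ms before each stimulus (the baseline window; at
  2 Hz the preceding twitch has relaxed to well under 1% of its peak with
  the default rates) to the next stimulus. Beats whose window contains a
  stretch/rest/preload event are tagged and excluded from analyses.
* **Amplitude** is raw-sample peak minus baseline mean; **TTP** is measured
  from the stimulus annotation (reproducible, unlike onset-threshold
  definitions); **T50** is found by linear interpolation between the samples
  bracketing the half-amplitude crossing after the peak. Oracle tests hold
  the sampled TTP within one sample of the closed form and the interpolated
  T50 within one sample of a 100×-oversampled reference.
* **Normalized maximal rates** are computed on a copy smoothed with a
  centered moving average before central differencing, divided by the
  amplitude. The default width is 3 ms: smoothing plus differencing forms an
  effective (width + 2 samples) kernel whose bias on the normalized rise
  rate of a τ = 50 ms exponential is ≈ 4.7%; a 5 ms window would push the
  bias past 5%. Width is exposed (`smooth_ms`) since published rates rarely
  state their filtering.
* **Degenerate twitches** (amplitude below 3× the baseline noise SD) are
  flagged and their features nulled — a convention, as exclusion criteria
  are rarely printed.
* **Ensemble averages** use the last ≤ 30 steady beats per preload after
  dropping 5 equilibration beats and any leading beats with amplitude drift
  above 2% per 10 beats.
* **SFR magnitude** is the mean force-amplitude percentage over the final 10
  beats of the record, referenced to the *first post-stretch twitch* (the
  first stimulus at or after the stretch-end marker). **PRP** references the
  *single last complete pre-pause twitch* — not a pre-pause ensemble — and
  searches the maximal effect over the first 10 post-pause beats, which is
  robust to the early diastolic dip. Both choices are configurable
  (`end_window`, `search_beats`); where the experimental definition is
  ambiguous the single-twitch reading was adopted and is flagged here.
* A subtlety the tests document: a beat's baseline window lies in the *tail*
  of the preceding twitch, so a beat that follows a pause (no tail) reads
  ~0.5% higher in Ca amplitude than an identical beat inside a paced train.
  This shifts the PRP first-beat Ca endpoint by about +0.5% relative to the
  envelope value, and makes the zero-gain SFR magnitude 100.0% only to
  ~0.005%, not to machine precision.

## Calibration of the committed defaults

`calibrate_defaults()` fixes each group's parameters against the reference
endpoint table in `inst/extdata/calibration-targets.csv` (group SFR and PRP
percentages, and four between-group kinetic contrasts), plus absolute
anchors that relative endpoints cannot pin down. All root finding runs on
the noise-free forward model itself.

1. **Ca kinetics.** The contrasts force the CONT Ca TTP to 33.33 ms
   (14.2 ms absolute / 42.6% relative prolongation) and the MCT values to
   47.53 ms / CONT + 9.1 ms for T50. The waveform family's T50/TTP floor of
   ≈ 1.68 then requires CONT T50 ≥ ~72 ms; the anchor is 75 ms. (τ_r, τ_d)
   follow by 1-D root finding on the shape parameter — time-scale invariance
   makes the inversion exact.
2. **Force rates.** In this model the twitch TTP is controlled almost
   entirely by $k_\mathrm{rel}$ (the activation-pulse width is set by the Ca
   kinetics and $n$), while $k_\mathrm{act}$ sets the activation level. So
   $k_\mathrm{rel}$ is solved against the TTP anchor (CONT 50 ms, MCT
   +21.5%) and $k_\mathrm{act}$ against a peak-activation anchor
   $A_\mathrm{peak} = 0.20$, which leaves headroom for the ~3× post-rest
   potentiation. Force T50 is emergent (≈ 41 ms CONT, ≈ 33 ms MCT), and the
   50-ms anchor keeps the relaxation tail below 0.01% of the twitch at the
   next stimulus.
3. **Cooperativity.** $g_\mathrm{load}$ comes analytically from the PRP
   first-beat Ca endpoint; $n$ is then the root of the *composed* map
   (re-solve the rates, run the full noise-free PRP pipeline, read the
   extent), which is monotone increasing in $n$. The PRP force/Ca endpoint
   pairs of the two groups are not consistent with a single exponent, so $n$
   is per-group (≈ 13.5 CONT, ≈ 27.6 MCT) — the minimal device absent a
   mechanism. Brackets for $n$ and $k_\mathrm{act}$ expand only until the
   target is straddled, because far above the root the compensating
   activation rate grows explosively.
4. **SFR gains.** $g_\mathrm{ca}$ is analytic from the Ca endpoint and the
   envelope weights of the reference and end-window beats; $g_\mathrm{sens}$
   is a 1-D root on the full noise-free SFR pipeline (positive for CONT,
   slightly negative for MCT, where the Ca rise alone overshoots the force
   target at the calibrated $n$).
5. **Scales.** $F_\mathrm{ref}$ anchors peak active tension at
   $L_\mathrm{MAX}$ to 6 mN/mm² (with strip diameters 250/280 µm); $\alpha$
   then places passive tension 5% above active at 95% $L_\mathrm{MAX}$.

The shipped defaults are the frozen output of this routine; a test re-runs
the MCT calibration and checks it lands on the committed values, and the
`achieved` table asserts every endpoint mean within 1%. The routine targets
*means only*: the printed endpoint SDs cannot be matched simultaneously with
the mean tolerances at these cohort sizes (see the dispersion note above).

## Problem sizes and runtime

The study conditions are 2 Hz pacing sampled at 1 kHz (configurable to
10 kHz; at 1 kHz every timing oracle holds to ≤ 1 ms): SFR records of
190 s (~380 beats), PRP records of 105 s, F–L runs of six 17.5-s preload
segments, with CONT n = 12 and MCT n = 11. One full endpoint reproduction
(`reproduce_endpoints()`, six cohorts, ~1600 simulated beats per SFR cohort)
takes well under a minute on one core, and the whole test suite a couple of
minutes.

## What the synthetic data do and do not show

The generator reproduces the *structure* of real recordings — pacing,
event-annotated protocols, realistic twitch and Ca-transient shapes and
kinetics, slow envelopes, noise — and its defaults reproduce the reference
group means. Passing tests therefore demonstrate that the analysis code
measures what it claims to measure, with known discretization and
convention errors. They do not validate the model biologically: there is no
SR Ca-flux or troponin-binding kinetics, no action-potential or temperature
dependence, no beat-to-beat coupling of the force state across stimuli
(each twitch decays essentially to rest), inter-muscle variability is
under-dispersed by design, and the SFR sensitization/amplitude
decomposition and per-group cooperativity are effective descriptions. The
T50-based inversion τ_d ≈ T50/ln 2 is reliable only for very well separated
time constants (≈ 7% error at τ_d = 20 τ_r, ~25% at 5 τ_r) — a caveat worth
remembering when reading decay constants off half-times.
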