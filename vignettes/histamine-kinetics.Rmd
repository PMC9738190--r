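---
title: "Modelling evoked brain histamine: the kinetic model, its metrics and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evoked brain histamine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histadyn)
```

## The problem

Fast-scan cyclic voltammetry at a carbon-fiber microelectrode records
extracellular histamine in the posterior hypothalamus at 10 Hz while the
medial forebrain bundle is stimulated for 2 s. Each recording is a 30 s
concentration-vs-time trace: a transient rise of 5–10 µM above baseline
that clears with a half-life of a few seconds, accompanied by a 30–50 nM
dip in serotonin (histamine inhibits serotonin terminals through H3
heteroreceptors). Drug challenges — VMAT2 blockers, a synthesis inhibitor,
an N-methyltransferase inhibitor, H3 agonists/antagonists, and H1/H2
antagonists — move the peak amplitude and the clearance half-life in
characteristic directions, and a kinetic model of the terminal is the tool
that turns those observations into mechanism.

`histadyn` implements that tool chain end to end: the compartmental model,
the drug presets, the per-trace metrics, the cohort statistics, generators
for synthetic data with the study's statistical structure, and bounded
least-squares recovery of model parameters from traces.

## The model

State variables: blood histidine `bHT` (clamped),
cytosolic histidine `cHT`, a histidine pool `HTpool`, cytosolic histamine
`cHA`, vesicular histamine `vHA`, extracellular histamine `eHA`, glial
histamine `gHA`, the bound-autoreceptor fraction `bHA`, and the active
G-protein and RGS fractions `gstar`, `tstar`.

Fluxes are Michaelis–Menten for every enzymatic/transport step and mass
action for receptor binding and the G-protein/RGS cascade — the standard
convention in this family of neurotransmitter models:

* histidine transport `bHT → cHT` (HTL), with a first-order sink
  `k_cht_loss · cHT` for competing histidine consumption;
* reversible first-order exchange `cHT ↔ HTpool`;
* synthesis `cHT → cHA` (histidine decarboxylase, HTDC);
* vesicular packaging `cHA → vHA` (VMAT2);
* release `vHA → eHA` at rate
  `k_rel · f(t) · vHA · max(0, 1 − α (g* − g*_eq)/g*_eq) · s(t)`;
* clearance `eHA → gHA` (transporter HAT), Michaelis–Menten in `eHA`
  multiplied by a trans-side inhibition `1/(1 + gHA/K_HAT_gi)`;
* N-methyltransferase degradation of `gHA` and `cHA` (HNMT);
* mass-action H3 binding `k_on·eHA·(1−bHA) − k_off·bHA`, and the cascade
  `g*' = k_Gact·bHA·(1−g*) − k_Gdeact·t*·g*`,
  `t*' = k_Tact·g*·(1−t*) − k_Tdeact·t*`.

Two flux terms deserve explanation because a pure Michaelis–Menten chain
cannot produce two of the robust experimental observations:

**Trans-side inhibition of clearance.** If clearance were Michaelis–Menten
in `eHA` alone, the extracellular dynamics would be completely decoupled
from the intracellular pools, and inhibiting N-methyltransferase (tacrine)
could not slow the measured clearance — yet slowed clearance with an
unchanged peak is exactly the observed tacrine signature. The factor
`1/(1 + gHA/K_HAT_gi)` encodes the textbook explanation: as metabolised
histamine accumulates inside, the transporter works against a growing
concentration gradient. `K_HAT_gi` defaults to 10 µM.

**A histidine sink.** Without a second consumer of cytosolic histidine,
the synthesis flux at steady state is clamped to the supply flux, and
inhibiting the decarboxylase (FMH) would merely raise `cHT` without
lowering release — contradicting the observed amplitude drop. The
first-order loss (`k_cht_loss = 0.02 s⁻¹`) represents histidine use by
protein synthesis and export, and restores supply-demand competition.

### Stimulation and the retrograde window

The firing drive is a square pulse: `f0` at rest, `f0·f_stim` during the
stimulation epoch (default onset 5 s, duration 2 s; the 60 Hz/360 µA/2 ms
electrical details are metadata only, since a 10 Hz record cannot resolve
individual pulses). The H1-triggered retrograde inhibition of release —
the messenger "S" hypothesised to act back on the terminal after
post-synaptic H1 activation — is a square window: release is multiplied by
`1 − s_strength` (default 0.8) between 9 s and 15 s. The window is engaged
only when a stimulation actually occurs (`f_stim > 1`): without evoked
histamine there is no H1 activation and hence no retrograde signal. This
also makes the resting state an exact fixed point of the simulation. An
H1 antagonist (diphenhydramine) removes the window (`s_strength = 0`),
which is what produces the slow post-drug clearance.

### Steady state and calibration

`steady_state()` solves the resting fixed point analytically: the supply
flux fixes `cHT` (one scalar root solve), `cHA` follows from packaging +
metabolism balance (a second scalar root), and every downstream compartment
is then in closed form. The residual is verified against the ODE
right-hand side at 1e-8 µM/s.

The feedback gain is normalised to 1 at `gstar_eq`, chosen as the control
resting value of `g*` (the normalisation is not otherwise constrained).
Two useful consequences: the resting `eHA` is independent of the
autoreceptor strength α (the vesicular pool rescales instead), matching
the fixed 5.32 µM baseline used across all H3 manipulations, and a preset
that only changes α leaves the initial condition of a simulation
untouched.

The control configuration shipped in
`inst/extdata/control_params.yaml` was calibrated once: `V_HAT` was
root-solved so the resting extracellular histamine is 5.32 µM, and
`f_stim` chosen so the control evoked peak (≈ 8.2 µM) and half-life
(≈ 3.1 s) sit inside the experimental 5–10 µM and 2–6 s bands. After
calibration `gstar_eq = 0.3294`. These two numbers are the only fitted
constants; everything else is a round-number choice at physiologically
plausible scales (vesicular histamine ≈ 190 µM, cytosolic micromolar
pools, second-scale receptor kinetics).

### Numerics

Integration is piecewise between the discontinuity times of the square
drive and window with `deSolve::lsoda` (rtol 1e-8, atol 1e-10), dense
output on the 10 Hz grid; no switching transient is smeared across a
segment boundary. Halving the tolerances moves the evoked peak by far less
than 0.1%. Simulations start from the steady state, so the evoked trace is
zero before stimulation by construction.

## Drug presets

Presets are deterministic parameter edits, registered in
`inst/extdata/presets.yaml`:

| preset | edit | rationale |
|---|---|---|
| control | identity | — |
| immepip | α = 1.9 | H3 agonism; fitted post-drug value |
| thioperamide_male | α = 0 | H3 antagonism releases the feedback |
| thioperamide_female | reuptake recalibrated to a 14.6 µM baseline | the female response was modelled through the raised baseline, not α |
| reserpine, tetrabenazine | V_MAT × 0.5 | VMAT inhibition |
| fmh | V_HTDC × 0.6 | synthesis inhibition |
| tacrine | V_HNMT (both) × 0.82 | metabolism inhibition |
| zolantidine | identity | no H2 mechanism in scope |
| dph | s_strength = 0 | H1 block removes the retrograde window |

The three scaling factors are calibration values, not measurements: the
experiments report amplitude/half-life changes, never enzyme-level
inhibition fractions. The defaults were chosen once so the simulated
changes fall inside the experimentally observed ranges (reserpine/TBZ
peaks down ~40%, FMH down ~30% with clearance within 20%, tacrine peak
within 10% with clearance slowed ~30%) and are exposed in the registry
for sensitivity analysis. Scaling presets record their application and
refuse to be applied twice; absolute presets are idempotent.

## Trace metrics

* `baseline()` — mean of all pre-stimulation samples (the window is not
  specified by the protocol; using all of it is the lowest-variance
  choice).
* `amp_max()` — maximum above baseline at/after stimulation onset,
  earliest-sample tie break.
* `half_life()` — fits `A·exp(−k(t−t_peak))` to the reuptake component,
  from the peak to the first return within 5% of baseline (robust to the
  post-window undershoot), and returns `ln 2 / k`; if the fit fails it
  falls back to the interpolated half-amplitude crossing and says so in
  the `method` attribute. Half-life is referenced to the peak, not to
  stimulation offset; on exact exponentials the two differ only by a
  constant and the fitted `k` is phase-invariant.
* `inhibition_amplitude()` — depth of the serotonin dip below baseline.
* `ha_5ht_ratio()` — µM histamine per nM serotonin, kept in the mixed
  units in which the quantity is tabulated (flagged in the `units`
  attribute).
* `current_to_concentration()` — 2.8 µM/nA (histamine) and 11 µM/nA
  (serotonin).
* `smooth_trace()` — zero-phase forward–backward Butterworth low-pass;
  the experimental rigs filter raw sweeps in hardware/vendor software, so
  this is a generic contract on concentration traces, not a reproduction
  of a 3 kHz sweep filter on 10 Hz data (which would be meaningless).

## Cohort statistics

The statistical battery mirrors the study's analysis plan: two-tailed
paired/independent t-tests; iterative two-sided Grubbs exclusion at 0.05
(applied once per metric per condition, before group testing); a
Shapiro–Wilk gate at 0.05 that routes non-normal comparisons to the
tie-corrected Kruskal–Wallis test; two-way ANOVA with Tukey–Kramer post
hoc; and ANCOVA slope comparison for the per-minute ambient serotonin
series. Two decisions were genuinely open:

* the ANOVA sum-of-squares type for unbalanced tables is unstated;
  Type II is used (via `car::Anova`) and recorded in the result's
  `ss_type` attribute;
* the contrast behind "first significant departure" of an ambient cohort
  is unstated; each post-injection minute is compared against the pooled
  control period within one Tukey–Kramer family, and the earliest
  adjusted p < 0.05 is reported.

All tests are two-sided at 0.05. Under null simulations (n = 6 per group,
1000 replicates) each test's type-I error is verified to sit in
[0.03, 0.07].

## Synthetic data

`gen_evoked_trace()` adds iid Gaussian noise (default sd 0.1 µM) to the
simulated histamine trace and builds the serotonin dip phenomenologically
(difference-of-exponentials pulse, default 40 nM depth, 0.5 s lag, 4 s
recovery, 2 nM noise) — the coupled serotonin kinetics live in cited prior
modelling work and are deliberately out of scope. `gen_cohort()` draws one
lognormal amplitude-scale multiplier per animal (sd(log) = 0.1, ≈ 10%
between-animal CV, consistent with reported SEM-to-mean ratios) and
applies it to the stimulation coupling `f_stim − 1`, so baselines are
untouched and evoked amplitudes scale; control and post-drug traces share
the animal effect, as in the paired designs. `gen_ambient_series()` builds
a piecewise-linear mean — 60.7 nM baseline, +0.05 nM/min for 30 control
minutes, then −0.21 nM/min for 60 minutes, continuous at the injection —
plus 1.3 nM iid noise.

What the generators do **not** emulate: electrode drift and fouling, 1/f
noise (no within-trace noise spectrum is characterised), estrous-cycle
structure, and any mechanistic serotonin coupling. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of
the pipeline, not the biology of a new recording.

The within-trace noise sd is not printed anywhere; 0.1 µM was chosen once
to match the visual scale of the published traces and is configurable.

## Parameter recovery

`fit_trace()` minimises the unweighted least-squares distance between the
simulated and observed trace on the 10 Hz grid (no loss function is
specified by the source analyses; weighting is exposed through the
residual API). Multi-start L-BFGS-B within box bounds, seeded start
points. `fit_autoreceptor()` is the 1-D specialisation for the
autoreceptor strength: coarse scan, golden-section refinement, explicit
endpoint checks so boundary optima (α = 0) are exact. Bounds default to
[0, 3], covering the fitted values {0, 0.9, 1.9} with headroom. On
noise-free traces the three fitted values are recovered to 1e-3; at 0.3 µM
trace noise the median recovery error over 50 replicates stays within 15%
for α ∈ {0.45, 0.9, 1.9}.

```{r recovery, eval = FALSE}
p <- ha_params()
trace <- simulate_evoked(apply_preset(p, "immepip"))$evoked
fit <- fit_autoreceptor(trace, p)
coef(fit)   # alpha = 1.9
plot(fit)
```

## Problem sizes

The test-suite simulations use the defaults above: 30 s traces at 10 Hz,
cohorts of 3–6 (150 for the Monte-Carlo mean check), 200 draws for the
band checks, 1000 replicates for type-I calibration, and 50 replicates per
α for noisy recovery. These sizes give comfortable statistical resolution
for every asserted band while keeping a full run in the minutes range on a
single core.

## Known limitations

* The equation set is this package's own reconstruction of the published
  compartment scheme; the original model's code is unpublished, so
  parameter values are not comparable term by term — only the calibrated
  observables (baseline, peak band, half-life band, fitted α values) are.
* The retrograde messenger is a fixed square window; its timing is taken
  from the fitted description (9–15 s) and does not adapt to the
  stimulation protocol.
* Whether autoreceptor feedback also acts on synthesis is unknown; it
  acts on release only here, and the config flags this choice.
* No plasma pharmacokinetics: presets are instantaneous parameter edits,
  so "60 min post-drug" maps to "the preset's new steady state".
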