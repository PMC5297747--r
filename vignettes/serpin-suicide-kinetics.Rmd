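---
title: "Branched suicide-substrate kinetics: model, generators and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branched suicide-substrate kinetics: model, generators and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpkin)
```

## The mechanism

Serpins are suicide inhibitors: the inhibitor is consumed in the act of
inhibiting. After the protease engages the serpin's reactive center loop,
the acyl-enzyme intermediate partitions between two fates —

* the **inhibitory branch** (rate `k_i`): loop insertion traps the protease
  in an SDS-resistant covalent complex, and
* the **substrate branch** (rate `k_s`): normal deacylation releases active
  protease and cleaved, spent serpin.

`serpkin` models this as mass action over seven species (free enzyme `E`,
initial complex `EI`, covalent complex `E_inh`, free serpin `I`, cleaved
serpin `I_clv`, substrate `S`, product `P`):

```
E + I  <-> EI   (k_on, k_off)
EI      -> E_inh    (k_i)
EI      -> E + I_clv (k_s)
```

Two standard summary quantities fall out of the branching:

* the **stoichiometry of inhibition**, SI = 1 + k_s/k_i — the mean number
  of serpin molecules consumed per protease inactivated;
* the **association rate constant**,
  k_ass = k_on · k_i / (k_off + k_i + k_s) — the partition-weighted net
  inactivation rate. The literature is not always explicit about whether a
  measured "association constant" means the encounter rate `k_on` or this
  net rate; we adopt the net rate, which is what a progress-curve experiment
  actually measures in branched suicide-substrate theory, and all recovery
  tests are written against that contract.

The chromogenic substrate is handled by a quasi-steady-state
Michaelis–Menten term, dP/dt = kcat·E·S/(Km+S), rather than an explicit ES
species: the downstream estimators only ever use `Km` through the
competition factor, so an explicit ES species would introduce parameters no
assay constrains. Competition between substrate and serpin for the enzyme
is implemented by scaling the serpin on-rate by 1/(1 + S/Km) — exactly the
factor the estimator chain later inverts.

Temperature and pH are condition *labels*, not mechanistic variables: the
reference tables map condition to (SI, k_ass) empirically and no
Arrhenius-type model is fitted (deliberately out of scope).

### Numerical choices

Integration uses `deSolve`'s stiff-aware `lsoda` at relative tolerance
1e-8 with an absolute tolerance scaled to the largest initial
concentration. Tiny negative concentrations from round-off are clamped to
zero; conservation of enzyme, serpin and substrate is tested to 1e-6
relative error. "Saturating incubation" in a titration means integrating
until free serpin or active enzyme falls below 1e-6 of its initial value
(capped at 1e6 s, via `lsodar` root-stopping). At a molar ratio exactly at
the SI both pools vanish together and the approach to completion is
algebraically slow (second-order decay), which the cap absorbs.

Internal units are molar and seconds throughout; file readers convert from
declared header units (mM, µM, nM; min). The absorbance-to-product scale is
a configurable `v0` in arbitrary signal units — chromogenic assays monitor
p-nitroaniline release without an absolute coefficient, and every estimator
is invariant to that scale.

## What the generators emulate

`gen_titration()`, `gen_progress_set()`, `gen_mm_dataset()` and
`gen_stability_profile()` produce datasets with the statistical structure
of the four assay families:

* titrations follow the ideal line `max(0, 1 − r/SI)`; points past the
  equivalence ratio are generated *at the floor*, as in real assays —
  excluding them is the estimator's decision, not the generator's;
* progress curves follow `P(t) = v0/kobs (1 − e^{−kobs t})` with
  `kobs = kunc·[I]`, either from a stated `kunc` or derived from a full
  mechanism;
* initial-rate sets follow `v = Vmax·S/(Km+S)`;
* stability profiles are piecewise plateaus with linear edge declines. The
  default temperature shape has plateau 0.95 on 35–75 °C with a right-edge
  decline of 0.022 per °C — hitting 0.40 at 100 °C — and the default pH
  shape is flat at 1.0 on pH 3–10; both parameterizations were fixed once
  from the qualitative features of a thermostable serpin's profile.

Noise is additive normal on the signal, truncated at zero, defaulting to
2% of the signal range — the simplest model consistent with absorbance
readout. No replicate correlation, baseline drift or plate-position effects
are emulated, and the noise model is homoscedastic. Passing recovery tests
on these data therefore shows the estimators invert the stated generating
process; it does not certify behaviour under instrument-specific artifacts.
Every generated object and file embeds its ground truth in metadata, so
recovery tests are self-describing, and identical seeds give bit-identical
files.

## The estimator chain

`fit_progress_curve()` fits the two-parameter exponential-plateau model by
Levenberg–Marquardt least squares. Initial values: `v0` from the OLS slope
of the first 10% of points; `kobs` from ln 2 over the half-plateau time
when a plateau is visible, otherwise a logarithmic restart grid over
1e-5–1 s⁻¹. A fit whose `kobs` implies under ~10% curvature across the
window (`kobs·t_max < 0.1`) is rejected as "no curvature": a straight line
carries no information about `kobs`. The fit is verified against a
brute-force grid search oracle in the test suite.

`fit_kunc()` is the OLS slope of `kobs` against `[I]` (intercept kept as a
diagnostic; duplicated concentrations simply enter as repeated
observations), and `correct_kass()` multiplies by (1 + S/Km), scaling the
standard error by the same factor. `run_kass_pipeline()` is exactly the
composition of the three stages — an identity the tests assert.

`estimate_si()` fits a free-intercept OLS line to the pre-floor segment of
a titration (points with residual activity below 0.05 are excluded) and
reports the x-intercept −intercept/slope with a delta-method standard
error. The intercept is *not* forced through 100% at ratio 0; its fitted
value is reported so departures are visible. Slopes above −1e-8 are
declared "no inhibition" — on exactly flat data round-off can produce a
slope of order 1e-17, which would otherwise invert to an absurd SI.

`fit_km()` offers two routes. The default double-reciprocal
(Lineweaver–Burk) fit is unweighted, matching how such assays are
classically reduced, and is exact on noise-free data. Because the
reciprocal transform amplifies noise at low substrate (1/v errors blow up
where v is small), the noisy Monte-Carlo recovery property uses the
`method = "direct"` nonlinear Michaelis–Menten fit, which is the
recommended estimator for real, noisy data; the two variants are also
cross-checked against each other within combined standard errors.

`summarize_stability()` reports the maximal contiguous grid range whose
retained activity meets a threshold (default 90%), plus the activity
extrema, with the no-inhibitor rate defined as 100%.

## Sequence annotation

`find_hinge_motif()` operationalizes the alanine-rich hinge of inhibitory
serpins: each 6-residue window scores the count of A plus half the count
of G/S/T, and windows scoring ≥ 4 are reported (1-based inclusive). The
threshold was chosen so the canonical `ATAATA` hinge (score 5) and the
consensus hinge of inhibitory serpins pass while random sequence rarely
does; window, weights and threshold are all arguments. `transfer_p1()`
maps a reference P1 site through a pairwise alignment given as a paired
index map — the alignment itself is an input (an optional
`align_pair()` helper wraps a global Biostrings alignment), because the
science is in the index bookkeeping, not the aligner. Mass arithmetic uses
a mean residue mass of 0.110 kD by default, or exact average residue
masses when a sequence is supplied, and a tag-mass adjustment exists
because reported full-protein masses may include purification tags.

The reference constants table assigns the fifth reported protease mass
(36 kD) to the thermophilic chymotrypsin-like protease; that mapping is
the only one consistent with its ~76 kD complex and is flagged in the
source rather than guessed silently.

## Problem sizes and limitations

The shipped layouts mirror common practice: titration ratios 0–35 (5
points per SI unit is ample for the x-intercept), five inhibitor
concentrations of 100–500 nM per k_ass determination, 1 mM substrate,
seven-point saturation grids spanning 0.2–20 × Km. Monte-Carlo recovery
properties use 100 seeds at 2% noise; all simulations run in seconds on
one CPU.

Known limitations: no tight-binding (Morrison) depletion correction beyond
what the mechanism itself produces; no global fit of all curves to the ODE;
no reversible-inhibition or serpin-denaturation kinetics; incubation times
in real titration protocols vary by protease and temperature and are not
always saturating — the simulator exposes finite-time incubation so that
effect can be explored, but the reference SI recovery assumes saturation.
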