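---
title: "Modeling cellular noise in EGF-ERK nuclear translocation signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cellular noise in EGF-ERK nuclear translocation signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erknoise)
```

## The scientific problem

Isogenic mammalian cells respond heterogeneously to the same growth-factor
stimulus. Two sources feed that heterogeneity: *intrinsic* noise — the
stochastic timing of individual reaction events, significant only at small
molecule numbers — and *extrinsic* noise — cell-to-cell differences in
protein abundances (and environment). In EGF signaling the question has an
extra edge: the dose response of total phosphorylated ERK (pERK) is graded,
but the dose response of *nuclear* ERK accumulation (nERK) is switch-like,
and a switch is far more sensitive to noise near its threshold than a graded
response is. This package implements, end to end, a simulation pipeline for
asking which noise source drives nuclear-ERK heterogeneity, which proteins'
variability matters, and how much protein variability is compatible with
measured single-cell distributions once measurement error is accounted for.

## The kinetic model

The packaged network (`reduced_egf_model_path()`) is a mass-action model of
the cascade

EGF → EGFR → (Shc) / Grb2 → Sos → Ras → Raf → MEK → ERK → NPC-gated nuclear
translocation,

with 37 species and 58 reactions in molecule-count units. Its architecture:

* **Receptor stage.** EGF (held constant — no ligand depletion) ligates
  EGFR; two ligand-bound receptors dimerize and transphosphorylate into a
  pEGFR dimer. The dimerization step makes the receptor output quadratic in
  ligand occupancy at low dose.
* **Adaptor and GTPase stage.** pEGFR recruits Grb2–Sos directly and through
  Shc; Sos-containing complexes load RasGTP, GAP unloads it.
* **Kinase cascade.** RasGTP binds Raf and activates it through an
  intermediate complex; active Raf doubly phosphorylates MEK and ppMEK
  doubly phosphorylates cytoplasmic ERK. Raf, MEK and ERK are
  dephosphorylated by dedicated phosphatase species (the ERK phosphatase is
  present in both cytoplasm and nucleus). ppERK phosphorylates Sos — a
  negative feedback that makes the stimulated time courses transient.
* **Nuclear translocation and its autoregulation.** ERK in every
  phospho-form shuttles through the nuclear pore complex (NPC) with rates
  keyed by (ERK form × NPC form × direction). Phosphorylated ERK imports
  much faster than it exports while the NPC is unphosphorylated, so nuclear
  ERK accumulates after stimulation. Nuclear ppERK phosphorylates the NPC in
  two steps (reactions **137–144**); doubly phosphorylated NPC exports ERK
  unidirectionally and fast. That closes a negative autoregulation loop:
  high nuclear ppERK accelerates its own export.

The autoregulation is what converts the graded pERK input into a switch-like
nERK output: it clamps the maximal fold change, which compresses the
EC10–EC90 window and therefore raises the Hill coefficient. Zeroing the rate
constants of reactions 137–144 (`knockout_npc_regulation()`) removes the
clamp, and the nERK dose response reverts to the graded, pERK-like shape —
the central mechanistic claim the deterministic analysis reproduces
(`analysis/01_dose_response.R`).

### Provenance of the packaged parameters

This is **not** a transcription of the published 78-species/150-reaction
model, whose parameter tables are distributed as spreadsheets; it is a
reduced variant with the same architecture, calibrated once, before any
testing, against published summary behaviors: graded pERK vs switch-like
nERK with a transition window near 0.02–0.12 ng/mL, equalized Hill
coefficients after the 137–144 knockout, and a basal intrinsic fold-change
CV near 0.35%. The NPC-phosphorylation block keeps the published indices
137–144 (reaction indices are labels here, not positions) so the knockout
contract is identical on any future transcribed model file. Two anchors are
exact by construction:

* the nuclear/cytoplasmic ERK split is 72,000/528,000 (nuclear fraction
  0.12), so the stationary binomial partition of ERK across the envelope
  gives a basal fold-change CV of `sqrt((1-p)/(N*p))` ≈ 0.35%;
* basal import/export constants are balanced exactly at the nominal split
  (`1.5e-7 * 528000 = 1.1e-6 * 72000`), so the shipped counts are a true
  dose-0 steady state, and any per-cell rescaling of protein abundances is
  again a steady state (all basal-active reactions are linear in the scaled
  totals). Per-cell pre-equilibration therefore converges immediately but is
  still run as a safety net.

Compartment volumes (cytoplasm 1e-12 L, nucleus 3e-13 L) are recorded as
metadata only: every bimolecular rate constant in the model file is already
volume-scaled to per-molecule-per-second, a convention chosen so the ODE and
SSA engines share one state representation (molecule counts).

## Simulation engines

* **Deterministic.** `integrate_network()` solves the mass-action ODEs with
  a stiff integrator (lsoda; rtol 1e-8, atol 1e-6 counts). The system is
  pre-equilibrated at dose 0 until the maximum relative rate of change falls
  below 1e-9, then EGF is applied at t = 0. Default horizon 3600 s with a
  10 s grid: at the lowest responding doses the nERK transient is still
  within 0.2% of its late maximum at 3600 s, so peak truncation is
  negligible; both choices are configurable.
* **Stochastic.** `ssa_simulate()` implements the exact direct-method
  Gillespie algorithm in C++ (homodimerization propensity n(n−1)/2;
  deterministic convention n²/2 — indistinguishable at these counts), with
  per-cell seeds derived from a master seed by a counter-based splitmix
  scheme so ensembles are order-independent and reproducible. For
  stimulated runs of the full network (event rates of order 1e5/s) an
  adaptive tau-leaping variant is available behind `method = "tau"`
  (epsilon 0.01, non-negativity by step halving, exact-stepping fallback);
  the test suite validates its first two moments against the direct method.

## Noise regimes

`noise_config()` crosses two flags: intrinsic (SSA) and extrinsic
(log-normal sampling of initial protein abundances). Extrinsic sampling is
**moment-matched**: each varied protein is drawn with mean equal to its
nominal abundance and the configured CV (σ² = ln(1+CV²), μ = ln(nominal) −
σ²/2) — mean-preserving rather than median-preserving because variability is
reported relative to nominal abundances. A protein split across compartments
(ERK, its phosphatase) receives one shared factor per cell, so compartment
ratios are preserved. Only free initial-condition proteins are varied;
complexes and the NPC stay nominal.

*Covariation* models shared expression capacity: `covariation = "full"`
applies one log-normal factor per cell to all varied proteins (the
correlated extreme suggested by measured abundance scatter), with a `rho`
parameter exposed for intermediate correlation. Under fold-change
normalization, covariation has no effect at dose 0 (each cell is normalized
to its own steady state) but suppresses heterogeneity at saturating dose,
because kinase and phosphatase abundances move together and their balance
sets the peak. This is why the model carries *explicit* phosphatase
species: with implicit first-order dephosphorylation a shared abundance
factor would unbalance every kinase/phosphatase pair and covariation would
inflate, not suppress, the response CV.

Every cell's readout is the **peak nERK fold change normalized to that
cell's own pre-stimulus nuclear ERK**. At dose 0 the readout is the fold
change at the end of the horizon rather than the path maximum: the maximum
of a stationary fluctuating path is biased upward, while the basal
distributions being emulated are centered at 1.0. The basal horizon (900 s
at the default rates, ≈3.4 relaxation times of the nuclear pool) recovers
more than 99.8% of the stationary variance.

## Measurement error (AME) and protein-variability recovery

Measured basal distributions are far wider (CV ≈ 4.4%) than the simulated
both-noise basal (CV ≈ 0.35%): almost all of the observed basal width is
measurement-derived. The *apparent measurement error* is modeled as a
multiplicative, dose-independent Gaussian factor N(1, cv²) applied to fold
changes — multiplicative rather than additive for positivity, equivalent
near mean 1 — so independent CVs compose in quadrature and
`estimate_ame()` solves cv_ame = sqrt(cv_obs² − cv_sim²). The underlying
single-cell measurements are not public; where an "observed" basal is
needed, the published Gaussian fit (mean 1.0, CV 4.4%) or a synthetic
dataset generated by this package stands in, and is labeled as such.

`recover_protein_cv()` closes the loop: for candidate protein CVs on a grid
(default 0–50% in 5% steps), it simulates per-dose ensembles, applies the
AME, computes CV(dose), and scores each candidate by the residual sum of
squares against the observed per-dose CVs. Recovery ensembles use the
per-cell ODE engine: at these molecule counts the intrinsic contribution to
the peak CV is an order of magnitude below both the AME and the extrinsic
component, and dropping it makes the grid search tractable on one CPU.

The `synthetic_data` stage supplies the pseudo-experimental datasets:
`generate_pseudo_experiment()` runs the kinetic model at a known truth
(protein CV, AME CV) and records full provenance so recovery is a
parameter-recovery experiment, and `fast_surrogate_generator()` provides a
model-free Hill-based fixture (documented as *not* the pathway mechanism)
for unit-testing the AME and information stages. Default scale is 1000
cells per dose at the dose set {0, 0.01, 0.05, 0.1, 0.5, 50} ng/mL — a
low/transition/high design; tests and the acceptance script run 200–300
cells per dose, which keeps CV estimates within a few percent relative
error while fitting a single-CPU budget.

## Mutual information

`mutual_information()` evaluates the plug-in estimator
I(R;S) = ΣΣ P(R,S) log₂ P(R,S)/(P(R)P(S)) on a dose × response-bin table
(0·log 0 := 0; uniform dose marginal). Plug-in MI on finite data is inflated,
increasingly so at finer binning, so `debiased_mi()` removes the leading
O(1/n) bias by subsample extrapolation: plug-in MI at the full sample and at
stratified half and quarter subsamples, a linear fit in 1/n, and its
intercept as the debiased estimate. The reported value is taken at the
smallest response bin count whose debiased estimate changes by less than 2%
(with a 0.01-bit absolute floor absorbing subsampling noise) when the bin
count doubles. This plateau rule is this package's documented procedure for
"bin-size optimization with jackknife debiasing"; the literature recipe it
gestures at is not reproduced verbatim in the available text. Estimates are
clipped at 0, and the suite checks the analytic oracles (independence → 0;
perfect k-dose discrimination → log₂ k; a worked 2×2 table → 0.278 bits; a
piecewise-uniform channel → 0.5 bits) plus the data-processing inequality
under AME.

## Design choices on genuinely open points

* **Dose grid**: 0 plus 24 log-spaced doses in [1e-4, 50] ng/mL; the source
  grid is unstated. `R_min` is a free Hill parameter rather than being
  pinned at the dose-0 response so pERK (nonzero basal) and nERK (basal 1)
  share one code path; EC values are computed from the fitted curve
  (EC_f = K·(f/(1−f))^{1/n}), not raw interpolation.
* **Hill fitting**: Levenberg–Marquardt least squares multi-started over
  n ∈ {0.5, 1, 2, 4}; a brute-force (n, K) grid search with analytic
  (R_min, R_max) serves as the oracle in tests.
* **Sweep classification**: a protein is "elevated" in a dose region when
  its maximum CV there exceeds twice the all-protein median CV of the
  region — a numeric stand-in for a visual grouping (type 1: elevated in
  [EC10, EC90]; type 2: above EC90; type 3: flat).
* **EGF dose handling**: EGF is a catalytic species (appears on both sides
  of the ligation reaction), so dose is constant by construction; the
  conversion 1e4 molecules per ng/mL is a model-file constant absorbed into
  the ligation rate.
* **Degenerate inputs**: zero-abundance proteins stay zero under extrinsic
  sampling (with a warning); zero total propensity in the SSA is an
  absorbing state, not an error; all-equal samples fit as CV 0.

## What the synthetic data do and do not show

The pseudo-experimental generator reproduces the statistical *structure* of
single-cell nuclear-ERK measurements: per-dose fold-change distributions
whose width comes from protein variability plus a multiplicative
measurement error, a basal distribution that is Gaussian with mean 1, and a
switch-like dose dependence. It does not emulate imaging artifacts,
segmentation error correlated across doses, dose-dependent measurement
error, cell-cycle or microenvironment covariates, or ligand depletion.
Passing the recovery and MI stages on these data therefore demonstrates
that the pipeline is *self-consistent* (it recovers known truths through
its own forward model at realistic scales) — not that the reduced network
is a quantitative model of any particular cell line.

## Problem sizes used by the tests and acceptance script

Dose-response fits use 17–25 doses at a 10–20 s output grid; basal
both-noise ensembles use 200 cells of exact SSA over 900 s; recovery uses
11 candidate CVs × 6 doses × 80 ODE cells against a 250–300-cell
pseudo-experiment; MI estimates use 1500–1800 cells over 6 doses. These are
the package's desk-scale defaults; all of them are parameters, and the
analysis scripts expose a `--smoke` flag scaling them down further.

## Known limitations

* The packaged network is a reduced calibration, not the published
  parameterization; quantitative Hill/EC agreement with the source model is
  approximate by construction (the qualitative contracts are tested).
* Tau-leaping is approximate; it is used only where flagged, and validated
  on moments, not full distributions.
* The AME model is dose-independent and Gaussian by reconstruction; if the
  original procedure composed errors additively or applied them to full
  trajectories rather than peaks, small systematic differences would appear
  near the basal state where the two conventions differ at second order.
* One-at-a-time sensitivity sweeps hold all other proteins exactly at
  nominal; residual background variability is not modeled.
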