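---
title: "An ODE model of TNF-induced NF-kB signalling in microglia and its scenario analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ODE model of TNF-induced NF-kB signalling in microglia and its scenario analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbsim)
```

## The biological question

Microglia respond to the inflammatory cytokine TNFα through the canonical
NF-κB pathway: TNFα activates the IκB kinase complex (IKK), active IKK
phosphorylates the inhibitor IκBα held in complex with NF-κB, phospho-IκBα is
ubiquitinated and degraded by the proteasome, and liberated NF-κB enters the
nucleus and drives transcription — including transcription of its own
inhibitors IκBα (direct negative feedback on the complex) and A20 (negative
feedback on IKK). Constitutive overexpression of the heat shock protein Hsp72
attenuates this response. Because Hsp72 has been reported to interact at
several different points of the pathway, the question this package addresses
in silico is: *which constitutive modifications of the network — alone or in
combination — can reproduce the full attenuation phenotype?* The phenotype to
match is: reduced peak IKK activity, reduced peak nuclear NF-κB, reduced
resting total IκBα, and *unchanged* resting NF-κB activity.

Hsp72 itself is not a model species. Because its concentration is constant in
the stably transfected cells being emulated, every hypothesized interaction
is encoded as a constant multiplicative factor on one or more rate constants
and/or initial protein pools — a `scenario`.

## Model structure

The model tracks 18 species (see `species_names()`), in four groups:

* **IKK module** — three interconverting forms with a conserved total:
  neutral `IKKn`, active `IKKa`, inactivated `IKKi`.
  Activation `IKKn -> IKKa` at rate `ka * TNF` occurs only while the TNF
  input is present (TNF is a binary input, not a species); inactivation
  `IKKa -> IKKi` at rate `ki + kiA20 * [A20]`; slow recycling
  `IKKi -> IKKn` at rate `kp`. Basal IKK activity is zero: without TNF no
  activation flux exists, consistent with near-undetectable phospho-IκBα in
  resting cells.
* **IκBα degradation chain** — free and complexed IκBα are phosphorylated by
  active IKK (`kc1a`, `kc2a`), pass through E3-ligase engagement (`kua1`) and
  poly-ubiquitination (`kuc1`), and are degraded by the proteasome (`kupd`);
  degradation of a complexed IκBα releases NF-κB. Two structural
  modifications relative to the canonical Lipniacki-family network: tagged
  intermediates also decay constitutively (`kdp`), and the cytoplasmic
  IκBα:NF-κB complex can be imported into the nucleus (`i2a`).
* **NF-κB shuttling** — free cytoplasmic NF-κB is imported (`i1`);
  nuclear IκBα (imported at `i1a`, exported at `e1a`) captures nuclear NF-κB
  (`a4`/`d4`, same association constants as in the cytoplasm) and the nuclear
  complex is exported (`e2a`).
* **Gene expression** — free nuclear NF-κB linearly drives transcription of
  IκBα and A20 mRNAs (`c1a`, `c1`), which are translated (`c2a`, `c2`) and
  degraded (`c3a`, `c3`, `c5a`, `c6a`, `c5`).

Total NF-κB (over its seven containing species) and total IKK are conserved
exactly; this is checked on every trajectory.

## Parameters, units, provenance

Concentrations are in µM and all rates per minute. The nominal values ship as
a machine-readable manifest (`parameter_manifest()`,
`inst/extdata/parameters.json`) recording, for every rate, its units, meaning
and provenance: values taken from the canonical Lipniacki-family NF-κB
parameterization, IκBα turnover adjusted to the fast free-IκBα /
stable complexed-IκBα regime of O'Dea-type measurements (`c5a` = 0.12/min
vs `c6a` = 0.0015/min), and the remainder assigned during calibration. The
calibration targets were the *described* population dynamics of TNFα-treated
BV2 microglia, not any fitted data: IKK activity peaking near 5 min, nuclear
NF-κB peaking 15–30 min at several-fold above basal, total IκBα dipping
between 5 and 20 min before overshooting its resting level at 60–90 min, and
feedback-transcript induction peaking 30–60 min.

One structural calibration choice deserves mention. IKK shutdown is carried
mainly by spontaneous inactivation (`ki` = 0.12/min) with slow recycling
(`kp` = 0.01/min) — the transient-IKK regime — while the A20 feedback
contributes a deliberately small basal term (`kiA20 * [A20]` ≈ 0.002/min at
rest). Because basal A20 scales with basal nuclear NF-κB, a large basal A20
term would make early IKK activation sensitive to the NF-κB pool size, and
the pool-reduction scenario would then alter the IKK trajectory — contradicting
the structural property that nothing downstream of IKK (except A20 induction,
which is too slow to matter early) can affect initial IKK activation. With
the shipped values, reducing the pool to 70% moves the IKKa trajectory by
about 0.6% of its peak over the first 30 minutes, while a 10-fold increase of
`kiA20` still cuts peak IKKa by ~8% and strongly suppresses late IKK.

## The simulation protocol

`equilibrate()` starts from the two pools — all NF-κB as cytoplasmic
IκBα:NF-κB complex, all IKK neutral, everything else zero — and integrates
the unstimulated system (default horizon 10⁵ min, checked at interior
checkpoints) until every species satisfies
`|d[x]_i/dt| <= tol * max(x_i, floor)` with `tol` = 1e-9 and a 1e-6 µM floor
guarding species that are exactly zero at rest (all tagged IκBα forms).
Non-convergence fails loudly, naming the worst species. Equilibration is done
by integration rather than root finding, matching the protocol being
reproduced and avoiding spurious algebraic roots.

`run_stimulus()` then integrates from the equilibrium with TNF present and
constant. Scenarios are applied *before* equilibration (constitutive
changes). The integrator is `deSolve::lsoda` with `rtol` = 1e-8,
`atol` = 1e-10 (equilibration uses tighter 1e-10/1e-14); halving the
tolerances moves the nuclear NF-κB peak by less than 1e-4 relative. Values
in (−1e-9, 0) arising from solver tolerance are clipped to zero with a
warning. The default output grid is 1-min spacing on [0, 150] densified to
0.25 min on [0, 10] where IKK changes fastest.

```{r protocol}
traj <- simulate_scenario(NULL)   # nominal model: equilibrate then stimulate
peak(observable(traj, "NFkBn"))
peak(observable(traj, "IKKa"))
```

## Readouts and normalizations

`observable()` maps trajectories to the measured quantities. "NF-κB
activity" is mapped to *free nuclear NF-κB* only — the DNA-binding ELISA
proxy; the nuclear IκBα:NF-κB complex is inhibited and does not count. This
is the single place that biology-to-model mapping is made. Total IκBα sums
free, complexed and tagged forms over both compartments; Ser32-phospho IκBα
maps to the tagged forms. `normalize_series()` reproduces the three
experimental conventions (reference time point, basal-to-10%-of-max affine
map, fold over initial) and stores its affine coefficients so it can be
inverted exactly.

## Scenarios and plausibility

`scenario_catalog()` holds every evaluated hypothesis as strictly positive
multiplicative factors; hypothetical scans (`kp`, `ki`, `kiA20`, and the
ubiquitin-chain rates) use dyadic factors over [1/16, 16], while factors
stated for specific figures (e.g. `kc2a` ∈ {1/5, 1/6, 1/10, 1/32},
`c2a` = 1/30, pool factors 0.70, 0.055, 1/8, 1/18) are taken verbatim.
`evaluate_scenario()` classifies a scenario as plausible iff it reduces basal
total IκBα, peak IKKa and peak nuclear NF-κB (ratio < 0.95 — a 5% margin so
that numerically unchanged readouts never count as "reduced"), while keeping
basal nuclear NF-κB within ±15% of nominal (the experiments report
indistinguishable resting activity without giving a number; the band is
recorded in every verdict).

```{r verdict}
nominal <- simulate_scenario(NULL)
combined <- scenario_catalog()$Fig6A_combined
evaluate_scenario(combined, nominal, simulate_scenario(combined))
```

Deviation between two trajectories (for the "IKK is unchanged" claims) is
measured as the sup-norm difference relative to the nominal observable's
maximum on the window; pointwise relative deviation is undefined at t = 0
where IKKa is exactly zero.

## Parameter-uncertainty ensembles

`sample_parameters()` draws every rate constant and both pools independently
and uniformly on ±20% of nominal (n = 100 by default, matching the analysis
being reproduced), under one integer seed. Only the two pools are perturbed
among initial conditions: they are the only free initial quantities — every
other species starts at zero and is re-derived by equilibration.
`run_ensemble()` equilibrates each draw under its own parameters, excludes
(and counts) failed draws, aborts above 5% failures, and averages member
trajectories pointwise. Applying a scenario on top of each draw's factors
equals centering the sampling on the scenario-modified model, because
multiplicative factors commute; reusing one draw list for the nominal and
scenario runs yields paired draws, which isolates the scenario effect from
sampling noise when comparing peak orderings.

## Synthetic assay data and statistics

`generate_assay()` emulates the four ELISA time courses (p65 DNA binding at
{0, 15, 20, 30, 105, 150} min with n = 6; IKK activity at {0, 2.5, 5, 10,
20} min with n = 6; total and phospho-IκBα at {0, 5, 20, 60, 90} min with
n = 9), each normalized by the control dataset's empirical mean at the
assay's stated reference time point. Noise is multiplicative lognormal with
median 1 (default CV 0.15); the experiments report only mean ± SD, so the
noise family is an assumption recorded in the dataset's spec. With CV = 0
the pipeline reproduces the reference-normalized model values exactly.
`generate_qpcr()` writes Ct tables (`Ct = offset − log2(level) + noise`,
default SD 0.25 cycles, stimulus-independent reference gene), and
`ddct_fold_change()` applies the ΔΔCt rule `fold = 2^(−ΔΔCt)`.

The statistical battery mirrors the experimental analysis: one-way ANOVA per
time point (time points use independently harvested cells, so no correction
across times), Newman–Keuls stepwise comparisons on ordered means gated on a
significant omnibus test (harmonic-mean n for unbalanced groups; with two
groups the decision coincides exactly with the pooled t-test since
q(α, 2, df) = √2·t), and a two-sided one-sample t against unity for
measurements normalized to the control group. Sidedness is not stated in the
emulated analysis; two-sided is used throughout. ANOVA is computed from the
definitional sums of squares (and cross-checked against `stats::oneway.test`
in the tests) so that the 10⁴-replicate type-I-error simulation runs in
seconds.

## What the tests do and do not show

The test suite checks conservation laws, fixed-point and solver-refinement
properties, the structural downstream-invariance of early IKK activation,
monotonicity of the `ka` scan, the plausibility classification of the
catalog, ensemble moments and pairing, noiseless round-trips of the synthetic
pipeline, and the statistics against independent oracles. Problem sizes in
the tests are the analysis' own: 100-draw ensembles on a 1-min grid and 10⁴
null replicates for test size. Because the synthetic data are generated from
the model itself with an assumed noise family, passing tests demonstrate
internal consistency and correct implementation of the procedures — not that
the model fits any particular measured dataset, whose numeric values are not
available here.

## Known limitations

The IKK activation module is a coarse three-state approximation of a rich
upstream network; only A20 feeds back on it. The model is deterministic and
population-averaged: single cells oscillate, and population averages damp
those oscillations, so comparisons are most meaningful during the first
activation phase (~30 min). Hsp72 is represented only through constant
multiplicative factors, so explicit binding kinetics, dose dependence and
dynamic Hsp72 induction are out of scope, as are receptor-level detail and
stochastic single-cell variants. The increased IκBα mRNA induction observed
experimentally in Hsp72-overexpressing cells is *not* reproduced by any
scenario in the catalog — under shared transcriptional control both feedback
transcripts fall together with NF-κB activity; the model's role there is to
show the discrepancy, and the package makes no attempt to patch it.
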