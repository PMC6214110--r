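---
title: "Quantitative pharmacophore modeling: models, costs, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pharmacophore modeling: models, costs, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoregen)
library(dplyr)
```

## The problem

A ligand-based 3D-QSAR pharmacophore model explains the potency of a
series of inhibitors — here, inhibitors of the calcium-activated chloride
channel anoctamin-1 (ANO1/TMEM16A) — by a small 3D arrangement of typed
chemical features: hydrogen-bond acceptor (HBA), hydrogen-bond donor
(HBD), hydrophobic (HY), and ring-aromatic (RA). A compound is active to
the degree that one of its conformers can superpose matching features onto
the model within per-feature distance tolerances. `phoregen` implements
the full workflow around that idea: feature perception from conformers,
HypoGen-style hypothesis generation scored by a description-length cost in
bits, fit-value activity estimation, a validation battery, and a
virtual-screening funnel.

## The fit value and the activity relation

Mapping a compound onto a hypothesis searches exhaustively over conformers,
type-compatible injective feature correspondences, and allowed omissions
(`max_omitted`, default 1, because even the least-active compound of the
reference series maps three of the four model features). The matched cloud
features are rigidly superposed onto the hypothesis centroids
(least-squares Kabsch; with fewer than three matched points the alignment
is translation-only), and the fit value is

$$F \;=\; \sum_{f\ \mathrm{matched}} w_f \, \max\!\left(0,\ 1 -
  \left(\frac{d_f}{t_f}\right)^2\right),$$

with displacement $d_f$, tolerance $t_f$ (default 1.6 Å), and weight
$w_f$ (nominal 2). Activity is estimated as
$\mathrm{IC}_{50} = 10^{\,b_0 - b_1 F}$ µM.

The slope is fixed at $b_1 = 1$. This is deliberate: the published
estimates of the reference series obey exactly that relation (compound 1:
fit 5.9, estimate 0.128 µM; compound 20: fit 3.58, estimate 26.6 µM — an
implied slope of 0.999 log10 units per fit unit). The scale of the
relation is carried instead by the per-feature weights, which are refit at
every cost evaluation by ridge regression of $\log_{10}\mathrm{IC}_{50}$
on the per-feature match contributions, with prior mean 2 and ridge
parameter $\lambda = (\sigma/\sigma_w)^2$ — precisely the MAP estimator
implied by the Gaussian weight cost below. An earlier design that refit a
free slope by ordinary least squares proved structurally degenerate:
smaller hypotheses could stretch the slope at no cost and out-rank the
true model by overfitting.

## The cost model (bits)

With activity uncertainty $u = 1.5$ (so error scale
$\sigma = \log_{10} u$) and weight scale $\sigma_w = 0.5$:

* error cost
  $\sum_i \left[ \delta_i^2 / (2\sigma^2 \ln 2) +
  \log_2(\sigma\sqrt{2\pi}) \right]$ with
  $\delta_i = \log_{10}\widehat{\mathrm{IC}}_{50,i} -
  \log_{10}\mathrm{IC}_{50,i}$;
* weight cost $\sum_f (w_f - 2)^2 / (2\sigma_w^2 \ln 2)$;
* configuration cost $\log_2(\text{candidate count})$, capped at 17 bits;
* total = error + weight + configuration;
* null cost = error cost of the featureless geometric-mean predictor;
* fixed cost = configuration cost $+\, n \log_2(\sigma\sqrt{2\pi})$
  (an ideal model predicting every point exactly).

The headline statistic is the cost difference (null − total): large values
mean the model explains far more than chance. Because these are
description lengths of continuous quantities, they can legitimately be
negative; only differences matter. Bit-for-bit agreement with Discovery
Studio's internal numbers is explicitly not a goal — the published cost
table is kept as a fixture (`ano1_reference_costs()`) and its printed
differences (121.00 and 130.804 bits) are reproduced as arithmetic, not
re-derived.

## The three generation phases

**Constructive.** Leads are compounds with
$\mathrm{IC}_{50} \le u^2 \min(\mathrm{IC}_{50})$ (at $u = 1.5$ this
reproduces the reference series' two leads at 0.107 and 0.194 µM). Every
3–5-feature subset of a lead conformer with pairwise centroid distances
≥ 2 Å that maps *fully* (no omissions, every displacement within
tolerance) into every other lead becomes a candidate; candidates with the
same type multiset and sorted distance profile within 0.5 Å are
deduplicated.

**Subtractive.** Candidates fully mapped by any inactive compound
(activity more than $10^{3.5}$-fold above the most active) are removed;
with a 273-fold activity span, the reference-like series has no such
compounds and the phase is a no-op, as intended.

**Optimization.** Each of the top candidates is refined in two stages.
First an EM-style consensus step: every training compound is superposed
onto the candidate and each centroid moves to the mean of the transformed
matched features (kept only if it lowers the cost). Without this step a
candidate's geometry stays at one lead's conformer and the per-feature
activity signal of the rest of the series is unrecoverable. Then simulated
annealing perturbs one centroid (≤ 0.5 Å) per step, with weights and
intercept refit at every evaluation, Metropolis acceptance on the total
cost, and a geometric cooling schedule (default $T_0 = 0.5$ bits, factor
0.97, 150 steps). Moves violating the 2 Å minimum inter-feature distance
are rejected outright. Location tolerances stay at the nominal 1.6 Å —
published hypotheses keep standard tolerances, and letting the search
tune them hands it an uncharged per-feature knob that fits activity
noise. All randomness is driven by the single engine seed.

During generation, scoring admits only complete mappings
(`max_omitted = 0`, the HypoGen default — the reference work kept all
generation parameters at their defaults except the uncertainty and the
minimum inter-feature distance). Allowing omissions during scoring lets
small hypotheses exploit correspondence freedom as an uncharged degree of
freedom and overfit. Estimation of external compounds (validation,
screening) keeps the one-omission budget.

## What the synthetic generator emulates — and what it does not

`plant_hypothesis()` and `generate_library()` provide ground truth.
A planted model (by default one feature of each type, pairwise ≥ 2 Å,
calibration $b_0 = 7$, $b_1 = 1$) is copied into each active compound
with Gaussian coordinate jitter and random distractor features; activities
follow $\log_{10}\mathrm{IC}_{50} = b_0 - b_1 F_{\text{true}} +
\mathcal N(0, \sigma_{\text{noise}})$, clamped into 0.107–29.2 µM (the
reference activity range) with clamp events counted.

Key design choices, fixed after structural calibration against the
published series (measured on generator outputs only):

* **Heterogeneous match quality.** Each active draws a per-compound
  jitter scale $\sigma_i = j \cdot \max(\sqrt{U(0,1)}, 0.25)$ Å with
  upper bound $j$ (`jitter_sigma`, default 1.0). This
  reproduces the published structure: active fits spanning roughly
  4.9–7.7 (printed series: 3.58–5.9), about 3 lead compounds out of 20
  (printed: 2), and a constructible planted arrangement in every scanned
  seed. A single shared jitter scale cannot satisfy the constructive
  phase's full-mapping gate and the activity-range emulation at the same
  time.
* **Training sets are decoy-free by default.** All 20 reference training
  compounds are genuine inhibitors. Decoys sit at fit ≈ 0, where the
  slope-one relation implies absurd activities whose clamping flattens
  the effective slope to ~0.3 and breaks the calibration; decoys belong
  in screening libraries (`decoy_fraction` is per-spec adjustable).
* **Clamping, not rejection**, keeps the library size exact; clamped
  activities mimic the assay floor/ceiling of the printed series.

What the generator does *not* emulate: real conformational flexibility
(synthetic compounds are single-conformer feature clouds), chemistry
(feature types are planted, not perceived from structures), correlated
feature geometry within scaffolds, and assay artifacts beyond log-normal
noise. Passing the recovery and screening batteries therefore shows the
engine's statistical machinery works under the stated conditions, not that
it reproduces any particular real-world series; the chemistry path is
exercised separately through small SMILES fixtures.

## Numerical choices and degenerate inputs

* Superposition uses proper rotations only (SVD sign correction); with
  fewer than three matched points the rotation is identity and only the
  centroids are matched.
* Mapping ties are broken by lower superposition RMSD, then conformer
  index, then lexicographically smallest correspondence, making every
  result deterministic.
* An exactly-tied activity pair has error value +1 (the printed tables
  round ties to −1; comparisons against them are by magnitude).
* Compounds with no admissible correspondence map with fit 0 ("unmapped")
  rather than erroring.
* The ridge weight fit clamps negative weights at 0; a candidate whose
  contribution matrix is constant falls back to the prior weights and the
  geometric-mean intercept.
* The conformer pipeline embeds from the canonical, pH-7.4-ionized
  SMILES with a seeded distance-geometry method, so ensembles are
  reproducible; the ensemble carries its own reference molecule because
  embedding renumbers atoms.

## Problem sizes

The shipped test batteries and the reproduction script use the study conditions
throughout: 20-compound training series at 0.2 log-units activity noise
(20 generator seeds for recovery, 10 for the Fischer ranking experiment,
19 scrambled runs per Fischer test at 95% confidence, 20 leave-one-out
folds), 200 random instances for the mapping-enumeration cross-check, and
a 200-compound screening library with 20 planted binders. Chemistry
fixtures are a handful of small molecules (ethanol, benzene, pentanol,
amides) whose properties are hand-checkable.

## Known limitations

* Absolute cost values are this package's own description-length
  instantiation; only their structure (identities, differences, ranking
  behavior) is comparable across implementations.
* Hydrophobic clusters are one feature per contiguous cluster; whether
  large fused-ring systems should split is undefined in the public
  feature definitions and not configurable yet.
* Feature directions (donor/acceptor axes, ring normals) are perceived
  and stored but not scored during mapping; the data model allows a
  vector-aware scoring upgrade.
* The ADMET stage filters user-supplied profile tables; no predictor is
  bundled.
* Scaffold keys prune terminal atoms iteratively, so exocyclic
  substituents (including carbonyl oxygens) are stripped from the
  framework — a known divergence from Murcko variants that keep
  double-bonded exocyclic atoms.
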