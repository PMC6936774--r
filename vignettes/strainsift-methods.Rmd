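---
title: "Methods: metabolomics-guided isolate prioritization with strainsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomics-guided isolate prioritization with strainsift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(strainsift)
```

## Scope and model

`strainsift` formalizes a screening workflow for microbial extract
libraries in which bioassay evidence (inhibition zones against indicator
strains) is combined with untargeted LC-HRMS and ¹H-NMR metabolomics to
decide which isolates to scale up. The package deliberately starts from
*aligned peak-list exports* — one table per ionization mode with feature
id, *m/z*, retention time and per-sample peak intensities — because raw
spectral processing (peak picking, deconvolution, alignment) is the job
of dedicated instrument software and is out of scope here, as are MS/MS
interpretation and NMR phasing/baseline work.

The underlying statistical picture is: extracts share a large common
metabolome (background features), a small number of strains carry
*unique* chemistry making them multivariate outliers, and bioactivity is
carried by a handful of *discriminant* metabolites systematically more
abundant in the active class. The workflow estimates all three layers
and combines them into a ranking.

## Clean-up rules and their parameters

All thresholds live in `cleanup_config()` and default to the values the
workflow is anchored on:

* `blank_intensity_threshold = 1e4` (intensity counts). Any feature
  whose solvent-blank intensity exceeds this is removed *entirely*. We
  interpret "subtraction" as whole-feature removal rather than intensity
  arithmetic: a blank-derived ion is an artifact wherever it appears,
  and subtracting heights would leave noise-level residues that corrupt
  scaling.
* `medium_fold = 20` (dimensionless). A feature survives only if some
  extract exceeds 20 times its culture-medium intensity. The rule is
  stated on the best extract; whether per-sample or max-over-samples
  comparison was intended is ambiguous, so we retain by the maximum and
  additionally zero individual extract intensities below
  `medium * fold`, which keeps the filter monotone (never increases an
  intensity, never adds a feature). A feature absent from the medium is
  kept whenever any extract shows signal.
* `mz_ppm_tol = 5` ppm: used for satellite matching, mode merging,
  formula search and dereplication alike.
* `rt_tol = 0.1` min: our own choice (no published value exists);
  chromatographic alignment across a single batch is typically better
  than 6 s. Exposed in the configuration.

Ion collapse treats every ion as a candidate base ([M+H]⁺ / [M−H]⁻),
predicts where its ¹³C satellite (+1.003355 Da, strictly lower
intensity) and its adducts/dimers would fall, and removes matching ions
inside the RT tolerance. The rule table (`default_adduct_rules()`) is
data, not code, and can be extended. The charge state is fixed at 1:
actinomycete secondary metabolites under 1500 Da overwhelmingly ionize
singly charged, and the dereplication tables this mirrors list only
singly charged adducts.

Mode merging converts both tables to neutral mass (proton mass 1.007276
Da; the electron mass is absorbed, a < 0.5 ppm effect at ≥ 150 Da, below
the 3 ppm instrument accuracy), pairs ions agreeing within tolerance
greedily by smallest ppm gap (ties: RT gap, then feature id — a
deterministic, argument-symmetric order), and overlays intensities by
per-sample *maximum*. Summing would double-count one analyte that
ionizes in both modes.

The stage order blank → medium → collapse → merge is enforced by a stage
stamp on the table; running stages out of order is an error, because the
fold-change rule is only meaningful on blank-free tables and merging is
only meaningful on collapsed ones.

## Formula prediction and dereplication

`enumerate_formulas()` searches the element box C 0–60, H 0–120, N 0–10,
O 0–20, S 0–3, P 0–2 (the box is a configuration default, not a claim
about any instrument vendor's settings) for compositions within the ppm
tolerance of a *neutral* mass, requiring RDBE ≥ 0, integer RDBE (an
even-electron neutral molecule) and, optionally (on by default),
0 ≤ H/C ≤ 3 — a standard element-ratio plausibility heuristic that is
switchable because it is a heuristic. Candidates are ranked by absolute
ppm error. An empty result is a meaningful outcome ("no prediction").
Matching runs on neutral mass after adduct resolution, because
dereplication tables report neutral MW against formulas.

Dereplication is exact-mass matching of neutral features against a
user-supplied compound table (`name, formula, exact_mass, source,
class`). The licensed commercial databases used in practice cannot be
shipped; the package instead ships a small demonstration database of
dereplication-anchor compounds and the synthetic generator emits its own
database with known ground truth. A feature with at least one hit is
"known"; per-isolate unknown fractions summarize novelty.

## Chemometrics

All multivariate code is written in the package (no external fitting
library) and cross-checked in the test suite against independent
oracles (SVD, one-component PLS from mixOmics, direct correlation
tests).

**Pareto scaling** divides mean-centered columns by √sd — the
conventional compromise for intensity data whose variance spans decades.
Zero-variance columns are dropped with a warning.

**PCA** uses sequential NIPALS with deflation. Convergence is a relative
squared score change below 1e-10 within 500 iterations; a component that
fails this is an error by default. One numerical reality deserves
mention: when two samples carry near-identical amounts of unique
chemistry, the leading eigenvalues come in near-degenerate pairs and
power iteration needs unboundedly many iterations to fix the exact axes,
although the *span* of the pair stabilizes almost immediately. Since
Hotelling T² is (nearly) invariant to rotations within such a pair, the
pipeline's outlier scan calls `pca_nipals(strict = FALSE)`, accepting
the estimate at the iteration cap; the same relaxation applies inside
cross-validation folds, where only the projection subspace enters PRESS.
Score signs follow a fixed convention (largest-|loading| element
positive) so runs are reproducible.

Q² uses 7-fold *contiguous-block* cross-validation in fixed sample
order: deterministic, and matching the de-facto default of the
commercial software this workflow mirrors. R²Xₐ = SS(tₐpₐᵀ)/SS(X);
deflation conserves total variance to numerical precision (tested).

**Hotelling outliers**: T²ᵢ = Σₐ t²ᵢₐ/var(tₐ) against
A(n−1)(n+1)/(n(n−A))·F₁₋α(A, n−A). The pipeline default of A = 4
components reflects the design assumption that a screening campaign
contains a handful of chemically unique strains; with fewer components
the weakest outlier direction can be truncated away.

**OPLS-DA** codes the active class +1, inactive −1. The predictive
weight is w ∝ Xᵀy (normalized); each orthogonal round computes
p = Xᵀt/(tᵀt), removes the predictive direction
(w₀ = p − (wᵀp)w, normalized), deflates X by t₀p₀ᵀ and recomputes the
predictive score. Predictive and summed orthogonal R²X are reported as
between-group and within-group percentage variation (they and the
residual add to 100 %). Q² is 7-fold contiguous-block cross-validated
class prediction. The pipeline fits the model after removing
target-*inactive* Hotelling outliers (configurable): their unique
chemistry otherwise dominates the within-class variation, which is
exactly the published practice of excluding secondary-strain-only
outliers from the target-strain model.

**S-plot and selection.** For each variable, cov = tᵀxⱼ/(n−1) and
corr = cov/(sd(t)·sd(xⱼ)). The per-feature "p-value" is the two-sided
correlation-test p against the predictive score (t-distribution, n−2
df). This is a deliberate, documented definition: the S-plot-derived
p-values in the commercial software are not specified by a published
formula, and correlation significance is the natural S-plot quantity;
we do not claim to reproduce any vendor's p-values numerically. The
active *side* is the sign of the mean predictive score over active
samples, removing quadrant ambiguity. Selection keeps active-side
variables with p ≤ 0.10 (the workflow's stated evidence threshold; an
abstract-level "P < 0.01" also appears in the source material — we
adopt 0.10 and record the discrepancy rather than resolve it), ranked
by p then |cov|.

## NMR bucketing

Spectra are integrated by exact trapezoid quadrature into 0.04 ppm
buckets over 0.5–12.5 ppm (bucket width is ours; 0.04 ppm is standard
metabolomics binning). Buckets touching an exclusion zone are removed
entirely; the default zones (DMSO 2.40–2.60, water 3.25–3.45 ppm) are
our bounds for the stated solvent deletions. Remaining buckets are
total-area normalized to 100 per spectrum — relative profiles are what
the comparison needs — and normalization is switchable. Bucketing the
point lists (rather than exporting full-resolution points) is the
implementable reading of "peak list" export; loadings stay indexed by
ppm so band interpretations (aliphatic 0–2, glycosidic 3–5, aromatic
6–8) carry through.

## Prioritization

Ranking is lexicographic gating, not a weighted score, mirroring the
sequential narrative of the source workflow: (1) active against the
target strain (zone strictly > 12 mm; flag-only records pass through),
(2) Hotelling outlier, (3) discriminant markers owned (argmax intensity,
ties to the lexicographically first isolate with a warning),
(4) unknown fraction. Isolates active only against non-target strains
therefore fall behind every target-active isolate. The relative weight
of novelty versus outlier status is genuinely open in the source
material; the gate order is our interpretation and each input is
exposed, so a user can re-rank.

## The synthetic campaign

`generate_dataset()` is the package's test bed and defines the study
conditions: 25 isolates, ~8,800 combined-mode features per extract after
clean-up (m/z 150–1500, RT 1–35 min), log-normal intensities
(μ = 11, σ = 1.5 on the natural log — heavy-tailed, straddling the 1e4
blank threshold), within-feature between-isolate noise sd 0.4 (log),
per-mode ionization probability 0.75, 1 ppm mass noise, 10 %/15 %
adduct/isotope satellites, 400 medium and 150 blank background features,
4 chemically distinct (outlier) isolates with 250 unique features each,
9 target-active isolates, and 12 planted discriminant markers at the
monoisotopic masses of real dereplication-anchor formulas
(borrelidin, lankacyclinol and congeners, etc.), boosted 3 within-noise
sd in active isolates and a further 4 sd in the producing isolate —
producer strains dominating trace cross-occurrence by roughly an order
of magnitude is the biologically realistic regime and makes ownership
identifiable. Half the planted masses appear in the emitted compound
database ("known"), half do not.

Two generator decisions deserve explicit statement. First, planted
markers are guaranteed to ionize in at least one mode; with independent
0.75 draws, 6 % of markers would otherwise not exist in the data at all
and recovery statistics would measure ionization luck rather than
pipeline behaviour. Background compounds keep the unconditional draw.
Second, marker masses double as regression anchors: the same printed
masses the chemistry tests assert exactly flow through the full
pipeline.

What the generator does **not** emulate — and hence what green tests do
not show about real data: chromatographic peak shapes and tailing,
retention-time drift between batches, ionization suppression between
co-eluting analytes, multiply charged species, in-source fragments, and
correlated (pathway-level) intensity structure between metabolites.
Recovery rates on this generator are upper bounds for instrument data.

Problem sizes used in the shipped tests: unit and property tests run on
a reduced campaign (600 base features per mode); the acceptance-level
recovery study runs the full default campaign over 20 seeds, which
completes in a few minutes on one CPU.

## Known limitations

* Exact reproduction of the source campaign's model statistics
  (R²/Q², component variance percentages, per-feature p-values) is not
  claimed: they depend on unavailable raw instrument data and a
  proprietary database. The package reproduces the *procedure* and the
  printed chemistry anchors, and validates the statistics by oracle
  equivalence and synthetic recovery.
* Dereplication is exact-mass only; isotope-pattern scoring and MS/MS
  annotation are out of scope.
* The NIPALS relaxation under near-degeneracy (above) trades exact
  principal axes for robustness of the outlier scan; users who need
  strict convergence semantics should call `pca_nipals()` directly with
  `strict = TRUE` (the default there).
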