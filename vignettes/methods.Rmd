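---
title: "Methods: conformational diversity and substitution stability effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational diversity and substitution stability effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdiv)
```

## The problem

A protein's native state is an ensemble of conformers in dynamic
equilibrium, yet stability-based interpretation of single amino acid
substitutions (SASs) is usually carried out on one crystal structure. When
the same substitution is scored on every available conformer, the estimated
folding free-energy change (ΔΔG, kcal/mol) can vary by more than the
typical engine error, to the point that the qualitative call — stabilizing,
neutral, destabilizing — depends on which conformer was chosen. `confdiv`
quantifies that ambiguity and asks whether the conformer ensemble, used
deliberately, improves discrimination of disease-related from neutral
substitutions.

The package deliberately does **not** implement a stability potential.
ΔΔG values are an input (one value per substitution per conformer, as
produced by an external engine through the adapter in
`run_stability_engine()`), with the convention **positive = destabilizing**.

## Structural descriptors

*RMSD.* Conformers of one protein share a sequence, so structural
comparison reduces to optimal rigid-body superposition of matched Cα atoms
(Kabsch algorithm via SVD, reflection-guarded), taken over the intersection
of positions resolved in both conformers; at least three shared positions
are required and no gap modelling is attempted. A protein's conformational
diversity is summarized by RMSDmax, the largest pairwise value.

*Solvent accessibility.* ASA is computed by Shrake–Rupley sampling with a
deterministic golden-spiral lattice (default 960 points per atom, probe
1.4 Å, van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å; unknown
elements fall back to carbon). Hydrogens, heteroatoms and waters are
excluded; a chain is treated in isolation, not in its biological assembly.
Absolute Å² is used throughout — the 20 Å² buried/exposed cutoff and every
derived number are on that scale — and the boundary value 20 Å² is assigned
to *exposed* so the two classes partition the line. ASA is exact for an
isolated atom by construction and is tested against the analytic two-sphere
spherical-cap formula; at 960 points per-residue values are within a few
percent of a 10,000-point lattice.

*PDB input.* Fixed-width ATOM records; MODEL/ENDMDL blocks become separate
conformers; alternate locations resolve to the highest occupancy, ties to
the first altloc identifier in collation order.

## Per-substitution aggregation and ambiguity

For each substitution the conformer values are reduced to min, max, mean
and spread (max − min); missing cells are dropped, never imputed. The
stability class uses a cutoff τ (default 2 kcal/mol, with 1 kcal/mol the
common alternative): destabilizing above +τ, stabilizing below −τ, neutral
in the closed band [−τ, +τ]. A substitution is *ambiguous* when its
conformers do not all land in one class; a protein is flagged when it
carries at least one ambiguous substitution.

For the accessibility–heterogeneity profile, each substitution's conformer
pair with the largest ΔΔG difference defines a signed ΔASA
(ASA at the high-ΔΔG conformer minus ASA at the low one); pairs are binned
into half-open 10 Å² intervals (lower edge inclusive, centers at the
midpoints) with per-bin mean and standard error of the ΔΔG spread. The
pairing rule is a declared design choice: the quantity needs an
orientation, and anchoring it to the extreme-ΔΔG pair makes the sign
carry information about whether burial accompanies destabilization.

## Disease-vs-neutral evaluation

Predictions use |ΔΔG| > τ → disease (perturbation in either direction is
pathogenic-like; a `destabilizing`-only rule is available since the
two-sided choice is a convention). Five conformer-selection strategies are
compared:

* **Global** — every (substitution, conformer) cell is an independent
  prediction, so conformer-rich proteins carry proportionally more weight;
* **Minimum / Maximum / Average** — one prediction per substitution from
  the corresponding summary statistic;
* **Random** — per resample, one uniformly chosen conformer value per
  substitution; reported metrics are means over resamples (default 1000),
  which makes the row comparable to the others while representing the
  "one arbitrary structure" practice.

Metrics are MCC, accuracy, specificity and sensitivity from the standard
contingency table (positive class = disease). A zero MCC denominator
yields 0; an empty sensitivity/specificity denominator yields `NA`.
Significance of a strategy against the random baseline is a one-sided
empirical p-value with add-one smoothing, p = (k+1)/(n+1) with k the
number of resampled MCCs at least as large as the reference. The
two-sample Kolmogorov–Smirnov test uses the exact ECDF supremum and the
asymptotic Kolmogorov distribution at the effective sample size
n₁n₂/(n₁+n₂) — adequate at the sample sizes in scope (hundreds), and
deliberately not the exact small-sample distribution.

Supporting analyses: per-conformer metrics (each conformer's column scored
alone, with the min–max MCC range per protein), the fraction of
substitutions having at least one conformer whose prediction matches the
phenotype, and — when ligand-bound flags are supplied externally — the
fraction of proteins whose maximum-ΔΔG conformer is a bound state (ties
count as bound if any tied conformer is bound).

## The synthetic world

The generator (`generate_dataset()`) emulates the statistical shape of a
curated human-variant ensemble collection: 119 proteins by default, 2–73
conformers per protein from a shifted negative binomial truncated to that
range (mean ≈ 8.6), about 6.75 substitutions per protein (dataset total
≈ 800) labelled disease with probability 0.60.

Cell values follow a hierarchical model: a substitution draws a base
effect *b* from its class model, and each conformer adds an independent
Gaussian deviation with standard deviation
`conformer_sigma * (0.17 + 0.285 |b|)` — conformer scatter grows with
effect magnitude, as stability-engine outputs do. Class models are shifted
gammas (stability-change estimates are right-skewed) with a minority
stabilizing component in both classes (weight 0.12 for disease, 0.07 for
neutral), because stabilizing substitutions are also documented as
disease-associated and because the two-sided prediction rule must be
exercised. A protein-level difficulty term flips a substitution's class
model with probability `0.5 (k/73)^0.8` for a protein with *k* conformers:
in real collections the conformer-richest proteins show markedly poorer
phenotype–stability correlation, and without this coupling the
cell-weighted Global strategy would not be the weakest, contrary to what
the emulated study reports. All randomness flows from one integer seed;
output is byte-identical across runs.

The frozen defaults were calibrated by simulation so that the
class-conditional means of the per-substitution minimum and maximum ΔΔG
approximate 1.47/4.63 kcal/mol (disease) and 0.38/1.86 kcal/mol (neutral);
the calibration is checked softly (±20%) by the acceptance suite, and the
exact values are recorded in
`system.file("extdata", "generator-defaults.cfg", package = "confdiv")`.
`missing_rate` defaults to 0 — the emulated pipeline produced a value for
every cell — and masking always preserves at least one value per
substitution.

What the generator does *not* emulate: real energetics (no sequence or
structure dependence of ΔΔG), correlation between substitution counts and
conformer counts (in real data conformer-rich proteins contribute many
substitutions, which is why a cell-weighted analysis there is much larger
than the substitution count), residue-type substitution biases, and any
coupling between the toy coordinates and the ΔΔG tables. A green test on
synthetic data therefore establishes that the pipeline's statistics behave
as specified on data with the documented shape — not that any biological
conclusion holds.

`generate_toy_structures()` builds poly-alanine-like backbones whose
pairwise RMSD is known by construction: conformer *k* displaces residue
*i* along z by `pattern[i] · (k−1) · d` with the balanced block pattern
(+1, −1, −1, +1). The pattern has zero sum and zero first moment along the
chain, so the optimal superposition is the identity and the RMSD is
exactly `|k−l|·d` when the residue count is a multiple of four; random
rigid motions are layered on top to exercise the superposition. (A naive
alternating ± pattern does not have this property on a linear chain — its
nonzero moment induces a compensating rotation.)

## Numerical and boundary choices

* τ boundary: |ΔΔG| = τ is neutral (closed neutral band).
* ASA 20 Å² boundary: exposed.
* MCC zero denominator → 0; undefined sensitivity/specificity → `NA`.
* ΔΔG sign: positive destabilizing, matching common engine output.
* Positions are 1-based sequence indices; an author-numbering map can be
  supplied (`apply_position_map()`), identity assumed otherwise.
* Missing ΔΔG cells are dropped from summaries; a substitution with no
  value at all is a validation error.
* KS p-values use the plain asymptotic series (100 terms); agreement with
  implementations using the dual theta expansion is ~1e-4.
* Engine adapter failures (nonzero exit, unparsable output) become missing
  cells with a logged warning, never fabricated values.

## Known limitations

* ASA is single-chain; interfaces in biological assemblies are invisible.
* No mmCIF input, no structure repair, no side-chain modelling.
* The random-baseline p-value is an empirical resampling construct; the
  emulated study did not state its test, so no exact correspondence is
  claimed.
* Whether per-conformer "perfect correlation" should use τ = 2 or 1 is a
  convention; the default is τ = 2 with the parameter exposed.
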