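# confdiv

Conformational diversity and the stability effects of single amino acid
substitutions (SASs).

## What it is for

Stability-based interpretation of missense variants usually scores a
substitution's folding free-energy change (ΔΔG, kcal/mol; positive =
destabilizing) on **one** protein structure. But the native state is an
ensemble of conformers, and the same substitution scored on each conformer
can yield values spanning several kcal/mol — enough to flip the qualitative
call between *stabilizing* (ΔΔG < −τ), *neutral* (|ΔΔG| ≤ τ) and
*destabilizing* (ΔΔG > τ) at the conventional cutoffs τ = 2 or 1 kcal/mol.

`confdiv` is for structural bioinformaticians who have (or simulate)
multi-conformer structures plus per-(substitution, conformer) ΔΔG tables
and want to:

* quantify ensemble geometry — pairwise/maximum Cα RMSD after optimal
  (Kabsch) superposition, Shrake–Rupley solvent accessibility, per-position
  ΔASA and buried/exposed (20 Å²) ambiguity;
* aggregate conformer ΔΔG values per substitution (min/max/mean/spread)
  and measure how often the stability class is conformer-dependent;
* evaluate disease-vs-neutral discrimination (prediction: |ΔΔG| > τ)
  under five conformer-selection strategies — Global (every cell), Minimum,
  Maximum, Average, and a resampled Random single-conformer baseline —
  with MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)), accuracy,
  specificity, sensitivity, an empirical p-value for a strategy against the
  random baseline, per-conformer MCC ranges, the fraction of substitutions
  with a perfectly agreeing conformer, bound-state enrichment of the
  maximum-ΔΔG conformer, and two-sample Kolmogorov–Smirnov comparisons.

ΔΔG estimation itself is out of scope: values come from an external engine
(e.g. a FoldX-class potential) through a command-template adapter
(`run_stability_engine()`), or from the calibrated synthetic generator.

## Worked example

Simulate a dataset with the statistical shape of a curated human-variant
ensemble collection (119 proteins, 2–73 conformers each, ~800 substitutions,
60% disease-related), then evaluate the strategies:

```r
library(confdiv)

ds <- generate_dataset(generator_config(seed = 42))
ds
#> <synthetic_dataset> 119 proteins, 1016 conformers, 779 substitutions (482 disease / 297 neutral), seed 42

su <- summarize_sas_table(ds$ddg, labels = ds$sas)
round(sapply(split(su$ddg_max, su$label), mean), 2)
#> disease neutral
#>    4.78    1.84

protein_ambiguity(ds$ddg, labels = ds$sas, tau = 2)$fraction_ambiguous
#> [1] 0.8655462

evaluate_all_strategies(ds$ddg, ds$sas, tau = 2, seed = 42,
                        n_resamples = 1000)
#>   strategy   mcc accuracy specificity sensitivity    n seed n_resamples
#> 1   Global 0.393    0.695       0.731       0.671 6279   NA          NA
#> 2  Minimum 0.326    0.611       0.859       0.459  779   NA          NA
#> 3  Maximum 0.462    0.747       0.660       0.801  779   NA          NA
#> 4  Average 0.464    0.736       0.747       0.728  779   NA          NA
#> 5   Random 0.436    0.716       0.760       0.689  779   42        1000

perfect_conformer_fraction(ds$ddg, ds$sas, tau = 2)
#> [1] 0.8748395
```

Reading the output: the class-conditional mean of the per-substitution
*maximum* ΔΔG is far higher for disease (≈4.8) than neutral (≈1.8)
substitutions, most proteins contain at least one substitution whose
stability class flips between conformers, and the Maximum strategy beats
both the cell-weighted Global analysis and the single-random-conformer
baseline — the qualitative behaviour the package is built to study. For
~87% of substitutions at least one conformer's prediction matches the
phenotype exactly.

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "confdiv.R", package = "confdiv"))')
Rscript "$CLI" simulate --out run/sim --seed 42
Rscript "$CLI" analyze  --ddg run/sim/ddg.tsv --sas run/sim/sas.tsv --out run/analyze
Rscript "$CLI" evaluate --ddg run/sim/ddg.tsv --sas run/sim/sas.tsv \
        --out run/evaluate --seed 42 --conformers run/sim/conformers.tsv
```

`geometry --pdb-dir DIR --out DIR` adds the RMSD/ASA reports for a
directory of (multi-model) PDB files; `analyze --geometry-asa` then
produces the binned ΔASA-vs-Δ(ΔΔG) profile. Every run writes a
`manifest.json`; exit codes are 0 (success), 1 (data error), 2 (usage
error).

## Documentation

`vignettes/methods.Rmd` describes the models, the calibrated synthetic
world and its limits, and every numerical/boundary convention (τ and ASA
boundaries, missing-data policy, ΔΔG sign, KS p-value series).
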