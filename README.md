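# methylewas

An R package for genome-wide DNA-methylation case/control analysis on
Illumina Methylation450-style beta-value matrices. It is aimed at analysts
running epigenome-wide association studies (EWAS) of immune-mediated
disease from sorted cell populations — the motivating setting is systemic
lupus erythematosus (SLE), where strong interferon-pathway hypomethylation
coexists with mild, widespread methylation shifts produced by changes in
the composition of the CD4+ T-cell pool.

The pipeline covers:

- **QC**: masking of beta scores with detection p > 0.01, removal of
  samples with > 1.5% missing autosomal data points and of probes failing
  in > 10% of samples, removal of blacklisted (multi-/mis-mapping) probes
  with SNP-overlap probes flagged but retained.
- **Normalization**: empirical-Bayes batch adjustment (native
  implementation; parametric and nonparametric Monte-Carlo modes) run on
  random non-overlapping subsets of at most 20,000 CpGs, separately per
  Infinium chemistry, with chromosome X adjusted per sex; followed by
  Infinium II → I harmonization via the quadratic
  β′ = c₀ + c₁β + c₂β², fitted from I/II probe pairs < 50 bp apart. The
  published coefficients (0.001514, 0.3323, 0.7411) ship with the package.
- **Association**: per-CpG ordinary least squares of methylation on a
  case/control (or flare/quiescent) indicator with age, sex and ethnicity
  covariates; complete cases per CpG; permutation p-values (random or
  exhaustive); Benjamini–Hochberg FDR; significance tiers p < 1e-8 and
  FDR < 1%.
- **Characterization**: QQ data, log₂ hyper:hypo directionality per
  −log₁₀(p) bin (+0.5 continuity correction), the biphasic band
  1e-11 < p < 1e-8, and enrichment of intermediate (20–80%)
  control-group methylation among significant CpGs.
- **Gene enrichment**: CpG→gene mapping within a ±5 kb window, shared /
  cell-type-specific gene classification across cell types, and gene-set
  enrichment (GMT) by one-sided Fisher's exact test with fold enrichment.
- **Replication & mixture model**: cross-cohort replication (fraction
  significant at p < 0.01; delta-concordance R²), sorted-subset
  attenuation ratios, and the exact decomposition of a bulk methylation
  difference into compositional and intrinsic components,

  Δ_bulk = Σₖ (f_k^case − f_k^ctrl)·μ_k^case + Σₖ f_k^ctrl·(μ_k^case − μ_k^ctrl).

- **Synthetic data**: a seeded generator of 450K-like datasets (bimodal
  beta background, batch shifts on the logit scale, chemistry distortion,
  planted IFN-like hypomethylation up to 40 percentage points, mixture-driven
  compositional probes, sorted-subset cohorts) with a truth record, so the
  whole pipeline is testable without external data.

## Worked example

Simulate a desk-scale cohort, run QC → batch adjustment → chemistry
harmonization → association, and compare against the generator's truth
record:

```r
library(methylewas)
library(dplyr)

cfg <- simulation_config(n_probes = 2000, n_cases = 40, n_controls = 40, seed = 424)
sim <- simulate_dataset(cfg)

qc   <- run_qc(sim$beta, sim$detection, sim$manifest)
adj  <- batch_adjust(qc$beta, sim$samples,
                     batch_adjust_config(mode = "nonparametric", seed = 425),
                     manifest = sim$manifest)
fit  <- fit_chemistry_correction(adj, sim$manifest)
fit
#> chemistry fit: b' = 0.00292568 + 0.355197*b + 0.716745*b^2  (100 pairs, <50 bp)
norm  <- apply_chemistry_correction(adj, sim$manifest, fit)
assoc <- run_association(norm, sim$samples, contrast_spec(), manifest = sim$manifest)
count(assoc, tier)
#> # A tibble: 3 × 2
#>   tier                       n
#>   <chr>                  <int>
#> 1 highly_significant       112
#> 2 moderately_significant    84
#> 3 ns                      1804
```

The refitted chemistry coefficients sit close to the packaged published
values (0.001514, 0.3323, 0.7411); the small offsets come from batch
adjustment and measurement noise. Of the 2,000 CpGs, 112 reach the
highly-significant tier (p < 1e-8) — this includes all 30 planted
IFN-like probes, whose estimated deltas average −0.24 (hypomethylation in
cases) — and 84 more pass FDR < 1%, mostly mild compositional effects:

```r
truth <- sim$truth$probes
assoc |>
  inner_join(truth, by = "probe_id") |>
  filter(role == "ifn") |>
  summarise(n = n(), mean_delta = mean(delta), all_highly = all(tier == "highly_significant"))
#> # A tibble: 1 × 3
#>       n mean_delta all_highly
#>   <int>      <dbl> <lgl>
#> 1    30     -0.239 TRUE
```

Sorted-subset cohorts separate the two kinds of biology: intrinsic
(IFN-like) effects keep their amplitude in every purified subtype, while
compositional effects collapse:

```r
subs    <- simulate_sorted_subsets(cfg, sim$truth)
subtabs <- lapply(subs, \(s) run_association(s$beta, s$samples, contrast_spec()))
subset_attenuation(assoc, subtabs)
#> Sorted-subset attenuation report
#>   probes: 2000 (compositional: 461, indeterminate: 102, intrinsic: 101, unstable: 1336)
#> # A tibble: 3 × 5
#>   subset     stratum n_tested fraction_replicated delta_concordance_r2
#>   <chr>      <chr>      <int>               <dbl>                <dbl>
#> 1 naive      all         2000              0.0265                0.578
#> 2 memory     all         2000              0.022                 0.598
#> 3 regulatory all         2000              0.022                 0.577
```

(`unstable` marks probes whose bulk delta is below 0.01 in magnitude, where
attenuation ratios are not meaningful — here mostly true null probes.)

A YAML-driven entry point chains the stages with a run manifest and seeds
(`run_pipeline()`, or `inst/cli/methylewas.R` from a shell); reruns with the
same config and seeds are byte-identical.

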