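---
title: "Methods: case/control methylation analysis on 450K-style arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/control methylation analysis on 450K-style arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `methylewas`: the
models, the parameters that matter, the numerical choices, and what the
synthetic-data generator does and does not emulate. It is the package's own
account of its methods; every quantitative statement here is one the test
suite or the acceptance script computes.

## Data model

Methylation is represented as beta scores — per-probe proportions of
methylated signal in [0, 1] — in a probes × samples matrix with a matching
detection p-value matrix (the probability that a probe's total intensity is
indistinguishable from background). Probe metadata (Infinium chemistry I/II,
chromosome, 1-based position, blacklist and SNP flags) and per-sample
phenotypes (disease, activity, age, sex, ethnicity, cell type, batch) travel
as tibbles. Gene annotation is stored in the BED convention (0-based
half-open intervals); probe positions are 1-based, and the conversion is
done once at the mapping boundary. This makes the ±5 kb window rule
unambiguous: a probe at 1-based position $p$ is assigned to a gene spanning
$[s, e)$ iff $s - w \le p - 1 < e + w$ with $w = 5000$ bp. Strand is stored
but ignored by proximity, since no strand rule is defined for CpG-to-gene
distance.

## QC cascade

Fixed order: detection mask → sample filter → probe filter → blacklist.

* detection p > 0.01 (strict) masks a cell;
* a sample is dropped iff its missing fraction over *autosomal* probes is
  strictly greater than 1.5% — computed before any probe removal, since the
  reference denominator is the full autosomal probe set;
* a probe is dropped iff missing in strictly more than 10% of the retained
  samples;
* blacklisted (multi-/mis-mapping) probes are removed; SNP-overlap probes
  are counted but kept.

No value is altered, only masked or removed, so a second pass finds nothing
new — with one caveat: a sample sitting within a hair of the 1.5% threshold
can flip on a second pass because probe removal changes the denominator.
The cascade is therefore idempotent away from the threshold boundary, which
is the regime the thresholds are designed for.

## Batch adjustment

Technical variation shared by the samples of one array (a "batch" of 12) is
removed by an empirical-Bayes location/scale model, implemented natively in
the package. Per probe $g$ and batch $i$, after standardizing by a
covariate-protected fit (disease, age, sex, ethnicity are protected so the
adjustment cannot absorb the disease signal), batch means $\gamma_{ig}$ and
variances $\delta^2_{ig}$ are shrunk toward common priors and divided out:

* **parametric mode**: normal prior on $\gamma$, inverse-gamma on
  $\delta^2$, hyperparameters estimated by moments, posterior found by the
  standard fixed-point iteration (convergence tolerance 1e-4);
* **nonparametric mode** (default, matching the original description of the
  procedure): Monte-Carlo integration over the empirical prior formed by
  the other probes' $(\hat\gamma, \hat\delta^2)$ estimates, subsampled to
  `mc_draws = 1000` draws per batch (seeded). The draw count is a
  configurable default chosen to keep the integration error well below the
  measurement noise at desk scale.

Probes are partitioned into random non-overlapping subsets of at most
`subset_size = 20000` CpGs, each adjusted independently (the historical
motivation is parallelism; the unit tests verify that subsetted and full
runs agree within 1e-3 mean absolute difference). Chemistries are adjusted
separately; chromosome X is adjusted separately per sex. Missing cells are
mean-imputed for the fit and re-masked afterwards. Output is clipped to
[0, 1]. Batches with fewer than two samples pass through with a warning;
with fewer than two batches the input is returned unchanged.

Our implementation is cross-checked in the test suite against the reference
ComBat implementation in `sva` (maximum absolute difference below 1e-5 on a
parametric run). One behavioural property deserves emphasis: after EB
adjustment, explicit per-CpG batch tests are *conservative*, not uniform —
shrinkage removes even the chance component of per-batch means, so batch
p-values pile up near 1. This is equally true of the reference
implementation. "Batch effects removed" therefore means *no residual
batch-driven inflation* (no excess of small batch p-values), and that is
what the acceptance test asserts, via a one-sided Kolmogorov–Smirnov check
against the inflation direction.

## Chemistry harmonization

The two Infinium chemistries report systematically different beta
distributions. Type II values are mapped toward the type I scale by
$\beta' = c_0 + c_1\beta + c_2\beta^2$. The packaged published coefficients
are (0.001514, 0.3323, 0.7411); `fit_chemistry_correction()` re-estimates
them from the data by pairing every type I probe with every type II probe
within 50 bp (strict) on the same chromosome — at that distance latent
methylation is locally shared — and regressing per-probe mean betas
(type I response, type II predictor) with ordinary least squares. Per-probe
means are used rather than pooled per-sample pairs; both are defensible
readings of "observed pairs of beta scores", and means are the more stable
choice at small sample counts. A minimum of 50 pairs is required.

The quadratic exceeds 1 at $\beta = 1$ (raw value 1.074914), so corrected
values are clipped to [0, 1] to preserve the proportion contract; the raw
value is available via `predict_chemistry(..., clip = FALSE)`. The mapping
is monotone non-decreasing on [0, 1] for the published coefficients
($c_1 + 2 c_2 \beta \ge 0$). The generator distorts type II probes with the
exact closed-form inverse of this quadratic, which is what makes
coefficient recovery a sharp oracle: noise-free pairs refit to the printed
values within 1e-6.

## Association model

Per CpG, ordinary least squares of the beta value on a group indicator plus
covariates, on complete cases:

$$\beta_{gj} = \alpha_g + \Delta_g \cdot \mathrm{case}_j + \mathbf{x}_j^T
\boldsymbol\gamma_g + \varepsilon_{gj}$$

$\Delta_g$ — the covariate-adjusted case-minus-control difference in
proportion units, negative meaning hypomethylation in cases — is the
reported delta, with a two-sided t-test p-value. Covariates: age (years),
sex (indicator), ethnicity (indicators, most frequent level as reference).
The flare-vs-quiescent contrast is the same model on cases only. On
chromosome X the analysis is restricted to females and the sex covariate
dropped. Each contrast group must retain at least 3 samples. Probes with a
constant response report delta 0 and a missing p; all-missing probes are
emitted with `n_used = 0`. Internally probes are grouped by missingness
pattern so the linear algebra is vectorised; the per-probe results equal
`lm()` to 1e-10 in the tests.

Significance tiers follow two thresholds: *highly significant* at
p < 1e-8 (an approximate genome-wide Bonferroni level for ~470k tests) and
*moderately significant* at Benjamini–Hochberg FDR < 1%.
`tier_thresholds()` reports the data-dependent p cutoff that achieves the
FDR target (the largest p among passing rows). BH is computed by
`stats::p.adjust`; the number of tests is the number of non-missing
p-values, and missing p-values propagate as missing q-values.

Permutation p-values randomize the group labels and recompute the t
statistic: the add-one estimator $(1 + \#\{|t^*| \ge |t|\})/(1 + B)$ avoids
zero p-values for random permutations; `exhaustive = TRUE` enumerates all
distinct assignments and returns the exact permutation p (identity
included), which the tests verify against full enumeration with `lm()` at
3 + 3 samples.

## Signal characterization

* `qq_data()`: observed $-\log_{10} p$ against uniform expectations
  $(i - 0.5)/n$.
* `directionality_profile()`: per $-\log_{10}(p)$ bin (default width 1.0, a
  package choice — no canonical binning exists),
  $\log_2\frac{\#\{\Delta>0\}+0.5}{\#\{\Delta<0\}+0.5}$. The +0.5
  continuity correction keeps empty bins finite and makes the profile
  exactly antisymmetric under delta negation. Probes with $\Delta = 0$
  count in neither direction.
* `biphasic_band()`: the strict band $10^{-11} < p < 10^{-8}$ where a
  second, milder phenomenon overlaps the strong primary signal.
* `intermediate_methylation_enrichment()`: compares the fraction of
  significant CpGs whose *control-group* mean lies in [0.2, 0.8] against
  the array-wide fraction. Control means are used because the reference
  distribution is defined on unaffected samples. The odds ratio is the odds
  of the significant-set fraction against the array-wide fraction (so a
  significant set equal to the whole array gives OR exactly 1); the
  accompanying Fisher p contrasts significant vs non-significant probes.

## Gene mapping, classification, enrichment

Genes windows are the gene body ± 5 kb; probes may map to several genes or
none. Per gene and cell type, the best mapped CpG sets the status (highly:
p < 1e-8; moderate: FDR < 1%; else ns), and categories follow the shared /
cell-type-specific rules: highly in all cell types (`shared_all`); highly
in ≥ 1 and at least moderate in the rest (`shared_relaxed`); highly in
exactly one and ns elsewhere (`cell_type_specific`). These categories are
not closed under strengthening evidence — a gene highly significant in two
of three cell types and ns in the third belongs to none of them — which is
inherent to the definitions; monotonicity holds on the shared track
(moderate → highly can only move a gene up).

Gene-set enrichment works at probe level: a probe "hits" a set if mapped to
any member gene; fold enrichment is the top-list hit fraction over the
background hit fraction (background includes the top list); significance is
a one-sided Fisher's exact test (enrichment direction only, matching how
such results are reported). Ties in `top_k_probes()` break by descending
|delta|, then probe ID, so rankings are deterministic.

## Replication and the mixture model

Replication statistics over the probes shared by two cohorts: the fraction
with validation p below 0.01, and the squared Pearson correlation of the
per-CpG deltas (symmetric in the two cohorts by construction).

The mixture model represents a bulk tissue as subtype fractions $f_k$ and
per-subtype methylation profiles $\mu_k$; the bulk mean is $\sum_k f_k
\mu_k$. The bulk case-control delta splits *exactly* into

$$\Delta_{\mathrm{bulk}} = \underbrace{\sum_k (f_k^{case} - f_k^{ctrl})\,
\mu_k^{case}}_{\text{compositional}} + \underbrace{\sum_k f_k^{ctrl}\,
(\mu_k^{case} - \mu_k^{ctrl})}_{\text{intrinsic}}.$$

This is one of two equivalent exact splittings (the other weights the
fraction change by control profiles); the case-profile convention is fixed
and documented so results are reproducible. A component is "pure" when it
reaches 80% of $|\Delta_{\mathrm{bulk}}|$ and the other does not; probes
with cancelling components (zero bulk, nonzero parts) are flagged mixed
with a warning. The identity is property-tested on 1,000 random
specifications to 1e-9.

`subset_attenuation()` operationalizes the sorted-subset logic: the ratio
of each purified subtype's delta to the bulk delta. Intrinsic effects keep
ratios near 1; compositional effects collapse toward 0. The default flags —
median ratio ≥ 0.7 intrinsic, ≤ 0.3 compositional — mirror the observed
halving of replication in sorted subsets relative to the bulk pool, and are
configurable. Ratios are suppressed for bulk deltas below 0.01 in magnitude
(division instability dominates there).

## Synthetic-data generator

The generator is first-class, tested code. It emulates the statistical
structure the analysis assumes:

* **bimodal background**: probe means drawn 45/45/10 from Beta(1, 18),
  Beta(18, 1) and Uniform(0.2, 0.8), so well over 70% of probe means fall
  outside [0.2, 0.8] even after chemistry distortion;
* **cohort**: 49 cases / 58 controls by default (the motivating study's
  cohort), ~90% female, two ethnicity strata, batches of 12 with cases and
  controls interleaved so batch and disease are near-orthogonal;
* **IFN-like intrinsic effects**: case hypomethylation with deltas drawn
  from [0.10, 0.40] (the upper end matching the strongest reported
  effects), on control means in [0.55, 0.92];
* **compositional effects**: a three-subtype CD4-like mixture
  (naive/memory/regulatory at 45/35/20% in controls, 33/47/20% in cases; a
  shift toward memory-like cells, consistent with an activation account).
  Each compositional probe is a subtype "marker" (high in one subtype, low
  in the others, levels drawn from [0.6, 0.9] vs [0.1, 0.4]); markers are
  assigned to the expanding subtype with probability 0.7, so mild
  compositional effects skew toward hypermethylation while the strong
  intrinsic signal is purely hypomethylated — reproducing the biphasic,
  direction-switching signature;
* **technical structure**: batch shifts additive on the logit scale
  (SD 0.3, clipped back to [0, 1] — no generative form is prescribed for
  batch effects, and logit keeps proportions valid); truncated-normal
  within-group noise (SD 0.05); type II probes distorted by the exact
  inverse of the harmonization quadratic; I/II probe pairs placed 30 bp
  apart with shared latent means to support the chemistry fit; detection
  failures injected uniformly at random (rate 0.002) — no spatial failure
  model is assumed;
* **sorted subsets**: per-subtype cohorts (default 20 cases / 15 controls,
  smaller than the bulk cohort, as sorted validation sets are) in which
  each subtype expresses its own profile identically in both groups, so
  compositional effects vanish and intrinsic effects persist at full
  amplitude. Sorted matrices are generated on the normalized scale.

What the generator does **not** emulate: probe-level intensities, genomic
spatial autocorrelation beyond the proximal pairs, realistic batch-effect
magnitudes (unquantified in the motivating study; defaults are chosen for
testability), cell-type-specific noise structure, or population structure
beyond a two-level ethnicity label. Tests passing on synthetic data
therefore demonstrate the *statistical machinery* — calibration, recovery,
exact identities — not robustness to every artefact of real arrays.

## Problem sizes and determinism

The default test and acceptance workloads use 2,000–10,000 probes and
cohorts of 30–100 samples — sizes at which every distributional check has
adequate power while the full suite runs in about a minute. Every
stochastic stage takes an explicit integer seed and refuses to run without
one; pipeline reruns with the same config and seeds are byte-identical
(numeric TSVs are written at full precision with a round-tripping parser on
the read side).

## Known limitations

* The blacklist is consumed, not derived; no probe re-alignment is done.
* No reference-based cell-composition deconvolution is provided — the
  mixture model implements the compositional arithmetic and its exact
  decomposition, not a constrained-projection estimator.
* Quantile/BMIQ/SWAN-style normalizations are out of scope; the chemistry
  quadratic is the only cross-chemistry harmonization.
* Complete-case analysis per CpG; no imputation at the association stage.
* The EB batch adjustment's conservativeness for explicit batch tests (see
  above) is a property of the method family, not a defect of this
  implementation.
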