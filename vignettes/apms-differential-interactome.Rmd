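---
title: "Differential interactome analysis of AP-MS pull-downs"
author: "apmspi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential interactome analysis of AP-MS pull-downs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmspi)
```

## The problem

Affinity-purification mass spectrometry (AP-MS) compares what co-purifies
with several variants of a tagged bait protein. The design handled here has
four pull-down conditions — an empty-vector negative control (`EV`) and
three bait variants (`WT`, `ALT`, `NLS`, e.g. a canonical protein, an
alternative-C-terminus isoform, and a nuclear-localization-signal deletion)
— assayed in replicate multiplexed runs ("replicate batches"), optionally
under two treatments (untreated and oxidative stress) analyzed as
independent datasets.

Two nuisance processes dominate such data. Run-to-run differences in
labeling and loading shift whole batches; and the *amount of
immunoprecipitated bait* varies between samples and variants, dragging all
genuine binders up and down with it. The pipeline addresses the first by
batch-wise centering and the second by regressing every prey on the bait's
own profile.

## The procedure

1. **Relative log2 abundances.** Raw intensities are log2-transformed
   (`log2_transform()`, optional pseudocount) and each protein is centered
   to its row mean within each replicate batch (`center_batches()`). "Row"
   is the protein and "batch" is one multiplexed run: after centering,
   every protein has mean 0 within every run, so any per-protein offset
   constant within a run — including a planted batch effect — is removed
   exactly. Centering subtracts in log space, equivalent to dividing by the
   geometric mean on the linear scale.
2. **Binders over the control.** For each bait condition and treatment,
   every prey is tested against the EV samples with a two-sample t-test
   (`ev_enrichment()`; Student pooled-variance by default, Welch
   optionally). Binders require `log2FC > 0.5` *and* `p < 0.05`, both
   strict (`call_binders()`); raw p-values are used, since the threshold
   is a per-test criterion, with a BH-adjusted column emitted for
   reference only. Binder sets are partitioned across the three variants
   by a three-way Venn (`venn_partition()`).
3. **Bait regression.** Within a treatment, the centered values of the
   WT/ALT/NLS samples (EV excluded) are regressed per prey on the bait
   protein's own centered row, `prey = a·bait + b` (`bait_correct()`).
   The residuals are the bait-amount-corrected relative log2 abundances:
   by construction they have zero mean and zero correlation with the bait,
   which is precisely the removal of IP-efficiency variability. The
   per-prey Pearson correlation to the bait is computed on the same
   samples, and the binder union is filtered to preys with `r > 0.3`
   (`select_correlated_binders()`), discarding EV-enriched proteins that do
   not actually track the bait.
4. **Variant-versus-variant contrasts.** For ALT vs WT, NLS vs WT and NLS
   vs ALT, matched log2 ratios are formed per replicate batch on the
   corrected matrix (`matched_log2_ratios()`) and tested against mean zero
   with one-sample t-tests. Each correlated binder gets a
   **π value**, `π = log2FC × (−log10 p)`, combining effect size and
   confidence, and the subset is ranked by descending π
   (`rank_binders()`; ties by ascending p, then protein id, so ranks are a
   deterministic permutation).
5. **Overrepresentation.** The top-`n` proteins of a ranking (default 100)
   are tested against a user-supplied GMT gene-set collection with the
   hypergeometric upper tail P[X ≥ k], BH-adjusted across sets
   (`hypergeometric_ora()`), with the correlated-binder subset as the
   universe — the selection and the background live on the same filtered
   scale.

`run_apms()` composes the stages per treatment, writes every intermediate
as plain TSV with a header recording version, config hash and seed, and is
byte-reproducible at fixed config and seed.

## The synthetic-data generator

No public protein-level table ships with the package, so
`simulate_apms()` generates one under the model the analysis assumes. For
sample *s*, the bait log2 level is `B_s = μ_B + N(0, σ_bait²)` in bait
conditions and a low constant background in EV. A prey follows

```
y_ps = μ_p + β·(B_s − μ_B) + δ_{class,cond,treat} + batch_pb + N(0, σ²)
```

with `β = δ = 0` for background preys and in EV. Planted binders are
therefore simultaneously EV-enriched (δ) and bait-correlated (β) — the two
signals the pipeline exploits. Values below a linear-scale detection limit
are masked missing (a hard limit: simple and exactly testable, not a claim
about the dropout mechanism of real instruments). One seeded stream with a
fixed draw order makes runs bit-identical.

Default conditions (chosen once, from a power analysis of the planted
model, and not revisited): 2,000 proteins, 200 binders in each of five
classes (shared, WT-, ALT-, NLS-preferring, and a co-regulated "module"),
4 replicate batches, `β = 1`, `σ = 0.3`, bait-efficiency SD 0.5, batch SD
0.3, baseline `N(10, 1.5²)` log2 units, bait mean 12, detection limit 128.
Enrichment is `δ = 2` for shared binders and `2.5/1.5` for
preferred/non-preferred conditions — a 1 log2-unit preference difference,
large enough that per-condition EV tests at the study thresholds have
~95% power given the bait-efficiency variance that leaks into the
uncorrected comparison. The module class is flat at 1.5 except `δ = 2.5`
in ALT under oxidative stress, so stress-dependent module recovery has a
planted positive.

Two deliberate design choices differ from the most literal reading of the
generative sketch that motivated this package:

* **Preference lives in δ, not β.** The regression fits one slope per prey
  per treatment, pooled over the three bait conditions. A
  condition-varying β would make that fit mis-specified for every
  preference binder, so that "slope recovery" would measure
  mis-specification rather than estimation. With a common β the pooled fit
  is exactly well specified for condition-constant-δ preys, and the
  preference signal still reaches the contrasts through the residuals.
* **Gene-set decoys.** The planted module is written as one GMT record; the
  pipeline additionally generates seeded random decoy sets of matched size
  (`make_gene_sets()`), because "is the planted module the top term?" is
  only meaningful against competitors.

### What the generator does and does not emulate

It reproduces the statistical structure the method assumes: variable bait
pulldown, batch offsets, EV background, planted preference classes,
detection-limit missingness. It does not simulate peptides, TMT reporter
channels, isotopic impurity, ratio compression, search-engine behavior, or
correlated (co-complex) noise between preys. Passing recovery tests
therefore shows the pipeline is a correct and calibrated implementation of
its model — not that the model captures every pathology of real AP-MS
data.

## Numerical choices and degenerate inputs

* Zero-variance groups: equal-mean constant groups give `t = 0, p = 1`;
  unequal constant groups clamp p to the smallest positive double with a
  warning and a `degenerate` flag. This keeps noise-free simulations total
  without inventing significance machinery.
* A constant prey regresses to slope 0 with `r = 0` (flagged); a constant
  bait is a degenerate-regressor error, since no bait-correction is
  possible.
* π requires `p ∈ (0, 1]`; an upstream-clamped `p = 0` is re-clamped to
  the smallest positive double.
* Missing values are handled by available-case analysis throughout
  (pairwise-complete regression and correlation, per-batch pairing drops
  for matched ratios); nothing is imputed, because imputation would add
  assumptions none of the downstream tests could verify. Minimums: 2
  values per t-test group, 3 paired points per regression, 2 shared
  batches per contrast.
* The bait row is exempt from the minimum-observation filter (its EV cells
  are legitimately below detection) and excluded from all prey-level
  statistics.
* An empty Venn union reports a triple-overlap fraction of 0.

## Choices where the design was genuinely open

* **Batch scope.** Whether a "replicate batch" pools both treatments of a
  run or splits them is exposed as `batch_scope` (`"batch"`, the default,
  treats one multiplexed run as self-normalizing; `"batch_treatment"`
  splits).
* **EV samples and the correlation.** EV samples are excluded from the
  regression by construction; the correlation is computed on the same
  EV-free samples for consistency (an `include_ev`-style variant can be
  obtained by calling `pearson_to_bait()` directly on other columns).
* **Per-treatment regression.** One fit per treatment (untreated and
  stressed interactomes are separate datasets); `per_condition = TRUE` in
  `bait_correct()` gives the per-condition sensitivity analysis.
* **Noise-free exactness is asserted in two configurations**, because the
  generative model couples bait variance and regression identifiability:
  with bait-efficiency variance and condition-constant δ, slopes,
  correlations (r = 1) and residual contrasts are exact; with zero
  bait-efficiency variance the regressor is constant (a contracted error)
  and the centered-matrix matched ratios equal the planted preference
  differences exactly.
* **Evaluation scales.** The package's own tests run the full default
  scenario (2,000 × 32) once and reuse it across checks; unit tests use
  ~120-protein simulations. These sizes were chosen so the whole suite
  completes in well under a minute while keeping binomial error bands
  tight enough to be informative.

## Known limitations

* The slope of the bait regression is estimated from as many points as
  there are bait-variant samples per treatment (12 at the default design),
  so its sampling error is on the order of 0.2 at the default noise
  settings; the package asserts that the achieved RMSE attains the
  theoretical OLS bound (within 10%) rather than a fixed small constant.
  Preference binders carry additional between-condition enrichment
  dispersion in the pooled fit; their slope estimates are unbiased but
  noisier (reported separately as `slope_rmse_all`).
* Raw p-values drive binder calling (a per-test criterion, not an FDR);
  users needing error-rate control across proteins should use the emitted
  `p_adj`.
* The ORA substitutes a generic ranked-cutoff hypergeometric test for any
  network-based enrichment a specific database tool would provide; users
  supply their own GMT collections.
* No moderated-variance (empirical-Bayes) shrinkage: with 4 replicates the
  per-protein t-tests are exactly calibrated but not variance-pooled.

## A worked run

```{r, eval = FALSE}
library(apmspi)
cfg <- apms_config(seed = 42, out_dir = "apms_demo",
                   sim = sim_params(seed = 42))
res <- run_apms(cfg)
res$evaluation          # recovery metrics against the planted truth
res$ora$oxidative$ALT_vs_WT[1:3, ]  # planted module should lead
```

The same quantities are recomputed from scratch by
`scripts/acceptance.R --seed <int> --out <path>` at the repository root.
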