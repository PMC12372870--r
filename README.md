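# apmspi

Differential interactome analysis for affinity-purification mass
spectrometry (AP-MS), for proteomics analysts comparing the binding
partners of several bait protein variants — e.g. a canonical protein, an
alternative-C-terminus isoform, and a localization-signal deletion —
against an empty-vector (EV) negative control across replicate multiplexed
runs.

The pipeline implements, as tested reusable functions:

* **batch centering** — per-protein row-mean centering of log2 intensities
  within each replicate batch;
* **binder calling** — two-sample t-tests of each bait variant against EV,
  with strict thresholds log2FC > 0.5 and *P* < 0.05, and three-way Venn
  partitioning of the binder sets;
* **bait regression** — per-prey ordinary least squares
  *y* = *ax* + *b* on the bait protein's own profile (EV excluded); the
  residuals are bait-amount-corrected relative abundances, removing
  variability in immunoprecipitation efficiency;
* **correlation filtering** — retaining binders with Pearson *r* > 0.3 to
  the bait;
* **π-value ranking** — matched per-batch log2 ratios between variants,
  one-sample t-tests, and π = log2FC × (−log10 *P*) as the significance
  ranking of the correlated-binder subset;
* **overrepresentation analysis** — hypergeometric upper-tail tests of the
  top-ranked proteins against a user-supplied GMT gene-set collection;
* **a synthetic-data generator** (`simulate_apms()`) with planted binder
  classes, bait-efficiency variability, batch effects and a labeled
  co-regulated module, so every stage can be benchmarked against known
  ground truth.

## Worked example

```r
library(apmspi)
cfg <- apms_config(seed = 42, out_dir = "apms_demo",
                   sim = sim_params(seed = 42))
res <- run_apms(cfg)
```

The run simulates 2,000 proteins (1,000 planted binders in five classes)
in 4 replicate batches under two treatments, then analyzes them, logging:

```
untreated: binders over EV -- WT 968, ALT 880, NLS 962; triple overlap 86.6% of the union
untreated: 989 binders of any variant; 965 pass Pearson r > 0.3
oxidative: binders over EV -- WT 973, ALT 976, NLS 982; triple overlap 98.2% of the union
oxidative: 987 binders of any variant; 818 pass Pearson r > 0.3
```

and evaluating recovery against the planted truth
(`res$evaluation`): EV binder-calling sensitivity 0.93/0.97
(untreated/oxidative) with FDR < 0.01; the planted ALT-preferring binders'
median ALT-vs-WT π rank falls at fraction 0.095 of the ranked set
(top decile); and the planted co-regulated module is the top ORA term for
the ALT-vs-WT top-π selection under oxidative stress:

```r
head(res$ora$oxidative$ALT_vs_WT[, c("set_name", "overlap", "p_value")], 3)
#>         set_name overlap      p_value
#> 1 planted_module      53 8.751212e-12
#> 2       decoy_15      15 4.101396e-02
#> 3       decoy_01      14 1.200089e-01
```

Every intermediate table is written as commented TSV under `out_dir`, and
runs are byte-reproducible at fixed config and seed. A thin command-line
wrapper lives at `inst/scripts/apms.R`
(`Rscript apms.R <simulate|run> --seed ... --out-dir ...`). The methods
vignette (`vignettes/apms-differential-interactome.Rmd`) documents the
model, the generator's assumptions, and every numerical choice.

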