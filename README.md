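# mirtarnet

Network-assisted selection of miRNA target predictions and analysis of the
binding-site features that distinguish the selected subset from the
background.

## The problem

Seed-match predictions of miRNA binding sites in 3'-UTRs (TargetScan-style)
have high false-positive rates, and validated-interaction databases are too
small and inconsistent to learn discriminative features from. `mirtarnet`
implements a network-based strategy: miRNA families whose targets are
over-represented among the genes bound by a transcription factor (known from
ChIP-seq) define a cleaner subset of predictions — the (enriched family,
factor-bound gene) pairs — and the binding-site properties of that subset
are contrasted against the remaining background of predictions to reveal
features of likely-true target sites: 3'-UTR length, site position, local GC
content, multi-site multiplicity, and inter-site spacing and GC.

## The statistics at the core

**Corrected Monte-Carlo enrichment.** For a factor dataset with *n*
factor-bound genes in the prediction universe, *m* of them targeted by
family *A*: each iteration draws *n* genes without replacement and counts
targets of *A* in the draw (*z*), rescaled by the site-density correction

    r  =  (total predicted sites in the factor genes) /
          (total predicted sites in the draw)

so that z\* = z·r compensates the tendency of factor-bound gene sets toward
long, prediction-rich UTRs. The p-value is the upper tail
p = (1 + #{z\* ≥ m}) / (n_iter + 1); per dataset, p-values are BH-adjusted
and families with p_adj < 0.05 in at least one dataset are selected.

**Ratio-of-means resampling.** A feature contrast between the selected set
(values x, size n_A) and background (values y, size n_B) uses z = x̄/ȳ; each
iteration resamples n_A values from the complete pool behind the selected
set and n_B from the pool behind the background (independently, without
replacement) to form z\*; for z > 1, p = (1 + #{z\* > z})/(n_iter + 1), for
z < 1 the lower tail. The procedure's effective null level is about twice
nominal (characterized in the methods vignette).

**Fisher's exact tests** compare single- vs multi-site pair proportions,
overall and per selected family.

A synthetic-data generator (`generate_dataset()`) plants seed-match sites
with configurable per-family rates, enrichment inside a factor-bound gene
subset, multi-site boosts, GC gradients and a GC dip around sites, so every
stage is testable offline; TargetScan-7.2-dialect flat files are read by
`read_utr_table()` / `read_site_table()` / `read_family_table()` for
full-scale runs (`mode = "targetscan"`).

## Worked example

```r
library(mirtarnet)

cfg <- run_config(
  mode = "synthetic", output_dir = "run1", rng_seed = 7,
  n_iter_enrich = 10000, n_iter_ratio = 10000
)
bundle <- run_pipeline(cfg)

bundle$selection$selected
#> [1] "fam01" "fam02" "fam03" "fam04"

head(bundle$enrichment[, c("family_id", "n", "m", "null_mean", "null_sd", "p_raw", "p_adj")], 5)
#>   family_id   n  m null_mean null_sd  p_raw p_adj
#> 1     fam01 124 51      26.3    4.09 0.0001 0.002
#> 2     fam02 124 37      22.1    3.96 0.0001 0.002
#> 3     fam03 124 47      32.1    4.43 0.0011 0.011
#> 4     fam04 124 41      25.5    4.23 0.0009 0.011
#> 5     fam05 124 16      17.1    3.44 0.6247 0.994
```

The generator planted 4-fold enrichment for families 1–4 inside the
factor-bound genes; the test recovers exactly those: for fam01, 51 of the
124 factor-bound genes are targets versus a corrected null expectation of
26.3 ± 4.1 targets in random draws of 124 genes, p_adj = 0.002. Feature
contrasts between the selected pairs and the background:

```r
bundle$stats$table1[c(1, 4, 6, 8), c("analysis", "n_selected", "mean_selected",
                                     "n_background", "mean_background", "ratio", "p")]
#>                analysis n_selected mean_selected n_background mean_background  ratio         p
#>              utr_length         88     2908.8295          473       2571.8393 1.1310 9.999e-05
#>  relative_site_position        351        0.4865         2775          0.4999 0.9733 2.460e-02
#>      intersite_distance        175     1025.5600          621       1984.3543 0.5168 9.999e-05
#>            intersite_gc        175        0.3283          621        0.3145 1.0439 3.270e-02

bundle$stats$fisher_overall
#>  selected_multi selected_single background_multi background_single odds_ratio         p
#>              97              79              478              1676      4.302 2.215e-19
```

Selected genes have longer UTRs (ratio 1.13; an emergent selection effect:
genes with more sequence collect more sites), selected pairs carry multiple
same-family sites far more often (97/176 vs 478/2154, odds ratio 4.3 — the
generator's multi-site boost acting on the enriched families), and
inter-site distances are shorter. `make_report(bundle)` renders these plus
the GC-profile tables as plain text; all tables are also written as TSV
under `output_dir`.

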