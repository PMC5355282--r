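# editome

Tools for calling and characterising the RNA editome of matched tumor/normal
cohorts from per-position DNA and RNA pileup tables.

A-to-I RNA editing — adenosine deamination by ADAR enzymes — appears as an
A→G mismatch between RNA-seq reads and the genome. Separating genuine editing
from sequencing error, alignment artifacts and genomic variants needs matched
DNA: a true editing site is homozygous reference in genomic DNA while showing
a mismatch in RNA. `editome` is aimed at analysts with matched WGS + RNA-seq
tumor cohorts who want to (1) call editing sites with a quality-aware filter
cascade, (2) find *hyper-editing* (tumor-specific or tumor-elevated editing)
against each patient's matched normal, and (3) quantify downstream
consequences: amino-acid changes, exon-inclusion (PSI) coupling, and
editing–expression coupling.

## The statistics at the core

* **Sequencing-error model.** At a site of depth *n*, the edited-read count
  under the error hypothesis is *X* ~ Binomial(*n*, *p*), with *p* the
  sample-wide background mismatch rate. Candidates are kept at BH FDR ≤ 0.05
  on the upper-tail probability P(X ≥ k).
* **Filter cascade.** Basic depth/quality/frequency filter (depth ≥ 4, level
  ≥ 10%, ≥ 3 edited reads, BQ ≥ 20, MAPQ ≥ 20), known-variant exclusion,
  two-tailed Fisher strand-bias test (p < 0.005 discards), read-end position
  bias, simple-repeat / homopolymer / splice-region exclusion, and a genomic
  DNA homozygosity check (≥ 5×, ≤ 5% alternate, ≥ 90% reference).
* **Hyper-editing rules.** Per patient, a site is *tumor-specific* when
  called in the tumor (level ≥ 10%, ≥ 3 edit reads, ≥ 6×) while the normal
  has ≥ 6× coverage and zero edited reads; it is *differential* when
  Δ = level(tumor) − level(normal) > 0.2 with two-tailed Fisher p ≤ 0.05.
  Hypo-editing mirrors both rules.
* **Downstream quantities.** Editing rate (sites / Mb covered ≥ 4×),
  coverage-weighted editing index, PSI = ((J2+J4)/2) / ((J2+J4)/2 + J3) from
  junction counts, RPKM = 10⁶·C/(N·L/10³), Welch *t* edit+/edit−
  differential expression, and Pearson editing–expression correlation.

No patient data ship with the package. A synthetic-data generator
(`simulate_editome()`) builds matched normal/primary/metastatic trios with
the reported editome structure (91.3% A→G, 94.5% Alu, intron-dominated
regions, elevated tumor editing, homozygous-reference DNA, planted DNA-het
negative controls) plus ground-truth tables for recovery benchmarking.

## Worked example

```r
library(editome)

sim <- simulate_editome(sim_config(n_patients = 2), seed = 1)
res <- run_editome(sim)

res$summary[, c("sample_id", "n_sites", "editing_rate", "pct_AtoG",
                "pct_alu", "pct_intronic")]
#>        sample_id n_sites editing_rate pct_AtoG pct_alu pct_intronic
#> 1     P01_normal     244        68888    88.11   91.80        68.44
#> 2    P01_primary     298        84133    89.26   91.95        71.48
#> 3 P01_metastatic     296        83545    87.84   93.24        70.27
#> 4     P02_normal     247        69715    89.07   93.12        69.23
#> 5    P02_primary     292        82439    90.07   92.12        73.97
#> 6 P02_metastatic     307        86674    87.95   91.86        69.06
```

Each row is one sample: `n_sites` called editing sites, `editing_rate` sites
per megabase covered at ≥ 4× (large here because the synthetic study only
covers a few thousand positions), and the A→G / Alu / intronic percentages —
the signatures of genuine A-to-I editing (tumors sit above their matched
normals). Tumor/normal comparison and recovery against the simulator's truth:

```r
dplyr::count(res$pairs, comparison, class)
#>   comparison           class                  n
#> 1 metastatic_vs_normal hyper_differential   115
#> 2 metastatic_vs_normal hyper_specific       127
#> 3 metastatic_vs_normal hypo_differential      5
#> 4 metastatic_vs_normal hypo_specific          6
#> 5 primary_vs_normal    hyper_differential   124
#> 6 primary_vs_normal    hyper_specific       122
#> 7 primary_vs_normal    hypo_differential      3
#> 8 primary_vs_normal    hypo_specific          6

recovery_stats(res$calls[["P01_primary"]], sim$truth, sim$het_snps, "primary")
#>   n_callable n_called    tp    fp sensitivity precision het_calls
#> 1        270      298   293     5       0.919   0.983         0

res$psi_correlation
#> [1] 0.95
```

The caller recovers 92% of planted sites with true level ≥ 0.2 at 98%
precision, never calls a planted heterozygous DNA SNP, and the per-sample
editing index of the planted splice-affecting sites correlates strongly with
PSI, as planted. `tidy()`, `glance()`, `autoplot()` and the `plot_*()`
helpers give tibble summaries and ggplot figures of the same objects.

A thin command-line layer wraps the same functions:

```sh
Rscript inst/cli/editome-cli.R simulate --seed 17 --out study/
Rscript inst/cli/editome-cli.R run-all --in study/ --out results/
```

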