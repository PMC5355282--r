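---
title: "Calling and characterising a tumor RNA editome: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising a tumor RNA editome: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editome)
```

## The problem

A-to-I RNA editing — deamination of adenosine by ADAR enzymes — is read as an
A→G mismatch when RNA sequencing reads are compared with the genome. Telling
genuine editing apart from sequencing error, alignment artifacts and genomic
variants requires matched DNA and RNA from the same tissue: a real editing
site shows a mismatch in RNA while the genomic DNA is homozygous reference.
`editome` implements this matched-sample analysis for tumor/normal cohorts:
it calls editing sites from per-position pileup summaries, contrasts each
tumor with its matched normal to find hyper- and hypo-editing, and quantifies
downstream consequences (amino-acid changes, exon-inclusion coupling,
expression coupling).

## The calling model

Each RNA pileup position is reduced to at most one candidate: the majority
non-reference base. Multi-allelic positions (two alternates with three or
more reads each) are discarded — the editing model assumes a single variant
allele.

The cascade then applies, in order:

1. **Basic filter.** Depth ≥ 4, mean base quality of the alternate base ≥ 20,
   mean mapping quality ≥ 20, editing level (edited / total reads) ≥ 0.10 and
   ≥ 3 edited reads. The level, edit-base and depth thresholds are the rules
   a real editing site must ultimately meet; they are re-checked at the end
   of the cascade.
2. **Binomial sequencing-error test.** Under the error model, the edited-read
   count at a site of depth $n$ is $X \sim \mathrm{Binomial}(n, p)$ with $p$
   the sample-wide background mismatch rate (total non-reference bases over
   total bases, floored at $10^{-6}$). A candidate is kept when the
   upper-tail probability $P(X \ge k)$, Benjamini–Hochberg-adjusted across
   the sample's candidates, stays at or below an FDR of 0.05. The BH family
   is *all* candidate positions (every position with at least one mismatch),
   not only those passing the basic filter: with the family restricted to
   basic-filter survivors, an error-only position with three identical
   miscalls at depth 30 has $p \approx 5\times10^{-4}$ and is essentially
   always kept, because almost no other candidates remain to anchor the
   adjustment. Over the full mismatch family the same position lands at
   $q \approx 0.2$ and is correctly discarded, which is what keeps the caller
   quiet on error-only data.
3. **Known-variant exclusion.** Positions on a user-supplied list (e.g. a
   dbSNP extract) are dropped.
4. **Strand bias.** Two-tailed Fisher's exact test on the 2×2 table of
   forward/reverse counts of the reference and alternate base; candidates
   with $p < 0.005$ are dropped. A loose 0.05 would discard many true sites
   at deep coverage; 0.005 mirrors common practice in editing callers.
5. **Read-position bias.** A candidate is dropped when the fraction of its
   edited reads within 6 bp of a read end strictly exceeds 0.9 — a
   deterministic rule (rather than a rank test) chosen because it is exactly
   testable; edits piled onto read ends are alignment artifacts.
6. **Region exclusion.** Candidates in simple repeats, inside homopolymer
   runs of ≥ 5 identical bases (computed from an 11-bp reference context),
   or intronic within 4 bp of an exon boundary are dropped. The 4 bp window
   covers the donor/acceptor cores; exonic positions are never excluded by
   this rule, since coding-region sites adjacent to splice junctions are
   legitimate analysis targets.
7. **Genomic-DNA homozygosity.** The matched DNA pileup must cover the
   position at ≥ 5× with at most 5% of the RNA alternate base and at least
   90% reference — thresholds that tolerate isolated DNA sequencing errors at
   30–50× genomes while rejecting heterozygous variants decisively (a true
   het sits near 50%).

Every rejected candidate is kept in an audit table with its first failing
flag, and the per-stage rejection counts (the "funnel") always sum back to
the candidate count. The filters are pure predicates computed for all
candidates, so the called set does not depend on audit order.

Fisher's exact test is implemented by the point-probability method (the
two-tailed p is the total probability of tables, at the observed margins,
no more probable than the observed one) with the convention that any zero
margin gives $p = 1$; it is verified in the test suite against exhaustive
enumeration over all tables with margins ≤ 15.

## Hyper- and hypo-editing

For each patient, every position called in either the tumor or the matched
normal is compared using raw pileup counts in the partner sample (the partner
need not pass its own filters — requiring that would make "tumor-specific"
unobservable by construction). Two rules, each with a mirror image:

* **Tumor-specific** (`hyper_specific`): the site passed the full cascade in
  the tumor with level ≥ 0.10, ≥ 3 edited reads and depth ≥ 6, while the
  normal is covered at ≥ 6× with *zero* edited reads.
* **Differential** (`hyper_differential`): the editing-level difference
  Δ = tumor − normal is strictly greater than 0.2 and the two-tailed Fisher
  test on edited/non-edited read counts gives p ≤ 0.05.

When both rules hold, the specific label wins so class counts stay disjoint.
Swapping the two samples exchanges hyper and hypo sets exactly — a property
the test suite checks on every fixture. Editing rate (sites per megabase of
transcriptome covered at ≥ 4×) and hyper-editing rate use the same covered
length, making samples of different depth comparable.

## Downstream quantities

* **Editing level**: edited reads / total reads at a site.
* **Editing index** of a region: total edited reads over total reads across
  the region's adenosine sites, i.e. per-site levels weighted by coverage;
  sites below 4× are excluded. The index is a general region/site-set
  operation, so analyses of one exon are a configuration, not special-cased
  code.
* **PSI** from three junction counts — two inclusion junctions J2, J4 and a
  skipping junction J3: $\mathrm{PSI} = \frac{(J_2+J_4)/2}{(J_2+J_4)/2 + J_3}$,
  with samples totalling fewer than 10 junction reads excluded.
* **RPKM** $= 10^6 C / (N L / 10^3)$, log2 fold changes with an explicit
  missing value when either side is zero (no pseudocount: the choice is left
  to the consumer).
* **edit+/edit− differential expression**: a sample is edit+ for a gene when
  it carries at least one A→G hyper-editing site in the gene's UTRs; groups
  of at least four samples are compared with a Welch *t*-test on RPKM (Welch
  chosen over pooled-variance since equal variances cannot be assumed across
  the groups; a log-scale option exists but is off by default).
* **External score filters**: splicing-impact Z-scores are thresholded at
  |Z| ≥ 2 and PHRED-scaled deleteriousness scores at ≥ 20, both inclusive;
  sites without a score record are dropped (conservative — only scored sites
  are reported).

## The synthetic cohort

No patient data ship with the package; a generator builds a cohort with the
reported statistical structure, and its ground truth drives the recovery
tests. Defaults (all exposed in `sim_config()`):

* 4 patients × 3 tissues (normal, primary, metastatic); 20 genes with 3–8
  exons, in-frame CDS and UTRs sized to host Alu elements; Alus placed in
  introns, UTRs, non-coding exons and intergenic space, never CDS.
* 500 editing-site positions shared by the cohort, placed by region mix
  (71.5% intronic, 10.5% 3'UTR, 9.7% intergenic, remainder split over 5'UTR,
  CDS and ncRNA) with an overall Alu fraction of 94.5% (compensated for CDS
  sites, which are never Alu) and 91.3% transcript-sense A→G types.
* Normal-tissue editing levels Beta(2, 8) — right-skewed low levels, matching
  the shape of editing-level distributions in bulk tissue; depths negative
  binomial (RNA mean 30, size 10; DNA mean 35) — overdispersed like real
  coverage; sequencing errors at 0.005/base spread uniformly over the three
  non-reference bases.
* Per tumor tissue, 120 hyper sites: 60 tumor-specific (normal level 0,
  tumor level uniform on [0.25, 0.8]) and 60 differential with
  Δ ~ Uniform(0.35, 0.65). The lower bound is calibrated so a planted
  differential site actually satisfies the observed-data rule (Δ > 0.2 with
  Fisher p ≤ 0.05) with high probability at 30× — with smaller planted
  shifts the "designated hyper subset" would not reliably be hyper-editable
  in its own sequencing data, defeating its purpose as ground truth.
* Negative controls: 10 heterozygous DNA SNPs (allele fraction 0.5 in both
  DNA and RNA; half of them also appear on the known-variant list, so both
  the list exclusion and the gDNA check are exercised), 20 positions with
  edits concentrated ≤ 6 bp from read ends, and 10 positions with all edited
  reads on one strand.
* 3000 background covered positions per sample keep the background mismatch
  estimate realistic (site-to-covered-position ratio ~1:6; real
  transcriptomes are sparser still, which only lowers the background rate
  further).
* Three "splice-affecting" sites in the 5'UTR of the gene with the longest
  5'UTR, edited at 0.10/0.55/0.40 in normal/primary/metastatic, couple the
  per-sample editing index to a latent PSI
  (`clamp(0.3 + 1.0 × index + N(0, 0.05))`), from which junction counts are
  multinomial at 80 reads.
* Expression counts are negative binomial (CV 0.2) around lognormal gene
  means, with designated genes shifted two-fold in edit+ samples. True
  levels are per-tissue constants shared across patients (matching the
  single-level-per-tissue truth schema), so hyper-site presence cannot vary
  between patients; the expression module therefore accepts an explicit
  per-sample edit+/edit− assignment for its power and null-calibration
  checks.

What the generator does *not* emulate: alignment around splice junctions and
indels, PCR duplicates, reference bias, fragment-level correlation between
neighbouring sites, batch effects, and tumor purity. Passing recovery tests
therefore demonstrate that the statistical rules are implemented correctly
and are well-calibrated under the stated error model — not that the caller
is robust to every artifact of real alignments, which upstream
preprocessing must handle.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive at the site level; BED inputs stay
  0-based half-open and are converted exactly once at the boundary
  (`[s, e)` covers 1-based `p` iff `s + 1 ≤ p ≤ e`).
* Ties in the majority-alternate choice are broken in base order A<C<G<T;
  the shared alternate of a tumor/normal pair is chosen by pooled count with
  the same tie-break, which keeps the pairing symmetric under sample swap.
* Boundary semantics: level ≥ 0.10 passes at exactly 0.10; the position-bias
  fraction must strictly exceed 0.9; Δ must strictly exceed 0.2; Fisher
  p ≤ 0.05 passes at exactly 0.05; score thresholds are inclusive as printed.
* Zero-depth positions, header-only files, empty interval sets and empty
  candidate lists are all legal inputs with defined (empty) outputs; division
  by a zero covered length or an empty editing-index site set is an error,
  not a silent NaN.
* `fisher_exact_two_tailed` compares table probabilities with a relative
  tolerance of 1e-7 (as `fisher.test` does) so that mathematically equal
  probabilities computed along different floating-point routes still count
  as ties.

## Problem sizes

The default study (4 patients, ~3 540 positions per sample, 12 samples)
simulates and analyses in well under a minute; the recovery benchmark in the
acceptance suite aggregates five such studies. These sizes give the
proportion recoveries binomial standard errors well below the tolerances
they are tested against while keeping the whole suite fast.

## Known limitations

* The caller consumes pileup summaries, not reads; read-level artifacts must
  be summarised upstream (strand-split counts and read-end distances are the
  required summaries). There is deliberately no converter from
  `samtools mpileup` text, which encodes neither cleanly.
* Editing types at unstranded (intergenic) sites are reported with the
  reference collapsed into {A, C}; the two strand-mirror classes cannot be
  distinguished without gene context.
* The hyper/hypo comparison treats each site independently; no
  multiple-testing correction is applied across paired sites.
* Splice-junction discovery, read mapping, SPIDEX/CADD score computation,
  survival analysis and pathway enrichment are out of scope; the package
  consumes their outputs as tables.

## A worked micro-example

```{r example, eval = FALSE}
sim <- simulate_editome(sim_config(n_patients = 2), seed = 1)
res <- run_editome(sim)
res$summary
dplyr::count(res$pairs, comparison, class)
recovery_stats(res$calls[["P01_primary"]], sim$truth, sim$het_snps, "primary")
plot_editing_rates(res$summary)
```
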