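#' Covered transcriptome length in megabases
#'
#' Number of pileup positions with depth at or above `min_depth`, in Mb; the
#' denominator of the per-sample editing rate.
#'
#' @param pileup Pileup tibble.
#' @param min_depth Minimum depth for a position to count (default 4).
#' @return Length in megabases.
#' @export
covered_length_mb <- function(pileup, min_depth = 4) {
  if (nrow(pileup) == 0) return(0)
  sum(pileup_base_counts(pileup)$depth >= min_depth) / 1e6
}

#' Editing rate
#'
#' Editing sites per megabase of transcriptome covered at the minimum depth;
#' normalises site counts for sequencing and expression differences between
#' samples.
#'
#' @param n_sites Number of editing sites.
#' @param covered_length_mb Covered length in Mb; must be positive.
#' @return Sites per megabase.
#' @export
editing_rate <- function(n_sites, covered_length_mb) {
  if (any(covered_length_mb <= 0)) abort("covered length must be positive")
  n_sites / covered_length_mb
}

#' Editing-type proportions
#'
#' Fraction of sites per transcript-sense mismatch class (e.g. `A->G`).
#'
#' @param sites Sites tibble with an `editing_type` column.
#' @return Tibble `editing_type, n, fraction`; empty input gives zero rows.
#' @export
type_proportions <- function(sites) {
  if (nrow(sites) == 0) {
    return(tibble(editing_type = character(), n = integer(), fraction = numeric()))
  }
  dplyr::count(sites, .data$editing_type, name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n))
}

#' Genomic-region proportions
#'
#' @param sites Sites tibble with a `region` column.
#' @return Tibble `region, n, fraction`.
#' @export
region_proportions <- function(sites) {
  if (nrow(sites) == 0) {
    return(tibble(region = character(), n = integer(), fraction = numeric()))
  }
  dplyr::count(sites, .data$region, name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n))
}

#' Fraction of sites inside Alu elements
#'
#' @param sites Sites tibble with a logical `alu` column.
#' @return A single fraction (`NaN` on empty input).
#' @export
alu_proportion <- function(sites) {
  mean(sites$alu)
}

#' Coverage-weighted editing index over a region
#'
#' Aggregate editing level of a set of sites: total edited reads divided by
#' total reads, i.e. the per-site levels weighted by their coverage. Sites
#' covered below `min_depth` are excluded. For a single qualifying site the
#' index equals its editing level.
#'
#' @param sites Tibble with `edit_count` and `depth` columns (and `chrom`,
#'   `pos` when `region` is used).
#' @param region Optional single-row tibble `chrom, start, end` (1-based
#'   inclusive) restricting the sites.
#' @param min_depth Minimum per-site depth (default 4).
#' @return The editing index in `[0, 1]`.
#' @export
editing_index <- function(sites, region = NULL, min_depth = 4) {
  if (!is.null(region)) {
    sites <- filter(sites, .data$chrom == region$chrom[1],
                    .data$pos >= region$start[1], .data$pos <= region$end[1])
  }
  sites <- filter(sites, .data$depth >= min_depth)
  if (nrow(sites) == 0) abort("no qualifying sites for the editing index")
  sum(sites$edit_count) / sum(sites$depth)
}

#' Fraction of edited genes that are cancer-related
#'
#' @param hit_genes Character vector of genes carrying the editing events of
#'   interest (e.g. non-synonymous A->G hyper-editing); must be non-empty.
#' @param cancer_genes Character vector of cancer-related genes.
#' @return `|hit ∩ cancer| / |hit|`.
#' @export
cancer_gene_fraction <- function(hit_genes, cancer_genes) {
  hit_genes <- unique(hit_genes)
  if (length(hit_genes) == 0) abort("hit gene set is empty")
  mean(hit_genes %in% cancer_genes)
}

#' Per-sample editome summary row
#'
#' @param sites Called sites tibble for one sample.
#' @param pileup The sample's RNA pileup.
#' @param sample_id Sample label.
#' @param min_depth Depth threshold for the covered length (default 4).
#' @return One-row tibble: `sample_id, n_sites, covered_mb, editing_rate,
#'   pct_AtoG, pct_alu, pct_intronic, pct_utr3, pct_utr5, pct_cds,
#'   pct_intergenic`.
#' @export
summarize_editome <- function(sites, pileup, sample_id = "sample", min_depth = 4) {
  mb <- covered_length_mb(pileup, min_depth)
  pct_region <- function(r) if (nrow(sites) == 0) NA_real_ else {
    100 * mean(sites$region == r, na.rm = TRUE)
  }
  tibble(
    sample_id = sample_id,
    n_sites = nrow(sites),
    covered_mb = mb,
    editing_rate = if (mb > 0) editing_rate(nrow(sites), mb) else NA_real_,
    pct_AtoG = if (nrow(sites) == 0) NA_real_ else {
      100 * mean(sites$editing_type == "A->G", na.rm = TRUE)
    },
    pct_alu = if (nrow(sites) == 0) NA_real_ else 100 * alu_proportion(sites),
    pct_intronic = pct_region("intronic"),
    pct_utr3 = pct_region("UTR3"),
    pct_utr5 = pct_region("UTR5"),
    pct_cds = pct_region("CDS"),
    pct_intergenic = pct_region("intergenic")
  )
}
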