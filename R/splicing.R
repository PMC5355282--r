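#' Percent spliced in from three junction counts
#'
#' For a cassette exon flanked by junctions `J2` (upstream inclusion), `J4`
#' (downstream inclusion) and `J3` (the skipping junction),
#' `PSI = ((J2 + J4) / 2) / ((J2 + J4) / 2 + J3)`. Samples whose three
#' junction counts total fewer than `min_total` reads are excluded (`PSI`
#' is `NA` with `excluded = TRUE`). Rows with all three counts zero have no
#' junction evidence at all and raise an error.
#'
#' @param junctions Tibble with columns `J2`, `J3`, `J4` (and typically
#'   `sample_id`, `gene_id`).
#' @param min_total Minimum total junction reads to quantify (default 10).
#' @return `junctions` with `psi` and `excluded` columns added.
#' @export
compute_psi <- function(junctions, min_total = 10) {
  if (any(junctions$J2 < 0 | junctions$J3 < 0 | junctions$J4 < 0)) {
    abort("junction counts must be non-negative")
  }
  total <- junctions$J2 + junctions$J3 + junctions$J4
  if (any(total == 0)) abort("no junction evidence: all three counts are zero")
  incl <- (junctions$J2 + junctions$J4) / 2
  mutate(junctions,
         psi = if_else(total < min_total, NA_real_, incl / (incl + .data$J3)),
         excluded = total < min_total)
}

#' Pearson correlation between PSI and editing index
#'
#' Correlates per-sample percent-spliced-in values with per-sample editing
#' indices, dropping samples whose PSI was excluded for low junction
#' coverage. At least three complete pairs are required.
#'
#' @param psi Numeric vector of PSI values (`NA` = excluded sample).
#' @param editing_index Numeric vector of editing indices, same samples.
#' @return Pearson product-moment correlation coefficient.
#' @export
psi_vs_editing <- function(psi, editing_index) {
  keep <- !is.na(psi) & !is.na(editing_index)
  x <- psi[keep]; y <- editing_index[keep]
  if (length(x) < 3) abort("fewer than 3 paired samples after exclusions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance in PSI or editing index")
  }
  cor(x, y, method = "pearson")
}

#' Compare PSI between sample groups
#'
#' Wilcoxon rank-sum comparison of PSI between samples carrying at least one
#' of a set of hyper-editing sites and samples carrying none.
#'
#' @param psi Numeric vector of PSI values (`NA` excluded).
#' @param edited Logical vector: does the sample carry >= 1 of the sites?
#' @return Tibble `n_edited, n_unedited, median_edited, median_unedited, p`.
#' @export
psi_group_test <- function(psi, edited) {
  keep <- !is.na(psi)
  psi <- psi[keep]; edited <- edited[keep]
  if (sum(edited) == 0 || sum(!edited) == 0) {
    abort("both groups must be non-empty")
  }
  p <- suppressWarnings(wilcox.test(psi[edited], psi[!edited])$p.value)
  tibble(n_edited = sum(edited), n_unedited = sum(!edited),
         median_edited = stats::median(psi[edited]),
         median_unedited = stats::median(psi[!edited]), p = p)
}
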