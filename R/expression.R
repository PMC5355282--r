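#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e6 * C / (N * L / 1e3)` with `C` the gene's uniquely mapped read
#' count, `N` the library's total uniquely mapped reads and `L` the gene's
#' total exon length in bp.
#'
#' @param C Gene read counts (>= 0).
#' @param N Library totals (> 0).
#' @param L Exon lengths in bp (> 0).
#' @return RPKM values.
#' @examples
#' rpkm(1000, 1e7, 2000) # 50
#' @export
rpkm <- function(C, N, L) {
  if (any(N <= 0)) abort("total mapped reads N must be positive")
  if (any(L <= 0)) abort("exon length L must be positive")
  1e6 * C / (N * L / 1e3)
}

#' Log2 fold change between tumor and normal expression
#'
#' `log2(rpkm_tumor / rpkm_normal)`; undefined (`NA`) when either side is
#' zero — no pseudocount is applied, so downstream consumers must handle
#' missingness explicitly.
#'
#' @param rpkm_tumor,rpkm_normal Non-negative RPKM values.
#' @return Log2 fold changes, `NA` where undefined.
#' @export
log_fold_change <- function(rpkm_tumor, rpkm_normal) {
  if (any(rpkm_tumor < 0) || any(rpkm_normal < 0)) {
    abort("RPKM values must be non-negative")
  }
  if_else(rpkm_tumor == 0 | rpkm_normal == 0, NA_real_,
          log2(rpkm_tumor / rpkm_normal))
}

#' Partition samples into edit+ / edit- groups for a gene
#'
#' A sample is `edit+` for a gene when it carries at least one `A->G`
#' hyper-editing site in the gene's UTRs (5' or 3'); all other samples are
#' `edit-`.
#'
#' @param samples Character vector of sample ids to partition.
#' @param gene Gene id.
#' @param hyper_sites Tibble of hyper-editing sites with columns `sample_id`,
#'   `gene_id`, `region`, `editing_type`.
#' @return List with character vectors `edit_plus` and `edit_minus`.
#' @export
edit_group_partition <- function(samples, gene, hyper_sites) {
  plus_ids <- hyper_sites %>%
    filter(.data$gene_id == gene, .data$editing_type == "A->G",
           .data$region %in% c("UTR5", "UTR3")) %>%
    pull("sample_id") %>% unique()
  list(edit_plus = samples[samples %in% plus_ids],
       edit_minus = samples[!samples %in% plus_ids])
}

#' Differential expression between edit+ and edit- samples
#'
#' Welch two-sample t-test on RPKM values, requiring at least `min_n` samples
#' per group (genes below that are skipped: the return is `NULL` with a
#' message).
#'
#' @param expr_plus RPKM values of the edit+ samples.
#' @param expr_minus RPKM values of the edit- samples.
#' @param min_n Minimum group size (default 4).
#' @param log_scale Test on `log2(RPKM + 1)` instead of raw RPKM (default
#'   `FALSE`; the raw scale is the default analysis).
#' @return One-row tibble `n_plus, n_minus, mean_plus, mean_minus, t, p`, or
#'   `NULL` when a group is too small.
#' @export
edit_group_test <- function(expr_plus, expr_minus, min_n = 4, log_scale = FALSE) {
  if (length(expr_plus) < min_n || length(expr_minus) < min_n) {
    inform(paste0("group too small (", length(expr_plus), " vs ",
                  length(expr_minus), "); gene skipped"))
    return(NULL)
  }
  xp <- if (log_scale) log2(expr_plus + 1) else expr_plus
  xm <- if (log_scale) log2(expr_minus + 1) else expr_minus
  if (stats::sd(c(xp, xm)) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(xp, xm, var.equal = FALSE)
  }
  tibble(n_plus = length(expr_plus), n_minus = length(expr_minus),
         mean_plus = mean(expr_plus), mean_minus = mean(expr_minus),
         t = unname(tt$statistic), p = tt$p.value)
}

#' Correlation between a site's editing level and host-gene expression
#'
#' Pearson product-moment correlation across samples. Samples covered below
#' `min_depth` at the site or with editing level exactly zero are excluded;
#' at least three samples must remain.
#'
#' @param levels Per-sample editing levels at the site.
#' @param expr Per-sample RPKM of the host gene.
#' @param depth Per-sample read depth at the site.
#' @param min_depth Minimum depth to retain a sample (default 4).
#' @return Pearson correlation coefficient.
#' @export
editing_expression_correlation <- function(levels, expr, depth = NULL,
                                           min_depth = 4) {
  keep <- !is.na(levels) & !is.na(expr) & levels > 0
  if (!is.null(depth)) keep <- keep & depth >= min_depth
  x <- levels[keep]; y <- expr[keep]
  if (length(x) < 3) abort("fewer than 3 samples retained after exclusions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance after exclusions")
  cor(x, y, method = "pearson")
}

#' Edit+/edit- differential expression across all genes
#'
#' Runs [edit_group_partition()] and [edit_group_test()] for every gene with
#' hyper-editing in UTRs, over a cohort expression table.
#'
#' @param expression Tibble `sample_id, gene_id, unique_read_count,
#'   exon_length_bp`.
#' @param library_sizes Tibble `sample_id, total_mapped_reads`.
#' @param hyper_sites Tibble of per-sample hyper-editing sites (columns
#'   `sample_id, gene_id, region, editing_type`).
#' @param samples Sample ids to include (defaults to all in `expression`).
#' @param min_n Minimum group size (default 4).
#' @return Tibble `gene_id, n_edit_plus, n_edit_minus, mean_rpkm_plus,
#'   mean_rpkm_minus, t_p` (skipped genes absent).
#' @export
edit_group_de <- function(expression, library_sizes, hyper_sites,
                          samples = NULL, min_n = 4) {
  samples <- samples %||% unique(expression$sample_id)
  expr <- expression %>%
    filter(.data$sample_id %in% samples) %>%
    left_join(library_sizes, by = "sample_id") %>%
    mutate(rpkm = rpkm(.data$unique_read_count, .data$total_mapped_reads,
                       .data$exon_length_bp))
  genes <- hyper_sites %>%
    filter(.data$editing_type == "A->G", .data$region %in% c("UTR5", "UTR3")) %>%
    pull("gene_id") %>% unique()
  res <- purrr::map(genes, function(g) {
    grp <- edit_group_partition(samples, g, hyper_sites)
    ge <- filter(expr, .data$gene_id == g)
    xp <- ge$rpkm[match(grp$edit_plus, ge$sample_id)]
    xm <- ge$rpkm[match(grp$edit_minus, ge$sample_id)]
    xp <- xp[!is.na(xp)]; xm <- xm[!is.na(xm)]
    tt <- suppressMessages(edit_group_test(xp, xm, min_n = min_n))
    if (is.null(tt)) return(NULL)
    tibble(gene_id = g, n_edit_plus = tt$n_plus, n_edit_minus = tt$n_minus,
           mean_rpkm_plus = tt$mean_plus, mean_rpkm_minus = tt$mean_minus,
           t_p = tt$p)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), n_edit_plus = integer(),
                  n_edit_minus = integer(), mean_rpkm_plus = numeric(),
                  mean_rpkm_minus = numeric(), t_p = numeric())
  }
  structure(out, class = c("edit_group_de", class(out)))
}
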