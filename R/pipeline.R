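#' Run the full editome analysis over a simulated or loaded study
#'
#' Calls editing sites in every sample, compares each tumor to its matched
#' normal (hyper/hypo editing), builds per-sample editome summaries,
#' quantifies PSI and its correlation with the editing index of the
#' designated splice-affected sites, and runs the edit+/edit- differential
#' expression scan.
#'
#' @param study An `editome_sim` from [simulate_editome()] or a directory
#'   written by [write_simulation()].
#' @param config A [caller_config()].
#' @param pair_cfg A [pair_config()].
#' @param index_sites Optional tibble `chrom, pos, alt` of sites over which
#'   the per-sample editing index is computed for the PSI analysis; defaults
#'   to the study's planted splice-affecting sites when available, otherwise
#'   to called A->G sites in the junction gene.
#' @return An `editome_result` list: `calls` (named list of `editing_calls`),
#'   `summary`, `pairs`, `psi`, `psi_correlation`, `de`, `samples`.
#' @export
run_editome <- function(study, config = caller_config(),
                        pair_cfg = pair_config(), index_sites = NULL) {
  if (is.character(study)) study <- load_study(study)
  ann <- annotation_bundle(
    gene_models = study$reference$gene_models,
    alu = study$reference$alu,
    repeats = study$reference$repeats,
    known_variants = study$known_variants,
    genome = study$reference$genome
  )
  samples <- study$samples
  calls <- list()
  summary_rows <- list()
  for (sid in samples$sample_id) {
    cl <- call_editing_sites(study$rna[[sid]], study$dna[[sid]],
                             annotation = ann, config = config,
                             sample_id = sid)
    calls[[sid]] <- cl
    summary_rows[[sid]] <- summarize_editome(cl$sites, study$rna[[sid]], sid,
                                             min_depth = config$min_depth)
  }
  summary <- bind_rows(summary_rows)

  pairs <- list()
  for (pt in unique(samples$patient)) {
    nid <- paste0(pt, "_normal")
    if (!nid %in% names(calls)) next
    for (tt in c("primary", "metastatic")) {
      tid <- paste0(pt, "_", tt)
      if (!tid %in% names(calls)) next
      pr <- call_pairs(calls[[tid]], calls[[nid]], study$rna[[tid]],
                       study$rna[[nid]], config = pair_cfg)
      if (nrow(pr) > 0) {
        pairs[[tid]] <- mutate(pr, patient_id = pt,
                               comparison = paste0(tt, "_vs_normal"),
                               sample_id = tid, .before = 1)
      }
    }
  }
  pairs <- bind_rows(pairs)

  psi <- NULL; psi_correlation <- NA_real_
  if (!is.null(study$junctions) && nrow(study$junctions) > 0) {
    psi <- compute_psi(study$junctions)
    isites <- index_sites %||% study$splice_sites
    idx <- purrr::map_dbl(psi$sample_id, function(sid) {
      if (!is.null(isites)) {
        editing_index_at(study$rna[[sid]], isites, min_depth = config$min_depth)
      } else {
        g <- psi$gene_id[1]
        s <- filter(calls[[sid]]$sites, .data$gene_id == g,
                    .data$editing_type == "A->G",
                    .data$depth >= config$min_depth)
        if (nrow(s) == 0) NA_real_ else editing_index(s, min_depth = config$min_depth)
      }
    })
    psi$editing_index <- idx
    ok <- !is.na(psi$psi) & !is.na(psi$editing_index)
    if (sum(ok) >= 3 && stats::sd(psi$psi[ok]) > 0 &&
        stats::sd(psi$editing_index[ok]) > 0) {
      psi_correlation <- psi_vs_editing(psi$psi, psi$editing_index)
    }
  }

  de <- NULL
  if (!is.null(study$expression) && nrow(pairs) > 0) {
    hyper_sites <- pairs %>%
      filter(startsWith(.data$class, "hyper")) %>%
      inner_join(
        bind_rows(purrr::map(calls, ~ .x$sites), .id = "sample_id"),
        by = c("sample_id", "chrom", "pos")
      ) %>%
      select("sample_id", "gene_id", "region", "editing_type")
    de <- purrr::map(c("primary", "metastatic"), function(tt) {
      ids <- samples$sample_id[samples$tissue == tt]
      out <- edit_group_de(study$expression, study$library_sizes,
                           filter(hyper_sites,
                                  .data$sample_id %in% ids),
                           samples = ids)
      if (nrow(out) > 0) mutate(out, group = tt, .before = 1) else NULL
    }) %>% bind_rows()
  }

  structure(list(calls = calls, summary = summary, pairs = pairs, psi = psi,
                 psi_correlation = psi_correlation, de = de,
                 samples = samples),
            class = "editome_result")
}

#' Load a study directory written by [write_simulation()]
#'
#' @param dir Directory containing the study files.
#' @return A list shaped like an `editome_sim` (without truth-derived fields
#'   when those files are absent).
#' @export
load_study <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  need <- function(f) {
    if (!file.exists(fp(f))) abort(paste0("missing study file: ", fp(f)))
    fp(f)
  }
  samples <- readr::read_tsv(need("samples.tsv"), show_col_types = FALSE,
                             progress = FALSE)
  rna <- list(); dna <- list()
  for (sid in samples$sample_id) {
    rna[[sid]] <- read_pileup(need(paste0(sid, ".rna.pileup.tsv")))
    dna[[sid]] <- read_pileup(need(paste0(sid, ".dna.pileup.tsv")))
  }
  opt_tsv <- function(f, ...) {
    if (file.exists(fp(f))) readr::read_tsv(fp(f), show_col_types = FALSE,
                                            progress = FALSE, ...) else NULL
  }
  truth <- opt_tsv("truth.tsv")
  splice_sites <- if (!is.null(truth) && "splice_site" %in% names(truth)) {
    filter(truth, .data$splice_site)
  } else NULL
  list(
    reference = list(
      genome = read_genome_fasta(need("genome.fa")),
      gene_models = read_gene_models(need("genes.gtf")),
      alu = read_intervals(need("alu.bed")),
      repeats = read_intervals(need("repeats.bed"))
    ),
    known_variants = if (file.exists(fp("known_variants.tsv"))) {
      read_known_variants(fp("known_variants.tsv"))
    } else NULL,
    samples = samples, rna = rna, dna = dna,
    junctions = opt_tsv("junctions.tsv"),
    expression = opt_tsv("expression.tsv"),
    library_sizes = opt_tsv("library.tsv"),
    truth = truth, splice_sites = splice_sites
  )
}

#' Write analysis results as TSV tables
#'
#' @param result An `editome_result` from [run_editome()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  sites <- bind_rows(purrr::map(result$calls, ~ .x$sites), .id = "sample_id")
  audit <- bind_rows(purrr::map(result$calls, ~ .x$audit), .id = "sample_id")
  readr::write_tsv(format_site_table(sites), fp("sites.tsv"))
  readr::write_tsv(format_site_table(audit), fp("audit.tsv"))
  readr::write_tsv(result$summary, fp("summary.tsv"))
  if (!is.null(result$pairs) && nrow(result$pairs) > 0) {
    readr::write_tsv(
      select(result$pairs, "patient_id", "comparison", "chrom", "pos",
             "tumor_level", "normal_level", "delta", "fisher_p", "class"),
      fp("pairs.tsv"))
  }
  if (!is.null(result$psi)) {
    psi_out <- mutate(result$psi,
                      psi = if_else(is.na(.data$psi), ".",
                                    format(.data$psi, digits = 6)))
    readr::write_tsv(psi_out, fp("psi.tsv"))
  }
  if (!is.null(result$de) && nrow(result$de) > 0) {
    readr::write_tsv(result$de, fp("expression_de.tsv"))
  }
  invisible(dir)
}

# Order and fill the exported site-table schema; missing token ".".
format_site_table <- function(sites) {
  cols <- c("sample_id", "chrom", "pos", "strand", "ref", "alt",
            "editing_type", "depth", "edit_count", "editing_level", "region",
            "gene_id", "alu", "p_binom", "q_binom", "p_strand", "filter_flag",
            "aa_change")
  for (cc in setdiff(cols, names(sites))) sites[[cc]] <- NA
  sites <- sites[, cols]
  sites$filter_flag <- coalesce(as.character(sites$filter_flag), ".")
  sites
}

#' Recovery of planted editing sites by the caller
#'
#' Compares one sample's calls with the simulator's truth: sensitivity over
#' the callable planted sites (true level in this tissue at or above
#' `min_truth_level`), precision over all planted positions edited in this
#' tissue, and the number of calls at planted DNA-heterozygous positions.
#'
#' @param calls An `editing_calls` object.
#' @param truth Truth tibble from the simulator.
#' @param het_snps Het-SNP tibble from the simulator.
#' @param tissue One of `normal, primary, metastatic`.
#' @param min_truth_level Level above which a planted site counts as
#'   callable (default 0.2).
#' @return One-row tibble `n_callable, n_called, tp, fp, sensitivity,
#'   precision, het_calls`.
#' @export
recovery_stats <- function(calls, truth, het_snps, tissue,
                           min_truth_level = 0.2) {
  lv <- truth[[paste0("level_", tissue)]]
  key <- function(ch, p) paste(ch, p)
  called <- key(calls$sites$chrom, calls$sites$pos)
  edited <- key(truth$chrom, truth$pos)[lv > 0]
  callable <- key(truth$chrom, truth$pos)[lv >= min_truth_level]
  het <- key(het_snps$chrom, het_snps$pos)
  tp <- sum(called %in% edited)
  tibble(
    n_callable = length(callable), n_called = length(called),
    tp = tp, fp = length(called) - tp,
    sensitivity = if (length(callable) > 0) mean(callable %in% called) else NA_real_,
    precision = if (length(called) > 0) tp / length(called) else NA_real_,
    het_calls = sum(called %in% het)
  )
}

#' Recovery of planted hyper-editing sites
#'
#' @param pairs Pair table from [call_pairs()] or [run_editome()] for one
#'   tumor sample.
#' @param truth Truth tibble.
#' @param tissue `primary` or `metastatic`.
#' @return One-row tibble `n_planted, n_recovered, sensitivity`.
#' @export
hyper_recovery_stats <- function(pairs, truth, tissue) {
  flagged <- truth[truth[[paste0("hyper_", tissue)]], ]
  hyper <- filter(pairs, startsWith(.data$class, "hyper"))
  rec <- paste(flagged$chrom, flagged$pos) %in% paste(hyper$chrom, hyper$pos)
  tibble(n_planted = nrow(flagged), n_recovered = sum(rec),
         sensitivity = if (nrow(flagged) > 0) mean(rec) else NA_real_)
}
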