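#' Caller configuration
#'
#' Thresholds of the editing-site filter cascade. Defaults follow the printed
#' rules where they exist (minimal editing level 10%, minimal edit bases 3,
#' minimal depth 4x) and conservative common practice elsewhere; see the
#' methods vignette for the rationale behind each unstated threshold.
#'
#' @param min_editing_level Minimum fraction of edited reads (default 0.10).
#' @param min_edit_bases Minimum edited-read count (default 3).
#' @param min_depth Minimum RNA depth (default 4).
#' @param min_base_quality Minimum mean Phred base quality of the alt base (20).
#' @param min_mapq Minimum mean mapping quality (20).
#' @param binom_fdr BH FDR ceiling for the binomial sequencing-error test (0.05).
#' @param strand_bias_p Two-tailed Fisher strand-bias p below which a
#'   candidate is discarded (0.005).
#' @param end_distance_bp Read-end window for the position-bias rule (6).
#' @param end_fraction Fraction of alt observations within `end_distance_bp`
#'   of a read end that must be exceeded to discard (0.9, strict).
#' @param splice_window_bp Intronic window next to exon boundaries treated as
#'   splice region (4).
#' @param homopolymer_len Minimum identical-base run length for the
#'   homopolymer exclusion (5).
#' @param dna_min_depth Minimum genomic-DNA depth for the homozygosity check (5).
#' @param dna_max_alt_fraction Maximum DNA fraction of the RNA alt base (0.05).
#' @param dna_min_ref_fraction Minimum DNA reference-base fraction (0.90).
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_editing_level = 0.10,
                          min_edit_bases = 3,
                          min_depth = 4,
                          min_base_quality = 20,
                          min_mapq = 20,
                          binom_fdr = 0.05,
                          strand_bias_p = 0.005,
                          end_distance_bp = 6,
                          end_fraction = 0.9,
                          splice_window_bp = 4,
                          homopolymer_len = 5,
                          dna_min_depth = 5,
                          dna_max_alt_fraction = 0.05,
                          dna_min_ref_fraction = 0.90) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_edit_bases >= 1,
            cfg$min_editing_level >= 0, cfg$min_editing_level <= 1,
            cfg$end_fraction >= 0, cfg$end_fraction <= 1,
            cfg$binom_fdr > 0, cfg$binom_fdr <= 1)
  structure(cfg, class = "caller_config")
}

# Per-base totals and reference counts for a pileup.
pileup_base_counts <- function(pileup) {
  totals <- purrr::map(BASES, function(b) {
    pileup[[paste0("count", b, "_fwd")]] + pileup[[paste0("count", b, "_rev")]]
  })
  names(totals) <- BASES
  m <- do.call(cbind, totals)
  depth <- rowSums(m)
  ref_idx <- match(pileup$ref, BASES) # NA for ref N
  ref_count <- ifelse(is.na(ref_idx), 0L, m[cbind(seq_len(nrow(m)), ref_idx)])
  list(m = m, depth = depth, ref_count = ref_count)
}

#' Summarise editing candidates from an RNA pileup
#'
#' Reduces each pileup position to at most one editing candidate: the single
#' majority non-reference base. Positions with no non-reference observation
#' yield no candidate. Multi-allelic positions (two or more non-reference
#' bases each reaching `min_edit_bases`) and positions with reference `N` are
#' emitted flagged (`multiallelic`, `ref_N`) so that they appear in the audit
#' trail but can never be called.
#'
#' @param pileup Pileup tibble (see [read_pileup()]).
#' @param config A [caller_config()].
#' @return Candidate tibble: `chrom, pos, ref, alt, depth, edit_count,
#'   editing_level, alt_bq, mean_mapq, ref_fwd, ref_rev, alt_fwd, alt_rev,
#'   end_distances, candidate_flag`.
#' @export
summarize_candidates <- function(pileup, config = caller_config()) {
  if (nrow(pileup) == 0) return(empty_candidates())
  bc <- pileup_base_counts(pileup)
  m <- bc$m
  ref_idx <- match(pileup$ref, BASES)
  nonref <- m
  nonref[cbind(which(!is.na(ref_idx)), ref_idx[!is.na(ref_idx)])] <- -1L
  # majority non-reference base; ties broken by base order A<C<G<T
  alt_idx <- max.col(nonref, ties.method = "first")
  alt_count <- nonref[cbind(seq_len(nrow(m)), alt_idx)]
  n_strong_alt <- rowSums(nonref >= config$min_edit_bases & nonref > 0)

  keep <- (alt_count > 0 & !is.na(ref_idx)) | (pileup$ref == "N" & bc$depth > 0)
  if (!any(keep)) return(empty_candidates())

  alt <- BASES[alt_idx]
  flag <- rep(NA_character_, nrow(pileup))
  flag[n_strong_alt >= 2] <- "multiallelic"
  flag[pileup$ref == "N"] <- "ref_N"
  alt[pileup$ref == "N"] <- NA_character_
  alt_count[pileup$ref == "N"] <- 0L

  alt_bq <- purrr::map_dbl(which(keep), function(i) {
    if (is.na(alt[i])) return(0)
    pileup[[paste0("meanBQ_", alt[i])]][i]
  })
  strand_count <- function(base, dir) {
    purrr::map_int(which(keep), function(i) {
      b <- if (identical(base, "ref")) pileup$ref[i] else alt[i]
      if (is.na(b) || b == "N") return(0L)
      as.integer(pileup[[paste0("count", b, "_", dir)]][i])
    })
  }
  idx <- which(keep)
  tibble(
    chrom = pileup$chrom[idx],
    pos = pileup$pos[idx],
    ref = pileup$ref[idx],
    alt = alt[idx],
    depth = as.integer(bc$depth[idx]),
    edit_count = as.integer(alt_count[idx]),
    editing_level = ifelse(bc$depth[idx] > 0, alt_count[idx] / bc$depth[idx], 0),
    alt_bq = alt_bq,
    mean_mapq = pileup$mean_mapq[idx],
    ref_fwd = strand_count("ref", "fwd"),
    ref_rev = strand_count("ref", "rev"),
    alt_fwd = strand_count("alt", "fwd"),
    alt_rev = strand_count("alt", "rev"),
    end_distances = pileup$alt_end_distances[idx],
    candidate_flag = flag[idx]
  )
}

empty_candidates <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    depth = integer(), edit_count = integer(), editing_level = numeric(),
    alt_bq = numeric(), mean_mapq = numeric(),
    ref_fwd = integer(), ref_rev = integer(), alt_fwd = integer(), alt_rev = integer(),
    end_distances = character(), candidate_flag = character()
  )
}

#' Basic depth/quality/frequency filter
#'
#' Adds a `flag_basic` column: `NA` where the candidate passes, otherwise the
#' first failing check among `low_depth`, `low_base_quality`, `low_mapq`,
#' `low_level`, `few_edit_bases`.
#'
#' @param candidates Candidate tibble from [summarize_candidates()].
#' @param config A [caller_config()].
#' @return `candidates` with `flag_basic` added.
#' @export
basic_filter <- function(candidates, config = caller_config()) {
  mutate(candidates, flag_basic = case_when(
    .data$depth < config$min_depth ~ "low_depth",
    .data$alt_bq < config$min_base_quality ~ "low_base_quality",
    .data$mean_mapq < config$min_mapq ~ "low_mapq",
    .data$editing_level < config$min_editing_level ~ "low_level",
    .data$edit_count < config$min_edit_bases ~ "few_edit_bases",
    TRUE ~ NA_character_
  ))
}

#' Strand-bias filter
#'
#' Two-tailed Fisher's exact test on the 2x2 table of forward/reverse read
#' counts of the reference and alt base; candidates with
#' `p < config$strand_bias_p` are flagged `strand_bias`.
#'
#' @inheritParams basic_filter
#' @return `candidates` with `p_strand` and `flag_strand` added.
#' @export
strand_bias_filter <- function(candidates, config = caller_config()) {
  p <- if (nrow(candidates) == 0) numeric(0) else {
    fisher_exact_two_tailed(candidates$ref_fwd, candidates$ref_rev,
                            candidates$alt_fwd, candidates$alt_rev)
  }
  mutate(candidates, p_strand = p,
         flag_strand = if_else(.data$p_strand < config$strand_bias_p,
                               "strand_bias", NA_character_))
}

parse_end_distances <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || s == "." || s == "") return(integer(0))
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

#' Read-position bias filter
#'
#' A candidate is discarded when the fraction of its alt observations lying
#' within `end_distance_bp` of a read end strictly exceeds `end_fraction`
#' (edits clustered at read ends are alignment artifacts).
#'
#' @inheritParams basic_filter
#' @return `candidates` with `flag_position` added.
#' @export
position_bias_filter <- function(candidates, config = caller_config()) {
  dists <- parse_end_distances(candidates$end_distances)
  needs <- candidates$edit_count > 0 & !is.na(candidates$alt)
  if (any(needs & lengths(dists) == 0)) {
    abort("missing end distances for candidate(s) with edited reads")
  }
  frac <- purrr::map_dbl(dists, function(d) {
    if (length(d) == 0) return(0)
    mean(d <= config$end_distance_bp)
  })
  mutate(candidates,
         flag_position = if_else(frac > config$end_fraction,
                                 "position_bias", NA_character_))
}

# Is the centre of an 11-mer context inside a run of >= min_run identical bases?
homopolymer_at_center <- function(context, min_run = 5) {
  purrr::map_lgl(context, function(ctx) {
    if (is.na(ctx)) return(FALSE)
    chars <- strsplit(ctx, "", fixed = TRUE)[[1]]
    center <- (length(chars) + 1L) %/% 2L
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(starts <= center & ends >= center)
    r$lengths[i] >= min_run && r$values[i] != "N"
  })
}

# 2*flank+1 context around pos, padded with N at contig edges.
genome_context <- function(genome, chrom, pos, flank = 5L) {
  purrr::map2_chr(chrom, pos, function(ch, p) {
    seqs <- genome[[ch]]
    if (is.null(seqs)) return(NA_character_)
    n <- nchar(seqs)
    lo <- max(1L, p - flank); hi <- min(n, p + flank)
    core <- substr(seqs, lo, hi)
    paste0(strrep("N", lo - (p - flank)), core, strrep("N", (p + flank) - hi))
  })
}

#' Repeat / homopolymer / splice-region exclusion
#'
#' Flags candidates that (a) overlap a supplied simple-repeat interval
#' (`simple_repeat`), (b) sit inside a run of `homopolymer_len` or more
#' identical reference bases within the 11-bp context (`homopolymer`), or
#' (c) are intronic within `splice_window_bp` of an annotated exon boundary
#' (`splice_region`). Exonic positions are never excluded by the splice rule.
#' A context whose centre base is `N` is flagged `ref_N`. Checks whose inputs
#' are not supplied are skipped.
#'
#' @inheritParams basic_filter
#' @param repeats Simple-repeat intervals from [read_intervals()], or `NULL`.
#' @param genome Named character vector of reference sequences, or `NULL`.
#' @param gene_models A `gene_models` tibble, or `NULL`.
#' @return `candidates` with `flag_region` added (and `region`, `gene_strand`,
#'   `gene_id` when `gene_models` is given).
#' @export
region_exclusion_filter <- function(candidates, repeats = NULL, genome = NULL,
                                    gene_models = NULL, config = caller_config()) {
  n <- nrow(candidates)
  in_repeat <- if (is.null(repeats)) rep(FALSE, n) else {
    overlaps_point(repeats, candidates$chrom, candidates$pos)
  }
  ctx <- if (is.null(genome)) rep(NA_character_, n) else {
    genome_context(genome, candidates$chrom, candidates$pos)
  }
  center_n <- !is.na(ctx) & substr(ctx, 6, 6) == "N"
  homopoly <- homopolymer_at_center(ctx, config$homopolymer_len)
  if (!is.null(gene_models)) {
    reg <- classify_region(candidates, gene_models,
                           splice_window_bp = config$splice_window_bp)
    candidates$region <- reg$region
    candidates$gene_id <- reg$gene_id
    candidates$gene_strand <- reg$strand
    splice <- reg$region == "splicing"
  } else {
    splice <- rep(FALSE, n)
  }
  mutate(candidates, flag_region = case_when(
    center_n ~ "ref_N",
    in_repeat ~ "simple_repeat",
    homopoly ~ "homopolymer",
    splice ~ "splice_region",
    TRUE ~ NA_character_
  ))
}

#' Genomic-DNA homozygosity check
#'
#' A candidate passes only when the matched DNA pileup covers the position at
#' `dna_min_depth` or more, carries at most `dna_max_alt_fraction` of the RNA
#' alt base, and at least `dna_min_ref_fraction` reference base. Positions
#' without DNA coverage fail with `no_dna_coverage`; heterozygous genomic
#' variants fail with `dna_not_homozygous`.
#'
#' @inheritParams basic_filter
#' @param dna_pileup DNA pileup tibble at the same coordinates.
#' @return `candidates` with `dna_depth` and `flag_dna` added.
#' @export
gdna_homozygosity_check <- function(candidates, dna_pileup, config = caller_config()) {
  if (nrow(dna_pileup) > 0) {
    bc <- pileup_base_counts(dna_pileup)
    dna <- tibble(
      chrom = dna_pileup$chrom, pos = dna_pileup$pos,
      dna_depth = as.integer(bc$depth),
      dna_A = bc$m[, 1], dna_C = bc$m[, 2], dna_G = bc$m[, 3], dna_T = bc$m[, 4]
    )
  } else {
    dna <- tibble(chrom = character(), pos = integer(), dna_depth = integer(),
                  dna_A = integer(), dna_C = integer(), dna_G = integer(),
                  dna_T = integer())
  }
  out <- left_join(candidates, dna, by = c("chrom", "pos"))
  base_col <- function(base) {
    v <- rep(NA_real_, nrow(out))
    for (b in BASES) {
      sel <- !is.na(base) & base == b
      v[sel] <- out[[paste0("dna_", b)]][sel]
    }
    v
  }
  alt_n <- base_col(out$alt)
  ref_n <- base_col(out$ref)
  out$flag_dna <- case_when(
    is.na(out$dna_depth) | out$dna_depth == 0 ~ "no_dna_coverage",
    out$dna_depth < config$dna_min_depth ~ "low_dna_depth",
    alt_n / out$dna_depth > config$dna_max_alt_fraction |
      ref_n / out$dna_depth < config$dna_min_ref_fraction ~ "dna_not_homozygous",
    TRUE ~ NA_character_
  )
  select(out, -dplyr::any_of(c("dna_A", "dna_C", "dna_G", "dna_T")))
}

#' Bundle the annotation resources used by the caller
#'
#' @param gene_models A `gene_models` tibble or `NULL`.
#' @param alu Alu intervals ([read_intervals()]) or `NULL`.
#' @param repeats Simple-repeat intervals or `NULL`.
#' @param known_variants Tibble `chrom, pos` ([read_known_variants()]) or `NULL`.
#' @param genome Named character vector of reference sequences or `NULL`.
#' @return An `annotation_bundle` list.
#' @export
annotation_bundle <- function(gene_models = NULL, alu = NULL, repeats = NULL,
                              known_variants = NULL, genome = NULL) {
  structure(list(gene_models = gene_models, alu = alu, repeats = repeats,
                 known_variants = known_variants, genome = genome),
            class = "annotation_bundle")
}

#' Call RNA editing sites from matched RNA and DNA pileups
#'
#' Runs the full quality-aware cascade on one sample: candidate
#' summarisation, basic depth/quality/frequency filter, binomial
#' sequencing-error test (BH-adjusted across the sample's candidates, kept at
#' `q <= binom_fdr`), known-variant exclusion, strand-bias and read-position
#' bias filters, simple-repeat/homopolymer/splice-region exclusion, and the
#' genomic-DNA homozygosity check; surviving candidates are annotated
#' (region, gene, strand-collapsed editing type, Alu flag, amino-acid change
#' for CDS sites). Every rejected candidate is retained in an audit table
#' with its first failing flag.
#'
#' @param rna_pileup RNA pileup tibble for the sample.
#' @param dna_pileup Matched DNA pileup tibble.
#' @param annotation An [annotation_bundle()] (all components optional).
#' @param config A [caller_config()].
#' @param sample_id Sample label recorded in the output tables.
#' @return An `editing_calls` object: list with `sites` (called sites
#'   tibble), `audit` (rejected candidates with `filter_flag`), `funnel`
#'   (per-stage rejection counts), `background_rate`, `config`, `sample_id`.
#' @export
call_editing_sites <- function(rna_pileup, dna_pileup,
                               annotation = annotation_bundle(),
                               config = caller_config(),
                               sample_id = "sample") {
  cand <- summarize_candidates(rna_pileup, config)
  if (nrow(cand) == 0) {
    return(new_editing_calls(cand, cand, config, NA_real_, sample_id, annotation))
  }
  cand <- basic_filter(cand, config)

  bg <- estimate_background_mismatch_rate(rna_pileup)
  family <- is.na(cand$candidate_flag)
  cand$p_binom <- NA_real_
  cand$p_binom[family] <- binomial_error_test(cand$edit_count[family],
                                              cand$depth[family], bg)
  cand$q_binom <- NA_real_
  cand$q_binom[family] <- bh_adjust(cand$p_binom[family])
  cand$flag_binom <- if_else(!is.na(cand$q_binom) & cand$q_binom > config$binom_fdr,
                             "binomial_error", NA_character_)

  kv <- annotation$known_variants
  cand$flag_known <- if (!is.null(kv) && nrow(kv) > 0) {
    if_else(paste(cand$chrom, cand$pos) %in% paste(kv$chrom, kv$pos),
            "known_variant", NA_character_)
  } else NA_character_

  cand <- strand_bias_filter(cand, config)
  cand <- position_bias_filter(cand, config)
  cand <- region_exclusion_filter(cand, repeats = annotation$repeats,
                                  genome = annotation$genome,
                                  gene_models = annotation$gene_models,
                                  config = config)
  cand <- gdna_homozygosity_check(cand, dna_pileup, config)

  cand$flag_final <- if_else(
    cand$editing_level < config$min_editing_level |
      cand$edit_count < config$min_edit_bases |
      cand$depth < config$min_depth,
    "final_threshold", NA_character_)

  cand$filter_flag <- coalesce(cand$candidate_flag, cand$flag_basic,
                               cand$flag_binom, cand$flag_known,
                               cand$flag_strand, cand$flag_position,
                               cand$flag_region, cand$flag_dna, cand$flag_final)
  new_editing_calls(cand[is.na(cand$filter_flag), ],
                    cand[!is.na(cand$filter_flag), ],
                    config, bg, sample_id, annotation)
}

new_editing_calls <- function(passed, rejected, config, background_rate,
                              sample_id, annotation) {
  sites <- annotate_sites(passed, annotation)
  sites$filter_flag <- rep(".", nrow(sites))
  audit <- annotate_sites(rejected, annotation)
  audit$filter_flag <- if (nrow(rejected)) rejected$filter_flag else character(0)
  funnel <- bind_rows(
    tibble(stage = "candidates", n = nrow(passed) + nrow(rejected)),
    if (nrow(rejected)) dplyr::count(rejected, stage = .data$filter_flag, name = "n"),
    tibble(stage = "called", n = nrow(passed))
  )
  structure(list(sites = sites, audit = audit, funnel = funnel,
                 background_rate = background_rate, config = config,
                 sample_id = sample_id),
            class = "editing_calls")
}

#' @export
print.editing_calls <- function(x, ...) {
  cat("<editing_calls> sample:", x$sample_id, "\n")
  cat("  candidates:", sum(x$funnel$n[x$funnel$stage == "candidates"]),
      " called:", nrow(x$sites),
      " background mismatch rate:", signif(x$background_rate, 3), "\n")
  invisible(x)
}
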