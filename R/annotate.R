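#' Classify genomic positions against gene models
#'
#' Assigns each position one region label with the precedence
#' `CDS > splicing > UTR5 > UTR3 > ncRNA > intronic > intergenic` when
#' transcripts overlap; `splicing` means intronic within `splice_window_bp`
#' of an annotated exon boundary, and `ncRNA` means exonic in a transcript
#' without CDS. The gene and strand come from the transcript granting the
#' winning label; intergenic positions get gene `"."`.
#'
#' @param positions Tibble with columns `chrom`, `pos` (1-based).
#' @param gene_models A `gene_models` tibble ([read_gene_models()]).
#' @param splice_window_bp Intronic bp next to an exon treated as splice
#'   region (default 4).
#' @return Tibble `region, gene_id, transcript_id, strand`, one row per input
#'   position, in input order.
#' @export
classify_region <- function(positions, gene_models, splice_window_bp = 4) {
  n <- nrow(positions)
  out <- tibble(region = rep("intergenic", n), gene_id = rep(".", n),
                transcript_id = rep(NA_character_, n),
                strand = rep(NA_character_, n))
  if (is.null(gene_models) || nrow(gene_models) == 0 || n == 0) return(out)
  idx <- region_index(gene_models, splice_window_bp)
  q <- tibble(chrom = positions$chrom, pos = as.integer(positions$pos),
              .row = seq_len(n))
  hits <- inner_join(q, idx,
                     by = join_by("chrom", "pos" >= "start", "pos" <= "end"),
                     relationship = "many-to-many") %>%
    group_by(.data$.row) %>%
    slice_min(.data$priority, n = 1, with_ties = FALSE) %>%
    ungroup()
  out$region[hits$.row] <- hits$region
  out$gene_id[hits$.row] <- hits$gene_id
  out$transcript_id[hits$.row] <- hits$transcript_id
  out$strand[hits$.row] <- hits$strand
  out
}

# One interval row per (region label, transcript); priority implements the
# cross-transcript precedence.
region_index <- function(models, splice_window_bp = 4) {
  models <- as_tibble(models)
  base_cols <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  coding_tx <- unique(models$transcript_id[models$feature == "CDS"])

  cds <- filter(models, .data$feature == "CDS") %>%
    select(dplyr::all_of(base_cols)) %>% mutate(region = "CDS", priority = 1L)
  utr5 <- filter(models, .data$feature == "UTR5") %>%
    select(dplyr::all_of(base_cols)) %>% mutate(region = "UTR5", priority = 3L)
  utr3 <- filter(models, .data$feature == "UTR3") %>%
    select(dplyr::all_of(base_cols)) %>% mutate(region = "UTR3", priority = 4L)
  ncx <- filter(models, .data$feature == "exon",
                !.data$transcript_id %in% coding_tx) %>%
    select(dplyr::all_of(base_cols)) %>% mutate(region = "ncRNA", priority = 5L)

  introns <- filter(models, .data$feature == "exon") %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    summarise(istart = list(head(.data$end, -1) + 1L),
              iend = list(.data$start[-1] - 1L), .groups = "drop") %>%
    tidyr::unnest(c("istart", "iend")) %>%
    rename(start = "istart", end = "iend") %>%
    filter(.data$end >= .data$start)

  splice <- bind_rows(
    mutate(introns, end = pmin(.data$start + splice_window_bp - 1L, .data$end)),
    mutate(introns, start = pmax(.data$end - splice_window_bp + 1L, .data$start))
  ) %>% mutate(region = "splicing", priority = 2L)
  intronic <- mutate(introns, region = "intronic", priority = 6L)

  bind_rows(cds, splice, utr5, utr3, ncx, intronic) %>%
    arrange(.data$priority, .data$transcript_id, .data$start)
}

#' Collapse a genomic mismatch onto the transcript sense
#'
#' Editing chemistry acts on the transcribed strand, so mismatches are
#' reported in transcript sense: on `-` strand genes both alleles are
#' complemented (genomic `T->C` becomes `A->G`). When no gene strand is
#' available (intergenic sites) the strand is inferred so that the reference
#' allele lies in `{A, C}`, and the site is flagged as inferred.
#'
#' @param ref,alt Genomic reference and alternate bases.
#' @param strand Gene strand `"+"`/`"-"`, or `NA` to infer.
#' @return Tibble `editing_type, strand, strand_inferred`, one row per input.
#' @export
collapse_editing_type <- function(ref, alt, strand = NA_character_) {
  n <- max(length(ref), length(alt), length(strand))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n); strand <- rep_len(strand, n)
  if (any(!is.na(ref) & !is.na(alt) & ref == alt)) {
    abort("collapse_editing_type: ref and alt must differ")
  }
  inferred <- is.na(strand)
  strand[inferred] <- if_else(ref[inferred] %in% c("A", "C"), "+", "-")
  flip <- strand == "-"
  tref <- if_else(flip, comp_base(ref), ref)
  talt <- if_else(flip, comp_base(alt), alt)
  tibble(editing_type = paste0(tref, "->", talt), strand = strand,
         strand_inferred = inferred)
}

#' Is a position inside an Alu element?
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param alu_intervals Alu intervals from [read_intervals()] (BED coords).
#' @return Logical vector.
#' @export
annotate_alu <- function(chrom, pos, alu_intervals) {
  if (is.null(alu_intervals)) return(rep(FALSE, length(pos)))
  overlaps_point(alu_intervals, chrom, pos)
}

#' Amino-acid consequence of an editing event in a CDS
#'
#' Given the coding sequence in transcript orientation, the 1-based CDS
#' position of the edit and the alternate base (transcript sense), returns
#' the cDNA change (`c.A1099G`), the protein change (`p.S367G`) and whether
#' the substitution is synonymous. The codon index is `ceiling(c / 3)`;
#' translation uses the standard genetic code.
#'
#' @param cds_sequence Coding sequence (multiple of 3, transcript sense).
#' @param cds_pos 1-based position of the edited base within the CDS.
#' @param alt_base Alternate base in transcript sense.
#' @return A list with `cdna_change`, `protein_change`, `synonymous`.
#' @export
amino_acid_change <- function(cds_sequence, cds_pos, alt_base) {
  len <- nchar(cds_sequence)
  if (len %% 3 != 0) abort("CDS length is not divisible by 3")
  if (cds_pos < 1 || cds_pos > len) abort("cds_pos outside the CDS")
  ref_base <- substr(cds_sequence, cds_pos, cds_pos)
  if (ref_base == alt_base) abort("alt base equals the CDS reference base")
  codon_idx <- ceiling(cds_pos / 3)
  codon_start <- (codon_idx - 1L) * 3L + 1L
  codon <- substr(cds_sequence, codon_start, codon_start + 2L)
  offset <- ((cds_pos - 1L) %% 3L) + 1L
  mut_codon <- codon
  substr(mut_codon, offset, offset) <- alt_base
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[mut_codon])
  list(
    cdna_change = paste0("c.", ref_base, cds_pos, alt_base),
    protein_change = paste0("p.", aa_ref, codon_idx, aa_alt),
    synonymous = identical(aa_ref, aa_alt)
  )
}

#' Coding sequence of a transcript, in transcript orientation
#'
#' @param gene_models A `gene_models` tibble.
#' @param genome Named character vector of reference sequences.
#' @param transcript_id Transcript to extract.
#' @return A character scalar (empty for non-coding transcripts).
#' @export
cds_sequence <- function(gene_models, genome, transcript_id) {
  seg <- filter(as_tibble(gene_models), .data$transcript_id == !!transcript_id,
                .data$feature == "CDS") %>% arrange(.data$start)
  if (nrow(seg) == 0) return("")
  seq <- paste0(purrr::map2_chr(seg$start, seg$end,
                                ~ substr(genome[[seg$chrom[1]]], .x, .y)),
                collapse = "")
  if (seg$strand[1] == "-") seq <- revcomp(seq)
  seq
}

revcomp <- function(x) {
  paste(rev(comp_base(strsplit(x, "", fixed = TRUE)[[1]])), collapse = "")
}

# 1-based CDS coordinate (transcript sense) of a genomic position, NA if the
# position is not inside the transcript's CDS.
cds_coordinate <- function(gene_models, transcript_id, chrom, pos) {
  seg <- filter(as_tibble(gene_models), .data$transcript_id == !!transcript_id,
                .data$feature == "CDS", .data$chrom == !!chrom) %>%
    arrange(.data$start)
  if (nrow(seg) == 0) return(NA_integer_)
  hit <- which(pos >= seg$start & pos <= seg$end)
  if (length(hit) == 0) return(NA_integer_)
  lens <- seg$end - seg$start + 1L
  if (seg$strand[1] == "+") {
    before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0L
    as.integer(before + (pos - seg$start[hit]) + 1L)
  } else {
    after <- if (hit < nrow(seg)) sum(lens[seq(hit + 1L, nrow(seg))]) else 0L
    as.integer(after + (seg$end[hit] - pos) + 1L)
  }
}

#' Keep sites passing an external splicing / deleteriousness score threshold
#'
#' Applies the inclusive printed thresholds to user-supplied score tables:
#' `rule = "spidex"` keeps sites with splicing Z-score `|Z| >= 2`;
#' `rule = "cadd"` keeps sites with PHRED-scaled score `>= 20`. Sites without
#' a score record are dropped and their number reported via a message.
#'
#' @param sites Sites tibble with `chrom, pos, ref, alt` (genomic alleles).
#' @param scores Score table from [read_score_table()].
#' @param rule `"spidex"` or `"cadd"`.
#' @return The subset of `sites` passing the threshold.
#' @export
filter_by_external_score <- function(sites, scores, rule = c("spidex", "cadd")) {
  rule <- rlang::arg_match(rule)
  wanted_type <- c(spidex = "spidex_z", cadd = "cadd_phred")[[rule]]
  scores <- filter(scores, .data$score_type == wanted_type)
  joined <- left_join(sites, select(scores, "chrom", "pos", "ref", "alt", "score"),
                      by = c("chrom", "pos", "ref", "alt"))
  missing_n <- sum(is.na(joined$score))
  if (missing_n > 0) {
    inform(paste0(missing_n, " site(s) without a ", wanted_type,
                  " record were dropped"))
  }
  keep <- if (rule == "spidex") {
    !is.na(joined$score) & abs(joined$score) >= 2
  } else {
    !is.na(joined$score) & joined$score >= 20
  }
  sites[keep, , drop = FALSE]
}

# Fill annotation columns on (passed or rejected) candidates and order the
# site-table schema.
annotate_sites <- function(cand, annotation = annotation_bundle()) {
  n <- nrow(cand)
  if (!"region" %in% names(cand)) {
    if (n > 0 && !is.null(annotation$gene_models)) {
      reg <- classify_region(cand, annotation$gene_models)
      cand$region <- reg$region
      cand$gene_id <- reg$gene_id
      cand$transcript_id <- reg$transcript_id
      cand$gene_strand <- reg$strand
    } else {
      cand$region <- rep(NA_character_, n)
      cand$gene_id <- rep(".", n)
      cand$transcript_id <- rep(NA_character_, n)
      cand$gene_strand <- rep(NA_character_, n)
    }
  }
  if (!"transcript_id" %in% names(cand)) cand$transcript_id <- rep(NA_character_, n)
  ok <- !is.na(cand$alt)
  cand$editing_type <- NA_character_
  cand$strand <- NA_character_
  cand$strand_inferred <- NA
  if (any(ok)) {
    coll <- collapse_editing_type(cand$ref[ok], cand$alt[ok],
                                  cand$gene_strand[ok])
    cand$editing_type[ok] <- coll$editing_type
    cand$strand[ok] <- coll$strand
    cand$strand_inferred[ok] <- coll$strand_inferred
  }
  cand$alu <- if (!is.null(annotation$alu) && n > 0) {
    annotate_alu(cand$chrom, cand$pos, annotation$alu)
  } else rep(NA, n)
  cand$aa_change <- rep(NA_character_, n)
  if (n > 0 && !is.null(annotation$gene_models) && !is.null(annotation$genome)) {
    invalid <- attr(annotation$gene_models, "cds_invalid") %||% character(0)
    cds_rows <- which(cand$region == "CDS" & !is.na(cand$transcript_id) &
                        !cand$transcript_id %in% invalid & !is.na(cand$alt))
    for (i in cds_rows) {
      cpos <- cds_coordinate(annotation$gene_models, cand$transcript_id[i],
                             cand$chrom[i], cand$pos[i])
      if (is.na(cpos)) next
      seq <- cds_sequence(annotation$gene_models, annotation$genome,
                          cand$transcript_id[i])
      talt <- if (cand$gene_strand[i] == "-") comp_base(cand$alt[i]) else cand$alt[i]
      ref_at <- substr(seq, cpos, cpos)
      if (identical(ref_at, talt)) next
      ch <- amino_acid_change(seq, cpos, talt)
      cand$aa_change[i] <- paste0(ch$cdna_change, "/", ch$protein_change)
    }
  }
  for (col in c("p_binom", "q_binom", "p_strand")) {
    if (!col %in% names(cand)) cand[[col]] <- rep(NA_real_, n)
  }
  select(cand, dplyr::any_of(c(
    "chrom", "pos", "strand", "ref", "alt", "editing_type", "depth",
    "edit_count", "editing_level", "region", "gene_id", "alu",
    "p_binom", "q_binom", "p_strand", "aa_change", "strand_inferred",
    "transcript_id"
  )))
}
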