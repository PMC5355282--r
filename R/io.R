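PILEUP_COLS <- c(
  "chrom", "pos", "ref",
  "countA_fwd", "countA_rev", "countC_fwd", "countC_rev",
  "countG_fwd", "countG_rev", "countT_fwd", "countT_rev",
  "meanBQ_A", "meanBQ_C", "meanBQ_G", "meanBQ_T",
  "mean_mapq", "alt_end_distances"
)

#' Read a per-site pileup table
#'
#' The pileup is a tab-separated table with a single `#`-prefixed header line
#' and one row per genomic position: strand-split base counts, per-base mean
#' base qualities (Phred; 0 where the base was not observed), mean mapping
#' quality, and the distances of each majority-non-reference observation to
#' its nearest read end (comma-separated integers, `.` when there are none).
#' Coordinates are 1-based.
#'
#' @param path Path to a pileup TSV.
#' @return A tibble with one row per position and columns
#'   `chrom, pos, ref, count{A,C,G,T}_{fwd,rev}, meanBQ_{A,C,G,T},
#'   mean_mapq, alt_end_distances`.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort(paste0("empty pileup file (no header): ", path))
  if (!startsWith(header, "#")) {
    abort(paste0("pileup header must begin with '#': ", path))
  }
  n_fields <- utils::count.fields(path, sep = "\t", quote = "",
                                  comment.char = "")
  bad_width <- which(n_fields[-1] != length(PILEUP_COLS))[1] # [-1]: the header
  if (!is.na(bad_width)) {
    abort(paste0("malformed pileup line ", bad_width + 1L, " in ", path,
                 ": expected ", length(PILEUP_COLS), " columns, found ",
                 n_fields[bad_width + 1L]))
  }
  tbl <- readr::read_tsv(
    path,
    skip = 1L,
    col_names = PILEUP_COLS,
    col_types = readr::cols(
      chrom = "c", pos = "d", ref = "c",
      countA_fwd = "d", countA_rev = "d", countC_fwd = "d", countC_rev = "d",
      countG_fwd = "d", countG_rev = "d", countT_fwd = "d", countT_rev = "d",
      meanBQ_A = "d", meanBQ_C = "d", meanBQ_G = "d", meanBQ_T = "d",
      mean_mapq = "d", alt_end_distances = "c"
    ),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed pileup line ", probs$row[1] + 1L, " in ", path, ": ", probs$expected[1]
    ))
  }
  validate_pileup(tbl, path)
}

validate_pileup <- function(tbl, path = "<pileup>") {
  count_cols <- paste0("count", rep(BASES, each = 2), c("_fwd", "_rev"))
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort(paste0("malformed pileup line ", idx[1] + 1L, " in ", path, ": ", msg))
    }
  }
  for (cc in count_cols) {
    bad(tbl[[cc]] < 0 | tbl[[cc]] != floor(tbl[[cc]]), paste0("negative or non-integer ", cc))
  }
  bad(tbl$pos < 1 | tbl$pos != floor(tbl$pos), "pos must be a positive integer")
  bad(!tbl$ref %in% c(BASES, "N"), "unknown reference base")
  tbl$pos <- as.integer(tbl$pos)
  tbl
}

#' Write a pileup table
#'
#' @param pileup Pileup tibble (see [read_pileup()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  stopifnot(identical(names(pileup), PILEUP_COLS))
  header <- paste0("#", paste(PILEUP_COLS, collapse = "\t"))
  body <- do.call(paste, c(lapply(pileup, as.character), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' BED3+ input, 0-based half-open coordinates. Intervals are kept in BED
#' coordinates; point queries against 1-based site positions go through
#' [overlaps_point()], which performs the conversion (a BED interval
#' `[s, e)` covers 1-based position `p` iff `s + 1 <= p <= e`).
#'
#' @param path Path to a BED file.
#' @param expected_label Optional label; when given, the 4th column is checked
#'   to match it on every row.
#' @return A tibble `chrom, start, end, label` sorted by chrom and start.
#' @export
read_intervals <- function(path, expected_label = NULL) {
  tbl <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    comment = "#", progress = FALSE, show_col_types = FALSE
  )
  if (nrow(tbl) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(), label = character()))
  }
  if (ncol(tbl) < 3) abort(paste0("BED file needs >= 3 columns: ", path))
  out <- tibble(
    chrom = tbl[[1]],
    start = suppressWarnings(as.integer(tbl[[2]])),
    end = suppressWarnings(as.integer(tbl[[3]])),
    label = if (ncol(tbl) >= 4) tbl[[4]] else NA_character_
  )
  if (any(is.na(out$start)) || any(is.na(out$end))) {
    abort(paste0("non-integer BED coordinates in ", path))
  }
  if (any(out$end <= out$start)) {
    abort(paste0("BED interval with end <= start at line ",
                 which(out$end <= out$start)[1], " in ", path))
  }
  if (!is.null(expected_label) && !all(out$label == expected_label)) {
    abort(paste0("BED labels do not all equal '", expected_label, "' in ", path))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Does a 1-based position overlap any interval?
#'
#' @param intervals Interval tibble from [read_intervals()] (BED, 0-based
#'   half-open).
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Logical vector.
#' @export
overlaps_point <- function(intervals, chrom, pos) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(pos)))
  q <- tibble(chrom = chrom, pos = as.integer(pos), .row = seq_along(pos))
  hit <- inner_join(
    q, intervals,
    by = join_by("chrom", "pos" >= "start", "pos" <= "end"),
    relationship = "many-to-many"
  ) %>%
    # BED start is 0-based: pos >= start + 1 <=> pos > start
    filter(.data$pos > .data$start) %>%
    pull(".row")
  seq_along(pos) %in% hit
}

#' Write intervals as BED
#' @param intervals Interval tibble (`chrom, start, end, label`), BED coords.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  lines <- paste(intervals$chrom, intervals$start, intervals$end,
                 if_else(is.na(intervals$label), ".", intervals$label),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read stranded gene models from GTF
#'
#' Consumes a GTF subset with feature types `exon`, `CDS`, `five_prime_utr`
#' and `three_prime_utr` (other rows are ignored); `gene_id` and
#' `transcript_id` attributes are required. Coordinates are 1-based inclusive
#' per the GTF standard. CDS phase is ignored; reading frame is recomputed
#' from CDS segment order and strand. Transcripts whose total CDS length is
#' not divisible by 3 are flagged with a warning and refused by
#' [amino_acid_change()]-related helpers.
#'
#' @param path Path to a GTF file.
#' @return A `gene_models` tibble with columns
#'   `gene_id, transcript_id, chrom, strand, feature, start, end` where
#'   `feature` is one of `exon, CDS, UTR5, UTR3`. The attribute
#'   `cds_invalid` lists transcripts with out-of-frame CDS.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- as.character(gr$type) %in% c("exon", "CDS", "five_prime_utr", "three_prime_utr")
  gr <- gr[keep]
  tbl <- tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = dplyr::recode(as.character(gr$type),
                            five_prime_utr = "UTR5", three_prime_utr = "UTR3"),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  if (any(is.na(tbl$gene_id)) || any(is.na(tbl$transcript_id))) {
    abort(paste0("GTF rows missing gene_id/transcript_id in ", path))
  }
  new_gene_models(tbl)
}

#' Construct a gene-models object from a feature tibble
#'
#' @param tbl Tibble with columns
#'   `gene_id, transcript_id, chrom, strand, feature, start, end`
#'   (1-based inclusive; feature in `exon, CDS, UTR5, UTR3`).
#' @return A validated `gene_models` tibble.
#' @export
new_gene_models <- function(tbl) {
  tbl <- arrange(as_tibble(tbl), .data$transcript_id, .data$start) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  stopifnot(all(tbl$feature %in% c("exon", "CDS", "UTR5", "UTR3")),
            all(tbl$strand %in% c("+", "-")))
  # exons of one transcript must be sorted and non-overlapping
  ex <- filter(tbl, .data$feature == "exon") %>% group_by(.data$transcript_id)
  overlap <- summarise(ex, bad = any(.data$start[-1] <= head(.data$end, -1)), .groups = "drop")
  if (any(overlap$bad)) {
    abort(paste0("overlapping exons in transcript ",
                 overlap$transcript_id[which(overlap$bad)[1]]))
  }
  cds_len <- filter(tbl, .data$feature == "CDS") %>%
    group_by(.data$transcript_id) %>%
    summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop")
  invalid <- cds_len$transcript_id[cds_len$len %% 3L != 0L]
  if (length(invalid) > 0) {
    warn(paste0("CDS length not divisible by 3 for transcript(s): ",
                paste(invalid, collapse = ", "),
                "; amino-acid operations will refuse them"))
  }
  structure(tbl, cds_invalid = invalid, class = c("gene_models", class(tbl)))
}

#' Write gene models as GTF
#' @param models A `gene_models` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  feat <- dplyr::recode(models$feature, UTR5 = "five_prime_utr", UTR3 = "three_prime_utr")
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   models$gene_id, models$transcript_id)
  lines <- paste(models$chrom, "editome", feat, models$start, models$end,
                 ".", models$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a known-variant exclusion list
#'
#' Accepts a VCF (only CHROM and POS are consumed) or a two-column TSV of
#' `chrom, pos` (1-based). Used to drop known genomic variants (e.g. dbSNP
#' entries) from editing candidates.
#'
#' @param path Path to a `.vcf` file or a 2-column TSV.
#' @return A tibble `chrom, pos` of positions to exclude.
#' @export
read_known_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    vcf <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) { # single-variant VCFs come back as a bare vector
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    }
    if (is.null(fix) || nrow(fix) == 0) {
      return(tibble(chrom = character(), pos = integer()))
    }
    pos <- suppressWarnings(as.integer(fix[, "POS"]))
    if (any(is.na(pos))) abort(paste0("non-integer POS in VCF ", path))
    return(distinct(tibble(chrom = as.character(fix[, "CHROM"]), pos = pos)))
  }
  tbl <- readr::read_tsv(path, col_names = c("chrom", "pos"),
                         col_types = "cc", comment = "#",
                         progress = FALSE, show_col_types = FALSE)
  pos <- suppressWarnings(as.integer(tbl$pos))
  if (nrow(tbl) > 0 && any(is.na(pos))) {
    abort(paste0("non-integer position at line ", which(is.na(pos))[1], " in ", path))
  }
  distinct(tibble(chrom = tbl$chrom, pos = pos))
}

#' Read an external per-variant score table
#'
#' TSV with columns `chrom, pos, ref, alt, score, score_type` where
#' `score_type` is `spidex_z` (splicing-impact Z-score) or `cadd_phred`
#' (PHRED-scaled deleteriousness score). Duplicate `(chrom, pos, ref, alt,
#' score_type)` keys keep the last record, with a warning.
#'
#' @param path Path to the score TSV.
#' @return A tibble `chrom, pos, ref, alt, score, score_type`.
#' @export
read_score_table <- function(path) {
  tbl <- readr::read_tsv(
    path, col_names = c("chrom", "pos", "ref", "alt", "score", "score_type"),
    col_types = readr::cols(chrom = "c", pos = "i", ref = "c", alt = "c",
                            score = "d", score_type = "c"),
    comment = "#", progress = FALSE, show_col_types = FALSE
  )
  bad <- !tbl$score_type %in% c("spidex_z", "cadd_phred")
  if (any(bad)) {
    abort(paste0("unknown score_type '", tbl$score_type[which(bad)[1]],
                 "' at line ", which(bad)[1], " in ", path))
  }
  key <- paste(tbl$chrom, tbl$pos, tbl$ref, tbl$alt, tbl$score_type)
  if (anyDuplicated(key)) {
    warn(paste0(sum(duplicated(key)), " duplicate score key(s) in ", path,
                "; keeping the last record for each"))
    tbl <- tbl[!duplicated(key, fromLast = TRUE), ]
  }
  tbl
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences (names are chromosome names).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write a genome as FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
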