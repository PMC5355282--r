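#' Simulation configuration
#'
#' Study conditions of the synthetic cohort: trios of matched
#' normal/primary/metastatic samples whose editome has the reported
#' structure — A->G dominating the editing types (91.3%), most sites inside
#' Alu elements (94.5%), an intron-dominated region distribution (71.5%
#' intronic, 10.5% 3'UTR, 9.7% intergenic), homozygous-reference DNA at
#' edited positions, elevated editing in tumors, and planted heterozygous
#' DNA SNPs as negative controls. Distributional choices (Beta editing
#' levels, negative-binomial depths) are documented in the methods vignette.
#'
#' @param n_patients Number of patient trios (default 4).
#' @param n_genes Number of genes in the synthetic reference (default 20).
#' @param chroms Chromosome names.
#' @param coding_fraction Fraction of genes given a CDS (default 0.8).
#' @param exon_count_range,exon_length_range,intron_length_range,
#'   intergenic_gap_range Gene-structure ranges in bp.
#' @param alu_length Length of placed Alu elements (bp).
#' @param alu_site_fraction Overall fraction of editing sites inside Alus.
#' @param a_to_g_fraction Fraction of sites with transcript-sense A->G type.
#' @param region_mix Named site fractions over
#'   `intronic, UTR3, intergenic, UTR5, CDS, ncRNA` (sums to 1).
#' @param n_sites Planted editing-site positions shared by the cohort.
#' @param n_background Covered but unedited positions per sample.
#' @param n_hyper_per_tumor Hyper-editing sites planted per tumor tissue
#'   (half tumor-specific, half differential).
#' @param level_shape1,level_shape2 Beta parameters of normal-tissue editing
#'   levels (default Beta(2, 8)).
#' @param tumor_level_shift Mean elevation of tumor levels on the hyper
#'   subset; realised through `hyper_specific_level_range` and
#'   `hyper_delta_range`.
#' @param hyper_specific_level_range Tumor level range of tumor-specific
#'   sites (normal level is 0).
#' @param hyper_delta_range Editing-level difference range of differential
#'   hyper sites.
#' @param rna_depth_mean,rna_depth_size RNA depth negative binomial.
#' @param dna_depth_mean,dna_depth_size DNA depth negative binomial.
#' @param seq_error Per-base sequencing error rate of the RNA reads.
#' @param n_dna_het_snps Planted heterozygous DNA SNPs (negative controls).
#' @param n_position_artifacts Positions with edits clustered at read ends
#'   (exercise the position-bias filter).
#' @param n_strand_artifacts Positions with all edited reads on one strand
#'   (exercise the strand-bias filter).
#' @param read_length Read length used for end-distance simulation.
#' @param junction_depth Total junction reads per sample for the PSI gene.
#' @param psi_base,psi_slope,psi_noise_sd Latent PSI model:
#'   `clamp(psi_base + psi_slope * editing_index + noise)`.
#' @param splice_window_bp Intronic bp next to exons left unplanted.
#' @param expr_cv Coefficient of variation of expression counts.
#' @param expr_fold_shift Fold change planted in edit+ samples.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 4,
                       n_genes = 20,
                       chroms = c("chr1", "chr2"),
                       coding_fraction = 0.8,
                       exon_count_range = c(3, 8),
                       exon_length_range = c(120, 400),
                       intron_length_range = c(300, 1500),
                       intergenic_gap_range = c(3000, 8000),
                       alu_length = 300,
                       alu_site_fraction = 0.945,
                       a_to_g_fraction = 0.913,
                       region_mix = c(intronic = 0.715, UTR3 = 0.105,
                                      intergenic = 0.097, UTR5 = 0.083 / 3,
                                      CDS = 0.083 / 3, ncRNA = 0.083 / 3),
                       n_sites = 500,
                       n_background = 3000,
                       n_hyper_per_tumor = 120,
                       level_shape1 = 2, level_shape2 = 8,
                       tumor_level_shift = 0.15,
                       hyper_specific_level_range = c(0.25, 0.8),
                       hyper_delta_range = c(0.35, 0.65),
                       rna_depth_mean = 30, rna_depth_size = 10,
                       dna_depth_mean = 35, dna_depth_size = 10,
                       seq_error = 0.005,
                       n_dna_het_snps = 10,
                       n_position_artifacts = 20,
                       n_strand_artifacts = 10,
                       read_length = 100,
                       junction_depth = 80,
                       psi_base = 0.3, psi_slope = 1, psi_noise_sd = 0.05,
                       splice_window_bp = 4,
                       expr_cv = 0.2,
                       expr_fold_shift = 2) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(cfg$region_mix) - 1) < 1e-9,
            cfg$alu_site_fraction >= 0, cfg$alu_site_fraction <= 1,
            cfg$a_to_g_fraction >= 0, cfg$a_to_g_fraction <= 1,
            cfg$rna_depth_mean > 0, cfg$dna_depth_mean > 0)
  structure(cfg, class = "sim_config")
}

TISSUES <- c("normal", "primary", "metastatic")

# non-reference base indices for each reference base index
OTHER_BASES <- t(vapply(1:4, function(r) setdiff(1:4, r), integer(3)))

#' Generate a synthetic reference: genome, gene models, Alu and repeat tracks
#'
#' Genes have 3-8 exons with UTRs and in-frame CDS; Alu elements are placed
#' inside introns, UTRs, non-coding exons and intergenic space (never CDS);
#' a few simple-repeat intervals are placed in intergenic space. The returned
#' `strata` table partitions the plantable genome by region class and Alu
#' status and is consumed by [plant_truth()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; same seed, same reference.
#' @return List: `genome` (named character vector), `gene_models`,
#'   `alu`, `repeats` (interval tibbles, BED coords), `strata`.
#' @export
generate_reference <- function(config = sim_config(), seed = 1) {
  withr::with_seed(seed, build_reference(config))
}

build_reference <- function(cfg) {
  margin <- 600L
  chrom_of_gene <- rep(cfg$chroms, length.out = max(cfg$n_genes, 1))
  # fixed number of non-coding genes (scattered) so the ncRNA stratum exists
  n_nc <- round(cfg$n_genes * (1 - cfg$coding_fraction))
  nc_genes <- if (n_nc > 0) sample(cfg$n_genes, n_nc) else integer(0)
  feats <- list()
  spans <- list()
  cursor <- setNames(rep(margin, length(cfg$chroms)), cfg$chroms)
  if (cfg$n_genes > 0) {
    for (g in seq_len(cfg$n_genes)) {
      ch <- chrom_of_gene[g]
      gap <- sample(cfg$intergenic_gap_range[1]:cfg$intergenic_gap_range[2], 1)
      gstart <- cursor[[ch]] + gap
      strand <- sample(c("+", "-"), 1)
      coding <- !g %in% nc_genes
      n_e <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1)
      elen <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2], n_e,
                     replace = TRUE)
      if (!coding) {
        # one exon large enough to host an Alu element
        elen[1] <- max(elen[1], cfg$alu_length + 40L)
      }
      # first/last exon in transcript order; UTRs long enough to host Alus
      tf <- if (strand == "+") 1L else n_e
      tl <- if (strand == "+") n_e else 1L
      u5 <- sample(250:500, 1)
      u3 <- sample(350:800, 1)
      if (coding) {
        elen[tf] <- elen[tf] + u5
        elen[tl] <- elen[tl] + u3
      }
      ilen <- if (n_e > 1) {
        sample(cfg$intron_length_range[1]:cfg$intron_length_range[2], n_e - 1,
               replace = TRUE)
      } else integer(0)
      estart <- gstart + cumsum(c(0L, head(elen, -1) + ilen))
      eend <- estart + elen - 1L
      gid <- sprintf("GENE%03d", g)
      tid <- sprintf("TX%03d", g)
      rows <- tibble(gene_id = gid, transcript_id = tid, chrom = ch,
                     strand = strand, feature = "exon",
                     start = estart, end = eend)
      if (coding) {
        cds <- rows[, c("start", "end")]
        if (strand == "+") {
          cds$start[tf] <- cds$start[tf] + u5
          cds$end[tl] <- cds$end[tl] - u3
        } else {
          cds$end[tf] <- cds$end[tf] - u5
          cds$start[tl] <- cds$start[tl] + u3
        }
        total <- sum(cds$end - cds$start + 1L)
        rem <- total %% 3L
        if (rem > 0) { # trim the 3' end into the 3' UTR to stay in frame
          if (strand == "+") cds$end[tl] <- cds$end[tl] - rem
          else cds$start[tl] <- cds$start[tl] + rem
        }
        utr5 <- if (strand == "+") {
          tibble(start = rows$start[tf], end = cds$start[tf] - 1L)
        } else {
          tibble(start = cds$end[tf] + 1L, end = rows$end[tf])
        }
        utr3 <- if (strand == "+") {
          tibble(start = cds$end[tl] + 1L, end = rows$end[tl])
        } else {
          tibble(start = rows$start[tl], end = cds$start[tl] - 1L)
        }
        rows <- bind_rows(
          rows,
          tibble(gene_id = gid, transcript_id = tid, chrom = ch,
                 strand = strand, feature = "CDS",
                 start = cds$start, end = cds$end),
          tibble(gene_id = gid, transcript_id = tid, chrom = ch,
                 strand = strand, feature = "UTR5",
                 start = utr5$start, end = utr5$end),
          tibble(gene_id = gid, transcript_id = tid, chrom = ch,
                 strand = strand, feature = "UTR3",
                 start = utr3$start, end = utr3$end)
        )
      }
      feats[[g]] <- rows
      spans[[g]] <- tibble(chrom = ch, start = gstart, end = max(eend))
      cursor[[ch]] <- max(eend)
    }
  }
  chrom_len <- setNames(as.integer(cursor + margin), cfg$chroms)
  genome <- vapply(cfg$chroms, function(ch) {
    paste(sample(BASES, chrom_len[[ch]], replace = TRUE), collapse = "")
  }, character(1))

  if (length(feats) == 0) {
    models <- new_gene_models(tibble(gene_id = character(),
                                     transcript_id = character(),
                                     chrom = character(), strand = character(),
                                     feature = character(), start = integer(),
                                     end = integer()))
    empty_iv <- tibble(chrom = character(), start = integer(),
                       end = integer(), label = character())
    return(list(genome = genome, gene_models = models, alu = empty_iv,
                repeats = empty_iv, strata = tibble(
                  chrom = character(), start = integer(), end = integer(),
                  class = character(), alu = logical(), strand = character())))
  }
  models <- suppressWarnings(new_gene_models(bind_rows(feats)))
  spans <- bind_rows(spans)

  segs <- reference_segments(models, spans, chrom_len, cfg)
  # simple repeats: intergenic, away from everything else
  rep_iv <- place_in_segments(segs[segs$class == "intergenic", ], n = 4,
                              len = 150L)
  segs <- subtract_intervals(segs, rep_iv)
  # Alu elements: one per eligible non-CDS segment with probability 0.7;
  # every non-CDS class keeps at least one Alu so all planting strata exist
  eligible <- segs$class != "CDS" &
    (segs$end - segs$start + 1L) >= cfg$alu_length + 20L
  take <- eligible & stats::runif(nrow(segs)) < 0.7
  for (cl in setdiff(unique(segs$class), "CDS")) {
    in_cl <- which(eligible & segs$class == cl)
    if (length(in_cl) > 0 && !any(take[in_cl])) {
      widest <- in_cl[which.max(segs$end[in_cl] - segs$start[in_cl])]
      take[widest] <- TRUE
    }
  }
  alu_rows <- list()
  out_segs <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    seg_len <- s$end - s$start + 1L
    if (take[i]) {
      a_start <- s$start + sample.int(seg_len - cfg$alu_length - 10L, 1)
      a_end <- a_start + cfg$alu_length - 1L
      alu_rows[[length(alu_rows) + 1]] <-
        tibble(chrom = s$chrom, start = a_start, end = a_end,
               class = s$class, strand = s$strand)
      out_segs[[length(out_segs) + 1]] <- bind_rows(
        mutate(s, end = a_start - 1L, alu = FALSE),
        tibble(chrom = s$chrom, start = a_start, end = a_end, class = s$class,
               strand = s$strand, alu = TRUE),
        mutate(s, start = a_end + 1L, alu = FALSE)
      ) %>% filter(.data$end >= .data$start)
    } else {
      out_segs[[length(out_segs) + 1]] <- mutate(s, alu = FALSE)
    }
  }
  strata <- bind_rows(out_segs)
  alu_tbl <- bind_rows(alu_rows)
  alu_bed <- if (nrow(alu_tbl) > 0) {
    tibble(chrom = alu_tbl$chrom, start = alu_tbl$start - 1L,
           end = alu_tbl$end, label = "Alu")
  } else tibble(chrom = character(), start = integer(), end = integer(),
                label = character())
  rep_bed <- if (nrow(rep_iv) > 0) {
    tibble(chrom = rep_iv$chrom, start = rep_iv$start - 1L, end = rep_iv$end,
           label = "simple_repeat")
  } else tibble(chrom = character(), start = integer(), end = integer(),
                label = character())
  list(genome = genome, gene_models = models, alu = alu_bed,
       repeats = rep_bed, strata = strata)
}

# Plantable 1-based segments by region class.
reference_segments <- function(models, spans, chrom_len, cfg) {
  w <- cfg$splice_window_bp
  tx_cds <- unique(models$transcript_id[models$feature == "CDS"])
  pick <- function(f) filter(as_tibble(models), .data$feature == f) %>%
    select("chrom", "start", "end", "strand")
  cds <- mutate(pick("CDS"), class = "CDS")
  utr5 <- mutate(pick("UTR5"), class = "UTR5")
  utr3 <- mutate(pick("UTR3"), class = "UTR3")
  ncx <- filter(as_tibble(models), .data$feature == "exon",
                !.data$transcript_id %in% tx_cds) %>%
    select("chrom", "start", "end", "strand") %>% mutate(class = "ncRNA")
  introns <- filter(as_tibble(models), .data$feature == "exon") %>%
    group_by(.data$transcript_id, .data$chrom, .data$strand) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(istart = list(head(.data$end, -1) + 1L + w),
              iend = list(.data$start[-1] - 1L - w), .groups = "drop") %>%
    tidyr::unnest(c("istart", "iend")) %>%
    rename(start = "istart", end = "iend") %>%
    filter(.data$end >= .data$start) %>%
    select("chrom", "start", "end", "strand") %>% mutate(class = "intronic")
  inter <- purrr::map(names(chrom_len), function(ch) {
    sp <- filter(spans, .data$chrom == ch) %>% arrange(.data$start)
    starts <- c(150L, sp$end + 150L)
    ends <- c(sp$start - 150L, chrom_len[[ch]] - 150L)
    tibble(chrom = ch, start = starts, end = ends, strand = NA_character_,
           class = "intergenic") %>% filter(.data$end >= .data$start)
  }) %>% bind_rows()
  bind_rows(cds, utr5, utr3, ncx, introns, inter) %>%
    filter(.data$end >= .data$start)
}

# n intervals of length len placed inside random segments, non-overlapping by
# construction (one per chosen segment).
place_in_segments <- function(segs, n, len) {
  segs <- filter(segs, .data$end - .data$start + 1L >= len + 10L)
  if (nrow(segs) == 0 || n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  rows <- sample.int(nrow(segs), min(n, nrow(segs)))
  purrr::map(rows, function(i) {
    s <- segs[i, ]
    a <- s$start + sample.int(s$end - s$start + 2L - len, 1) - 1L
    tibble(chrom = s$chrom, start = a, end = a + len - 1L)
  }) %>% bind_rows()
}

# Remove (1-based) intervals from segments, splitting as needed.
subtract_intervals <- function(segs, iv) {
  if (nrow(iv) == 0) return(segs)
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    cuts <- filter(iv, .data$chrom == s$chrom, .data$start <= s$end,
                   .data$end >= s$start) %>% arrange(.data$start)
    if (nrow(cuts) == 0) { out[[length(out) + 1]] <- s; next }
    cur <- s$start
    for (j in seq_len(nrow(cuts))) {
      if (cuts$start[j] - 1L >= cur) {
        out[[length(out) + 1]] <- mutate(s, start = cur, end = cuts$start[j] - 1L)
      }
      cur <- max(cur, cuts$end[j] + 1L)
    }
    if (cur <= s$end) out[[length(out) + 1]] <- mutate(s, start = cur)
  }
  bind_rows(out)
}
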