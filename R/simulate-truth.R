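#' Plant ground-truth editing sites, hyper subsets and DNA-het controls
#'
#' Places editing sites on the reference respecting the configured region mix
#' and Alu fraction, draws transcript-sense editing types (A->G dominant),
#' assigns per-tissue true editing levels (Beta-distributed in normal tissue)
#' and designates the hyper subsets: per tumor tissue, half tumor-specific
#' sites (normal level 0, elevated tumor level) and half differential sites
#' (level difference above 0.2). Three splice-affecting sites are planted in
#' the 5' UTR of a designated PSI gene with editing elevated in tumors.
#' Heterozygous DNA SNPs are planted at separate positions as negative
#' controls. The reference genome is modified so that every planted position
#' carries the required reference base; positions inside homopolymer runs,
#' splice windows or simple repeats are avoided.
#'
#' @param reference Output of [generate_reference()] (its `genome` is
#'   updated and returned alongside).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `truth` (one row per planted site with per-tissue levels and
#'   hyper flags), `het_snps`, `psi_gene`, and the updated `reference`.
#' @export
plant_truth <- function(reference, config = sim_config(), seed = 1) {
  withr::with_seed(seed, build_truth(reference, config))
}

build_truth <- function(reference, cfg) {
  strata <- reference$strata
  genome <- reference$genome
  used <- new.env(parent = emptyenv())
  for (ch in names(genome)) assign(ch, integer(0), envir = used)

  p_cds <- unname(cfg$region_mix["CDS"])
  p_alu_noncds <- min(1, cfg$alu_site_fraction / (1 - p_cds))

  draw_site_position <- function(class, alu) {
    pool <- strata[strata$class == class & strata$alu == alu, ]
    if (nrow(pool) == 0 && alu) { # degrade to non-Alu rather than fail
      alu <- FALSE
      pool <- strata[strata$class == class & !strata$alu, ]
    }
    if (nrow(pool) == 0) abort(paste0("no plantable segment for class ", class,
                                      " alu=", alu))
    wt <- pool$end - pool$start + 1
    for (i in 1:400) {
      row <- pool[sample.int(nrow(pool), 1, prob = wt), ]
      pos <- row$start + sample.int(row$end - row$start + 1L, 1) - 1L
      prev <- get(row$chrom, envir = used)
      if (length(prev) == 0 || min(abs(prev - pos)) >= 11L) {
        assign(row$chrom, c(prev, pos), envir = used)
        return(list(chrom = row$chrom, pos = pos,
                    strand = row$strand %||% NA_character_, alu = alu))
      }
    }
    abort("could not place a site; reference too small for the site count")
  }

  set_base <- function(chrom, pos, base) {
    s <- genome[[chrom]]
    substr(s, pos, pos) <- base
    genome[[chrom]] <<- s
  }

  draw_type <- function(intergenic) {
    ty <- if (stats::runif(1) < cfg$a_to_g_fraction) "A->G" else {
      sample(setdiff(EDITING_TYPES, "A->G"), 1)
    }
    if (intergenic) {
      # keep the transcript-sense ref in {A, C} so strand inference is exact
      r <- substr(ty, 1, 1)
      if (r %in% c("G", "T")) {
        ty <- paste0(comp_base(r), "->", comp_base(substr(ty, 4, 4)))
      }
    }
    ty
  }

  # splice-affecting sites of the PSI gene (none in an editing-free study)
  n_extra <- if (cfg$n_sites > 0) 3L else 0L
  classes <- sample(names(cfg$region_mix), cfg$n_sites, replace = TRUE,
                    prob = cfg$region_mix)
  # PSI gene: the coding gene with the longest 5' UTR
  u5 <- filter(as_tibble(reference$gene_models), .data$feature == "UTR5") %>%
    mutate(len = .data$end - .data$start + 1L) %>%
    arrange(dplyr::desc(.data$len))
  psi_gene <- if (nrow(u5) > 0) u5$gene_id[1] else NA_character_

  rows <- vector("list", cfg$n_sites + n_extra)
  for (i in seq_len(cfg$n_sites + n_extra)) {
    is_splice_site <- i > cfg$n_sites
    if (is_splice_site) {
      class <- "UTR5"
      alu <- FALSE
      repeat {
        pool <- strata[strata$class == "UTR5", ]
        seg <- filter(pool, .data$chrom == u5$chrom[1],
                      .data$start >= u5$start[1], .data$end <= u5$end[1])
        if (nrow(seg) == 0) abort("PSI gene 5' UTR has no plantable segment")
        wt <- seg$end - seg$start + 1
        row <- seg[sample.int(nrow(seg), 1, prob = wt), ]
        pos <- row$start + sample.int(row$end - row$start + 1L, 1) - 1L
        prev <- get(row$chrom, envir = used)
        if (length(prev) == 0 || min(abs(prev - pos)) >= 11L) {
          assign(row$chrom, c(prev, pos), envir = used)
          loc <- list(chrom = row$chrom, pos = pos, strand = row$strand)
          alu <- any(strata$alu & strata$chrom == row$chrom &
                       strata$start <= pos & strata$end >= pos)
          break
        }
      }
      type <- "A->G"
    } else {
      class <- classes[i]
      alu <- if (class == "CDS") FALSE else stats::runif(1) < p_alu_noncds
      loc <- draw_site_position(class, alu)
      alu <- loc$alu
      type <- draw_type(class == "intergenic")
    }
    strand <- loc$strand
    if (is.na(strand)) strand <- "+"
    tref <- substr(type, 1, 1)
    talt <- substr(type, 4, 4)
    gref <- if (strand == "-") comp_base(tref) else tref
    galt <- if (strand == "-") comp_base(talt) else talt
    old <- substr(genome[[loc$chrom]], loc$pos, loc$pos)
    set_base(loc$chrom, loc$pos, gref)
    # avoid homopolymer contexts (the caller would exclude the site)
    ctx <- genome_context(genome, loc$chrom, loc$pos)
    if (homopolymer_at_center(ctx, 5)) {
      # break the run by flipping a neighbour two bases away
      nb_pos <- loc$pos + 2L
      nb <- substr(genome[[loc$chrom]], nb_pos, nb_pos)
      set_base(loc$chrom, nb_pos, setdiff(BASES, c(nb, gref))[1])
    }
    rows[[i]] <- tibble(chrom = loc$chrom, pos = loc$pos, strand = strand,
                        ref = gref, alt = galt, editing_type = type,
                        region = class, alu = alu,
                        splice_site = is_splice_site)
  }
  truth <- bind_rows(rows)
  if (nrow(truth) == 0) {
    truth <- tibble(chrom = character(), pos = integer(), strand = character(),
                    ref = character(), alt = character(),
                    editing_type = character(), region = character(),
                    alu = logical(), splice_site = logical())
  }
  reg <- classify_region(truth, reference$gene_models,
                         splice_window_bp = cfg$splice_window_bp)
  truth$gene_id <- reg$gene_id

  n <- nrow(truth)
  truth$level_normal <- rbeta(n, cfg$level_shape1, cfg$level_shape2)
  truth$level_primary <- truth$level_normal
  truth$level_metastatic <- truth$level_normal

  n_hyper <- min(cfg$n_hyper_per_tumor, cfg$n_sites %/% 2)
  ordinary <- which(!truth$splice_site)
  hyper_idx <- sample(ordinary, min(2 * n_hyper, length(ordinary)))
  assign_hyper <- function(truth, idx, tissue) {
    lv <- paste0("level_", tissue)
    n_spec <- length(idx) %/% 2
    spec <- idx[seq_len(n_spec)]
    diff <- setdiff(idx, spec)
    truth$level_normal[spec] <- 0
    truth$level_primary[spec] <- 0
    truth$level_metastatic[spec] <- 0
    truth[[lv]][spec] <- runif(length(spec), cfg$hyper_specific_level_range[1],
                               cfg$hyper_specific_level_range[2])
    truth[[lv]][diff] <- pmin(truth$level_normal[diff] +
                                runif(length(diff), cfg$hyper_delta_range[1],
                                      cfg$hyper_delta_range[2]), 0.95)
    truth
  }
  half <- length(hyper_idx) %/% 2
  truth <- assign_hyper(truth, hyper_idx[seq_len(half)], "primary")
  truth <- assign_hyper(truth, hyper_idx[seq(half + 1, length(hyper_idx))],
                        "metastatic")
  # splice-affecting sites: edited everywhere, elevated in tumors
  sp <- which(truth$splice_site)
  truth$level_normal[sp] <- 0.10
  truth$level_primary[sp] <- 0.55
  truth$level_metastatic[sp] <- 0.40

  hyper_rule <- function(tl, nl) (nl == 0 & tl >= 0.1) | (tl - nl > 0.2)
  truth$hyper_primary <- hyper_rule(truth$level_primary, truth$level_normal)
  truth$hyper_metastatic <- hyper_rule(truth$level_metastatic, truth$level_normal)

  het <- vector("list", cfg$n_dna_het_snps)
  for (i in seq_len(cfg$n_dna_het_snps)) {
    loc <- draw_site_position(sample(names(cfg$region_mix), 1,
                                     prob = cfg$region_mix), FALSE)
    gref <- substr(genome[[loc$chrom]], loc$pos, loc$pos)
    if (gref == "N") { gref <- "A"; set_base(loc$chrom, loc$pos, "A") }
    het[[i]] <- tibble(chrom = loc$chrom, pos = loc$pos, ref = gref,
                       alt = sample(setdiff(BASES, gref), 1))
  }
  het_snps <- if (cfg$n_dna_het_snps > 0) bind_rows(het) else {
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character())
  }
  reference$genome <- genome
  list(truth = truth, het_snps = het_snps, psi_gene = psi_gene,
       reference = reference)
}
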