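#' Simulate matched DNA and RNA pileups for every sample of the cohort
#'
#' For each patient trio (normal, primary, metastatic) and each position —
#' planted editing sites, background covered positions, read-end and
#' strand-bias artifact positions, and DNA-het SNPs — RNA depth is drawn from
#' a negative binomial, edited reads from `Binomial(depth, true level)`, and
#' uniform sequencing errors are sprinkled over the three non-reference
#' bases. Strand splits are binomial; read-end distances are uniform over
#' `[0, read_length / 2]` for genuine edits and concentrated within 6 bp at
#' artifact positions. DNA pileups are homozygous reference except at the
#' planted heterozygous SNPs.
#'
#' @param planted Output of [plant_truth()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `samples` (tibble `sample_id, patient, tissue`), `rna` and
#'   `dna` (named lists of pileup tibbles), `positions` (the per-position
#'   role/level table).
#' @export
simulate_pileups <- function(planted, config = sim_config(), seed = 1) {
  withr::with_seed(seed, build_pileups(planted, config))
}

build_pileups <- function(planted, cfg) {
  ref <- planted$reference
  truth <- planted$truth
  positions <- sim_position_table(planted, cfg)
  samples <- tidyr::expand_grid(patient = sprintf("P%02d", seq_len(cfg$n_patients)),
                                tissue = TISSUES) %>%
    mutate(sample_id = paste0(.data$patient, "_", .data$tissue))
  rna <- list(); dna <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rna[[sid]] <- sim_one_pileup(positions, samples$tissue[i], cfg, kind = "rna")
    dna[[sid]] <- sim_one_pileup(positions, samples$tissue[i], cfg, kind = "dna")
  }
  list(samples = samples, rna = rna, dna = dna, positions = positions)
}

# One row per simulated position with its role and per-tissue true levels.
sim_position_table <- function(planted, cfg) {
  truth <- planted$truth
  ref <- planted$reference
  genome <- ref$genome
  site_rows <- tibble(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    role = "site",
    level_normal = truth$level_normal,
    level_primary = truth$level_primary,
    level_metastatic = truth$level_metastatic
  )
  het_rows <- if (nrow(planted$het_snps) > 0) {
    tibble(chrom = planted$het_snps$chrom, pos = planted$het_snps$pos,
           ref = planted$het_snps$ref, alt = planted$het_snps$alt,
           role = "het", level_normal = 0.5, level_primary = 0.5,
           level_metastatic = 0.5)
  } else NULL

  taken <- paste(site_rows$chrom, site_rows$pos)
  if (!is.null(het_rows)) taken <- c(taken, paste(het_rows$chrom, het_rows$pos))
  draw_positions <- function(n) {
    if (n == 0) return(NULL)
    strata <- ref$strata
    wt <- strata$end - strata$start + 1
    rows <- sample.int(nrow(strata), 3 * n, replace = TRUE, prob = wt)
    pos <- strata$start[rows] +
      floor(runif(3 * n) * (strata$end[rows] - strata$start[rows] + 1))
    tb <- tibble(chrom = strata$chrom[rows], pos = as.integer(pos)) %>%
      distinct() %>%
      filter(!paste(.data$chrom, .data$pos) %in% taken) %>%
      head(n)
    taken <<- c(taken, paste(tb$chrom, tb$pos))
    tb$ref <- purrr::map2_chr(tb$chrom, tb$pos, ~ substr(genome[[.x]], .y, .y))
    tb
  }
  bg <- draw_positions(cfg$n_background)
  bg_rows <- if (!is.null(bg) && nrow(bg) > 0) {
    mutate(bg, alt = NA_character_, role = "background", level_normal = 0,
           level_primary = 0, level_metastatic = 0)
  } else NULL
  art_alt <- function(tb) purrr::map_chr(tb$ref, ~ sample(setdiff(BASES, .x), 1))
  pa <- draw_positions(cfg$n_position_artifacts)
  pa_rows <- if (!is.null(pa) && nrow(pa) > 0) {
    mutate(pa, alt = art_alt(pa), role = "artifact_position",
           level_normal = 0.2, level_primary = 0.2, level_metastatic = 0.2)
  } else NULL
  sa <- draw_positions(cfg$n_strand_artifacts)
  sa_rows <- if (!is.null(sa) && nrow(sa) > 0) {
    mutate(sa, alt = art_alt(sa), role = "artifact_strand",
           level_normal = 0.4, level_primary = 0.4, level_metastatic = 0.4)
  } else NULL
  bind_rows(site_rows, het_rows, bg_rows, pa_rows, sa_rows) %>%
    filter(.data$ref %in% BASES) %>%
    arrange(.data$chrom, .data$pos)
}

sim_one_pileup <- function(positions, tissue, cfg, kind = c("rna", "dna")) {
  kind <- rlang::arg_match(kind)
  n <- nrow(positions)
  ref_idx <- match(positions$ref, BASES)
  alt_idx <- match(positions$alt, BASES)
  if (kind == "rna") {
    depth <- rnbinom(n, mu = cfg$rna_depth_mean, size = cfg$rna_depth_size)
    level <- positions[[paste0("level_", tissue)]]
    err <- cfg$seq_error
  } else {
    depth <- rnbinom(n, mu = cfg$dna_depth_mean, size = cfg$dna_depth_size)
    level <- if_else(positions$role == "het", 0.5, 0)
    err <- 0
  }
  k <- rbinom(n, depth, if_else(is.na(alt_idx), 0, level))
  rem <- depth - k
  e <- if (err > 0) rbinom(n, rem, err) else integer(n)
  e1 <- rbinom(n, e, 1 / 3)
  e2 <- rbinom(n, e - e1, 1 / 2)
  e3 <- e - e1 - e2
  counts <- matrix(0L, nrow = n, ncol = 4)
  idx <- seq_len(n)
  counts[cbind(idx, ref_idx)] <- rem - e
  add_at <- function(cols, val) {
    cells <- cbind(idx, cols)
    counts[cells] <<- counts[cells] + val
  }
  ok_alt <- !is.na(alt_idx)
  if (any(ok_alt)) {
    cells <- cbind(idx[ok_alt], alt_idx[ok_alt])
    counts[cells] <- counts[cells] + k[ok_alt]
  }
  add_at(OTHER_BASES[cbind(ref_idx, 1L)], e1)
  add_at(OTHER_BASES[cbind(ref_idx, 2L)], e2)
  add_at(OTHER_BASES[cbind(ref_idx, 3L)], e3)

  fwd <- matrix(0L, nrow = n, ncol = 4)
  for (b in 1:4) fwd[, b] <- rbinom(n, counts[, b], 0.5)
  onesided <- positions$role == "artifact_strand" & ok_alt
  if (any(onesided)) {
    cells <- cbind(idx[onesided], alt_idx[onesided])
    fwd[cells] <- counts[cells]
  }
  rev <- counts - fwd

  bq <- matrix(round(rnorm(n * 4, 35, 2), 1), nrow = n)
  bq[counts == 0] <- 0
  mapq <- pmax(round(rnorm(n, 50, 3), 1), 0)

  # majority non-reference base drives the end-distance list
  nonref <- counts
  nonref[cbind(idx, ref_idx)] <- -1L
  maj <- max.col(nonref, ties.method = "first")
  m <- nonref[cbind(idx, maj)]
  m[m < 0] <- 0L
  dist_str <- rep(".", n)
  if (sum(m) > 0) {
    max_d <- if_else(positions$role == "artifact_position",
                     cfg$end_distance_artifact %||% 6,
                     floor(cfg$read_length / 2))
    all_d <- floor(runif(sum(m)) * (rep(max_d, m) + 1))
    spl <- split(all_d, rep(idx, m))
    dist_str[as.integer(names(spl))] <-
      vapply(spl, function(x) paste(x, collapse = ","), character(1))
  }

  tibble(
    chrom = positions$chrom, pos = positions$pos, ref = positions$ref,
    countA_fwd = fwd[, 1], countA_rev = rev[, 1],
    countC_fwd = fwd[, 2], countC_rev = rev[, 2],
    countG_fwd = fwd[, 3], countG_rev = rev[, 3],
    countT_fwd = fwd[, 4], countT_rev = rev[, 4],
    meanBQ_A = bq[, 1], meanBQ_C = bq[, 2], meanBQ_G = bq[, 3],
    meanBQ_T = bq[, 4],
    mean_mapq = mapq, alt_end_distances = dist_str
  )
}

#' Simulate junction counts coupled to the editing index
#'
#' Per sample, a latent percent-spliced-in value
#' `clamp(psi_base + psi_slope * editing_index + noise)` is converted to
#' expected junction proportions `p_J2 = p_J4 = psi / (1 + psi)`,
#' `p_J3 = (1 - psi) / (1 + psi)` and the three counts are drawn from a
#' multinomial at the configured junction depth.
#'
#' @param editing_indices Tibble `sample_id, editing_index` (NA indices use
#'   the baseline PSI).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param gene_id Gene label for the junction table.
#' @return Tibble `sample_id, gene_id, J2, J3, J4, psi_latent`.
#' @export
simulate_junctions <- function(editing_indices, config = sim_config(), seed = 1,
                               gene_id = "PSI_GENE") {
  withr::with_seed(seed, {
    idx <- coalesce(editing_indices$editing_index, 0)
    psi <- pmin(pmax(config$psi_base + config$psi_slope * idx +
                       rnorm(length(idx), 0, config$psi_noise_sd), 0.02), 0.98)
    counts <- vapply(psi, function(ps) {
      p <- c(ps, 1 - ps, ps) / (1 + ps)
      as.integer(rmultinom(1, config$junction_depth, p))
    }, integer(3))
    tibble(sample_id = editing_indices$sample_id, gene_id = gene_id,
           J2 = counts[1, ], J3 = counts[2, ], J4 = counts[3, ],
           psi_latent = psi)
  })
}

#' Simulate a gene-expression table with planted edit+ shifts
#'
#' Gene counts are negative binomial around lognormal gene means (coefficient
#' of variation `expr_cv`); designated genes are shifted `expr_fold_shift`-fold
#' in edit+ samples. A per-sample edit+/- assignment may be supplied (e.g.
#' derived from hyper-editing truth); otherwise one is drawn with at least
#' `min_group` samples per group. Optionally, one designated gene's
#' expression is coupled to a per-sample editing level
#' (`mu * 2^(couple_beta * level)`), emulating expression modulation by UTR
#' editing.
#'
#' @param samples Character vector of sample ids.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_genes Number of genes in the table.
#' @param n_shift_genes Number of genes with the planted edit+ shift.
#' @param assignment Named logical vector (`TRUE` = edit+) or `NULL` to draw.
#' @param min_group Minimum group size when drawing the assignment.
#' @param couple_levels Optional named per-sample editing levels for the
#'   coupled gene.
#' @param couple_beta Log2 slope of the coupling (default -2).
#' @return List: `expression` (`sample_id, gene_id, unique_read_count,
#'   exon_length_bp`), `library_sizes` (`sample_id, total_mapped_reads`),
#'   `assignment`, `shift_genes`, `coupled_gene`.
#' @export
simulate_expression <- function(samples, config = sim_config(), seed = 1,
                                n_genes = 50, n_shift_genes = 5,
                                assignment = NULL, min_group = 4,
                                couple_levels = NULL, couple_beta = -2) {
  withr::with_seed(seed, {
    ns <- length(samples)
    if (is.null(assignment)) {
      min_group <- max(1L, min(min_group, ns %/% 2L))
      repeat {
        assignment <- setNames(runif(ns) < 0.5, samples)
        if (sum(assignment) >= min_group && sum(!assignment) >= min_group) break
      }
    }
    genes <- sprintf("EG%03d", seq_len(n_genes))
    shift_genes <- head(genes, n_shift_genes)
    coupled_gene <- if (!is.null(couple_levels)) tail(genes, 1) else NA_character_
    exon_len <- sample(800:5000, n_genes, replace = TRUE)
    base_mu <- stats::rlnorm(n_genes, meanlog = log(500), sdlog = 1)
    size <- 1 / config$expr_cv^2
    rows <- purrr::map(seq_along(samples), function(si) {
      mu <- base_mu
      if (isTRUE(assignment[[samples[si]]])) {
        mu[genes %in% shift_genes] <- mu[genes %in% shift_genes] *
          config$expr_fold_shift
      }
      if (!is.null(couple_levels)) {
        mu[genes == coupled_gene] <- mu[genes == coupled_gene] *
          2^(couple_beta * couple_levels[[samples[si]]])
      }
      tibble(sample_id = samples[si], gene_id = genes,
             unique_read_count = rnbinom(n_genes, mu = mu, size = size),
             exon_length_bp = exon_len)
    })
    expression <- bind_rows(rows)
    lib <- expression %>% group_by(.data$sample_id) %>%
      summarise(total_mapped_reads = sum(.data$unique_read_count),
                .groups = "drop")
    list(expression = expression, library_sizes = lib,
         assignment = assignment, shift_genes = shift_genes,
         coupled_gene = coupled_gene)
  })
}

#' Simulate the full synthetic study
#'
#' Convenience wrapper running [generate_reference()], [plant_truth()],
#' [simulate_pileups()], [simulate_junctions()] (coupled to the per-sample
#' editing index at the planted splice-affecting sites), and
#' [simulate_expression()], plus synthetic external score tables, all
#' deterministically from one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `editome_sim` list with `reference`, `truth`, `het_snps`,
#'   `known_variants`, `samples`, `rna`, `dna`, `junctions`, `expression`,
#'   `scores`, `psi_gene`, `splice_sites`, `config`, `seed`.
#' @export
simulate_editome <- function(config = sim_config(), seed = 1) {
  reference <- generate_reference(config, seed)
  planted <- plant_truth(reference, config, seed + 1L)
  pile <- simulate_pileups(planted, config, seed + 2L)

  splice_sites <- filter(planted$truth, .data$splice_site)
  idx <- purrr::map_dbl(pile$samples$sample_id, function(sid) {
    editing_index_at(pile$rna[[sid]], splice_sites)
  })
  junctions <- simulate_junctions(
    tibble(sample_id = pile$samples$sample_id, editing_index = idx),
    config, seed + 3L, gene_id = planted$psi_gene %||% "PSI_GENE")

  expr <- simulate_expression(pile$samples$sample_id, config, seed + 4L)

  scores <- withr::with_seed(seed + 5L, {
    tr <- planted$truth
    z <- rnorm(nrow(tr), 0, 1.5)
    z[tr$splice_site] <- (2 + abs(rnorm(sum(tr$splice_site)))) *
      sign(rnorm(sum(tr$splice_site)) + 0.5)
    cadd <- runif(nrow(tr), 0, 35)
    bind_rows(
      tibble(chrom = tr$chrom, pos = tr$pos, ref = tr$ref, alt = tr$alt,
             score = round(z, 3), score_type = "spidex_z"),
      tibble(chrom = tr$chrom, pos = tr$pos, ref = tr$ref, alt = tr$alt,
             score = round(cadd, 2), score_type = "cadd_phred")
    )
  })
  # half the het SNPs are "known" germline variants (the exclusion list);
  # the rest must be caught by the gDNA homozygosity check alone
  known <- head(planted$het_snps, nrow(planted$het_snps) %/% 2) %>%
    select(dplyr::any_of(c("chrom", "pos")))

  structure(list(
    reference = planted$reference, truth = planted$truth,
    het_snps = planted$het_snps, known_variants = known,
    samples = pile$samples, rna = pile$rna, dna = pile$dna,
    positions = pile$positions, junctions = junctions,
    expression = expr$expression, library_sizes = expr$library_sizes,
    expr_assignment = expr$assignment, expr_shift_genes = expr$shift_genes,
    scores = scores, psi_gene = planted$psi_gene,
    splice_sites = splice_sites, config = config, seed = seed
  ), class = "editome_sim")
}

# Coverage-weighted editing index of a pileup at given truth sites (edited
# reads of the planted alt base / total reads; depth >= 4).
editing_index_at <- function(pileup, sites, min_depth = 4) {
  ac <- pileup_allele_counts(pileup, sites$chrom, sites$pos)
  ai <- match(sites$alt, BASES)
  edit <- ac$m[cbind(seq_len(nrow(sites)), ai)]
  keep <- ac$depth >= min_depth
  if (!any(keep)) return(NA_real_)
  sum(edit[keep]) / sum(ac$depth[keep])
}

#' Write a simulated study to disk
#'
#' Emits every file format the pipeline consumes: per-sample RNA/DNA pileup
#' TSVs, reference FASTA, gene-model GTF, Alu and simple-repeat BEDs, the
#' known-variant list, external score table, junction and expression tables,
#' the sample sheet, and the ground-truth site table.
#'
#' @param sim An `editome_sim` from [simulate_editome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_genome_fasta(sim$reference$genome, fp("genome.fa"))
  write_gtf(sim$reference$gene_models, fp("genes.gtf"))
  write_bed(sim$reference$alu, fp("alu.bed"))
  write_bed(sim$reference$repeats, fp("repeats.bed"))
  readr::write_tsv(sim$known_variants, fp("known_variants.tsv"),
                   col_names = FALSE)
  readr::write_tsv(sim$scores, fp("scores.tsv"), col_names = FALSE)
  readr::write_tsv(sim$truth, fp("truth.tsv"))
  readr::write_tsv(sim$het_snps, fp("het_snps.tsv"))
  readr::write_tsv(sim$samples, fp("samples.tsv"))
  readr::write_tsv(sim$junctions, fp("junctions.tsv"))
  readr::write_tsv(sim$expression, fp("expression.tsv"))
  readr::write_tsv(sim$library_sizes, fp("library.tsv"))
  for (sid in sim$samples$sample_id) {
    write_pileup(sim$rna[[sid]], fp(paste0(sid, ".rna.pileup.tsv")))
    write_pileup(sim$dna[[sid]], fp(paste0(sid, ".dna.pileup.tsv")))
  }
  invisible(dir)
}
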