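test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 1, n_sites = 40, n_background = 200,
                    n_hyper_per_tumor = 10)
  a <- simulate_editome(cfg, seed = 23)
  b <- simulate_editome(cfg, seed = 23)
  expect_identical(a$truth, b$truth)
  expect_identical(a$rna[["P01_primary"]], b$rna[["P01_primary"]])
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$reference$genome, b$reference$genome)

  c <- simulate_editome(cfg, seed = 24)
  expect_false(identical(a$truth, c$truth))
})

test_that("planted truth respects its own invariants", {
  sim <- small_sim()
  tr <- sim$truth
  expect_true(all(tr$level_normal >= 0 & tr$level_normal <= 1))
  # hyper flag implies delta > 0.2 or an unedited normal
  for (tis in c("primary", "metastatic")) {
    lv <- tr[[paste0("level_", tis)]]
    flag <- tr[[paste0("hyper_", tis)]]
    ok <- (tr$level_normal == 0 & lv >= 0.1) | (lv - tr$level_normal > 0.2)
    expect_true(all(ok[flag]))
  }
  # het SNPs never overlap editing sites
  expect_equal(length(intersect(paste(tr$chrom, tr$pos),
                                paste(sim$het_snps$chrom, sim$het_snps$pos))),
               0L)
  # reference base at each planted site matches the truth record
  g <- sim$reference$genome
  at <- vapply(seq_len(nrow(tr)),
               function(i) substr(g[[tr$chrom[i]]], tr$pos[i], tr$pos[i]),
               character(1))
  expect_identical(at, tr$ref)
})

test_that("the generated annotation is internally consistent", {
  sim <- small_sim()
  # written GTF reloads without frame warnings and matches the model table
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$reference$gene_models, f)
  expect_no_warning(back <- read_gene_models(f))
  expect_equal(attr(back, "cds_invalid"), character(0))
  expect_setequal(unique(back$gene_id), unique(sim$reference$gene_models$gene_id))

  # truth regions agree with classify_region on the generated models
  reg <- classify_region(sim$truth, sim$reference$gene_models)
  expect_equal(reg$region, sim$truth$region)

  # truth alu flags agree with the written Alu track
  expect_equal(annotate_alu(sim$truth$chrom, sim$truth$pos, sim$reference$alu),
               sim$truth$alu)
})

test_that("planted type and region fractions are recovered at n = 2000", {
  cfg <- sim_config(n_sites = 2000, n_genes = 80, n_background = 0,
                    n_dna_het_snps = 0, n_position_artifacts = 0,
                    n_strand_artifacts = 0)
  ref <- generate_reference(cfg, seed = 31)
  planted <- plant_truth(ref, cfg, seed = 32)
  tr <- planted$truth
  expect_equal(mean(tr$editing_type == "A->G"), 0.913, tolerance = 0.03 / 0.913)
  expect_equal(mean(tr$alu), 0.945, tolerance = 0.03 / 0.945)
  expect_equal(mean(tr$region == "intronic"), 0.715, tolerance = 0.04 / 0.715)
  expect_equal(mean(tr$region == "UTR3"), 0.105, tolerance = 0.04 / 0.105)
  expect_equal(mean(tr$region == "intergenic"), 0.097, tolerance = 0.04 / 0.097)
})

test_that("simulated pileups reflect the planted levels and honour invariants", {
  sim <- small_sim()
  p <- sim$rna[["P01_primary"]]
  # distance lists length-match the majority non-reference count
  cand <- summarize_candidates(p)
  dist_n <- lengths(editome:::parse_end_distances(cand$end_distances))
  expect_true(all(dist_n == cand$edit_count | is.na(cand$alt)))

  # mean observed alt fraction across planted sites tracks the true level
  tr <- dplyr::filter(sim$truth, level_primary >= 0.2)
  obs <- dplyr::inner_join(cand, tr, by = c("chrom", "pos"))
  expect_equal(mean(obs$editing_level - obs$level_primary), 0, tolerance = 0.03)

  # DNA pileups are homozygous reference away from het SNPs
  d <- sim$dna[["P01_primary"]]
  bc <- editome:::pileup_base_counts(d)
  het <- paste(d$chrom, d$pos) %in% paste(sim$het_snps$chrom, sim$het_snps$pos)
  expect_true(all(bc$ref_count[!het] == bc$depth[!het]))
})

test_that("error-only data produce at most a stray candidate at depth 30", {
  cfg <- sim_config(n_patients = 1, n_sites = 0, n_background = 500,
                    n_dna_het_snps = 0, n_position_artifacts = 0,
                    n_strand_artifacts = 0, n_hyper_per_tumor = 0)
  sim <- simulate_editome(cfg, seed = 41)
  cand <- summarize_candidates(sim$rna[["P01_normal"]])
  # Binomial(30, 0.005) rarely reaches 3 identical errors at one position
  expect_lte(sum(cand$edit_count >= 3), 2L)
})

test_that("tumor samples carry more editing than their matched normals", {
  sim <- small_sim()
  n_edited <- function(tissue) {
    lv <- sim$truth[[paste0("level_", tissue)]]
    sum(lv >= 0.1)
  }
  expect_gt(n_edited("primary"), n_edited("normal"))
  expect_gt(n_edited("metastatic"), n_edited("normal"))
})
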