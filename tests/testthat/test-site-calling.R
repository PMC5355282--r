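test_that("candidate summarisation picks the single majority alt base", {
  p <- pileup_row(pos = 1000, ref = "A", counts = list(A = c(15, 0), G = c(5, 0)),
                  end_distances = "10,20,30,40,50")
  cand <- summarize_candidates(p)
  expect_equal(cand$alt, "G")
  expect_equal(cand$depth, 20L)
  expect_equal(cand$editing_level, 0.25)
  expect_true(is.na(cand$candidate_flag))

  multi <- pileup_row(ref = "A", counts = list(A = c(10, 0), G = c(5, 0),
                                               C = c(5, 0)))
  expect_equal(summarize_candidates(multi)$candidate_flag, "multiallelic")

  refonly <- pileup_row(ref = "A", counts = list(A = c(20, 0)))
  expect_equal(nrow(summarize_candidates(refonly)), 0L)

  refn <- pileup_row(ref = "N", counts = list(A = c(10, 0), G = c(5, 0)))
  expect_equal(summarize_candidates(refn)$candidate_flag, "ref_N")
})

test_that("basic filter thresholds flip exactly at the printed rules", {
  cand <- function(depth, edits, bq = 35, mapq = 50) {
    summarize_candidates(pileup_row(
      ref = "A", counts = list(A = c(depth - edits, 0), G = c(edits, 0)),
      bq = list(G = bq), mapq = mapq,
      end_distances = paste(rep(30, edits), collapse = ",")
    ))
  }
  pass_flag <- function(...) basic_filter(cand(...))$flag_basic

  expect_true(is.na(pass_flag(20, 5)))
  expect_equal(pass_flag(3, 3), "low_depth")       # depth 3 < 4
  expect_true(is.na(pass_flag(4, 3)))              # depth 4 passes
  expect_equal(pass_flag(4, 2), "few_edit_bases")  # 2 edits, level 0.5
  expect_equal(pass_flag(20, 5, bq = 19), "low_base_quality")
  expect_equal(pass_flag(20, 5, mapq = 19), "low_mapq")
  # editing level 0.0999 vs 0.100: 9.99 not constructible with integers;
  # use 999/10000 vs 100/1000
  low <- summarize_candidates(pileup_row(
    ref = "A", counts = list(A = c(9001, 0), G = c(999, 0)),
    end_distances = paste(rep(30, 999), collapse = ",")))
  expect_equal(basic_filter(low)$flag_basic, "low_level")
  at <- summarize_candidates(pileup_row(
    ref = "A", counts = list(A = c(900, 0), G = c(100, 0)),
    end_distances = paste(rep(30, 100), collapse = ",")))
  expect_true(is.na(basic_filter(at)$flag_basic))
})

test_that("strand-bias filter uses the two-tailed Fisher test", {
  balanced <- summarize_candidates(pileup_row(
    ref = "A", counts = list(A = c(10, 10), G = c(5, 5)),
    end_distances = paste(rep(30, 10), collapse = ",")))
  expect_true(is.na(strand_bias_filter(balanced)$flag_strand))

  skewed <- summarize_candidates(pileup_row(
    ref = "A", counts = list(A = c(50, 50), G = c(20, 0)),
    end_distances = paste(rep(30, 20), collapse = ",")))
  out <- strand_bias_filter(skewed)
  expect_equal(out$flag_strand, "strand_bias")
  expect_equal(out$p_strand, fisher_oracle(50, 50, 20, 0), tolerance = 1e-9)
  expect_lt(out$p_strand, 0.005)
})

test_that("position-bias filter requires the end-distance fraction to exceed 0.9", {
  cand <- function(dists) summarize_candidates(pileup_row(
    ref = "A", counts = list(A = c(30, 0), G = c(length(dists), 0)),
    end_distances = paste(dists, collapse = ",")))

  expect_equal(position_bias_filter(cand(c(1, 2, 3, 4)))$flag_position,
               "position_bias") # fraction 1 > 0.9
  expect_true(is.na(position_bias_filter(cand(c(2, 30, 45)))$flag_position))
  # exactly 0.9 must NOT trigger (strict inequality at the boundary)
  expect_true(is.na(position_bias_filter(
    cand(c(rep(5, 9), 40)))$flag_position))

  missing <- cand(30)
  missing$end_distances <- "."
  expect_error(position_bias_filter(missing), "missing end distances")
})

test_that("repeat, homopolymer and splice-region exclusion", {
  models <- toy_gene_models()
  # genome: site at pos 100 sits centred in GGGAAAAAGGG (A-run of 5)
  genome <- c(chr1 = paste(rep("ACGT", 700), collapse = ""))
  s <- genome[["chr1"]]
  substr(s, 95, 105) <- "GGGAAAAAGGG"
  genome[["chr1"]] <- s

  cand <- function(pos, edits = 5, depth = 30) summarize_candidates(pileup_row(
    pos = pos, ref = "A", counts = list(A = c(depth - edits, 0), G = c(edits, 0)),
    end_distances = paste(rep(30, edits), collapse = ",")))

  out <- region_exclusion_filter(cand(100), genome = genome,
                                 gene_models = models)
  expect_equal(out$flag_region, "homopolymer")

  # intronic, 3 bp from the exon ending at 300 (window 4) -> splice region
  out2 <- region_exclusion_filter(cand(303), genome = genome,
                                  gene_models = models)
  expect_equal(out2$flag_region, "splice_region")

  # exonic position 1 bp inside the exon is never splice-excluded
  out3 <- region_exclusion_filter(cand(300), genome = genome,
                                  gene_models = models)
  expect_true(is.na(out3$flag_region))

  # intronic, 5 bp from the boundary: outside the window
  out4 <- region_exclusion_filter(cand(305), genome = genome,
                                  gene_models = models)
  expect_true(is.na(out4$flag_region))

  reps <- tibble::tibble(chrom = "chr1", start = 499L, end = 520L,
                         label = "simple_repeat")
  out5 <- region_exclusion_filter(cand(500), repeats = reps, genome = genome,
                                  gene_models = models)
  expect_equal(out5$flag_region, "simple_repeat")
})

test_that("gDNA homozygosity check enforces depth and allele fractions", {
  cand <- summarize_candidates(pileup_row(
    pos = 500, ref = "A", counts = list(A = c(20, 0), G = c(10, 0)),
    end_distances = paste(rep(30, 10), collapse = ",")))
  dna <- function(a, g, pos = 500) pileup_row(
    pos = pos, ref = "A", counts = list(A = c(a, 0), G = c(g, 0)))

  expect_true(is.na(gdna_homozygosity_check(cand, dna(30, 0))$flag_dna))
  expect_equal(gdna_homozygosity_check(cand, dna(16, 14))$flag_dna,
               "dna_not_homozygous")
  expect_equal(gdna_homozygosity_check(cand, dna(3, 0))$flag_dna,
               "low_dna_depth")
  expect_equal(gdna_homozygosity_check(cand, dna(30, 0, pos = 999))$flag_dna,
               "no_dna_coverage")
})

test_that("the full cascade recovers planted sites and rejects DNA hets", {
  sim <- small_sim()
  ann <- annotation_bundle(sim$reference$gene_models, sim$reference$alu,
                           sim$reference$repeats, sim$known_variants,
                           sim$reference$genome)
  calls <- call_editing_sites(sim$rna[["P01_primary"]], sim$dna[["P01_primary"]],
                              ann, sample_id = "P01_primary")
  st <- recovery_stats(calls, sim$truth, sim$het_snps, "primary")
  expect_gte(st$sensitivity, 0.9)
  expect_equal(st$het_calls, 0L)

  # no called site violates the final thresholds
  expect_true(all(calls$sites$editing_level >= 0.10))
  expect_true(all(calls$sites$edit_count >= 3))
  expect_true(all(calls$sites$depth >= 4))

  # audit funnel sums: candidates = called + per-filter rejections
  f <- calls$funnel
  expect_equal(f$n[f$stage == "candidates"],
               sum(f$n[!f$stage %in% c("candidates", "called")]) +
                 f$n[f$stage == "called"])

  # the cascade is deterministic
  calls2 <- call_editing_sites(sim$rna[["P01_primary"]],
                               sim$dna[["P01_primary"]], ann,
                               sample_id = "P01_primary")
  expect_identical(calls$sites, calls2$sites)
})

test_that("a sub-threshold planted level and ref-only pileups give no calls", {
  # planted level 0.05: even with perfect sampling the 10% rule rejects it
  edits <- 2L # 2/40 = 0.05
  p <- pileup_row(pos = 50, ref = "A",
                  counts = list(A = c(38, 0), G = c(edits, 0)),
                  end_distances = "30,40")
  dna <- pileup_row(pos = 50, ref = "A", counts = list(A = c(30, 0)))
  calls <- call_editing_sites(p, dna)
  expect_equal(nrow(calls$sites), 0L)
  expect_true(calls$audit$filter_flag[1] %in% c("low_level", "few_edit_bases"))

  refonly <- pileup_rows(
    pileup_row(pos = 1, ref = "A", counts = list(A = c(15, 15))),
    pileup_row(pos = 2, ref = "C", counts = list(C = c(20, 10)))
  )
  expect_equal(nrow(call_editing_sites(refonly, dna)$sites), 0L)
})

test_that("known variants are excluded by the cascade", {
  covered <- dplyr::bind_rows(lapply(1:20, function(i) {
    pileup_row(pos = i, ref = "C", counts = list(C = c(15, 15)))
  }))
  p <- dplyr::bind_rows(
    covered,
    pileup_row(pos = 70, ref = "A", counts = list(A = c(20, 20), G = c(10, 10)),
               end_distances = paste(rep(25, 20), collapse = ","))
  )
  dna <- pileup_row(pos = 70, ref = "A", counts = list(A = c(30, 0)))
  ann <- annotation_bundle(known_variants = tibble::tibble(chrom = "chr1",
                                                           pos = 70L))
  calls <- call_editing_sites(p, dna, ann)
  expect_equal(nrow(calls$sites), 0L)
  expect_equal(calls$audit$filter_flag, "known_variant")
})
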