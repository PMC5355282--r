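make_pair_fixture <- function(t_edit, t_depth, n_edit, n_depth, pos = 100L) {
  tumor_p <- pileup_row(pos = pos, ref = "A",
                        counts = list(A = c(t_depth - t_edit, 0),
                                      G = c(t_edit, 0)))
  normal_p <- pileup_row(pos = pos, ref = "A",
                         counts = list(A = c(n_depth - n_edit, 0),
                                       G = c(n_edit, 0)))
  sites <- tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "G")
  list(tumor = fake_calls(sites, "P01_primary"),
       normal = fake_calls(sites[0, ], "P01_normal"),
       tumor_p = tumor_p, normal_p = normal_p)
}

test_that("tumor-specific sites require 6x in both samples and a clean normal", {
  fx <- make_pair_fixture(3, 20, 0, 10)
  pairs <- call_pairs(fx$tumor, fx$normal, fx$tumor_p, fx$normal_p)
  expect_equal(pairs$class, "hyper_specific")
  expect_equal(pairs$tumor_level, 0.15)

  # normal depth 5 < 6: the specific rule must not fire
  fx2 <- make_pair_fixture(6, 20, 0, 5)
  pairs2 <- call_pairs(fx2$tumor, fx2$normal, fx2$tumor_p, fx2$normal_p,
                       audit = TRUE)
  expect_false(any(pairs2$class == "hyper_specific"))

  # a single edited base in the normal also blocks the specific rule
  fx3 <- make_pair_fixture(3, 20, 1, 20)
  pairs3 <- call_pairs(fx3$tumor, fx3$normal, fx3$tumor_p, fx3$normal_p,
                       audit = TRUE)
  expect_false(any(pairs3$class == "hyper_specific"))
})

test_that("differential sites need delta strictly above 0.2 and Fisher p <= 0.05", {
  # delta exactly 0.20 -> none
  fx <- make_pair_fixture(8, 20, 4, 20)
  pairs <- call_pairs(fx$tumor, fx$normal, fx$tumor_p, fx$normal_p, audit = TRUE)
  expect_equal(pairs$class, "none")

  # delta 0.55 with tiny Fisher p -> hyper_differential
  fx2 <- make_pair_fixture(12, 20, 1, 20)
  pairs2 <- call_pairs(fx2$tumor, fx2$normal, fx2$tumor_p, fx2$normal_p)
  expect_equal(pairs2$class, "hyper_differential")
  expect_equal(pairs2$fisher_p, fisher_oracle(12, 8, 1, 19), tolerance = 1e-9)
  expect_lte(pairs2$fisher_p, 0.05)
})

test_that("classification boundaries flip exactly at the stated thresholds", {
  base <- list(tumor_level = 0.5, tumor_edits = 10L, tumor_depth = 20L,
               tumor_called = TRUE, normal_edits = 2L, normal_depth = 20L,
               normal_called = FALSE)
  cls <- function(normal_level, fisher_p) {
    classify_pair(base$tumor_level, base$tumor_edits, base$tumor_depth,
                  base$tumor_called, normal_level, base$normal_edits,
                  base$normal_depth, base$normal_called, fisher_p = fisher_p)
  }
  expect_equal(cls(0.300, 0.01), "none")                # delta = 0.200
  expect_equal(cls(0.299, 0.01), "hyper_differential")  # delta = 0.201
  expect_equal(cls(0.25, 0.050), "hyper_differential")  # p = 0.050 classifies
  expect_equal(cls(0.25, 0.051), "none")                # p = 0.051 does not

  # tumor depth 5 vs 6 flips the specific rule
  spec <- function(tumor_depth, normal_depth) {
    classify_pair(0.5, 3L, tumor_depth, TRUE, 0, 0L, normal_depth, FALSE)
  }
  expect_equal(spec(6L, 6L), "hyper_specific")
  expect_equal(spec(5L, 6L), "none")
  expect_equal(spec(6L, 5L), "none")
})

test_that("swapping tumor and normal exchanges hyper and hypo exactly", {
  sim <- small_sim()
  ann <- annotation_bundle(sim$reference$gene_models, sim$reference$alu,
                           sim$reference$repeats, sim$known_variants,
                           sim$reference$genome)
  tc <- call_editing_sites(sim$rna[["P01_primary"]], sim$dna[["P01_primary"]],
                           ann, sample_id = "P01_primary")
  nc <- call_editing_sites(sim$rna[["P01_normal"]], sim$dna[["P01_normal"]],
                           ann, sample_id = "P01_normal")
  fwd <- call_pairs(tc, nc, sim$rna[["P01_primary"]], sim$rna[["P01_normal"]])
  rev <- call_pairs(nc, tc, sim$rna[["P01_normal"]], sim$rna[["P01_primary"]])
  key <- function(x, classes) {
    sort(paste(x$chrom, x$pos)[x$class %in% classes])
  }
  expect_identical(key(fwd, c("hyper_specific", "hyper_differential")),
                   key(rev, c("hypo_specific", "hypo_differential")))
  expect_identical(key(fwd, c("hypo_specific", "hypo_differential")),
                   key(rev, c("hyper_specific", "hyper_differential")))
})

test_that("identical samples yield no hyper or hypo calls", {
  sim <- small_sim()
  ann <- annotation_bundle(sim$reference$gene_models, sim$reference$alu,
                           sim$reference$repeats, sim$known_variants,
                           sim$reference$genome)
  tc <- call_editing_sites(sim$rna[["P01_primary"]], sim$dna[["P01_primary"]],
                           ann, sample_id = "P01_primary")
  same <- call_pairs(tc, tc, sim$rna[["P01_primary"]], sim$rna[["P01_primary"]])
  expect_equal(nrow(same), 0L)
})

test_that("mismatched patients are rejected and rates divide by megabases", {
  sites <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "G")
  expect_error(call_pairs(fake_calls(sites, "P01_primary"),
                          fake_calls(sites, "P02_normal"),
                          pileup_row(), pileup_row()),
               "mismatched patient")

  expect_equal(hyper_editing_rate(47, 1.5), 47 / 1.5)
  expect_equal(hyper_editing_rate(0, 2), 0)
  expect_error(hyper_editing_rate(5, 0), "positive")
})
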