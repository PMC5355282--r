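test_that("region classification follows the precedence order", {
  models <- toy_gene_models()
  pos <- tibble::tibble(chrom = "chr1",
                        pos = c(200L, 50L, 120L, 600L, 2100L, 350L, 303L))
  reg <- classify_region(pos, models)
  expect_equal(reg$region,
               c("CDS", "intergenic", "UTR5", "UTR3", "ncRNA", "intronic",
                 "splicing"))
  expect_equal(reg$gene_id[1], "GENE1")
  expect_equal(reg$gene_id[2], ".")
  expect_equal(reg$strand[5], "-")
})

test_that("overlapping transcripts resolve by precedence (CDS first, UTR3 over intron)", {
  models <- new_gene_models(tibble::tribble(
    ~gene_id, ~transcript_id, ~chrom, ~strand, ~feature, ~start, ~end,
    "GA", "TA", "chr1", "+", "exon", 100L, 200L,
    "GA", "TA", "chr1", "+", "exon", 301L, 400L,
    "GA", "TA", "chr1", "+", "CDS", 150L, 200L,
    "GA", "TA", "chr1", "+", "CDS", 301L, 351L,
    "GA", "TA", "chr1", "+", "UTR5", 100L, 149L,
    "GA", "TA", "chr1", "+", "UTR3", 352L, 400L,
    "GB", "TB", "chr1", "+", "exon", 50L, 120L,
    "GB", "TB", "chr1", "+", "exon", 360L, 500L
  ))
  # 380 is UTR3 of TA and intron of TB -> UTR3 wins, gene from TA
  # (380 is also exonic in TB, but TB is non-coding -> ncRNA ranks below UTR3)
  reg <- classify_region(tibble::tibble(chrom = "chr1", pos = 380L), models)
  expect_equal(reg$region, "UTR3")
  expect_equal(reg$gene_id, "GA")
  # 160 is CDS of TA and intron of TB -> CDS
  reg2 <- classify_region(tibble::tibble(chrom = "chr1", pos = 160L), models)
  expect_equal(reg2$region, "CDS")
})

test_that("editing types collapse onto the transcript sense", {
  expect_equal(collapse_editing_type("T", "C", "-")$editing_type, "A->G")
  expect_equal(collapse_editing_type("A", "G", "+")$editing_type, "A->G")
  inferred <- collapse_editing_type("G", "A", NA)
  expect_equal(inferred$editing_type, "C->T")
  expect_equal(inferred$strand, "-")
  expect_true(inferred$strand_inferred)
  expect_error(collapse_editing_type("A", "A", "+"), "must differ")
})

test_that("type collapsing is complement-consistent over all 12 x 2 cases", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref in c("A", "C", "G", "T")) {
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      for (strand in c("+", "-")) {
        a <- collapse_editing_type(ref, alt, strand)$editing_type
        b <- collapse_editing_type(comp[[ref]], comp[[alt]],
                                   setdiff(c("+", "-"), strand))$editing_type
        expect_identical(a, b)
      }
    }
  }
})

test_that("region labels partition positions (exactly one label each)", {
  models <- toy_gene_models()
  pos <- tibble::tibble(chrom = "chr1", pos = seq(1L, 2500L, by = 7L))
  reg <- classify_region(pos, models)
  expect_equal(nrow(reg), nrow(pos))
  expect_true(all(reg$region %in% c("CDS", "splicing", "UTR5", "UTR3",
                                    "ncRNA", "intronic", "intergenic")))
})

test_that("amino-acid change reproduces known editing consequences", {
  # codon 367 = AGC (Ser); editing its first base (c.1099) A->G gives GGC (Gly)
  cds <- paste(c(rep("GCT", 366), "AGC", rep("GCT", 33)), collapse = "")
  ch <- amino_acid_change(cds, 1099, "G")
  expect_equal(ch$cdna_change, "c.A1099G")
  expect_equal(ch$protein_change, "p.S367G")
  expect_false(ch$synonymous)

  # codon 579 = CAT (His); editing its middle base (c.1736) A->G gives CGT (Arg)
  cds2 <- paste(c(rep("GCT", 578), "CAT", rep("GCT", 2)), collapse = "")
  ch2 <- amino_acid_change(cds2, 1736, "G")
  expect_equal(ch2$cdna_change, "c.A1736G")
  expect_equal(ch2$protein_change, "p.H579R")
  expect_false(ch2$synonymous)

  # GCA -> GCG is synonymous (both Ala)
  cds3 <- paste(c("ATG", "GCA"), collapse = "")
  ch3 <- amino_acid_change(cds3, 6, "G")
  expect_true(ch3$synonymous)

  expect_error(amino_acid_change("ATGGC", 2, "G"), "divisible by 3")
  expect_error(amino_acid_change("ATGGCA", 9, "G"), "outside")
})

test_that("amino-acid change agrees with translating the full mutant CDS", {
  set.seed(7)
  for (i in 1:25) {
    n_codon <- sample(5:40, 1)
    repeat {
      cds <- paste(sample(c("A", "C", "G", "T"), n_codon * 3, replace = TRUE),
                   collapse = "")
      aa0 <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                if.fuzzy.codon = "X"))
      # avoid premature stops so the oracle diff is well-defined
      if (!grepl("\\*", substr(aa0, 1, n_codon - 1))) break
    }
    pos <- sample(n_codon * 3, 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ch <- amino_acid_change(cds, pos, alt)
    mut <- cds
    substr(mut, pos, pos) <- alt
    aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                              if.fuzzy.codon = "X"))
    diffs <- which(strsplit(aa0, "")[[1]] != strsplit(aa1, "")[[1]])
    if (ch$synonymous) {
      expect_equal(length(diffs), 0L)
    } else {
      expect_equal(length(diffs), 1L)
      expect_equal(ch$protein_change,
                   paste0("p.", substr(aa0, diffs, diffs), diffs,
                          substr(aa1, diffs, diffs)))
    }
  }
})

test_that("Alu annotation is a plain interval overlap", {
  alu <- tibble::tibble(chrom = "chr1", start = 999L, end = 1010L, label = "Alu")
  expect_true(annotate_alu("chr1", 1005, alu))
  expect_false(annotate_alu("chr1", 1011, alu))
  expect_false(annotate_alu("chr1", 1005, alu[0, ]))
})

test_that("external score filters apply inclusive printed thresholds", {
  sites <- tibble::tibble(chrom = "chr16", pos = c(1L, 2L, 3L, 4L),
                          ref = "A", alt = "G")
  scores <- tibble::tibble(
    chrom = "chr16", pos = c(1L, 2L, 3L),
    ref = "A", alt = "G",
    score = c(2.0, 1.99, -2.5),
    score_type = "spidex_z"
  )
  kept <- suppressMessages(filter_by_external_score(sites, scores, "spidex"))
  expect_equal(kept$pos, c(1L, 3L)) # |Z| >= 2 inclusive; missing row dropped

  cadd <- dplyr::mutate(scores, score = c(20, 19.9, 35),
                        score_type = "cadd_phred")
  kept2 <- suppressMessages(filter_by_external_score(sites, cadd, "cadd"))
  expect_equal(kept2$pos, c(1L, 3L))

  expect_message(filter_by_external_score(sites, scores, "spidex"), "dropped")
  expect_error(filter_by_external_score(sites, scores, "sift"))
})
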