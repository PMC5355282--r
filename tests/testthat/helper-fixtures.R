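# Construct a pileup tibble from compact per-base specs.
# counts: named list base -> c(fwd, rev); bq defaults to 35 for observed bases.
pileup_row <- function(chrom = "chr1", pos = 100L, ref = "A",
                       counts = list(), bq = NULL, mapq = 50,
                       end_distances = ".") {
  all_counts <- list(A = c(0L, 0L), C = c(0L, 0L), G = c(0L, 0L), T = c(0L, 0L))
  for (b in names(counts)) all_counts[[b]] <- as.integer(counts[[b]])
  bqs <- setNames(rep(0, 4), c("A", "C", "G", "T"))
  for (b in names(all_counts)) if (sum(all_counts[[b]]) > 0) bqs[[b]] <- 35
  if (!is.null(bq)) for (b in names(bq)) bqs[[b]] <- bq[[b]]
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    countA_fwd = all_counts$A[1], countA_rev = all_counts$A[2],
    countC_fwd = all_counts$C[1], countC_rev = all_counts$C[2],
    countG_fwd = all_counts$G[1], countG_rev = all_counts$G[2],
    countT_fwd = all_counts$T[1], countT_rev = all_counts$T[2],
    meanBQ_A = bqs[["A"]], meanBQ_C = bqs[["C"]], meanBQ_G = bqs[["G"]],
    meanBQ_T = bqs[["T"]],
    mean_mapq = mapq, alt_end_distances = end_distances
  )
}

pileup_rows <- function(...) dplyr::bind_rows(...)

# A two-gene annotation: GENE1 (+, coding, 2 exons) and GENE2 (-, non-coding).
toy_gene_models <- function() {
  new_gene_models(tibble::tribble(
    ~gene_id, ~transcript_id, ~chrom, ~strand, ~feature, ~start, ~end,
    "GENE1", "TX1", "chr1", "+", "exon", 100L, 300L,
    "GENE1", "TX1", "chr1", "+", "exon", 401L, 700L,
    "GENE1", "TX1", "chr1", "+", "UTR5", 100L, 150L,
    "GENE1", "TX1", "chr1", "+", "CDS",  151L, 300L,
    "GENE1", "TX1", "chr1", "+", "CDS",  401L, 550L,
    "GENE1", "TX1", "chr1", "+", "UTR3", 551L, 700L,
    "GENE2", "TX2", "chr1", "-", "exon", 2000L, 2400L
  ))
}

# Minimal editing_calls stub for pair-level tests.
fake_calls <- function(sites, sample_id = "P01_primary") {
  structure(list(sites = sites, audit = sites[0, ],
                 funnel = tibble::tibble(stage = "candidates", n = nrow(sites)),
                 background_rate = 0.005, config = caller_config(),
                 sample_id = sample_id),
            class = "editing_calls")
}

# Independent two-tailed Fisher oracle: exhaustive enumeration of all tables
# with the observed margins, probabilities from exact factorials.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0) return(1)
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  tab_prob <- function(x) {
    # P(table) = choose(m1, x) choose(m2, n1 - x) / choose(m1 + m2, n1)
    exp(lfactorial(m1) - lfactorial(x) - lfactorial(m1 - x) +
          lfactorial(m2) - lfactorial(n1 - x) - lfactorial(m2 - n1 + x) -
          (lfactorial(m1 + m2) - lfactorial(n1) - lfactorial(m1 + m2 - n1)))
  }
  probs <- vapply(lo:hi, tab_prob, numeric(1))
  p_obs <- probs[(lo:hi) == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Small cached simulation shared across test files.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 1, n_sites = 80, n_background = 1500,
                        n_hyper_per_tumor = 20)
      cache <<- simulate_editome(cfg, seed = 17)
    }
    cache
  }
})
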