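test_that("RPKM follows the printed formula and its homogeneity", {
  expect_equal(rpkm(1000, 1e7, 2000), 50)
  expect_equal(rpkm(0, 1e7, 2000), 0)
  expect_equal(rpkm(2000, 2e7, 2000), rpkm(1000, 1e7, 2000)) # C,N double
  expect_equal(rpkm(2 * 1000, 1e7, 2000), 2 * rpkm(1000, 1e7, 2000))
  expect_equal(rpkm(1000, 1e7, 2 * 2000), rpkm(1000, 1e7, 2000) / 2)
  expect_error(rpkm(10, 0, 100), "positive")
  expect_error(rpkm(10, 100, 0), "positive")
})

test_that("log fold change is log2 with explicit missingness at zero", {
  expect_equal(log_fold_change(50, 25), 1)
  expect_equal(log_fold_change(30, 30), 0)
  expect_true(is.na(log_fold_change(50, 0)))
  expect_true(is.na(log_fold_change(0, 50)))
})

test_that("edit+/edit- partition needs an A->G hyper site in a UTR", {
  hyper <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    gene_id = c("X", "X", "X"),
    region = c("UTR3", "CDS", "UTR3"),
    editing_type = c("A->G", "A->G", "C->T")
  )
  grp <- edit_group_partition(c("s1", "s2", "s3", "s4"), "X", hyper)
  expect_equal(grp$edit_plus, "s1")   # UTR + A->G only
  expect_setequal(grp$edit_minus, c("s2", "s3", "s4"))
})

test_that("edit-group test is a Welch t with a minimum group size", {
  same <- rep(c(1, 2, 3, 4), 2)
  res <- edit_group_test(same, same)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_equal(res$t, 0, tolerance = 1e-12)

  expect_message(skipped <- edit_group_test(c(1, 2, 3), rnorm(10, 5)),
                 "skipped")
  expect_null(skipped)

  a <- c(10, 12, 9, 11, 13); b <- c(20, 22, 19, 21, 23)
  expect_equal(edit_group_test(a, b)$p, edit_group_test(b, a)$p)
  expect_equal(edit_group_test(a, b)$t, -edit_group_test(b, a)$t)
  expect_equal(edit_group_test(a, b)$p,
               t.test(a, b, var.equal = FALSE)$p.value)
})

test_that("a planted two-fold expression shift is detected with good power", {
  cfg <- sim_config()
  hits <- vapply(1:25, function(seed) {
    sim <- simulate_expression(sprintf("s%02d", 1:16), cfg, seed = seed,
                               n_genes = 6, n_shift_genes = 1,
                               assignment = setNames(rep(c(TRUE, FALSE), each = 8),
                                                     sprintf("s%02d", 1:16)))
    g <- sim$shift_genes[1]
    e <- dplyr::left_join(sim$expression, sim$library_sizes, by = "sample_id")
    e <- dplyr::filter(e, gene_id == g)
    x <- rpkm(e$unique_read_count, e$total_mapped_reads, e$exon_length_bp)
    plus <- sim$assignment[e$sample_id]
    edit_group_test(x[plus], x[!plus])$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("editing-expression correlation applies the exclusion rules", {
  levels <- c(0.5, 0.4, 0.3, 0.2, 0.1)
  expr <- c(1, 2, 3, 4, 5)
  expect_equal(editing_expression_correlation(levels, expr), -1)

  # a zero-level sample and a low-depth sample are excluded
  lv <- c(levels, 0)
  ex <- c(expr, 100)
  expect_equal(editing_expression_correlation(lv, ex), -1)
  dp <- c(10, 10, 3, 10, 10)
  r_excl <- editing_expression_correlation(levels, expr, depth = dp)
  expect_equal(r_excl, cor(levels[-3], expr[-3]))

  expect_error(editing_expression_correlation(c(0.1, 0.2), c(1, 2)),
               "fewer than 3")
  expect_error(editing_expression_correlation(rep(0.2, 5), expr),
               "zero variance")
})

test_that("a planted negative editing-expression coupling is recovered", {
  set.seed(10)
  lv <- setNames(runif(24, 0.05, 0.7), sprintf("s%02d", 1:24))
  sim <- simulate_expression(names(lv), sim_config(), seed = 9, n_genes = 8,
                             n_shift_genes = 0, couple_levels = lv,
                             couple_beta = -2)
  e <- dplyr::left_join(sim$expression, sim$library_sizes, by = "sample_id")
  e <- dplyr::filter(e, gene_id == sim$coupled_gene)
  x <- rpkm(e$unique_read_count, e$total_mapped_reads, e$exon_length_bp)
  r <- editing_expression_correlation(lv[e$sample_id], x)
  expect_lt(r, -0.15)
})

test_that("the cohort edit-group scan returns the documented schema", {
  set.seed(11)
  samples <- sprintf("s%02d", 1:12)
  hyper <- tibble::tibble(sample_id = samples[1:5], gene_id = "EG001",
                          region = "UTR3", editing_type = "A->G")
  expression <- tidyr::expand_grid(sample_id = samples, gene_id = "EG001") |>
    dplyr::mutate(unique_read_count = rpois(12, 500), exon_length_bp = 2000L)
  lib <- tibble::tibble(sample_id = samples, total_mapped_reads = 1e6)
  de <- edit_group_de(expression, lib, hyper)
  expect_named(de, c("gene_id", "n_edit_plus", "n_edit_minus",
                     "mean_rpkm_plus", "mean_rpkm_minus", "t_p"))
  expect_equal(de$n_edit_plus, 5L)
  expect_equal(de$n_edit_minus, 7L)
  g <- glance(de)
  expect_named(g, c("n_genes", "n_significant"))
})
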