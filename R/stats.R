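#' Upper-tail binomial test against a background mismatch rate
#'
#' Probability of observing at least `k` mismatch reads out of `n` under the
#' sequencing-error model `Binomial(n, p)`, where `p` is the sample-wide
#' background mismatch rate (see [estimate_background_mismatch_rate()]). Small
#' p-values indicate the mismatch is unlikely to be sequencing error.
#'
#' @param k Integer vector, mismatch (edit) read counts, `0 <= k <= n`.
#' @param n Integer vector, site depths.
#' @param p Background mismatch rate(s) in (0, 1).
#' @return Numeric vector of upper-tail probabilities `P(X >= k)`.
#' @examples
#' binomial_error_test(3, 20, 0.01)
#' binomial_error_test(0, 20, 0.01) # 1: the whole support
#' @export
binomial_error_test <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) {
    abort("binomial_error_test: k must satisfy 0 <= k <= n")
  }
  if (any(p <= 0) || any(p >= 1)) {
    abort("binomial_error_test: p must lie strictly inside (0, 1)")
  }
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted values, in input order. Thin wrapper
#' over [stats::p.adjust()] that tolerates empty input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted values, same order and length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("bh_adjust: p-values must be in [0, 1] and non-missing")
  }
  p.adjust(p, method = "BH")
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Point-probability method: the p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. Any zero margin returns 1 by
#' convention. Vectorised over the four cells.
#'
#' @param a,b,c,d Non-negative integer cell counts of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return Numeric vector of two-tailed p-values.
#' @examples
#' fisher_exact_two_tailed(3, 0, 0, 3) # 0.1
#' fisher_exact_two_tailed(5, 5, 5, 5) # 1
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    abort("fisher_exact_two_tailed: all cell counts must be non-negative")
  }
  purrr::pmap_dbl(list(a, b, c, d), function(a, b, c, d) {
    m1 <- a + b   # row 1 margin
    m2 <- c + d   # row 2 margin
    n1 <- a + c   # column 1 margin
    n2 <- b + d
    if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0) return(1)
    lo <- max(0L, n1 - m2)
    hi <- min(n1, m1)
    support <- lo:hi
    probs <- dhyper(support, m1, m2, n1)
    p_obs <- probs[support == a]
    # relative tolerance guards ties computed along different floating routes
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  })
}

#' Sample-wide background mismatch rate
#'
#' Total non-reference base observations divided by total base observations
#' over a whole sample's RNA pileup, floored at 1e-6. This is the error-rate
#' parameter of the binomial sequencing-error test.
#'
#' @param pileup Pileup tibble as returned by [read_pileup()].
#' @return A single rate in (0, 1).
#' @export
estimate_background_mismatch_rate <- function(pileup) {
  counts <- pileup_base_counts(pileup)
  total <- counts$depth
  if (sum(total) == 0) abort("no coverage: pileup has zero base observations")
  mism <- total - counts$ref_count
  max(sum(mism) / sum(total), 1e-6)
}
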