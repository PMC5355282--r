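#' Paired-comparison configuration
#'
#' Thresholds of the tumor/normal hyper- and hypo-editing rules: a
#' tumor-specific site needs editing level >= `min_level`, `min_edit_bases`
#' edited reads and depth >= `min_depth` in the tumor while the matched
#' normal is covered at `min_depth` or more without a single edited base; a
#' differential site needs an editing-level difference strictly greater than
#' `min_delta` with two-tailed Fisher p <= `max_p`. Hypo-editing mirrors both
#' rules.
#'
#' @param min_depth Minimum depth in both samples for the specific rule (6).
#' @param min_level Minimum editing level in the edited sample (0.10).
#' @param min_edit_bases Minimum edited reads in the edited sample (3).
#' @param min_delta Editing-level difference that must be exceeded (0.2).
#' @param max_p Fisher p-value ceiling for the differential rule (0.05).
#' @return A `pair_config` list.
#' @export
pair_config <- function(min_depth = 6, min_level = 0.10, min_edit_bases = 3,
                        min_delta = 0.2, max_p = 0.05) {
  structure(as.list(environment()), class = "pair_config")
}

#' Classify one site of a tumor/normal pair
#'
#' Vectorised rule engine over precomputed per-site quantities. When a site
#' satisfies both the specific and the differential rule, the specific label
#' wins so that counts stay disjoint. Sites uncovered in either sample are
#' `none`.
#'
#' @param tumor_level,normal_level Editing levels (edited / total reads).
#' @param tumor_edits,normal_edits Edited-read counts.
#' @param tumor_depth,normal_depth Total read counts.
#' @param tumor_called,normal_called Logical: did the site pass the full
#'   calling cascade in that sample?
#' @param fisher_p Two-tailed Fisher p on
#'   `rbind(c(tumor_edits, tumor_depth - tumor_edits),
#'          c(normal_edits, normal_depth - normal_edits))`; computed when `NULL`.
#' @param config A [pair_config()].
#' @return Character vector in `hyper_specific, hyper_differential,
#'   hypo_specific, hypo_differential, none`.
#' @export
classify_pair <- function(tumor_level, tumor_edits, tumor_depth, tumor_called,
                          normal_level, normal_edits, normal_depth, normal_called,
                          fisher_p = NULL, config = pair_config()) {
  if (is.null(fisher_p)) {
    fisher_p <- fisher_exact_two_tailed(tumor_edits, tumor_depth - tumor_edits,
                                        normal_edits, normal_depth - normal_edits)
  }
  delta <- tumor_level - normal_level
  hyper_spec <- tumor_called & tumor_level >= config$min_level &
    tumor_edits >= config$min_edit_bases & tumor_depth >= config$min_depth &
    normal_depth >= config$min_depth & normal_edits == 0
  hypo_spec <- normal_called & normal_level >= config$min_level &
    normal_edits >= config$min_edit_bases & normal_depth >= config$min_depth &
    tumor_depth >= config$min_depth & tumor_edits == 0
  hyper_diff <- delta > config$min_delta & fisher_p <= config$max_p
  hypo_diff <- delta < -config$min_delta & fisher_p <= config$max_p
  case_when(
    tumor_depth == 0 | normal_depth == 0 ~ "none",
    hyper_spec ~ "hyper_specific",
    hypo_spec ~ "hypo_specific",
    hyper_diff ~ "hyper_differential",
    hypo_diff ~ "hypo_differential",
    TRUE ~ "none"
  )
}

#' Compare called editing sites between a tumor and its matched normal
#'
#' Takes the union of positions called in either sample, recovers raw edited
#' and total read counts for the shared alt base from both pileups, and
#' classifies every position with [classify_pair()]. Editing levels in the
#' partner sample come from raw pileup counts (the partner need not pass its
#' own filters).
#'
#' @param tumor_calls,normal_calls `editing_calls` objects from
#'   [call_editing_sites()] for the two samples of one patient.
#' @param tumor_pileup,normal_pileup The samples' RNA pileups.
#' @param config A [pair_config()].
#' @param audit Keep `none`-class rows too? (default `FALSE`).
#' @return Tibble: `chrom, pos, ref, alt, tumor_edit_count, tumor_depth,
#'   tumor_level, normal_edit_count, normal_depth, normal_level, delta,
#'   fisher_p, class`.
#' @export
call_pairs <- function(tumor_calls, normal_calls, tumor_pileup, normal_pileup,
                       config = pair_config(), audit = FALSE) {
  pt <- function(x) sub("_.*$", "", x$sample_id)
  if (!is.na(pt(tumor_calls)) && !is.na(pt(normal_calls)) &&
      grepl("_", tumor_calls$sample_id) && grepl("_", normal_calls$sample_id) &&
      pt(tumor_calls) != pt(normal_calls)) {
    abort(paste0("mismatched patient ids: ", tumor_calls$sample_id, " vs ",
                 normal_calls$sample_id))
  }
  ts <- select(tumor_calls$sites, "chrom", "pos", "ref", t_alt = "alt")
  ns <- select(normal_calls$sites, "chrom", "pos", "ref", n_alt = "alt")
  u <- dplyr::full_join(ts, ns, by = c("chrom", "pos", "ref"))
  if (nrow(u) == 0) return(empty_pairs(audit))

  tc <- pileup_allele_counts(tumor_pileup, u$chrom, u$pos)
  nc <- pileup_allele_counts(normal_pileup, u$chrom, u$pos)
  # shared alt base: agree when both called; otherwise prefer the larger
  # pooled count, ties broken by base order (symmetric under sample swap)
  alt <- purrr::pmap_chr(list(u$t_alt, u$n_alt, seq_len(nrow(u))),
    function(ta, na, i) {
      if (!is.na(ta) && !is.na(na) && ta == na) return(ta)
      cands <- stats::na.omit(unique(c(ta, na)))
      if (length(cands) == 1) return(cands)
      pooled <- purrr::map_dbl(cands, ~ tc$m[i, match(.x, BASES)] +
                                         nc$m[i, match(.x, BASES)])
      cands[order(-pooled, match(cands, BASES))][1]
    })
  ai <- match(alt, BASES)
  t_edit <- tc$m[cbind(seq_along(ai), ai)]
  n_edit <- nc$m[cbind(seq_along(ai), ai)]
  out <- tibble(
    chrom = u$chrom, pos = u$pos, ref = u$ref, alt = alt,
    tumor_edit_count = as.integer(t_edit), tumor_depth = as.integer(tc$depth),
    tumor_level = ifelse(tc$depth > 0, t_edit / tc$depth, NA_real_),
    normal_edit_count = as.integer(n_edit), normal_depth = as.integer(nc$depth),
    normal_level = ifelse(nc$depth > 0, n_edit / nc$depth, NA_real_),
    tumor_called = !is.na(u$t_alt), normal_called = !is.na(u$n_alt)
  ) %>% mutate(
    delta = .data$tumor_level - .data$normal_level,
    fisher_p = fisher_exact_two_tailed(
      .data$tumor_edit_count, .data$tumor_depth - .data$tumor_edit_count,
      .data$normal_edit_count, .data$normal_depth - .data$normal_edit_count),
    class = classify_pair(
      coalesce(.data$tumor_level, 0), .data$tumor_edit_count, .data$tumor_depth,
      .data$tumor_called,
      coalesce(.data$normal_level, 0), .data$normal_edit_count, .data$normal_depth,
      .data$normal_called, fisher_p = .data$fisher_p, config = config)
  ) %>% select(-"tumor_called", -"normal_called")
  if (!audit) out <- filter(out, .data$class != "none")
  out
}

empty_pairs <- function(audit) {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), tumor_edit_count = integer(),
         tumor_depth = integer(), tumor_level = numeric(),
         normal_edit_count = integer(), normal_depth = integer(),
         normal_level = numeric(), delta = numeric(), fisher_p = numeric(),
         class = character())
}

# Per-base totals of a pileup at requested positions (zero rows for positions
# absent from the pileup).
pileup_allele_counts <- function(pileup, chrom, pos) {
  bc <- pileup_base_counts(pileup)
  key <- paste(pileup$chrom, pileup$pos)
  idx <- match(paste(chrom, pos), key)
  m <- matrix(0L, nrow = length(pos), ncol = 4, dimnames = list(NULL, BASES))
  depth <- numeric(length(pos))
  hit <- !is.na(idx)
  m[hit, ] <- bc$m[idx[hit], , drop = FALSE]
  depth[hit] <- bc$depth[idx[hit]]
  list(m = m, depth = depth)
}

#' Hyper- (or hypo-) editing rate
#'
#' Number of hyper-editing sites per megabase of transcriptome covered at the
#' minimum calling depth.
#'
#' @param n_sites Number of hyper- (or hypo-) editing sites.
#' @param covered_length_mb Covered transcriptome length in Mb
#'   ([covered_length_mb()]); must be positive.
#' @return Sites per megabase.
#' @export
hyper_editing_rate <- function(n_sites, covered_length_mb) {
  if (any(covered_length_mb <= 0)) abort("covered length must be positive")
  n_sites / covered_length_mb
}
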