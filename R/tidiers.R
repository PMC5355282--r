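#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the called sites of an `editing_calls` object
#'
#' @param x An `editing_calls` object.
#' @param ... Unused.
#' @return The called-sites tibble with a `sample_id` column.
#' @export
tidy.editing_calls <- function(x, ...) {
  mutate(x$sites, sample_id = x$sample_id, .before = 1)
}

#' One-row summary of an `editing_calls` object
#'
#' @param x An `editing_calls` object.
#' @param ... Unused.
#' @return Tibble with candidate/called counts, background mismatch rate and
#'   the dominant editing-type fraction.
#' @export
glance.editing_calls <- function(x, ...) {
  n_cand <- x$funnel$n[x$funnel$stage == "candidates"]
  tibble(
    sample_id = x$sample_id,
    n_candidates = if (length(n_cand)) n_cand else 0L,
    n_called = nrow(x$sites),
    background_rate = x$background_rate,
    frac_a_to_g = if (nrow(x$sites) > 0) mean(x$sites$editing_type == "A->G")
                  else NA_real_
  )
}

#' Tidy an edit-group differential-expression table
#'
#' @param x An `edit_group_de` tibble.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.edit_group_de <- function(x, ...) as_tibble(x)

#' One-row summary of an edit-group differential-expression scan
#'
#' @param x An `edit_group_de` tibble.
#' @param ... Unused.
#' @return Tibble `n_genes, n_significant` (at p <= 0.05).
#' @export
glance.edit_group_de <- function(x, ...) {
  tibble(n_genes = nrow(x), n_significant = sum(x$t_p <= 0.05, na.rm = TRUE))
}

#' Plot the filter funnel of an `editing_calls` object
#'
#' @param object An `editing_calls` object.
#' @param ... Unused.
#' @return A ggplot barchart of candidates, per-filter rejections and calls.
#' @export
autoplot.editing_calls <- function(object, ...) {
  f <- mutate(object$funnel, stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sites",
                  title = paste0("Filter funnel: ", object$sample_id)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of editing-type proportions
#'
#' @param sites Sites tibble with `editing_type` (optionally `sample_id` for
#'   faceting).
#' @return A ggplot object.
#' @export
plot_type_proportions <- function(sites) {
  props <- if ("sample_id" %in% names(sites)) {
    sites %>% group_by(.data$sample_id) %>%
      dplyr::count(.data$editing_type) %>%
      mutate(fraction = .data$n / sum(.data$n)) %>% ungroup()
  } else type_proportions(sites)
  p <- ggplot2::ggplot(props, ggplot2::aes(x = stats::reorder(.data$editing_type,
                                                              -.data$fraction),
                                           y = .data$fraction)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "editing type (transcript sense)", y = "fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("sample_id" %in% names(props)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$sample_id))
  }
  p
}

#' Scatter plot of PSI against the editing index
#'
#' @param psi Tibble from [run_editome()]'s `psi` slot (`psi`,
#'   `editing_index` columns).
#' @return A ggplot object with a linear trend.
#' @export
plot_psi_editing <- function(psi) {
  d <- filter(psi, !is.na(.data$psi), !is.na(.data$editing_index))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$editing_index, y = .data$psi)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(x = "editing index", y = "percent spliced in") +
    ggplot2::theme_minimal()
}

#' Per-sample editing rates by tissue
#'
#' @param summary Summary tibble from [run_editome()] (needs `sample_id`,
#'   `editing_rate`).
#' @return A ggplot object.
#' @export
plot_editing_rates <- function(summary) {
  d <- mutate(summary, tissue = sub("^.*_", "", .data$sample_id),
              patient = sub("_.*$", "", .data$sample_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tissue, y = .data$editing_rate)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tissue), size = 2) +
    ggplot2::labs(x = NULL, y = "editing sites / Mb covered") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
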