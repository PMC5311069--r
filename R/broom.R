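# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pre-expansion enrichment result
#'
#' @param x A `tcr_enrichment` object.
#' @param ... Unused.
#' @return The per-bin tibble (`bin`, counts, proportions, `z`, `p`,
#'   `flagged`).
#' @export
tidy.tcr_enrichment <- function(x, ...) x$table

#' One-row summary of a pre-expansion enrichment result
#'
#' @param x A `tcr_enrichment` object.
#' @param ... Unused.
#' @return A tibble with `frac_gt2_expanded`, `frac_gt2_all`,
#'   `n_flagged`, `alpha`.
#' @export
glance.tcr_enrichment <- function(x, ...) {
  tibble::tibble(
    frac_gt2_expanded = x$frac_gt2_expanded,
    frac_gt2_all = x$frac_gt2_all,
    n_flagged = sum(x$table$flagged),
    alpha = x$alpha
  )
}

#' Tidy a usage-null table
#'
#' @param x A `usage_null` tibble.
#' @param ... Unused.
#' @return A plain tibble with `gene`, `mean_freq`, `sd_freq`.
#' @export
tidy.usage_null <- function(x, ...) tibble::as_tibble(unclass(x))

#' One-row summary of a usage-null table
#'
#' @param x A `usage_null` tibble.
#' @param ... Unused.
#' @return A tibble recording the resampling settings.
#' @export
glance.usage_null <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_resamples = attr(x, "n_resamples"),
    sample_size = attr(x, "sample_size"),
    segment = attr(x, "segment"),
    weighting = attr(x, "weighting")
  )
}

#' One-row summary of a gene-skew table
#'
#' @param x A `usage_skew` tibble.
#' @param ... Unused.
#' @return A tibble with flag counts and the band width `k`.
#' @export
glance.usage_skew <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_over = sum(x$flag == "over"),
    n_under = sum(x$flag == "under"),
    k = attr(x, "k")
  )
}

#' One-row summary of a specificity report
#'
#' @param x A `tcr_specificity` tibble.
#' @param ... Unused.
#' @return A tibble with `n_selected`, `n_nonspecific`,
#'   `max_carrier_abundance` (NA when no clone is selected).
#' @export
glance.tcr_specificity <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x),
    n_nonspecific = sum(x$nonspecific),
    max_carrier_abundance = if (nrow(x) > 0) max(x$abundance_carrier) else NA_integer_,
    hi_threshold = attr(x, "hi_threshold"),
    lo_threshold = attr(x, "lo_threshold")
  )
}

#' Tidy a sequence-logo matrix into long format
#'
#' @param x A `logo_matrix` object.
#' @param ... Unused.
#' @return A tibble with `position`, `residue`, `frequency` (zero
#'   frequencies omitted).
#' @export
tidy.logo_matrix <- function(x, ...) tidy_logo(x)
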