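# ggplot2 views of the main result types.

#' Plot the stimulation-index distribution
#'
#' Histogram of SI values, faceted by condition when several are
#' present. The strongly expanded right tail is the antigen-driven
#' signal; the bulk sits at or slightly below 0.
#'
#' @param object A `tcr_si` tibble from [compute_si()].
#' @param bin_width Histogram bin width (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcr_si <- function(object, bin_width = 1, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$si)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "stimulation index (log2 fold change)",
                  y = "clonotypes") +
    ggplot2::theme_minimal()
  if (length(unique(object$condition)) > 1) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}

#' Plot observed gene usage against the resampling null
#'
#' Observed frequency (y) versus null mean (x) per gene, with the
#' mean +/- k SD band; genes outside the band are labelled. Points on
#' the diagonal are used as often in the expanded set as expected from
#' random sampling of the ex vivo repertoire.
#'
#' @param object A `usage_skew` tibble from [flag_skewed_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usage_skew <- function(object, ...) {
  k <- attr(object, "k")
  flagged <- object[object$flag != "ns", , drop = FALSE]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$null_mean, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = pmax(.data$null_mean - k * .data$null_sd, 0),
                   xmax = .data$null_mean + k * .data$null_sd),
      height = 0, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag), size = 2) +
    ggplot2::geom_text(data = flagged, ggplot2::aes(label = .data$gene),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(over = "firebrick",
                                            under = "steelblue", ns = "grey40")) +
    ggplot2::labs(x = "null mean frequency (random draws)",
                  y = "observed frequency (expanded set)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the pre-expansion abundance enrichment
#'
#' Side-by-side per-bin proportions of ex vivo abundance for the
#' expanded set and for all ex vivo clonotypes; bins whose proportions
#' differ at the configured level are starred.
#'
#' @param object A `tcr_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcr_enrichment <- function(object, ...) {
  tab <- object$table
  long <- tidyr::pivot_longer(
    tab, dplyr::all_of(c("prop_expanded", "prop_all")),
    names_to = "set", values_to = "proportion")
  long$set <- ifelse(long$set == "prop_expanded", "expanded", "all ex vivo")
  long$bin <- factor(long$bin, levels = tab$bin)
  stars <- tab[tab$flagged, , drop = FALSE]
  stars$bin <- factor(stars$bin, levels = tab$bin)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$proportion,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = stars,
      ggplot2::aes(x = .data$bin,
                   y = pmax(.data$prop_expanded, .data$prop_all) + 0.02,
                   label = "*"),
      inherit.aes = FALSE, size = 5) +
    ggplot2::scale_fill_manual(values = c("expanded" = "grey25",
                                          "all ex vivo" = "grey70")) +
    ggplot2::labs(x = "ex vivo abundance bin", y = "proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
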