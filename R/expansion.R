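# Stimulation-index computation, expanded-set extraction, cross-condition
# specificity, and pre-expansion abundance enrichment.

#' Per-clonotype stimulation indices
#'
#' The stimulation index (SI) of a clonotype is the log2 of its
#' abundance in the in vitro culture relative to its abundance in the
#' ex vivo baseline -- the number of cell doublings if death is
#' ignored. Clonotypes absent from the ex vivo sample have their
#' baseline abundance imputed as `impute_value` (default 1: a clone
#' observed after proliferation must have started with at least one
#' cell, and ex vivo abundances have median 1). Raw counts are used,
#' not depth-normalized frequencies; set `normalize = TRUE` for a
#' frequency-based SI.
#'
#' @param cultured In vitro repertoire tibble (one condition).
#' @param ex_vivo Ex vivo repertoire tibble of the same chain.
#' @param impute_value Positive baseline value for clonotypes unseen ex
#'   vivo.
#' @param normalize If `TRUE`, abundances are divided by sample totals
#'   before the ratio (off by default).
#' @return A tibble of class `tcr_si`, one row per cultured clonotype:
#'   identity columns, `abundance_in`, `abundance_ex` (0 if absent),
#'   `imputed`, and `si`. Clonotypes present only ex vivo get no row.
#' @examples
#' ex <- as_repertoire(tibble::tibble(
#'   chain = "beta", v_call = "TRBV2", j_call = "TRBJ1-1",
#'   junction = c("TGTGCATTT", "TGTACCTTT"), junction_aa = c("CAF", "CTF"),
#'   duplicate_count = c(1L, 2L)), condition = "ex_vivo")
#' cu <- as_repertoire(tibble::tibble(
#'   chain = "beta", v_call = "TRBV2", j_call = "TRBJ1-1",
#'   junction = c("TGTGCATTT", "TGTCATTTT"), junction_aa = c("CAF", "CHF"),
#'   duplicate_count = c(8L, 4L)), condition = "antigen")
#' compute_si(cu, ex)
#' @export
compute_si <- function(cultured, ex_vivo, impute_value = 1, normalize = FALSE) {
  stopifnot(is.data.frame(cultured), is.data.frame(ex_vivo))
  if (nrow(cultured) == 0) stop("cultured repertoire is empty", call. = FALSE)
  if (impute_value <= 0) stop("impute_value must be positive", call. = FALSE)
  if (!setequal(unique(cultured$chain), unique(ex_vivo$chain))) {
    stop("chain mismatch between cultured and ex vivo repertoires", call. = FALSE)
  }
  ex_tbl <- ex_vivo %>%
    dplyr::select(dplyr::all_of(repertoire_key_cols()),
                  abundance_ex = "duplicate_count")
  out <- cultured %>%
    dplyr::select(dplyr::all_of(c("sample_id", "condition",
                                  repertoire_key_cols(), "junction_aa")),
                  abundance_in = "duplicate_count") %>%
    dplyr::left_join(ex_tbl, by = repertoire_key_cols()) %>%
    dplyr::mutate(
      imputed = is.na(.data$abundance_ex),
      abundance_ex = dplyr::coalesce(.data$abundance_ex, 0L)
    )
  if (normalize) {
    tot_in <- sum(cultured$duplicate_count)
    tot_ex <- sum(ex_vivo$duplicate_count)
    out$si <- log2((out$abundance_in / tot_in) /
                     (pmax(out$abundance_ex, impute_value) / tot_ex))
  } else {
    out$si <- log2(out$abundance_in / pmax(out$abundance_ex, impute_value))
  }
  class(out) <- c("tcr_si", class(out))
  out
}

#' Extract the expanded clonotype set
#'
#' Clonotypes with SI strictly greater than `threshold` (default 3,
#' i.e. an eightfold increase or three divisions).
#'
#' @param si A `tcr_si` tibble from [compute_si()].
#' @param threshold SI cutoff; strict inequality.
#' @return The rows of `si` with `si > threshold`.
#' @export
expanded_clonotypes <- function(si, threshold = 3) {
  stopifnot(is.data.frame(si), "si" %in% names(si))
  si[si$si > threshold, , drop = FALSE]
}

#' Count the expanded set and express it as a fraction of detection
#'
#' Reports the expanded-set size alongside three denominators, since
#' "fraction of TCRs detected" can be read against the cultured sample,
#' the ex vivo sample, or their union of distinct clonotypes.
#'
#' @param si A `tcr_si` tibble.
#' @param ex_vivo The ex vivo repertoire the SI was computed against.
#' @param threshold SI cutoff (strict).
#' @return A one-row tibble: `n_expanded`, `n_cultured`, `n_ex_vivo`,
#'   `n_union`, and the fraction of each denominator.
#' @export
expansion_summary <- function(si, ex_vivo, threshold = 3) {
  n_exp <- nrow(expanded_clonotypes(si, threshold))
  keys_cult <- clonotype_key(si)
  keys_ex <- clonotype_key(ex_vivo)
  n_union <- length(union(keys_cult, keys_ex))
  tibble::tibble(
    n_expanded = n_exp,
    n_cultured = length(keys_cult),
    n_ex_vivo = length(keys_ex),
    n_union = n_union,
    frac_of_cultured = n_exp / length(keys_cult),
    frac_of_ex_vivo = n_exp / length(keys_ex),
    frac_of_union = n_exp / n_union
  )
}

#' Histogram of stimulation indices
#'
#' Half-open bins `[lo, hi)` aligned to multiples of `bin_width`.
#' Counts conserve the number of records.
#'
#' @param si A `tcr_si` tibble (or any data frame with an `si` column).
#' @param bin_width Positive bin width (default 1).
#' @return A tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
si_histogram <- function(si, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  lo <- floor(si$si / bin_width) * bin_width
  tab <- table(lo)
  tibble::tibble(
    bin_lo = as.numeric(names(tab)),
    bin_hi = as.numeric(names(tab)) + bin_width,
    count = as.integer(tab)
  )
}

#' Cross-condition specificity of strongly expanded clonotypes
#'
#' Selects clonotypes strongly expanded in the antigen culture
#' (SI > `hi_threshold`) that are also present in the carrier culture
#' (SI > `lo_threshold`), and reports their abundances in both cultures
#' and ex vivo. A clone whose carrier SI also exceeds `hi_threshold` is
#' flagged `nonspecific`. Antigen-specific expansion shows as high
#' antigen abundance with uniformly low carrier abundance.
#'
#' @param si_antigen,si_carrier `tcr_si` tibbles computed against the
#'   same ex vivo baseline.
#' @param hi_threshold Antigen SI cutoff (default 8, strict).
#' @param lo_threshold Carrier presence cutoff (default 1, strict).
#' @return A tibble of class `tcr_specificity`: identity columns,
#'   `abundance_antigen`, `abundance_carrier`, `abundance_ex`,
#'   `si_antigen`, `si_carrier`, `nonspecific`.
#' @export
specificity_compare <- function(si_antigen, si_carrier,
                                hi_threshold = 8, lo_threshold = 1) {
  sid_a <- unique(si_antigen$sample_id)
  sid_c <- unique(si_carrier$sample_id)
  if (!is.na(sid_a[1]) && !is.na(sid_c[1]) && !setequal(sid_a, sid_c)) {
    stop("SI tables derive from different samples: ",
         paste(sid_a, collapse = ","), " vs ", paste(sid_c, collapse = ","),
         call. = FALSE)
  }
  a <- si_antigen %>%
    dplyr::select(dplyr::all_of(repertoire_key_cols()), "junction_aa",
                  abundance_antigen = "abundance_in",
                  abundance_ex = "abundance_ex", si_antigen = "si")
  b <- si_carrier %>%
    dplyr::select(dplyr::all_of(repertoire_key_cols()),
                  abundance_carrier = "abundance_in", si_carrier = "si")
  out <- a %>%
    dplyr::filter(.data$si_antigen > hi_threshold) %>%
    dplyr::inner_join(b, by = repertoire_key_cols()) %>%
    dplyr::filter(.data$si_carrier > lo_threshold) %>%
    dplyr::mutate(nonspecific = .data$si_carrier > hi_threshold) %>%
    dplyr::arrange(dplyr::desc(.data$abundance_antigen))
  class(out) <- c("tcr_specificity", class(out))
  attr(out, "hi_threshold") <- hi_threshold
  attr(out, "lo_threshold") <- lo_threshold
  out
}

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' `z = (x1/n1 - x2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with pooled
#' `p = (x1+x2)/(n1+n2)`; the p-value comes from the standard normal,
#' no continuity correction. Degenerate tables (pooled proportion 0 or
#' 1) return `z = 0, p = 1`. Vectorized over all four arguments.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return A tibble with columns `z` and `p`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (any(n1 < 1 | n2 < 1) || any(x1 < 0 | x2 < 0) ||
      any(x1 > n1 | x2 > n2)) {
    stop("need 0 <= x <= n and n >= 1 in both groups", call. = FALSE)
  }
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (x1 / n1 - x2 / n2) / se)
  p <- ifelse(se == 0, 1, 2 * stats::pnorm(-abs(z)))
  tibble::tibble(z = z, p = p)
}

#' Pre-expansion abundance enrichment of the expanded set
#'
#' Compares the ex vivo abundance distribution of the expanded
#' clonotypes against that of all ex vivo clonotypes, bin by bin, with
#' a two-proportion z-test per bin (no multiple-testing correction by
#' default, mirroring a per-bin p < alpha readout; set
#' `bonferroni = TRUE` to adjust). Expanded clonotypes unseen ex vivo
#' count in the lowest bin with abundance 0. Also reports the fraction
#' of expanded clonotypes with ex vivo abundance > 2, the headline
#' scalar of a memory-biased response.
#'
#' @param expanded Expanded rows of a `tcr_si` tibble (needs the
#'   identity columns and `abundance_ex`), or any keyed tibble; ex vivo
#'   abundances are looked up from `ex_vivo`.
#' @param ex_vivo Ex vivo repertoire tibble.
#' @param breaks Increasing abundance bin edges; bins are `[lo, hi)`,
#'   and the default integer bins 0..9 end in an overflow bin.
#' @param alpha Per-bin significance level (default 0.01).
#' @param bonferroni Adjust p-values across bins before flagging.
#' @return An object of class `tcr_enrichment`: a list with `table`
#'   (per-bin tibble: `bin`, `n_expanded`, `n_all`, `prop_expanded`,
#'   `prop_all`, `z`, `p`, `flagged`), `frac_gt2_expanded`,
#'   `frac_gt2_all`, `alpha`.
#' @export
abundance_enrichment <- function(expanded, ex_vivo,
                                 breaks = c(0:10, Inf), alpha = 0.01,
                                 bonferroni = FALSE) {
  if (nrow(expanded) == 0) stop("expanded set is empty", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  ex_tbl <- ex_vivo %>%
    dplyr::select(dplyr::all_of(repertoire_key_cols()),
                  abundance_ex_lookup = "duplicate_count")
  exp_ab <- expanded %>%
    dplyr::select(dplyr::all_of(repertoire_key_cols())) %>%
    dplyr::left_join(ex_tbl, by = repertoire_key_cols()) %>%
    dplyr::pull("abundance_ex_lookup")
  exp_ab[is.na(exp_ab)] <- 0L
  all_ab <- ex_vivo$duplicate_count
  bin_of <- function(x) cut(x, breaks = breaks, right = FALSE,
                            include.lowest = TRUE)
  lv <- levels(bin_of(numeric(0)))
  n_exp <- table(factor(bin_of(exp_ab), levels = lv))
  n_all <- table(factor(bin_of(all_ab), levels = lv))
  zt <- two_proportion_ztest(as.integer(n_exp), length(exp_ab),
                             as.integer(n_all), length(all_ab))
  p_flag <- if (bonferroni) stats::p.adjust(zt$p, "bonferroni") else zt$p
  tab <- tibble::tibble(
    bin = lv,
    n_expanded = as.integer(n_exp),
    n_all = as.integer(n_all),
    prop_expanded = as.integer(n_exp) / length(exp_ab),
    prop_all = as.integer(n_all) / length(all_ab),
    z = zt$z,
    p = zt$p,
    flagged = p_flag < alpha
  )
  out <- list(
    table = tab,
    frac_gt2_expanded = mean(exp_ab > 2),
    frac_gt2_all = mean(all_ab > 2),
    alpha = alpha
  )
  class(out) <- "tcr_enrichment"
  out
}

#' @export
print.tcr_enrichment <- function(x, ...) {
  cat("Pre-expansion abundance enrichment\n")
  cat(sprintf("  fraction with ex vivo abundance > 2: expanded %.3f, all %.3f\n",
              x$frac_gt2_expanded, x$frac_gt2_all))
  cat(sprintf("  %d of %d bins flagged at alpha = %g\n",
              sum(x$table$flagged), nrow(x$table), x$alpha))
  print(x$table, ...)
  invisible(x)
}
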