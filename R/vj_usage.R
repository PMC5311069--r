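# V/J gene-usage quantification and resampling null for skew detection.

# Gene-level label: strip any allele suffix ("*01") so usage is compared at
# gene, not allele, resolution.
trim_allele <- function(gene) sub("\\*.*$", "", gene)

#' Gene-usage frequencies of a clonotype set
#'
#' Frequency of each V (or J) gene among the input clonotypes. By
#' default each distinct clonotype counts once (a clonal expansion is
#' one receptor); `weight = "abundance"` weights by `duplicate_count`.
#' Allele suffixes are trimmed before counting.
#'
#' @param x A repertoire or keyed tibble with `v_call`/`j_call` (and
#'   `duplicate_count` if abundance weighting is requested).
#' @param segment `"V"` or `"J"`.
#' @param weight `"clonotype"` (default) or `"abundance"`.
#' @return A tibble with `gene`, `n` (weight mass) and `frequency`
#'   (sums to 1), sorted by gene.
#' @export
gene_frequency <- function(x, segment = c("V", "J"),
                           weight = c("clonotype", "abundance")) {
  segment <- match.arg(segment)
  weight <- match.arg(weight)
  if (nrow(x) == 0) stop("empty clonotype set has no gene usage", call. = FALSE)
  gene <- trim_allele(if (segment == "V") x$v_call else x$j_call)
  w <- if (weight == "abundance") x$duplicate_count else base::rep(1, length(gene))
  out <- tibble::tibble(gene = gene, w = w) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(n = sum(.data$w), .groups = "drop") %>%
    dplyr::mutate(frequency = .data$n / sum(.data$n)) %>%
    dplyr::arrange(.data$gene)
  out
}

# Draw `size` clonotype occurrences from a repertoire. "abundance"
# weighting draws cells without replacement (multivariate hypergeometric,
# realized by sampling the expanded cell index vector); "uniform" draws
# distinct clonotypes uniformly without replacement.
draw_occurrences <- function(rep, size, weighting = c("abundance", "uniform")) {
  weighting <- match.arg(weighting)
  if (weighting == "abundance") {
    total <- sum(rep$duplicate_count)
    if (size > total) {
      stop("sample_size exceeds total ex vivo abundance", call. = FALSE)
    }
    cells <- base::rep.int(seq_len(nrow(rep)), rep$duplicate_count)
    idx <- sample(cells, size)
  } else {
    if (size > nrow(rep)) {
      stop("sample_size exceeds number of distinct clonotypes", call. = FALSE)
    }
    idx <- sample.int(nrow(rep), size)
  }
  rep[idx, , drop = FALSE]
}

#' Resampling null distribution of gene usage
#'
#' Estimates the sampling variability of gene-usage frequencies for a
#' set of a given size drawn at random from the ex vivo repertoire:
#' `n_resamples` equal-sized random samples are taken (by default
#' abundance-weighted without replacement, i.e. drawing cells), gene
#' frequencies computed per resample, and the per-gene mean and SD
#' across resamples returned. A gene-usage value outside mean ± k·SD
#' is then flagged by [flag_skewed_genes()].
#'
#' @param ex_vivo Ex vivo repertoire tibble.
#' @param sample_size Size of each resample (typically the expanded-set
#'   size).
#' @param segment `"V"` or `"J"`.
#' @param n_resamples Number of resamples (default 100).
#' @param weighting `"abundance"` (default; draws cells) or
#'   `"uniform"` (draws distinct clonotypes).
#' @param seed Optional seed.
#' @return A tibble of class `usage_null` with `gene`, `mean_freq`,
#'   `sd_freq`; attributes record `n_resamples`, `sample_size`,
#'   `segment` and `weighting`.
#' @export
resample_usage_null <- function(ex_vivo, sample_size, segment = c("V", "J"),
                                n_resamples = 100,
                                weighting = c("abundance", "uniform"),
                                seed = NULL) {
  segment <- match.arg(segment)
  weighting <- match.arg(weighting)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(ex_vivo) == 0) stop("ex vivo repertoire is empty", call. = FALSE)
  if (sample_size < 1) stop("sample_size must be >= 1", call. = FALSE)
  genes <- sort(unique(trim_allele(
    if (segment == "V") ex_vivo$v_call else ex_vivo$j_call)))
  freqs <- matrix(0, nrow = n_resamples, ncol = length(genes),
                  dimnames = list(NULL, genes))
  for (i in seq_len(n_resamples)) {
    gf <- gene_frequency(draw_occurrences(ex_vivo, sample_size, weighting),
                         segment = segment)
    freqs[i, gf$gene] <- gf$frequency
  }
  out <- tibble::tibble(
    gene = genes,
    mean_freq = unname(colMeans(freqs)),
    sd_freq = unname(apply(freqs, 2, stats::sd))
  )
  class(out) <- c("usage_null", class(out))
  attr(out, "n_resamples") <- n_resamples
  attr(out, "sample_size") <- sample_size
  attr(out, "segment") <- segment
  attr(out, "weighting") <- weighting
  out
}

#' Flag genes over/under-represented relative to the resampling null
#'
#' A gene is flagged `over` if its observed frequency exceeds the null
#' mean + k·SD, `under` if it falls below mean − k·SD (default k = 2).
#' Fold enrichment is observed/mean; when the null mean is 0 the fold
#' is not estimable and reported `NA`.
#'
#' @param observed A [gene_frequency()] tibble for the set under test.
#' @param null A [resample_usage_null()] tibble. Genes missing from
#'   either side enter with frequency 0.
#' @param k Band half-width in SDs (default 2).
#' @return A tibble of class `usage_skew`: `gene`, `observed`,
#'   `null_mean`, `null_sd`, `flag` (`"over"`, `"under"`, `"ns"`),
#'   `fold`.
#' @export
flag_skewed_genes <- function(observed, null, k = 2) {
  merged <- dplyr::full_join(
    dplyr::select(observed, "gene", observed = "frequency"),
    dplyr::select(tibble::as_tibble(null), "gene",
                  null_mean = "mean_freq", null_sd = "sd_freq"),
    by = "gene"
  ) %>%
    dplyr::mutate(
      observed = dplyr::coalesce(.data$observed, 0),
      null_mean = dplyr::coalesce(.data$null_mean, 0),
      null_sd = dplyr::coalesce(.data$null_sd, 0),
      flag = dplyr::case_when(
        .data$observed > .data$null_mean + k * .data$null_sd ~ "over",
        .data$observed < .data$null_mean - k * .data$null_sd ~ "under",
        TRUE ~ "ns"
      ),
      fold = ifelse(.data$null_mean > 0, .data$observed / .data$null_mean, NA_real_)
    ) %>%
    dplyr::arrange(.data$gene)
  class(merged) <- c("usage_skew", class(merged))
  attr(merged, "k") <- k
  merged
}
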