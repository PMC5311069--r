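# End-to-end orchestration: from a stacked experiment table (or manifest)
# to a report bundle with every analysis stage's output.

#' Analysis configuration
#'
#' Bundles the tunable thresholds of the full pipeline with the
#' defaults used throughout: SI imputation 1, expansion cutoff SI > 3,
#' specificity cutoffs SI > 8 (antigen) with presence SI > 1 (carrier),
#' per-bin enrichment test at alpha = 0.01, 100 usage resamples with a
#' mean +/- 2 SD band, Ward.D2 clustering, 100 random draws for the
#' diversity comparison.
#'
#' @param impute_value Baseline abundance imputed for clonotypes unseen
#'   ex vivo.
#' @param si_threshold Expanded-set SI cutoff (strict).
#' @param hi_threshold,lo_threshold Specificity cutoffs.
#' @param enrichment_breaks Abundance bin edges for the enrichment test.
#' @param alpha Per-bin significance level.
#' @param n_resamples Usage-null resamples.
#' @param k Usage-null band half-width in SDs.
#' @param cluster_method `"ward.D2"` or `"ward.D"`.
#' @param n_diversity_samples Random draws for the diversity comparison.
#' @param seed Seed for the resampling stages.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(impute_value = 1,
                            si_threshold = 3,
                            hi_threshold = 8,
                            lo_threshold = 1,
                            enrichment_breaks = c(0:10, Inf),
                            alpha = 0.01,
                            n_resamples = 100,
                            k = 2,
                            cluster_method = "ward.D2",
                            n_diversity_samples = 100,
                            seed = 1L) {
  stopifnot(is.finite(si_threshold) || si_threshold == Inf,
            alpha > 0, alpha < 1, impute_value > 0)
  cfg <- list(impute_value = impute_value, si_threshold = si_threshold,
              hi_threshold = hi_threshold, lo_threshold = lo_threshold,
              enrichment_breaks = enrichment_breaks, alpha = alpha,
              n_resamples = n_resamples, k = k,
              cluster_method = cluster_method,
              n_diversity_samples = n_diversity_samples, seed = seed)
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the full expansion analysis
#'
#' Per chain: computes SI for every cultured condition against the ex
#' vivo baseline, extracts the antigen-expanded set, compares antigen
#' vs carrier specificity, tests pre-expansion abundance enrichment,
#' flags skewed V and J genes against the resampling null, clusters
#' the expanded CDR3s, aligns the family of the most abundant expanded
#' clonotype, and compares expanded diversity to random draws. All
#' stages are deterministic given `config$seed`.
#'
#' @param experiment Either a stacked repertoire tibble (as produced by
#'   [make_paired_experiment()]`$repertoires` or [load_experiment()])
#'   containing an `ex_vivo` condition, or a manifest path.
#' @param config An [analysis_config()] list.
#' @param output_dir If given, every stage's table is written there as
#'   TSV (plus Newick trees and a gapped FASTA alignment).
#' @return A list of class `tcr_report`: `summary` (per chain and
#'   condition expanded counts with the three detection-fraction
#'   denominators), `si`, `expanded`, `specificity`, `enrichment`,
#'   `usage`, `clusters`, `msa`, `logo`, `diversity`, `config`.
#' @export
run_analysis <- function(experiment, config = analysis_config(),
                         output_dir = NULL) {
  if (is.character(experiment)) experiment <- load_experiment(experiment)
  stopifnot(is.data.frame(experiment))
  if (!"ex_vivo" %in% experiment$condition) {
    stop("experiment has no ex_vivo condition", call. = FALSE)
  }
  set.seed(config$seed)
  chain_set <- sort(unique(experiment$chain))
  res <- list(si = list(), expanded = list(), specificity = list(),
              enrichment = list(), usage = list(), clusters = list(),
              msa = list(), logo = list(), diversity = list())
  summary_rows <- list()
  for (ch in chain_set) {
    chain_tbl <- experiment[experiment$chain == ch, , drop = FALSE]
    ex <- chain_tbl[chain_tbl$condition == "ex_vivo", , drop = FALSE]
    cultured_conds <- setdiff(intersect(conditions(),
                                        unique(chain_tbl$condition)),
                              "ex_vivo")
    si_by_cond <- list()
    for (cond in cultured_conds) {
      cu <- chain_tbl[chain_tbl$condition == cond, , drop = FALSE]
      if (nrow(cu) == 0) next
      si_by_cond[[cond]] <- compute_si(cu, ex, impute_value = config$impute_value)
      smry <- expansion_summary(si_by_cond[[cond]], ex, config$si_threshold)
      summary_rows[[paste(ch, cond)]] <- dplyr::bind_cols(
        tibble::tibble(chain = ch, condition = cond), smry)
    }
    res$si[[ch]] <- dplyr::bind_rows(si_by_cond)
    if (is.null(si_by_cond$antigen)) next
    expanded <- expanded_clonotypes(si_by_cond$antigen, config$si_threshold)
    res$expanded[[ch]] <- expanded
    if (!is.null(si_by_cond$carrier)) {
      res$specificity[[ch]] <- specificity_compare(
        si_by_cond$antigen, si_by_cond$carrier,
        hi_threshold = config$hi_threshold, lo_threshold = config$lo_threshold)
    }
    if (nrow(expanded) > 0) {
      res$enrichment[[ch]] <- abundance_enrichment(
        expanded, ex, breaks = config$enrichment_breaks, alpha = config$alpha)
      for (seg in c("V", "J")) {
        null <- resample_usage_null(ex, nrow(expanded), segment = seg,
                                    n_resamples = config$n_resamples)
        skew <- flag_skewed_genes(gene_frequency(expanded, segment = seg),
                                  null, k = config$k)
        res$usage[[paste0(ch, "_", seg)]] <- skew
      }
    }
    if (nrow(expanded) >= 2) {
      labels <- make.unique(expanded$junction_aa, sep = "#")
      dm <- cdr3_distance_matrix(expanded$junction_aa, labels = labels)
      tree <- cdr3_cluster(dm, method = config$cluster_method)
      res$clusters[[ch]] <- tree
      anchor <- labels[which.max(expanded$abundance_in)]
      fam <- extract_family(tree, anchor, max_size = max(3, ceiling(nrow(expanded) / 4)))
      if (length(fam) >= 2) {
        fam_seqs <- stats::setNames(base::sub("#.*$", "", fam), fam)
        msa <- center_star_msa(fam_seqs, center = anchor)
        res$msa[[ch]] <- msa
        res$logo[[ch]] <- logo_matrix(msa)
      }
      res$diversity[[ch]] <- dplyr::bind_cols(
        tibble::tibble(chain = ch),
        diversity_vs_random(expanded$junction_aa, ex,
                            n_samples = config$n_diversity_samples))
    }
  }
  res$summary <- dplyr::bind_rows(summary_rows)
  res$config <- config
  class(res) <- "tcr_report"
  if (!is.null(output_dir)) write_report(res, output_dir)
  res
}

#' @export
print.tcr_report <- function(x, ...) {
  cat("TCR clonal expansion report\n")
  n_exp <- sum(x$summary$n_expanded[x$summary$condition == "antigen"])
  cat(sprintf("  expanded clonotypes (SI > %g, antigen, all chains): %d\n",
              x$config$si_threshold, n_exp))
  print(x$summary, ...)
  invisible(x)
}

#' Write every stage of a report to disk
#'
#' TSV per stage, Newick for trees, gapped FASTA for alignments. File
#' contents are a pure function of the report, so identical analyses
#' yield byte-identical output directories.
#'
#' @param report A `tcr_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  wt(report$summary, "summary.tsv")
  for (ch in names(report$si)) wt(report$si[[ch]], paste0("si_", ch, ".tsv"))
  for (ch in names(report$expanded)) {
    wt(report$expanded[[ch]], paste0("expanded_", ch, ".tsv"))
  }
  for (ch in names(report$specificity)) {
    wt(report$specificity[[ch]], paste0("specificity_", ch, ".tsv"))
  }
  for (ch in names(report$enrichment)) {
    wt(report$enrichment[[ch]]$table, paste0("enrichment_", ch, ".tsv"))
  }
  for (nm in names(report$usage)) wt(report$usage[[nm]], paste0("usage_", nm, ".tsv"))
  for (ch in names(report$clusters)) {
    cluster_newick(report$clusters[[ch]],
                   path = file.path(dir, paste0("tree_", ch, ".nwk")))
  }
  for (ch in names(report$msa)) {
    msa <- report$msa[[ch]]
    fasta <- paste0(">", names(msa), "\n", msa, collapse = "\n")
    writeLines(fasta, file.path(dir, paste0("msa_", ch, ".fasta")))
  }
  for (ch in names(report$logo)) {
    lm <- report$logo[[ch]]
    wt(tidy_logo(lm), paste0("logo_", ch, ".tsv"))
  }
  if (length(report$diversity) > 0) {
    wt(dplyr::bind_rows(report$diversity), "diversity.tsv")
  }
  invisible(dir)
}

tidy_logo <- function(x) {
  tibble::tibble(
    position = base::rep(seq_len(x$length), ncol(x$freq)),
    residue = base::rep(colnames(x$freq), each = x$length),
    frequency = as.vector(x$freq)
  ) %>%
    dplyr::filter(.data$frequency > 0) %>%
    dplyr::arrange(.data$position, dplyr::desc(.data$frequency), .data$residue)
}
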