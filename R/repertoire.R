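#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Column sets for the AIRR-style clonotype table dialect.
#
# `junction` is the CDR3 nucleotide sequence, `junction_aa` its translation,
# `duplicate_count` the UMI-corrected molecule count, following the AIRR
# Rearrangement column vocabulary.
repertoire_key_cols <- function() c("chain", "v_call", "j_call", "junction")

repertoire_cols <- function() {
  c("sample_id", "condition", "chain", "v_call", "j_call",
    "junction", "junction_aa", "duplicate_count")
}

conditions <- function() c("ex_vivo", "medium", "carrier", "antigen")
chains <- function() c("alpha", "beta")

#' Coerce and validate a clonotype table
#'
#' A *repertoire* is a tibble of clonotypes, one row per distinct
#' `(chain, v_call, j_call, junction)` identity key, with a positive
#' UMI count in `duplicate_count`. `as_repertoire()` validates column
#' presence and types, drops zero-count rows (an unobserved clonotype is
#' represented by absence), and collapses duplicate identity keys by
#' summing their counts. Collapsing is idempotent and conserves total
#' abundance.
#'
#' @param x A data frame with at least the columns `chain`, `v_call`,
#'   `j_call`, `junction` and `duplicate_count`. `junction_aa`,
#'   `sample_id` and `condition` are carried if present.
#' @param sample_id,condition Optional values used to fill the
#'   corresponding columns when absent from `x`.
#' @return A tibble with columns `sample_id`, `condition`, `chain`,
#'   `v_call`, `j_call`, `junction`, `junction_aa`, `duplicate_count`,
#'   collapsed on the identity key.
#' @examples
#' df <- tibble::tibble(
#'   chain = "beta", v_call = "TRBV1", j_call = "TRBJ1",
#'   junction = c("TGTGCA", "TGTGCA", "TGTACC"),
#'   junction_aa = c("CA", "CA", "CT"),
#'   duplicate_count = c(2L, 3L, 1L)
#' )
#' as_repertoire(df, sample_id = "s1", condition = "ex_vivo")
#' @export
as_repertoire <- function(x, sample_id = NULL, condition = NULL) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  needed <- setdiff(repertoire_key_cols(), names(x))
  if (length(needed) > 0 || !"duplicate_count" %in% names(x)) {
    stop("missing mandatory column(s): ",
         paste(c(needed, setdiff("duplicate_count", names(x))), collapse = ", "),
         call. = FALSE)
  }
  if (!"junction_aa" %in% names(x)) x$junction_aa <- NA_character_
  if (!"sample_id" %in% names(x)) {
    x$sample_id <- if (is.null(sample_id)) NA_character_ else sample_id
  } else if (!is.null(sample_id)) {
    x$sample_id <- sample_id
  }
  if (!"condition" %in% names(x)) {
    x$condition <- if (is.null(condition)) NA_character_ else condition
  } else if (!is.null(condition)) {
    x$condition <- condition
  }
  cond <- unique(x$condition[!is.na(x$condition)])
  bad <- setdiff(cond, conditions())
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_chain <- setdiff(unique(x$chain), chains())
  if (length(bad_chain) > 0) {
    stop("unknown chain label(s): ", paste(bad_chain, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(x$duplicate_count) || any(x$duplicate_count %% 1 != 0) ||
      any(x$duplicate_count < 0)) {
    stop("duplicate_count must be a non-negative integer", call. = FALSE)
  }
  # aa length x 3 must equal nt length whenever both are given
  has_aa <- !is.na(x$junction_aa)
  if (any(has_aa & nchar(x$junction_aa) * 3L != nchar(x$junction))) {
    stop("junction_aa length x 3 does not match junction length", call. = FALSE)
  }
  x <- x[x$duplicate_count > 0, , drop = FALSE]
  x$duplicate_count <- as.integer(round(x$duplicate_count))
  collapse_clonotypes(x[, repertoire_cols()])
}

# Sum duplicate_count over rows sharing an identity key. Non-key metadata
# (sample_id, condition, junction_aa) is taken from the first row of each key.
collapse_clonotypes <- function(x) {
  x %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(repertoire_key_cols()))) %>%
    dplyr::summarise(
      sample_id = dplyr::first(.data$sample_id),
      condition = dplyr::first(.data$condition),
      junction_aa = dplyr::first(.data$junction_aa),
      duplicate_count = sum(.data$duplicate_count),
      .groups = "drop"
    ) %>%
    dplyr::select(dplyr::all_of(repertoire_cols())) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(repertoire_key_cols())))
}

#' Read a clonotype table from a tab-separated file
#'
#' Reads one sample/condition repertoire from an AIRR-style TSV with
#' columns `chain`, `v_call`, `j_call`, `junction`, optional
#' `junction_aa`, and `duplicate_count`. Rows with count 0 are dropped,
#' duplicate identity keys are collapsed by summing counts.
#'
#' @param path Path to a TSV file.
#' @param condition Optional condition label (`ex_vivo`, `medium`,
#'   `carrier` or `antigen`) overriding/filling the file's column.
#' @param sample_id Optional sample identifier, as for `condition`.
#' @param strict If `TRUE` (default) malformed rows (e.g. non-integer
#'   counts) abort with an error; if `FALSE` they are dropped with a
#'   warning.
#' @return A repertoire tibble (see [as_repertoire()]).
#' @export
read_repertoire <- function(path, condition = NULL, sample_id = NULL,
                            strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  needed <- c(repertoire_key_cols(), "duplicate_count")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("file ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_raw <- suppressWarnings(as.numeric(x$duplicate_count))
  bad <- is.na(n_raw) | n_raw %% 1 != 0 | n_raw < 0
  if (any(bad)) {
    if (strict) {
      stop("non-integer duplicate_count in ", path, " (",
           sum(bad), " row(s)); use strict = FALSE to skip", call. = FALSE)
    }
    warning(sum(bad), " malformed row(s) skipped in ", path, call. = FALSE)
    x <- x[!bad, , drop = FALSE]
    n_raw <- n_raw[!bad]
  }
  x$duplicate_count <- as.integer(n_raw)
  if (nrow(x) == 0) warning("empty repertoire read from ", path, call. = FALSE)
  as_repertoire(x, sample_id = sample_id, condition = condition)
}

#' Write a repertoire to a tab-separated file
#'
#' Inverse of [read_repertoire()]: `read_repertoire(write_repertoire(r))`
#' recovers `r` exactly for any collapsed repertoire.
#'
#' @param rep A repertoire tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(is.data.frame(rep))
  readr::write_tsv(rep[, intersect(repertoire_cols(), names(rep))], path,
                   progress = FALSE)
  invisible(path)
}

#' Relative clonotype frequencies
#'
#' Appends a `frequency` column, `duplicate_count / sum(duplicate_count)`.
#' Frequencies sum to 1.
#'
#' @param rep A non-empty repertoire tibble.
#' @return The input tibble with a `frequency` column.
#' @export
clonotype_frequencies <- function(rep) {
  stopifnot(is.data.frame(rep))
  if (nrow(rep) == 0) stop("empty repertoire has no frequencies", call. = FALSE)
  dplyr::mutate(rep, frequency = .data$duplicate_count / sum(.data$duplicate_count))
}

#' Clonotype identity keys as strings
#'
#' Collapses the identity columns `(chain, v_call, j_call, junction)`
#' into one pipe-separated string per row, convenient for set operations.
#'
#' @param x A data frame holding the identity columns.
#' @return A character vector of keys.
#' @export
clonotype_key <- function(x) {
  paste(x$chain, x$v_call, x$j_call, x$junction, sep = "|")
}

#' Read a manifest of repertoire files
#'
#' A manifest is a TSV with columns `sample_id`, `condition`, `chain`,
#' `path` pointing at one repertoire file per row. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with one row per repertoire file.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  needed <- c("sample_id", "condition", "chain", "path")
  if (!all(needed %in% names(m))) {
    stop("manifest needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load all repertoires named by a manifest into one table
#'
#' @param manifest A manifest tibble from [read_manifest()] (or a path).
#' @param strict Passed to [read_repertoire()].
#' @return A single tibble stacking all repertoires, one row per
#'   clonotype per sample/condition/chain.
#' @export
load_experiment <- function(manifest, strict = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  purrr::pmap(manifest, function(sample_id, condition, chain, path) {
    r <- read_repertoire(path, condition = condition, sample_id = sample_id,
                         strict = strict)
    r[r$chain == chain, , drop = FALSE]
  }) %>%
    dplyr::bind_rows()
}
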