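# CDR3 amino-acid sequence similarity: Levenshtein distances, Ward
# clustering, family extraction, center-star alignment, sequence logos,
# and diversity comparison against random draws.

#' Levenshtein distance between sequence pairs
#'
#' Unit-cost edit distance (substitution, insertion, deletion each cost
#' 1). Vectorized elementwise over two equal-length vectors, with the
#' usual recycling of a length-1 argument.
#'
#' @param a,b Character vectors of sequences (empty strings allowed).
#' @return An integer vector of distances.
#' @examples
#' levenshtein_distance("kitten", "sitting")  # 3
#' @export
levenshtein_distance <- function(a, b) {
  if (length(a) == 1) a <- base::rep(a, length(b))
  if (length(b) == 1) b <- base::rep(b, length(a))
  stopifnot(length(a) == length(b))
  as.integer(mapply(function(x, y) utils::adist(x, y)[1, 1], a, b,
                    USE.NAMES = FALSE))
}

#' Pairwise Levenshtein distance matrix
#'
#' Symmetric integer matrix of unit-cost edit distances with zero
#' diagonal. Duplicate sequences are kept (distance-0 pairs): distinct
#' clonal events with the same amino-acid CDR3 remain separate leaves.
#'
#' @param seqs Character vector (length >= 2) of CDR3 amino-acid
#'   sequences.
#' @param labels Row/column labels; default the sequences themselves,
#'   disambiguated with [make.unique()].
#' @return A labelled symmetric integer matrix.
#' @export
cdr3_distance_matrix <- function(seqs, labels = NULL) {
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(labels)) labels <- make.unique(seqs, sep = "#")
  if (anyDuplicated(labels) > 0) stop("labels must be unique", call. = FALSE)
  dm <- utils::adist(seqs)
  dimnames(dm) <- list(labels, labels)
  storage.mode(dm) <- "integer"
  dm
}

#' Hierarchical clustering of a CDR3 distance matrix
#'
#' Agglomerative clustering with the Ward criterion (default
#' `"ward.D2"`; `"ward.D"` available for the classical variant). Rows
#' are sorted by label before clustering, so the result is a pure
#' function of the labelled distances, independent of input order.
#'
#' @param dm A symmetric distance matrix from [cdr3_distance_matrix()].
#' @param method `"ward.D2"` or `"ward.D"`.
#' @return A [stats::hclust] tree.
#' @export
cdr3_cluster <- function(dm, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  ord <- order(rownames(dm))
  dm <- dm[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(dm), method = method)
}

#' Export a cluster tree as a Newick string
#'
#' @param tree A [stats::hclust] tree.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to a file.
#' @export
cluster_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

# For each internal node of an hclust tree, the set of leaf indices below it.
node_leaves <- function(tree) {
  n <- nrow(tree$merge)
  leaves <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- tree$merge[i, ]
    leaves[[i]] <- unlist(lapply(kids, function(k) {
      if (k < 0) -k else leaves[[k]]
    }))
  }
  leaves
}

#' Extract the family (subtree) containing an anchor sequence
#'
#' Walks up the merge tree from the anchor leaf and returns the leaves
#' of the largest enclosing subtree that still satisfies the
#' constraint: all merge heights at most `h` (cut-height mode) or at
#' most `max_size` leaves (size mode). Exactly one of `h`/`max_size`
#' must be given. The anchor is always included.
#'
#' @param tree A [stats::hclust] tree with labels.
#' @param anchor A leaf label.
#' @param h Cut height.
#' @param max_size Maximum number of leaves.
#' @return Character vector of leaf labels in the anchor's family.
#' @export
extract_family <- function(tree, anchor, h = NULL, max_size = NULL) {
  if (is.null(h) == is.null(max_size)) {
    stop("give exactly one of h or max_size", call. = FALSE)
  }
  li <- match(anchor, tree$labels)
  if (is.na(li)) stop("unknown anchor label: ", anchor, call. = FALSE)
  leaves <- node_leaves(tree)
  best <- li  # leaf-only family
  for (i in seq_len(nrow(tree$merge))) {
    if (!li %in% leaves[[i]]) next
    ok <- if (!is.null(h)) tree$height[i] <= h else length(leaves[[i]]) <= max_size
    if (ok) best <- leaves[[i]] else break
  }
  tree$labels[sort(unique(best))]
}

# Global pairwise alignment with unit costs (Needleman-Wunsch on edit
# distance). Deterministic tie-break: diagonal, then gap in `b` (consume a),
# then gap in `a`. Returns the two gapped strings; the number of mismatched
# or gapped columns equals the Levenshtein distance.
align_pair <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    prev <- D[i, ]
    cur <- D[i + 1, ]
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (av[i] != bv[j]), prev[j + 1] + 1L,
                        cur[j] + 1L)
    }
    D[i + 1, ] <- cur
  }
  # traceback
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i + 1, j + 1] == D[i, j] + (av[i] != bv[j])) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1L) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       edits = D[n + 1, m + 1])
}

#' Center-star multiple sequence alignment
#'
#' Aligns every sequence to a center sequence with unit-cost global
#' pairwise alignments and merges the pairwise gap patterns into one
#' multiple alignment. Suited to near-identical short CDR3s; the center
#' should be the family's most abundant member. De-gapping any row
#' recovers its input sequence exactly.
#'
#' @param seqs Named or unnamed character vector (length >= 2).
#' @param center Index or name of the center sequence (default 1).
#' @return A character vector of equal-length gapped rows, in input
#'   order, named like `seqs`.
#' @export
center_star_msa <- function(seqs, center = 1) {
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.character(center)) center <- match(center, names(seqs))
  if (is.na(center) || center < 1 || center > length(seqs)) {
    stop("unknown center sequence", call. = FALSE)
  }
  c_seq <- seqs[[center]]
  others <- setdiff(seq_along(seqs), center)
  # master gapped center, plus each row aligned to it
  master <- strsplit(c_seq, "")[[1]]
  rows <- list()
  for (k in others) {
    al <- align_pair(c_seq, seqs[[k]])
    ca <- strsplit(al$a, "")[[1]]
    sa <- strsplit(al$b, "")[[1]]
    # merge ca (center with new gaps) into master; track insert positions
    new_master <- character(0)
    new_rows <- lapply(rows, function(r) character(0))
    new_cur <- character(0)
    i <- 1; j <- 1
    while (i <= length(master) || j <= length(ca)) {
      mi <- if (i <= length(master)) master[i] else NULL
      cj <- if (j <= length(ca)) ca[j] else NULL
      if (!is.null(mi) && mi == "-" && (is.null(cj) || cj != "-")) {
        # master has a gap the new alignment lacks: pad new row
        new_master <- c(new_master, "-")
        new_rows <- lapply(seq_along(rows), function(r) c(new_rows[[r]], rows[[r]][i]))
        new_cur <- c(new_cur, "-")
        i <- i + 1
      } else if (!is.null(cj) && cj == "-" && (is.null(mi) || mi != "-")) {
        # new alignment inserts a gap into the center: pad old rows
        new_master <- c(new_master, "-")
        new_rows <- lapply(seq_along(rows), function(r) c(new_rows[[r]], "-"))
        new_cur <- c(new_cur, sa[j])
        j <- j + 1
      } else {
        new_master <- c(new_master, mi)
        new_rows <- lapply(seq_along(rows), function(r) c(new_rows[[r]], rows[[r]][i]))
        new_cur <- c(new_cur, sa[j])
        i <- i + 1; j <- j + 1
      }
    }
    master <- new_master
    rows <- c(new_rows, list(new_cur))
  }
  out <- character(length(seqs))
  out[center] <- paste(master, collapse = "")
  for (k in seq_along(others)) {
    out[others[k]] <- paste(rows[[k]], collapse = "")
  }
  names(out) <- names(seqs)
  out
}

#' Position frequency matrix (sequence logo) of an alignment
#'
#' Per-position relative frequencies over the 20 amino acids plus the
#' gap character, with the per-position information content
#' `log2(21) - entropy` (bits) reported alongside.
#'
#' @param alignment Character vector of equal-length gapped rows.
#' @return A list of class `logo_matrix`: `freq` (positions x residues
#'   matrix, rows sum to 1), `info` (per-position bits), `length`.
#' @export
logo_matrix <- function(alignment) {
  if (length(alignment) == 0) stop("empty alignment", call. = FALSE)
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("alignment rows have unequal lengths", call. = FALSE)
  alphabet <- c(amino_acids(), "-")
  chars <- do.call(rbind, strsplit(alignment, ""))
  freq <- t(apply(chars, 2, function(col) {
    tab <- table(factor(col, levels = alphabet))
    as.numeric(tab) / length(col)
  }))
  colnames(freq) <- alphabet
  rownames(freq) <- seq_len(L)
  ent <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  out <- list(freq = freq, info = log2(length(alphabet)) - ent, length = L)
  class(out) <- "logo_matrix"
  out
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("Sequence logo matrix:", x$length, "positions\n")
  consensus <- colnames(x$freq)[apply(x$freq, 1, which.max)]
  cat("consensus:", paste(consensus, collapse = ""), "\n")
  invisible(x)
}

#' Mean pairwise Levenshtein distance of a sequence set
#'
#' Arithmetic mean over all unordered pairs (each pair once).
#'
#' @param seqs Character vector, length >= 2.
#' @return A single number.
#' @export
mean_pairwise_distance <- function(seqs) {
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  dm <- utils::adist(seqs)
  mean(dm[upper.tri(dm)])
}

#' Diversity of the expanded set versus random ex vivo draws
#'
#' Compares the mean pairwise CDR3 distance of the expanded set against
#' the distribution of the same statistic over `n_samples` equal-sized
#' random draws of distinct clonotypes from the ex vivo repertoire. A
#' strongly family-structured expanded set sits below the random band;
#' a diverse response sits only slightly below it.
#'
#' @param expanded_seqs CDR3 amino-acid sequences of the expanded set
#'   (length >= 2).
#' @param ex_vivo Ex vivo repertoire tibble (needs `junction_aa`).
#' @param n_samples Number of random draws (default 100).
#' @param weighting `"clonotype"` (default) samples distinct clonotypes
#'   uniformly; `"abundance"` draws cells.
#' @param seed Optional seed.
#' @return A one-row tibble of class `tcr_diversity`: `expanded_mean`,
#'   `random_mean`, `random_sd`, `z`, `n_expanded`, `n_samples`.
#' @export
diversity_vs_random <- function(expanded_seqs, ex_vivo, n_samples = 100,
                                weighting = c("clonotype", "abundance"),
                                seed = NULL) {
  weighting <- match.arg(weighting)
  if (!is.null(seed)) set.seed(seed)
  if (length(expanded_seqs) < 2) stop("need >= 2 expanded sequences", call. = FALSE)
  if (nrow(ex_vivo) < length(expanded_seqs)) {
    stop("ex vivo repertoire smaller than the expanded set", call. = FALSE)
  }
  obs <- mean_pairwise_distance(expanded_seqs)
  rnd <- vapply(seq_len(n_samples), function(i) {
    draw <- draw_occurrences(ex_vivo, length(expanded_seqs),
                             weighting = if (weighting == "abundance")
                               "abundance" else "uniform")
    mean_pairwise_distance(draw$junction_aa)
  }, numeric(1))
  rsd <- stats::sd(rnd)
  out <- tibble::tibble(
    expanded_mean = obs,
    random_mean = mean(rnd),
    random_sd = rsd,
    z = if (is.na(rsd) || rsd == 0) 0 else (obs - mean(rnd)) / rsd,
    n_expanded = length(expanded_seqs),
    n_samples = n_samples
  )
  class(out) <- c("tcr_diversity", class(out))
  out
}
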