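# Independent oracles and small fixture builders used across the suite.

# Levenshtein distance straight from the recursive definition (exponential;
# only for short strings).
lev_recursive <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_recursive(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost,
      lev_recursive(substr(a, 2, nchar(a)), b) + 1L,
      lev_recursive(a, substr(b, 2, nchar(b))) + 1L)
}

# All strings over `alphabet` of length 0..maxlen, grouped by length.
# Within length L, string i appends alphabet[(i - 1) %/% n_{L-1} + 1] to
# string ((i - 1) %% n_{L-1}) + 1 of length L-1 (column-major outer).
enum_strings <- function(alphabet, maxlen) {
  out <- vector("list", maxlen + 1)
  out[[1]] <- ""
  for (L in seq_len(maxlen)) {
    out[[L + 1]] <- as.vector(outer(out[[L]], alphabet, paste0))
  }
  out
}

# Full distance table over all strings of length <= maxlen, computed by the
# memoized recursive definition itself (blockwise over the append-one-char
# poset), independent of any library distance routine. Returns a list of
# integer matrices D[[li + 1]][[lj + 1]].
lev_definition_table <- function(alphabet, maxlen) {
  k <- length(alphabet)
  sizes <- k^(0:maxlen)
  D <- vector("list", maxlen + 1)
  for (li in 0:maxlen) D[[li + 1]] <- vector("list", maxlen + 1)
  for (lj in 0:maxlen) {
    D[[1]][[lj + 1]] <- matrix(as.integer(lj), 1, sizes[lj + 1])
  }
  for (li in seq_len(maxlen)) {
    D[[li + 1]][[1]] <- matrix(as.integer(li), sizes[li + 1], 1)
    pR <- ((seq_len(sizes[li + 1]) - 1) %% sizes[li]) + 1
    cR <- ((seq_len(sizes[li + 1]) - 1) %/% sizes[li]) + 1
    for (lj in seq_len(maxlen)) {
      pC <- ((seq_len(sizes[lj + 1]) - 1) %% sizes[lj]) + 1
      cC <- ((seq_len(sizes[lj + 1]) - 1) %/% sizes[lj]) + 1
      mismatch <- outer(cR, cC, function(a, b) as.integer(a != b))
      D[[li + 1]][[lj + 1]] <- pmin(
        D[[li]][[lj]][pR, pC, drop = FALSE] + mismatch,
        D[[li]][[lj + 1]][pR, , drop = FALSE] + 1L,
        D[[li + 1]][[lj]][, pC, drop = FALSE] + 1L
      )
    }
  }
  D
}

# Random amino-acid CDR3-like sequence.
random_aa <- function(n = 1, min_len = 8, max_len = 14) {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(alpha, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# Quick single-chain repertoire from junction/abundance vectors.
tiny_repertoire <- function(junction_nt, counts, chain = "beta",
                            v_call = "TRBV2", j_call = "TRBJ1-1",
                            junction_aa = NULL, condition = "ex_vivo",
                            sample_id = "t1") {
  if (is.null(junction_aa)) {
    junction_aa <- strrep("A", nchar(junction_nt) / 3)
  }
  as_repertoire(tibble::tibble(
    chain = chain, v_call = v_call, j_call = j_call,
    junction = junction_nt, junction_aa = junction_aa,
    duplicate_count = as.integer(counts)
  ), sample_id = sample_id, condition = condition)
}

# Small, fast generator settings used by several tests.
small_params <- function(...) {
  generator_params(n_clonotypes = 2000, n_responders = 8, n_families = 2,
                   family_size = 4, depth = 2000, ...)
}
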