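# Built-in synthetic V/J gene segment tables.
#
# These are NOT germline references: labels mimic IMGT-style names and the
# prefix/suffix sequences are fixed synthetic codon runs, generated once from
# a hard-coded seed so the table is identical in every session. Each V prefix
# starts with TGT (the canonical CDR3 cysteine), each J suffix ends with TTT
# (the canonical phenylalanine). All codons are stop-free, so any codon-level
# concatenation translates without stop codons.

# 61 sense codons and their amino acids (standard genetic code).
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- vapply(cods, function(cd) {
    standard_code_aa(cd)
  }, character(1))
  keep <- aa != "*"
  list(codon = cods[keep], aa = unname(aa[keep]))
}

# Standard genetic code lookup for a single codon (fixture construction
# and codon-level translation of generated junctions).
standard_code_aa <- function(codon) {
  code <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  unname(code[codon])
}

# One representative codon per amino acid, for back-translating amino-acid
# edits into nucleotide space.
aa_to_codon <- function() {
  ct <- codon_table()
  cods <- ct$codon[!duplicated(ct$aa)]
  names(cods) <- ct$aa[!duplicated(ct$aa)]
  cods
}

amino_acids <- function() sort(unique(codon_table()$aa))

# Deterministic synthetic segment table for one chain.
#
# 15 V and 10 J segments per chain; usage frequencies decay geometrically so
# gene usage is realistically non-uniform. V prefixes are 4 codons
# (TGT + 3 random), J suffixes 3 codons (2 random + TTT).
#' Synthetic TCR gene segment table
#'
#' Returns the built-in synthetic V/J segment fixture for one chain:
#' gene label, segment type, a fixed CDR3-proximal nucleotide
#' prefix/suffix, and a baseline usage frequency. Labels follow the
#' IMGT naming style but the sequences are synthetic, not germline.
#'
#' @param chain `"alpha"` or `"beta"`.
#' @return A tibble with columns `chain`, `segment` (`"V"`/`"J"`),
#'   `gene`, `sequence` (prefix for V, suffix for J) and `base_freq`
#'   (usage frequencies summing to 1 within each segment type).
#' @export
tcr_gene_segments <- function(chain = c("alpha", "beta")) {
  chain <- match.arg(chain)
  ct <- codon_table()
  rand_codons <- function(n, rng_seed) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(rng_seed)
    matrix(sample(ct$codon, n * 3, replace = TRUE), ncol = 3)
  }
  if (chain == "alpha") {
    v_names <- c(paste0("TRAV", c("1-1", "1-2", "2", "3", "4", "5", "8-1",
                                  "9-2", "12-1", "13-1", "17", "21", "26-1")),
                 "TRAV29/DV5", "TRAV38-1")
    j_names <- paste0("TRAJ", c(4, 9, 13, 20, 24, 31, 37, 42, 49, 53))
    seed_off <- 101L
  } else {
    v_names <- paste0("TRBV", c("2", "4-1", "5-1", "6-1", "6-5", "7-2", "9",
                                "11-2", "12-3", "15", "19", "20-1", "25-1",
                                "28", "30"))
    j_names <- paste0("TRBJ", c("1-1", "1-2", "1-4", "1-5", "2-1", "2-2",
                                "2-3", "2-5", "2-6", "2-7"))
    seed_off <- 202L
  }
  vc <- rand_codons(length(v_names), seed_off)
  v_seq <- paste0("TGT", vc[, 1], vc[, 2], vc[, 3])
  jc <- rand_codons(length(j_names), seed_off + 1L)
  j_seq <- paste0(jc[, 1], jc[, 2], "TTT")
  geom_freq <- function(n, rate) {
    f <- exp(-rate * (seq_len(n) - 1))
    f / sum(f)
  }
  dplyr::bind_rows(
    tibble::tibble(chain = chain, segment = "V", gene = v_names,
                   sequence = v_seq, base_freq = geom_freq(length(v_names), 0.18)),
    tibble::tibble(chain = chain, segment = "J", gene = j_names,
                   sequence = j_seq, base_freq = geom_freq(length(j_names), 0.22))
  )
}
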