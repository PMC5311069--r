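# Synthetic paired-repertoire generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# heavy-tailed ex vivo clone-size distribution, non-uniform V/J usage,
# CDR3s assembled as V-prefix + random codon insert + J-suffix, planted
# antigen-responsive clones grown under a division-time model, planted
# families of sequence-related CDR3s, and finite sequencing depth via
# multinomial sampling.

#' Parameters of the synthetic repertoire generator
#'
#' Bundles all knobs of the paired-experiment generator with defaults
#' that emulate the study conditions of a hapten-stimulation experiment:
#' Zipf clone sizes tuned to ex vivo mean abundance near 1.3 with
#' median 1; division times of 24 h for the first generation and
#' 16--18 h afterwards over a 6-day culture; responders drawn
#' preferentially from pre-expanded (higher-abundance) clones, as
#' expected for a memory recall response; and responder CDR3s grouped
#' into sequence families.
#'
#' @param n_clonotypes Clonotypes per chain in the ex vivo baseline.
#' @param clone_size_shape Zipf tail exponent of the clone-size law;
#'   the default 3.1 gives mean abundance about 1.32 at median 1.
#' @param insert_length_range Nucleotide length range of the random
#'   junction insert; lengths are used in whole codons (multiples of 3)
#'   so the junction stays in frame. The default `c(9, 27)` yields
#'   CDR3s of 10--16 amino acids, the typical length range of human
#'   TCR junctions.
#' @param n_responders Antigen-responsive clonotypes per chain.
#' @param responder_bias `"abundance"` (default) draws responders
#'   weighted by ex vivo abundance; `"uniform"` draws them uniformly.
#' @param division_time_first Hours to the first division (default 24).
#' @param division_time_later Two-element hour interval for later
#'   divisions (default `c(16, 18)`), drawn per clone.
#' @param culture_hours Culture duration in hours (default 144 = 6 days).
#' @param death_rate Per-day death probability of non-responding cells.
#' @param depth Sequencing depth (molecules sampled) per condition;
#'   `NULL` disables depth sampling and returns exact abundances. The
#'   default 10000 undersamples the baseline slightly, so observed ex
#'   vivo abundances keep mean near 1.3 and median 1.
#' @param n_families Number of planted CDR3 sequence families; family
#'   members are taken from the responder set.
#' @param family_size Clonotypes per family.
#' @param family_max_edits Maximum amino-acid edits between a family
#'   seed and each variant (must be >= 1; pairwise within-family
#'   distances are then at most `2 * family_max_edits`).
#' @param family_min_separation Minimum amino-acid Levenshtein distance
#'   required between family seed CDR3s.
#' @param carrier_responders Clones weakly expanded in the carrier
#'   condition (nonspecific response); 0 (default) disables it.
#' @param carrier_max_divisions Cap on divisions for carrier expansion.
#' @param seed Master seed; child seeds are derived per chain and stage.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_clonotypes = 10000,
                             clone_size_shape = 3.1,
                             insert_length_range = c(9, 27),
                             n_responders = 20,
                             responder_bias = c("abundance", "uniform"),
                             division_time_first = 24,
                             division_time_later = c(16, 18),
                             culture_hours = 144,
                             death_rate = 0.05,
                             depth = 10000,
                             n_families = 4,
                             family_size = 5,
                             family_max_edits = 1,
                             family_min_separation = 8,
                             carrier_responders = 0,
                             carrier_max_divisions = 3,
                             seed = NULL) {
  p <- list(
    n_clonotypes = as.integer(n_clonotypes),
    clone_size_shape = clone_size_shape,
    insert_length_range = insert_length_range,
    n_responders = as.integer(n_responders),
    responder_bias = match.arg(responder_bias),
    division_time_first = division_time_first,
    division_time_later = division_time_later,
    culture_hours = culture_hours,
    death_rate = death_rate,
    depth = if (is.null(depth) || is.na(depth)) NULL else as.integer(depth),
    n_families = as.integer(n_families),
    family_size = as.integer(family_size),
    family_max_edits = as.integer(family_max_edits),
    family_min_separation = family_min_separation,
    carrier_responders = as.integer(carrier_responders),
    carrier_max_divisions = as.integer(carrier_max_divisions),
    seed = seed
  )
  if (p$n_clonotypes < 1) stop("n_clonotypes must be positive", call. = FALSE)
  if (p$clone_size_shape <= 1) stop("clone_size_shape must exceed 1", call. = FALSE)
  if (p$n_responders > p$n_clonotypes) {
    stop("n_responders cannot exceed n_clonotypes", call. = FALSE)
  }
  if (p$n_families > 0 && p$family_max_edits < 1) {
    stop("family_max_edits must be >= 1 (zero-edit variants would duplicate keys)",
         call. = FALSE)
  }
  if (p$n_families * p$family_size > p$n_clonotypes) {
    stop("family_size x n_families cannot exceed n_clonotypes", call. = FALSE)
  }
  if (p$death_rate < 0 || p$death_rate >= 1) {
    stop("death_rate must be in [0, 1)", call. = FALSE)
  }
  class(p) <- "generator_params"
  p
}

# Zipf(shape) sampler on {1, ..., kmax}: P(k) proportional to k^-shape.
rzipf <- function(n, shape, kmax = 100000L) {
  k <- seq_len(kmax)
  sample.int(kmax, n, replace = TRUE, prob = k^(-shape))
}

#' Sample an ex vivo baseline repertoire
#'
#' Draws `n_clonotypes` distinct clonotypes: V/J calls from the built-in
#' non-uniform usage fixture, junctions assembled as V-prefix + random
#' stop-free codon insert + J-suffix (so every junction is in frame and
#' translates without stops), and Zipf-distributed abundances. Identity
#' keys are guaranteed unique (colliding inserts are redrawn).
#'
#' @param params A [generator_params()] list.
#' @param chain `"alpha"` or `"beta"`.
#' @param sample_id Sample label stamped on the output.
#' @param seed Optional seed for this stage.
#' @return A repertoire tibble with `condition = "ex_vivo"`.
#' @export
sample_baseline <- function(params, chain = c("alpha", "beta"),
                            sample_id = "synthetic", seed = NULL) {
  chain <- match.arg(chain)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_clonotypes
  seg <- tcr_gene_segments(chain)
  vtab <- seg[seg$segment == "V", ]
  jtab <- seg[seg$segment == "J", ]
  vi <- sample.int(nrow(vtab), n, replace = TRUE, prob = vtab$base_freq)
  ji <- sample.int(nrow(jtab), n, replace = TRUE, prob = jtab$base_freq)
  ct <- codon_table()
  lens <- params$insert_length_range
  codon_choices <- seq(floor(lens[1] / 3), floor(lens[2] / 3))
  draw_junction <- function(idx) {
    nc <- sample(codon_choices, length(idx), replace = TRUE)
    ins <- vapply(nc, function(k) {
      if (k == 0) return("")
      paste(sample(ct$codon, k, replace = TRUE), collapse = "")
    }, character(1))
    paste0(vtab$sequence[vi[idx]], ins, jtab$sequence[ji[idx]])
  }
  junction <- draw_junction(seq_len(n))
  # redraw colliding identity keys until all are distinct
  for (i in 1:100) {
    key <- paste(vtab$gene[vi], jtab$gene[ji], junction)
    dup <- which(duplicated(key))
    if (length(dup) == 0) break
    junction[dup] <- draw_junction(dup)
  }
  if (anyDuplicated(paste(vtab$gene[vi], jtab$gene[ji], junction)) > 0) {
    stop("could not generate distinct clonotype keys; widen insert_length_range",
         call. = FALSE)
  }
  rep <- tibble::tibble(
    sample_id = sample_id,
    condition = "ex_vivo",
    chain = chain,
    v_call = vtab$gene[vi],
    j_call = jtab$gene[ji],
    junction = junction,
    junction_aa = translate_codons(junction),
    duplicate_count = rzipf(n, params$clone_size_shape)
  )
  dplyr::arrange(rep, dplyr::across(dplyr::all_of(repertoire_key_cols())))
}

# Codon-wise translation of in-frame junctions built from sense codons.
translate_codons <- function(nt) {
  ct <- codon_table()
  lookup <- stats::setNames(ct$aa, ct$codon)
  vapply(nt, function(s) {
    if (nchar(s) == 0) return("")
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(lookup[cods], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Select antigen-responsive clonotypes
#'
#' Draws `n_responders` rows of the baseline, by default weighted by
#' abundance (a memory recall response favours pre-expanded clones).
#'
#' @param rep Ex vivo repertoire tibble.
#' @param params A [generator_params()] list.
#' @param seed Optional seed.
#' @return Integer row indices into `rep`.
#' @export
select_responders <- function(rep, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (params$n_responders == 0) return(integer(0))
  w <- if (params$responder_bias == "abundance") rep$duplicate_count else NULL
  sort(sample.int(nrow(rep), params$n_responders, prob = w))
}

#' Plant sequence-related CDR3 families
#'
#' Rewrites the junctions of chosen clonotypes so that they form
#' `n_families` families of `family_size` members each: a seed CDR3 and
#' variants at 1 to `family_max_edits` amino-acid edits (substitution,
#' insertion or deletion, applied in codon space so nucleotide and
#' amino-acid sequences stay consistent). Family members share the
#' seed's V and J call. Seeds are redrawn until pairwise seed distances
#' reach `family_min_separation`, so families are strongly conserved
#' within and weakly related between.
#'
#' @param rep Repertoire tibble to modify.
#' @param params A [generator_params()] list.
#' @param candidate_rows Optional row indices from which family members
#'   are taken (defaults to all rows).
#' @param seed Optional seed.
#' @return A list with `repertoire` (modified tibble) and `families`
#'   (tibble of identity keys plus `family_id`).
#' @export
plant_families <- function(rep, params, candidate_rows = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- params$n_families
  fs <- params$family_size
  if (nf == 0) {
    return(list(repertoire = rep,
                families = tibble::tibble(chain = character(), v_call = character(),
                                          j_call = character(), junction = character(),
                                          family_id = integer())))
  }
  if (params$family_max_edits < 1) {
    stop("family_max_edits must be >= 1", call. = FALSE)
  }
  if (is.null(candidate_rows)) candidate_rows <- seq_len(nrow(rep))
  need <- nf * fs
  if (length(candidate_rows) < need) {
    stop("not enough candidate rows to place families", call. = FALSE)
  }
  # pick well-separated seed rows among the candidates, greedily
  seed_rows <- NULL
  for (i in 1:100) {
    cand <- sample(candidate_rows)
    picked <- cand[1]
    for (r in cand[-1]) {
      if (length(picked) == nf) break
      if (min(utils::adist(rep$junction_aa[r], rep$junction_aa[picked])) >=
          params$family_min_separation) {
        picked <- c(picked, r)
      }
    }
    if (length(picked) == nf) {
      seed_rows <- picked
      break
    }
  }
  if (is.null(seed_rows)) {
    stop("could not find family seeds separated by family_min_separation; ",
         "lower family_min_separation or widen insert_length_range",
         call. = FALSE)
  }
  member_rows <- setdiff(candidate_rows, seed_rows)
  member_rows <- sample(member_rows, nf * (fs - 1))
  fam_assign <- tibble::tibble(row = seed_rows, family_id = seq_len(nf))
  if (fs > 1) {
    fam_assign <- dplyr::bind_rows(
      fam_assign,
      tibble::tibble(row = member_rows,
                     family_id = base::rep(seq_len(nf), each = fs - 1))
    )
  }
  existing_keys <- clonotype_key(rep)
  for (f in seq_len(nf)) {
    srow <- seed_rows[f]
    seed_aa <- rep$junction_aa[srow]
    seed_nt <- rep$junction[srow]
    vrows <- fam_assign$row[fam_assign$family_id == f & fam_assign$row != srow]
    for (r in vrows) {
      ok <- FALSE
      for (try in 1:50) {
        var <- edit_junction(seed_nt, seed_aa, params$family_max_edits)
        key <- paste(rep$chain[r], rep$v_call[srow], rep$j_call[srow],
                     var$nt, sep = "|")
        if (!key %in% existing_keys) {
          rep$v_call[r] <- rep$v_call[srow]
          rep$j_call[r] <- rep$j_call[srow]
          rep$junction[r] <- var$nt
          rep$junction_aa[r] <- var$aa
          existing_keys[r] <- key
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place family variant without key collision",
                    call. = FALSE)
    }
  }
  fams <- tibble::tibble(
    chain = rep$chain[fam_assign$row],
    v_call = rep$v_call[fam_assign$row],
    j_call = rep$j_call[fam_assign$row],
    junction = rep$junction[fam_assign$row],
    family_id = fam_assign$family_id
  )
  list(repertoire = rep, families = fams)
}

# Apply 1..max_edits amino-acid edits to a junction, in codon space, keeping
# the canonical first (C) and last (F) residues fixed.
edit_junction <- function(nt, aa, max_edits) {
  a2c <- aa_to_codon()
  alpha <- amino_acids()
  cods <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  res <- strsplit(aa, "")[[1]]
  n_edits <- sample.int(max_edits, 1)
  for (e in seq_len(n_edits)) {
    L <- length(res)
    op <- sample(c("sub", "ins", "del"), 1, prob = c(0.6, 0.2, 0.2))
    if (op == "del" && L <= 4) op <- "sub"
    pos <- sample(2:(L - 1), 1)
    if (op == "sub") {
      new_aa <- sample(setdiff(alpha, res[pos]), 1)
      res[pos] <- new_aa
      cods[pos] <- a2c[[new_aa]]
    } else if (op == "ins") {
      new_aa <- sample(alpha, 1)
      res <- append(res, new_aa, after = pos)
      cods <- append(cods, a2c[[new_aa]], after = pos)
    } else {
      res <- res[-pos]
      cods <- cods[-pos]
    }
  }
  list(nt = paste(cods, collapse = ""), aa = paste(res, collapse = ""))
}

#' Simulate an in vitro culture
#'
#' Applies the division-time growth model to responders and per-cell
#' death to non-responders. In the antigen condition each responder's
#' abundance is multiplied by `2^d`, where `d` is the largest integer
#' with `division_time_first + (d - 1) * t <= culture_hours` and `t` is
#' drawn per clone uniformly from `division_time_later`. Responders are
#' not expanded in medium or carrier cultures. Non-responders survive
#' the culture with per-cell probability `(1 - death_rate)^days`
#' (binomial thinning); clones losing all cells disappear.
#'
#' @param rep Ex vivo (pre-sampling) repertoire tibble.
#' @param truth Ground-truth tibble (identity keys of responders).
#' @param params A [generator_params()] list.
#' @param condition `"medium"`, `"carrier"` or `"antigen"`.
#' @param seed Optional seed.
#' @return A list with `repertoire` (post-culture, pre-sampling) and
#'   `divisions` (tibble of responder keys and their division counts;
#'   non-antigen conditions return zero rows).
#' @export
simulate_culture <- function(rep, truth, params,
                             condition = c("medium", "carrier", "antigen"),
                             seed = NULL) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  days <- params$culture_hours / 24
  surv <- (1 - params$death_rate)^days
  is_resp <- clonotype_key(rep) %in% clonotype_key(truth)
  out <- rep
  out$condition <- condition
  divisions <- tibble::tibble(chain = character(), v_call = character(),
                              j_call = character(), junction = character(),
                              divisions = integer())
  if (condition == "antigen" && any(is_resp)) {
    idx <- which(is_resp)
    t_later <- stats::runif(length(idx), params$division_time_later[1],
                            params$division_time_later[2])
    d <- if (params$culture_hours >= params$division_time_first) {
      as.integer(floor((params$culture_hours - params$division_time_first) /
                         t_later) + 1)
    } else {
      integer(length(idx))
    }
    out$duplicate_count[idx] <- out$duplicate_count[idx] * 2^d
    divisions <- tibble::tibble(
      chain = rep$chain[idx], v_call = rep$v_call[idx],
      j_call = rep$j_call[idx], junction = rep$junction[idx],
      divisions = d
    )
  }
  if (condition == "carrier" && params$carrier_responders > 0) {
    pool <- which(!is_resp)
    idx <- sample(pool, min(params$carrier_responders, length(pool)))
    d <- sample.int(params$carrier_max_divisions, length(idx), replace = TRUE)
    out$duplicate_count[idx] <- out$duplicate_count[idx] * 2^d
  }
  nr <- which(!is_resp)
  if (surv < 1 && length(nr) > 0) {
    out$duplicate_count[nr] <- stats::rbinom(length(nr),
                                             out$duplicate_count[nr], surv)
  }
  out <- out[out$duplicate_count > 0, , drop = FALSE]
  list(repertoire = out, divisions = divisions)
}

#' Sample a repertoire to a fixed sequencing depth
#'
#' Multinomial draw of `depth` molecules with probabilities proportional
#' to abundance; clonotypes drawn zero times are absent from the output,
#' and output total abundance equals `depth` exactly.
#'
#' @param rep Non-empty repertoire tibble.
#' @param depth Positive number of molecules to draw.
#' @param seed Optional seed.
#' @return A repertoire tibble of total abundance `depth`.
#' @export
sequence_sample <- function(rep, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(rep) == 0) stop("cannot sample an empty repertoire", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  counts <- as.integer(stats::rmultinom(1, depth, prob = rep$duplicate_count))
  out <- rep
  out$duplicate_count <- counts
  out[counts > 0, , drop = FALSE]
}

#' Generate a complete paired four-condition experiment
#'
#' Composes the generator stages per chain: baseline sampling, responder
#' selection, family planting on responder CDR3s, per-condition culture
#' simulation, and per-condition depth sampling (the ex vivo condition
#' is the sampled baseline). One master seed drives derived child seeds
#' per chain and stage, so the whole experiment is reproducible and
#' individual stages are independently re-runnable.
#'
#' @param params A [generator_params()] list.
#' @param chains Chains to simulate (default both).
#' @param sample_id Sample label.
#' @return A list with `repertoires` (one tibble stacking every
#'   condition and chain), `truth` (responder keys with `family_id` and
#'   antigen `divisions`) and `params`.
#' @examples
#' ex <- make_paired_experiment(generator_params(n_clonotypes = 500,
#'                                               n_responders = 4,
#'                                               n_families = 1,
#'                                               family_size = 3,
#'                                               depth = 1000, seed = 1))
#' dplyr::count(ex$repertoires, condition, chain)
#' @export
make_paired_experiment <- function(params, chains = c("alpha", "beta"),
                                   sample_id = "synthetic") {
  if (!is.null(params$seed)) set.seed(params$seed)
  stage_seeds <- matrix(sample.int(.Machine$integer.max, 10 * length(chains)),
                        nrow = length(chains))
  reps <- list()
  truths <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    ss <- stage_seeds[ci, ]
    base <- sample_baseline(params, ch, sample_id = sample_id, seed = ss[1])
    resp_rows <- select_responders(base, params, seed = ss[2])
    pf <- plant_families(base, params, candidate_rows = resp_rows, seed = ss[3])
    base <- pf$repertoire
    truth <- tibble::tibble(
      chain = base$chain[resp_rows], v_call = base$v_call[resp_rows],
      j_call = base$j_call[resp_rows], junction = base$junction[resp_rows],
      junction_aa = base$junction_aa[resp_rows]
    )
    truth <- dplyr::left_join(truth, pf$families,
                              by = c("chain", "v_call", "j_call", "junction"))
    cultures <- list(ex_vivo = base)
    for (cond in c("medium", "carrier", "antigen")) {
      sc <- simulate_culture(base, truth, params, cond,
                             seed = ss[match(cond, c("medium", "carrier", "antigen")) + 3])
      cultures[[cond]] <- sc$repertoire
      if (cond == "antigen") {
        truth <- dplyr::left_join(truth, sc$divisions,
                                  by = c("chain", "v_call", "j_call", "junction"))
      }
    }
    if (!is.null(params$depth)) {
      for (k in seq_along(cultures)) {
        cultures[[k]] <- sequence_sample(cultures[[k]], params$depth,
                                         seed = ss[6 + k])
      }
    }
    reps[[ch]] <- dplyr::bind_rows(cultures)
    truths[[ch]] <- truth
  }
  list(repertoires = dplyr::bind_rows(reps),
       truth = dplyr::bind_rows(truths),
       params = params)
}

#' Write an experiment's repertoires and ground truth to TSV files
#'
#' One file per condition and chain, named
#' `<sample_id>_<condition>_<chain>.tsv`, plus `<sample_id>_truth.tsv`
#' and a manifest `<sample_id>_manifest.tsv` consumable by
#' [load_experiment()].
#'
#' @param experiment Result of [make_paired_experiment()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reps <- experiment$repertoires
  sid <- reps$sample_id[1]
  groups <- dplyr::distinct(reps, .data$condition, .data$chain)
  paths <- character(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sub <- reps[reps$condition == groups$condition[i] &
                  reps$chain == groups$chain[i], ]
    paths[i] <- file.path(dir, paste0(sid, "_", groups$condition[i], "_",
                                      groups$chain[i], ".tsv"))
    write_repertoire(sub, paths[i])
  }
  readr::write_tsv(experiment$truth, file.path(dir, paste0(sid, "_truth.tsv")),
                   progress = FALSE)
  manifest <- tibble::tibble(sample_id = sid, condition = groups$condition,
                             chain = groups$chain, path = basename(paths))
  mpath <- file.path(dir, paste0(sid, "_manifest.tsv"))
  readr::write_tsv(manifest, mpath, progress = FALSE)
  invisible(mpath)
}
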