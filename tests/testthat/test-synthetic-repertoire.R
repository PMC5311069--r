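test_that("baseline clone sizes are heavy-tailed with median 1, junctions in frame", {
  p <- generator_params()
  b <- sample_baseline(p, "beta", seed = 11)
  expect_equal(nrow(b), p$n_clonotypes)
  expect_equal(stats::median(b$duplicate_count), 1)
  expect_gt(mean(b$duplicate_count), 1.1)
  expect_lt(mean(b$duplicate_count), 1.6)
  expect_equal(nchar(b$junction_aa) * 3, nchar(b$junction))
  expect_false(any(grepl("\\*", b$junction_aa)))
  expect_equal(anyDuplicated(clonotype_key(b)), 0)
  # junctions carry their V prefix and J suffix
  seg <- tcr_gene_segments("beta")
  vseq <- stats::setNames(seg$sequence[seg$segment == "V"],
                          seg$gene[seg$segment == "V"])
  expect_true(all(startsWith(b$junction, vseq[b$v_call])))
})

test_that("generated translations agree with an independent codon translator", {
  b <- sample_baseline(generator_params(n_clonotypes = 50), "alpha", seed = 2)
  oracle <- vapply(b$junction, function(nt) {
    paste(seqinr::translate(seqinr::s2c(nt)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_equal(b$junction_aa, oracle)
})

test_that("baseline generation is deterministic and handles n = 1", {
  p <- generator_params(n_clonotypes = 1, n_responders = 0, n_families = 0)
  expect_equal(nrow(sample_baseline(p, "beta", seed = 5)), 1)
  p2 <- generator_params(n_clonotypes = 300)
  expect_identical(sample_baseline(p2, "alpha", seed = 9),
                   sample_baseline(p2, "alpha", seed = 9))
})

test_that("division counts follow the division-time model in closed form", {
  # fixed t = 16 h: largest d with 24 + (d-1)*16 <= 144 is d = 8
  p <- generator_params(n_clonotypes = 200, n_responders = 5, n_families = 0,
                        division_time_later = c(16, 16), death_rate = 0,
                        depth = NULL)
  b <- sample_baseline(p, "beta", seed = 3)
  rows <- select_responders(b, p, seed = 4)
  truth <- b[rows, ]
  sc <- simulate_culture(b, truth, p, "antigen", seed = 5)
  expect_equal(unique(sc$divisions$divisions), 8L)
  # responder abundance multiplied by exactly 2^d
  key_r <- clonotype_key(truth)
  out_r <- sc$repertoire[clonotype_key(sc$repertoire) %in% key_r, ]
  in_r <- truth[match(clonotype_key(out_r), key_r), ]
  expect_equal(out_r$duplicate_count, in_r$duplicate_count * 2^8)
  # an abundance-1 responder at d = 9 reaches 512 pre-sampling
  p9 <- generator_params(n_clonotypes = 10, n_responders = 1, n_families = 0,
                         division_time_later = c(15, 15), death_rate = 0,
                         depth = NULL, clone_size_shape = 50)
  b9 <- sample_baseline(p9, "beta", seed = 1)
  expect_true(all(b9$duplicate_count == 1))
  r9 <- select_responders(b9, p9, seed = 2)
  sc9 <- simulate_culture(b9, b9[r9, ], p9, "antigen", seed = 3)
  expect_equal(unique(sc9$divisions$divisions), 9L)
  expect_equal(max(sc9$repertoire$duplicate_count), 512L)
})

test_that("no death and no responders leaves a culture unchanged", {
  p <- generator_params(n_clonotypes = 100, n_responders = 0, n_families = 0,
                        death_rate = 0, depth = NULL)
  b <- sample_baseline(p, "beta", seed = 7)
  sc <- simulate_culture(b, b[0, ], p, "medium", seed = 8)
  expect_equal(dplyr::select(sc$repertoire, -"condition"),
               dplyr::select(b, -"condition"))
})

test_that("culture conserves abundance exactly up to 2^d factors and deaths", {
  p <- generator_params(n_clonotypes = 500, n_responders = 10, n_families = 0,
                        death_rate = 0, depth = NULL)
  b <- sample_baseline(p, "beta", seed = 21)
  rows <- select_responders(b, p, seed = 22)
  truth <- b[rows, ]
  sc <- simulate_culture(b, truth, p, "antigen", seed = 23)
  gain <- sum(truth$duplicate_count * (2^sc$divisions$divisions - 1))
  expect_equal(sum(sc$repertoire$duplicate_count),
               sum(b$duplicate_count) + gain)
  # responders are not expanded outside the antigen condition
  sc_m <- simulate_culture(b, truth, p, "medium", seed = 24)
  expect_equal(sum(sc_m$repertoire$duplicate_count), sum(b$duplicate_count))
})

test_that("depth sampling is multinomial with exact total and dropout", {
  rep <- tiny_repertoire(c("TGTGCATTT", "TGTACCTTT"), c(50, 50))
  s1 <- sequence_sample(rep, 1, seed = 1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$duplicate_count, 1L)
  single <- tiny_repertoire("TGTGCATTT", 7)
  expect_equal(sequence_sample(single, 7, seed = 2)$duplicate_count, 7L)
  expect_error(sequence_sample(rep, 0), "positive")
  expect_error(sequence_sample(rep[0, ], 5), "empty")
  # a clonotype at relative frequency 0.5 lands near depth/2
  for (s in 1:5) {
    drawn <- sequence_sample(rep, 10000, seed = s)
    expect_true(all(drawn$duplicate_count >= 4800 & drawn$duplicate_count <= 5200))
    expect_equal(sum(drawn$duplicate_count), 10000)
  }
})

test_that("planted families are tight within and separated between", {
  p <- generator_params(n_clonotypes = 1000, n_responders = 12, n_families = 3,
                        family_size = 4, family_max_edits = 1)
  b <- sample_baseline(p, "beta", seed = 31)
  pf <- plant_families(b, p, seed = 32)
  expect_equal(nrow(pf$families), 12)
  expect_equal(anyDuplicated(clonotype_key(pf$repertoire)), 0)
  reps <- pf$repertoire
  fam_aa <- dplyr::left_join(pf$families,
                             dplyr::select(reps, dplyr::all_of(c(
                               "chain", "v_call", "j_call", "junction",
                               "junction_aa"))),
                             by = c("chain", "v_call", "j_call", "junction"))
  for (f in unique(fam_aa$family_id)) {
    aa <- fam_aa$junction_aa[fam_aa$family_id == f]
    dm <- utils::adist(aa)
    expect_lte(max(dm), 2 * p$family_max_edits)
  }
  # family members share V and J with their seed
  counts <- dplyr::count(fam_aa, .data$family_id, .data$v_call, .data$j_call)
  expect_equal(nrow(counts), 3)
  # identity edits are rejected up front
  expect_error(generator_params(family_max_edits = 0), "family_max_edits")
})

test_that("a full paired experiment is reproducible and truth-complete", {
  p <- small_params(seed = 77)
  e1 <- make_paired_experiment(p)
  e2 <- make_paired_experiment(p)
  expect_identical(e1, e2)
  expect_setequal(unique(e1$repertoires$condition), conditions())
  expect_setequal(unique(e1$repertoires$chain), c("alpha", "beta"))
  expect_equal(nrow(e1$truth), 2 * p$n_responders)
  expect_true(all(e1$truth$divisions >= 1))
  expect_equal(sum(!is.na(e1$truth$family_id)),
               2 * p$n_families * p$family_size)
  # sampled conditions hit the requested depth exactly
  totals <- dplyr::count(e1$repertoires, .data$condition, .data$chain,
                         wt = .data$duplicate_count)
  expect_true(all(totals$n == p$depth))
  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(e1, d1)
  write_experiment(e2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
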