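make_si_pair <- function(ex_counts, in_counts, junctions = NULL) {
  n <- max(length(ex_counts), length(in_counts))
  if (is.null(junctions)) {
    junctions <- paste0("TGT", strrep("GCA", seq_len(n)), "TTT")
  }
  aa <- strrep("A", nchar(junctions) / 3)
  ex <- tiny_repertoire(junctions[ex_counts > 0], ex_counts[ex_counts > 0],
                        junction_aa = aa[ex_counts > 0])
  cu <- tiny_repertoire(junctions[in_counts > 0], in_counts[in_counts > 0],
                        junction_aa = aa[in_counts > 0], condition = "antigen")
  list(ex = ex, cu = cu)
}

test_that("stimulation index is the log2 abundance ratio with imputation", {
  pr <- make_si_pair(c(1, 5, 0), c(8, 5, 512))
  si <- compute_si(pr$cu, pr$ex)
  si <- si[order(si$abundance_in), ]
  expect_equal(si$si, c(0, 3, 9))         # 5/5, 8/1, 512/imputed 1
  expect_equal(si$imputed, c(FALSE, FALSE, TRUE))
  expect_true(all(is.finite(si$si)))
  # identity: equal abundance gives SI 0 for any count
  for (a in c(1, 7, 33)) {
    pr2 <- make_si_pair(a, a)
    expect_equal(compute_si(pr2$cu, pr2$ex)$si, 0)
  }
})

test_that("SI is additive in doublings and covers only cultured clonotypes", {
  pr <- make_si_pair(c(2, 3), c(4, 6))
  pr2 <- make_si_pair(c(2, 3), c(8, 12))
  s1 <- compute_si(pr$cu, pr$ex)
  s2 <- compute_si(pr2$cu, pr2$ex)
  expect_equal(s2$si, s1$si + 1)
  # ex-vivo-only clonotypes get no record
  pr3 <- make_si_pair(c(1, 1, 4), c(2, 2, 0))
  expect_equal(nrow(compute_si(pr3$cu, pr3$ex)), 2)
  # chain mismatch is a domain error
  alpha_cu <- tiny_repertoire("TGTGCATTT", 3, chain = "alpha",
                              v_call = "TRAV2", j_call = "TRAJ4",
                              condition = "antigen")
  expect_error(compute_si(alpha_cu, pr$ex), "chain")
  expect_error(compute_si(pr$cu[0, ], pr$ex), "empty")
})

test_that("the expanded set uses a strict threshold and is monotone", {
  si <- tibble::tibble(si = c(2.9, 3.0, 3.1))
  expect_equal(nrow(expanded_clonotypes(si, 3)), 1)
  expect_equal(nrow(expanded_clonotypes(si[0, ], 3)), 0)
  set.seed(42)
  rand <- tibble::tibble(si = stats::rnorm(500, 0, 4))
  for (t in c(-2, 0, 1, 3, 6)) {
    hi <- expanded_clonotypes(rand, t + 1)$si
    lo <- expanded_clonotypes(rand, t)$si
    expect_true(all(hi %in% lo))
  }
})

test_that("expansion summary reports all three detection denominators", {
  pr <- make_si_pair(c(1, 1, 4), c(16, 2, 0))
  si <- compute_si(pr$cu, pr$ex)
  sm <- expansion_summary(si, pr$ex, threshold = 3)
  expect_equal(sm$n_expanded, 1)
  expect_equal(sm$n_cultured, 2)
  expect_equal(sm$n_ex_vivo, 3)
  expect_equal(sm$n_union, 3)
  expect_equal(sm$frac_of_cultured, 0.5)
})

test_that("SI histogram bins are half-open and conserve counts", {
  five <- tibble::tibble(si = rep(0, 5))
  h5 <- si_histogram(five)
  expect_equal(nrow(h5), 1)
  expect_equal(h5$count, 5)
  expect_equal(h5$bin_lo, 0)
  h2 <- si_histogram(tibble::tibble(si = c(-0.5, 0.5)))
  expect_equal(h2$bin_lo, c(-1, 0))
  expect_equal(h2$count, c(1, 1))
  set.seed(1)
  rand <- tibble::tibble(si = stats::rnorm(333))
  expect_equal(sum(si_histogram(rand, 0.5)$count), 333)
  expect_error(si_histogram(rand, 0), "positive")
})

test_that("pooled two-proportion z-test matches hand-computed and chi-square values", {
  zt <- two_proportion_ztest(20, 100, 10, 100)
  expect_equal(zt$z, 1.9803, tolerance = 1e-4)
  expect_equal(zt$p, 0.0477, tolerance = 1e-3)
  # equal proportions: z = 0, p = 1
  expect_equal(two_proportion_ztest(5, 50, 10, 100),
               tibble::tibble(z = 0, p = 1))
  # antisymmetry
  a <- two_proportion_ztest(13, 40, 5, 60)
  b <- two_proportion_ztest(5, 60, 13, 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # degenerate pooled proportions
  expect_equal(two_proportion_ztest(0, 10, 0, 20), tibble::tibble(z = 0, p = 1))
  expect_equal(two_proportion_ztest(10, 10, 20, 20), tibble::tibble(z = 0, p = 1))
  expect_error(two_proportion_ztest(5, 0, 1, 2), "n >= 1")
  # z^2 equals the uncorrected chi-square statistic (independent routine)
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    if ((x1 + x2) %in% c(0, n1 + n2)) next
    z <- two_proportion_ztest(x1, n1, x2, n2)$z
    chi <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$statistic)
    expect_equal(z^2, unname(chi), tolerance = 1e-9)
  }
})

test_that("specificity report isolates antigen-specific strong expanders", {
  junctions <- paste0("TGT", strrep("GCA", 1:4), "TTT")
  aa <- strrep("A", nchar(junctions) / 3)
  ex <- tiny_repertoire(junctions, c(1, 1, 1, 1), junction_aa = aa)
  antigen <- tiny_repertoire(junctions, c(600, 512, 3, 4), junction_aa = aa,
                             condition = "antigen")
  carrier <- tiny_repertoire(junctions, c(3, 700, 5, 1), junction_aa = aa,
                             condition = "carrier")
  si_a <- compute_si(antigen, ex)
  si_c <- compute_si(carrier, ex)
  rep <- specificity_compare(si_a, si_c)
  # clone 1: antigen SI > 8, carrier abundance 2 -> specific
  # clone 2: expanded in both -> nonspecific flag
  # clones 3,4: not strong expanders -> excluded
  expect_equal(nrow(rep), 2)
  expect_setequal(rep$nonspecific, c(FALSE, TRUE))
  specific <- rep[!rep$nonspecific, ]
  expect_equal(specific$abundance_carrier, 3L)
  expect_lt(max(specific$abundance_carrier), 10)
  gl <- glance(rep)
  expect_equal(gl$n_selected, 2)
  expect_equal(gl$n_nonspecific, 1)
  # no strong expanders -> empty report
  weak <- compute_si(tiny_repertoire(junctions, c(2, 2, 2, 2),
                                     junction_aa = aa, condition = "antigen"), ex)
  expect_equal(nrow(specificity_compare(weak, si_c)), 0)
  # mismatched baselines are rejected
  si_other <- si_c
  si_other$sample_id <- "other"
  expect_error(specificity_compare(si_a, si_other), "different samples")
})

test_that("abundance enrichment flags nothing when expanded set equals everything", {
  junctions <- paste0("TGT", strrep("GCA", 1:6), "TTT")
  aa <- strrep("A", nchar(junctions) / 3)
  ex <- tiny_repertoire(junctions, c(1, 1, 2, 3, 5, 8), junction_aa = aa)
  enr <- abundance_enrichment(ex, ex)
  expect_true(all(enr$table$z == 0))
  expect_false(any(enr$table$flagged))
  expect_equal(sum(enr$table$prop_expanded), 1, tolerance = 1e-9)
  expect_equal(sum(enr$table$prop_all), 1, tolerance = 1e-9)
  expect_error(abundance_enrichment(ex[0, ], ex), "empty")
})

test_that("planted high-abundance responders show up as enrichment", {
  set.seed(5)
  p <- generator_params(n_clonotypes = 3000, n_responders = 30, n_families = 0,
                        responder_bias = "abundance", depth = NULL,
                        death_rate = 0)
  b <- sample_baseline(p, "beta", seed = 51)
  rows <- select_responders(b, p, seed = 52)
  truth <- b[rows, ]
  sc <- simulate_culture(b, truth, p, "antigen", seed = 53)
  si <- compute_si(sc$repertoire, b)
  expanded <- expanded_clonotypes(si, 3)
  enr <- abundance_enrichment(expanded, b)
  # abundance-weighted responders are pre-expanded relative to the background
  expect_gt(enr$frac_gt2_expanded, enr$frac_gt2_all)
  gl <- glance(enr)
  expect_named(gl, c("frac_gt2_expanded", "frac_gt2_all", "n_flagged", "alpha"))
  # flagged bins, if any, point the right way: expanded depleted at count 1
  tab <- enr$table
  low_bin <- tab[tab$bin == "[1,2)", ]
  expect_lt(low_bin$prop_expanded, low_bin$prop_all)
})
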