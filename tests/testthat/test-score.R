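simple_match_set <- function(seqs = "ACDEFGH", picks, tol_ppm = 10, k = 0,
                             series = c("b", "y"), extra = numeric()) {
  p <- parse_proforma(seqs)
  fr <- generate_fragments(p, series)
  obs <- c(fr$neutral_mass[picks], extra)
  ms <- match_fragments(obs, fr, match_config(tol_ppm = tol_ppm, series = series,
                                              n_isotope_shifts = k))
  list(p = p, fr = fr, ms = ms)
}

test_that("cleavage-site coverage counts deduplicated sites", {
  p <- parse_proforma("PEPTIDE") # n = 7
  fr <- generate_fragments(p, c("b", "y"))
  empty <- match_fragments(numeric(), fr, match_config(series = c("b", "y")))
  expect_equal(sequence_coverage(empty, 7),
               list(n_covered_sites = 0L, coverage_fraction = 0))

  b3 <- fr$neutral_mass[fr$series == "b" & fr$index == 3]
  ms <- match_fragments(b3, fr, match_config(series = c("b", "y")))
  expect_equal(sequence_coverage(ms, 7),
               list(n_covered_sites = 1L, coverage_fraction = 1 / 6))

  # b3 and y4 evidence the same site between residues 3 and 4: no double count
  y4 <- fr$neutral_mass[fr$series == "y" & fr$index == 4]
  ms2 <- match_fragments(c(b3, y4), fr, match_config(series = c("b", "y")))
  expect_equal(nrow(ms2$matches), 2L)
  expect_equal(sequence_coverage(ms2, 7),
               list(n_covered_sites = 1L, coverage_fraction = 1 / 6))
  sites <- covered_sites(ms2, 7)
  expect_true(sites$n_term[3] && sites$c_term[3])
  expect_equal(sum(sites$n_term), 1L)
  expect_equal(sum(sites$c_term), 1L)
})

test_that("effective ion types follow the (1 + 2k) accounting", {
  for (k in 0:3) {
    for (ns in 1:6) {
      cfg <- match_config(series = c("a", "b", "c", "x", "y", "z")[seq_len(ns)],
                          n_isotope_shifts = k)
      expect_identical(effective_ion_types(cfg), ns * (1L + 2L * k))
    }
  }
})

test_that("p_score is the Poisson upper tail of the window model", {
  st <- simple_match_set(picks = c(2, 5, 9))
  m0 <- intact_mass(st$p)
  n <- proteoform_length(st$p)
  got <- p_score(st$ms, m0, n)
  # independent route: q_i summed by hand, tail via ppois
  f_eff <- (n - 1) * 2
  q <- pmin(1, f_eff * 2 * (st$ms$observed_mass_all * 10e-6) / m0)
  lambda <- sum(q)
  expect_equal(got, stats::ppois(2, lambda, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(got > 0 && got <= 1)
})

test_that("zero matches score neutrally", {
  st <- simple_match_set(picks = integer(), extra = c(5000.1, 6000.2))
  expect_equal(nrow(st$ms$matches), 0L)
  expect_equal(p_score(st$ms, intact_mass(st$p), 7), 1.0)
  expect_equal(pcs(st$ms, intact_mass(st$p), 7), 0.0)
})

test_that("PCS sums the information content of matched masses", {
  st <- simple_match_set(picks = 4)
  m0 <- intact_mass(st$p)
  q <- pmin(1, (7 - 1) * 2 * 2 * (st$ms$matches$observed_mass * 10e-6) / m0)
  expect_equal(pcs(st$ms, m0, 7), -log10(q))
  # unmatched masses contribute nothing
  st2 <- simple_match_set(picks = 4, extra = c(4999.9, 6666.6))
  expect_equal(pcs(st2$ms, m0, 7), pcs(st$ms, m0, 7))
})

test_that("enabling isotope shifts worsens both scores for identical matches", {
  st0 <- simple_match_set(seqs = "ACDEFGHIKLMPQR", picks = c(2, 6, 11, 17))
  st1 <- simple_match_set(seqs = "ACDEFGHIKLMPQR", picks = c(2, 6, 11, 17), k = 1)
  expect_identical(match_set_triples(st0$ms), match_set_triples(st1$ms))
  m0 <- intact_mass(st0$p)
  expect_gt(p_score(st1$ms, m0, 14), p_score(st0$ms, m0, 14))
  expect_lt(pcs(st1$ms, m0, 14), pcs(st0$ms, m0, 14))
  expect_identical(effective_ion_types(st1$ms$config),
                   3L * effective_ion_types(st0$ms$config))
})

test_that("intact-mass differences report Da and ppm against theory", {
  expect_equal(intact_mass_difference(10000, 10000),
               list(mass_difference_da = 0, mass_difference_ppm = 0))
  d <- intact_mass_difference(10000.0, 10000.01)
  expect_equal(d$mass_difference_da, 0.01, tolerance = 1e-9)
  expect_equal(d$mass_difference_ppm, 1.0, tolerance = 1e-6)
  d <- intact_mass_difference(10000.0, NULL)
  expect_true(is.na(d$mass_difference_da) && is.na(d$mass_difference_ppm))
})

test_that("score_report assembles all fields, including theoretical mode", {
  st <- simple_match_set(picks = c(2, 5))
  rep <- score_report(st$p, st$ms)
  expect_s3_class(rep, "pf_score_report")
  expect_equal(rep$n_matched_observed, 2L)
  expect_true(is.na(rep$intact_mass_observed) && is.na(rep$mass_difference_da))
  expect_equal(rep$intact_mass_theoretical, intact_mass(st$p))
  rep2 <- score_report(st$p, st$ms, intact_observed = intact_mass(st$p) + 0.02)
  expect_equal(rep2$mass_difference_da, 0.02, tolerance = 1e-9)
})

test_that("score bounds hold across random simulated inputs", {
  set.seed(77)
  p <- demo_proteoform()
  fr <- generate_fragments(p, c("b", "y"))
  for (i in 1:20) {
    sim <- simulate_observed(p, frac_matched = stats::runif(1),
                             ppm_sigma = 1, n_decoys = sample(0:30, 1),
                             seed = i)
    cfg <- match_config(tol_ppm = 10, series = c("b", "y"),
                        n_isotope_shifts = sample(0:2, 1))
    ms <- match_fragments(sim$observed, fr, cfg)
    ps <- p_score(ms, intact_mass(p), proteoform_length(p))
    expect_true(ps > 0 && ps <= 1)
    expect_gte(pcs(ms, intact_mass(p), proteoform_length(p)), 0)
  }
})

test_that("decoy-only p_score distribution is not anti-conservative", {
  # sanity calibration: on decoy-only inputs the fraction of p_score < 0.05
  # should not exceed 0.10
  p <- parse_proforma("ACDEFGHIKLMPQRSTVWYA")
  fr <- generate_fragments(p, c("b", "y"))
  n <- proteoform_length(p)
  m0 <- intact_mass(p)
  cfg <- match_config(tol_ppm = 20, series = c("b", "y"))
  set.seed(2026)
  hits <- replicate(400, {
    obs <- stats::runif(60, 0, m0)
    ms <- match_fragments(obs, fr, cfg)
    p_score(ms, m0, n) < 0.05
  })
  expect_lte(mean(hits), 0.10)
})
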