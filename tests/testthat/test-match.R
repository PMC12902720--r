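test_that("exact and isotope-shifted observations match as defined", {
  p <- parse_proforma("ACDEFGHIKLMNPQRSTVWY")
  fr <- generate_fragments(p, c("b", "y"))
  b3 <- fr$neutral_mass[fr$series == "b" & fr$index == 3]

  ms <- match_fragments(b3, fr, match_config(tol_ppm = 10, series = c("b", "y")))
  expect_equal(nrow(ms$matches), 1L)
  expect_equal(ms$matches$ppm_error, 0)
  expect_equal(ms$matches$shift_steps, 0L)
  expect_identical(as.character(ms$matches$series), "b")

  shifted <- b3 + 1.00235
  ms0 <- match_fragments(shifted, fr, match_config(tol_ppm = 10, series = c("b", "y")))
  expect_equal(nrow(ms0$matches), 0L)
  ms1 <- match_fragments(shifted, fr,
                         match_config(tol_ppm = 10, series = c("b", "y"),
                                      n_isotope_shifts = 1))
  expect_equal(nrow(ms1$matches), 1L)
  expect_equal(ms1$matches$shift_steps, 1L)
  expect_equal(ms1$matches$index, 3L)
})

test_that("empty observed input yields an empty match set", {
  fr <- generate_fragments(parse_proforma("PEPTIDE"), c("b", "y"))
  ms <- match_fragments(numeric(), fr, match_config())
  expect_equal(nrow(ms$matches), 0L)
  expect_equal(ms$n_observed, 0L)
  expect_equal(glance(ms)$n_matched, 0L)
})

test_that("the matcher reproduces the brute-force all-pairs oracle", {
  set.seed(31)
  for (rep in 1:40) {
    p <- rand_proteoform(n = sample(10:30, 1))
    fr <- generate_fragments(p, c("b", "y", "c", "z"))
    cfg <- match_config(
      tol_ppm = sample(c(5, 10, 50, 200), 1),
      series = c("b", "y", "c", "z"),
      n_isotope_shifts = sample(0:2, 1))
    m0 <- intact_mass(p)
    obs <- c(
      sample(fr$neutral_mass, 10) * (1 + stats::rnorm(10, 0, 5) * 1e-6) +
        sample(-1:1, 10, replace = TRUE) * cfg$isotope_spacing,
      stats::runif(15, 100, m0))
    ms <- match_fragments(obs, fr, cfg)
    br <- brute_force_match(obs, fr, cfg)
    expect_identical(match_set_triples(ms), oracle_triples(br))
    expect_equal(nrow(ms$candidates), length(br$candidates))
  }
})

test_that("matching is monotone in tolerance and in shift depth", {
  set.seed(5)
  p <- rand_proteoform(n = 25)
  fr <- generate_fragments(p, c("b", "y"))
  obs <- c(fr$neutral_mass[c(3, 8, 20)] * (1 + 3e-6),
           fr$neutral_mass[11] + 1.00235, stats::runif(20, 100, intact_mass(p)))
  n_prev <- -1L
  for (tol in c(1, 2, 5, 10, 50, 500)) {
    n <- nrow(match_fragments(obs, fr, match_config(tol_ppm = tol,
                                                    series = c("b", "y")))$matches)
    expect_gte(n, n_prev)
    n_prev <- n
  }
  n_prev <- -1L
  for (k in 0:3) {
    n <- nrow(match_fragments(obs, fr,
                              match_config(tol_ppm = 10, series = c("b", "y"),
                                           n_isotope_shifts = k))$matches)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("zero-shift matches always beat nonzero shifts", {
  set.seed(17)
  for (rep in 1:20) {
    p <- rand_proteoform(n = 20)
    fr <- generate_fragments(p, c("b", "y"))
    obs <- fr$neutral_mass[sample(nrow(fr), 8)] * (1 + stats::rnorm(8, 0, 2) * 1e-6)
    ms <- match_fragments(obs, fr, match_config(tol_ppm = 10, series = c("b", "y"),
                                                n_isotope_shifts = 2))
    cand0 <- ms$candidates[ms$candidates$shift_steps == 0L, ]
    for (id in unique(cand0$observed_id)) {
      expect_equal(ms$matches$shift_steps[ms$matches$observed_id == id], 0L)
    }
  }
})

test_that("permuting observed order only permutes ids", {
  set.seed(23)
  p <- rand_proteoform(n = 22)
  fr <- generate_fragments(p, c("b", "y", "c", "z"))
  obs <- c(fr$neutral_mass[sample(nrow(fr), 12)] * (1 + stats::rnorm(12, 0, 3) * 1e-6),
           stats::runif(10, 100, intact_mass(p)))
  cfg <- match_config(tol_ppm = 10, series = c("b", "y", "c", "z"),
                      n_isotope_shifts = 1)
  ms_a <- match_fragments(obs, fr, cfg)
  perm <- sample(length(obs))
  ms_b <- match_fragments(obs[perm], fr, cfg)
  key <- function(ms, masses) {
    m <- ms$matches
    sort(paste(signif(m$observed_mass, 12), m$series, m$index, m$shift_steps))
  }
  expect_identical(key(ms_a), key(ms_b))
})

test_that("mass-list files round-trip and ignore comments", {
  tf <- withr::local_tempfile(fileext = ".txt")
  obs <- observed_masses(tibble::tibble(
    neutral_mass = c(1234.567891, 2345.678912, 345.6),
    intensity = c(100.5, NA, 7)))
  write_mass_list(obs, tf)
  lines <- readLines(tf)
  expect_equal(length(lines), 3L)
  rt <- read_mass_list(tf)
  expect_equal(rt$neutral_mass, round(obs$neutral_mass, 6))
  expect_equal(rt$intensity, c(100.5, NA, 7))

  writeLines(c("# a comment", "1000.5\t3", "", "2000.25"), tf)
  rt <- read_mass_list(tf)
  expect_equal(rt$neutral_mass, c(1000.5, 2000.25))
  expect_equal(rt$id, 1:2)

  writeLines(c("12.3", "notamass"), tf)
  expect_error(read_mass_list(tf), class = "pf_mass_list_error")
})

test_that("invalid configurations and observations are rejected", {
  expect_error(match_config(tol_ppm = 0), "tol_ppm")
  expect_error(match_config(series = "w"), class = "pf_invalid_config")
  expect_error(observed_masses(c(100, -5)), class = "pf_invalid_observed")
})
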