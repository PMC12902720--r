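canonical_session <- function(seed = 1) {
  set.seed(seed)
  p <- rand_proteoform(n = sample(8:20, 1))
  n_obs <- sample(0:12, 1)
  obs <- tibble::tibble(
    neutral_mass = round(stats::runif(n_obs, 200, 5000), 6),
    intensity = ifelse(stats::runif(n_obs) < 0.5,
                       round(stats::runif(n_obs, 1, 1e4), 6), NA_real_))
  session(
    p, observed = obs,
    observed_intact = if (stats::runif(1) < 0.5) round(intact_mass(p) + 0.01, 6) else NULL,
    config = match_config(tol_ppm = sample(c(5, 10, 25), 1),
                          series = sample(c("b", "y", "c", "z"), sample(2:4, 1)),
                          n_isotope_shifts = sample(0:2, 1)),
    render = render_config(residues_per_line = sample(list(20L, 50L, "auto"), 1)[[1]],
                           theme = sample(c("light", "dark"), 1),
                           target_width_px = sample(c(600L, 900L), 1))
  )
}

expect_session_equal <- function(a, b) {
  expect_identical(write_proforma(a$proteoform), write_proforma(b$proteoform))
  expect_identical(intact_mass(a$proteoform), intact_mass(b$proteoform))
  expect_equal(a$observed$neutral_mass, b$observed$neutral_mass)
  expect_equal(a$observed$intensity, b$observed$intensity)
  expect_equal(a$observed_intact %||% NA_real_, b$observed_intact %||% NA_real_)
  expect_identical(a$config, b$config)
  expect_identical(a$render, b$render)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("pcml write-read round-trips field-by-field", {
  for (seed in 1:15) {
    s <- canonical_session(seed)
    tf <- withr::local_tempfile(fileext = ".pcml")
    write_pcml(s, tf)
    rt <- read_pcml(tf)
    expect_session_equal(s, rt)
  }
})

test_that("pcml output is canonical and byte-deterministic", {
  s <- canonical_session(42)
  t1 <- withr::local_tempfile(fileext = ".pcml")
  t2 <- withr::local_tempfile(fileext = ".pcml")
  t3 <- withr::local_tempfile(fileext = ".pcml")
  write_pcml(s, t1)
  write_pcml(s, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)), readBin(t2, "raw", file.size(t2)))
  write_pcml(read_pcml(t1), t3)
  expect_identical(readBin(t1, "raw", file.size(t1)), readBin(t3, "raw", file.size(t3)))
})

test_that("theoretical-mode sessions (no observed masses) persist", {
  s <- session(parse_proforma("PEPTIDE"))
  tf <- withr::local_tempfile(fileext = ".pcml")
  write_pcml(s, tf)
  rt <- read_pcml(tf)
  expect_equal(nrow(rt$observed), 0L)
  expect_null(rt$observed_intact)
  expect_identical(write_proforma(rt$proteoform), "PEPTIDE")
})

test_that("schema violations raise named, typed errors", {
  tf <- withr::local_tempfile(fileext = ".pcml")
  writeLines(c('<?xml version="1.0"?>', '<pcml schemaVersion="1.0">',
               "<proteoform></proteoform>", "</pcml>"), tf)
  expect_error(read_pcml(tf), "sequence", class = "pf_pcml_schema_error")

  writeLines(c('<?xml version="1.0"?>', '<pcml schemaVersion="99.0">',
               "<proteoform><sequence>PEP</sequence></proteoform>", "</pcml>"), tf)
  expect_error(read_pcml(tf), class = "pf_pcml_version_error")

  s <- canonical_session(3)
  write_pcml(s, tf)
  txt <- readLines(tf)
  writeLines(txt[1:(length(txt) - 2L)], tf) # truncate
  expect_error(read_pcml(tf), class = "pf_pcml_parse_error")
})

test_that("unknown extension elements survive a rewrite", {
  s <- session(parse_proforma("PEPTIDE"))
  t1 <- withr::local_tempfile(fileext = ".pcml")
  write_pcml(s, t1)
  txt <- readLines(t1)
  txt <- append(txt, '  <labNotes author="x">keep me</labNotes>',
                after = length(txt) - 1L)
  writeLines(txt, t1)
  rt <- read_pcml(t1)
  expect_length(rt$extensions, 1L)
  t2 <- withr::local_tempfile(fileext = ".pcml")
  write_pcml(rt, t2)
  expect_true(any(grepl("labNotes", readLines(t2))))
  expect_identical(write_proforma(read_pcml(t2)$proteoform), "PEPTIDE")
})

test_that("share blobs round-trip exactly and detect corruption", {
  for (seed in 1:10) {
    s <- canonical_session(seed + 100)
    blob <- export_share_state(s)
    expect_length(blob, 1L)
    expect_false(grepl("[\n\r ]", blob))
    rt <- import_share_state(blob)
    expect_session_equal(s, rt)
  }
  s <- session(parse_proforma("PEPTIDE"))
  blob <- export_share_state(s)
  expect_session_equal(s, import_share_state(blob))
  # flip one character in the body
  pos <- nchar(blob) %/% 2
  ch <- substr(blob, pos, pos)
  flipped <- paste0(substr(blob, 1, pos - 1), if (ch == "A") "B" else "A",
                    substr(blob, pos + 1, nchar(blob)))
  expect_error(import_share_state(flipped), class = "pf_blob_integrity_error")
  expect_error(import_share_state("garbage"), class = "pf_blob_integrity_error")
})
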