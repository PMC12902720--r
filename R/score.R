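# Report metrics: sequence coverage, Poisson P-score, PCS, intact-mass
# differences. The P-score/PCS model is self-contained and documented here;
# it honors the ion-type accounting rule that each off-by-one isotope shift
# adds 2 ion types per selected series, so enabling shift recovery always
# worsens both scores for an unchanged match list.

#' Sequence (cleavage-site) coverage
#'
#' Cleavage site i (between residues i and i+1, i = 1..n-1) is covered iff any
#' matched N-terminal-series fragment has index i, or any matched
#' C-terminal-series fragment has index n-i. A site evidenced from both
#' termini counts once.
#'
#' @param ms A `pf_match_set`.
#' @param n_residues Proteoform length (>= 2).
#' @return A list with `n_covered_sites` and `coverage_fraction`
#'   (= covered / (n-1)).
#' @export
sequence_coverage <- function(ms, n_residues) {
  stopifnot(inherits(ms, "pf_match_set"), n_residues >= 2)
  sites <- covered_sites(ms, n_residues)
  covered <- sum(sites$n_term | sites$c_term)
  list(n_covered_sites = covered,
       coverage_fraction = covered / (n_residues - 1))
}

#' Per-site coverage flags
#'
#' @param ms A `pf_match_set`.
#' @param n_residues Proteoform length.
#' @return A tibble with one row per cleavage site: `site` (1..n-1), `n_term`
#'   and `c_term` logical evidence flags.
#' @export
covered_sites <- function(ms, n_residues) {
  n <- as.integer(n_residues)
  m <- ms$matches
  nsite <- rep(FALSE, n - 1L)
  csite <- rep(FALSE, n - 1L)
  if (nrow(m)) {
    ni <- m$index[m$terminus == "N"]
    ci <- n - m$index[m$terminus == "C"]
    nsite[ni[ni >= 1 & ni <= n - 1L]] <- TRUE
    csite[ci[ci >= 1 & ci <= n - 1L]] <- TRUE
  }
  tibble::tibble(site = seq_len(n - 1L), n_term = nsite, c_term = csite)
}

# Per-observed random-match probabilities q_i under the Poisson null:
# q_i = min(1, F_eff * 2 * delta_i / intact_mass), delta_i = m_i * tol_ppm * 1e-6,
# F_eff = (n-1) * |series| * (1 + 2k).
.pf_match_probs <- function(ms, intact_mass, n_residues) {
  cfg <- ms$config
  f_eff <- (n_residues - 1) * effective_ion_types(cfg)
  delta <- ms_observed_masses(ms) * cfg$tol_ppm * 1e-6
  pmin(1, f_eff * 2 * delta / intact_mass)
}

# all observed masses in input order (matched or not)
ms_observed_masses <- function(ms) {
  if (!is.null(ms$observed_mass_all)) return(ms$observed_mass_all)
  rlang::abort("match set lacks observed masses; rebuild with match_fragments()")
}

#' Poisson P-score of a match set
#'
#' Probability of observing at least the achieved number of matched masses by
#' chance, under a Poisson random-match model: each observed mass i carries a
#' half-window `delta_i = m_i * tol_ppm * 1e-6` and single-mass random-match
#' probability `q_i = min(1, F_eff * 2 * delta_i / intact_mass)` where
#' `F_eff = (n-1) * |series| * (1 + 2k)` is the effective number of fragment
#' windows; `lambda = sum(q_i)` over all observed masses, and the score is
#' `P(X >= n_matched)` for `X ~ Poisson(lambda)`. Lower is better; zero
#' matches give 1.0. The upper tail is computed through the regularized
#' incomplete gamma survival form for numerical stability.
#'
#' @param ms A `pf_match_set`.
#' @param intact_mass Theoretical intact neutral mass in Da.
#' @param n_residues Proteoform length.
#' @return A probability in (0, 1].
#' @export
p_score <- function(ms, intact_mass, n_residues) {
  stopifnot(intact_mass > 0)
  n_matched <- nrow(ms$matches)
  if (n_matched == 0L) return(1.0)
  lambda <- sum(.pf_match_probs(ms, intact_mass, n_residues))
  # P(X >= n) for X ~ Poisson(lambda) equals the regularized lower incomplete
  # gamma function P(n, lambda)
  stats::pgamma(lambda, shape = n_matched, lower.tail = TRUE)
}

#' Proteoform characterization score (PCS)
#'
#' Sum over matched observed masses of `-log10(q_i)` with the q_i of the
#' [p_score()] model: each matched fragment contributes its information
#' content, and the (1 + 2k) ion-type inflation under isotope-shift recovery
#' lowers the score. Higher is better; zero matches give 0.
#'
#' @inheritParams p_score
#' @return A non-negative float.
#' @export
pcs <- function(ms, intact_mass, n_residues) {
  stopifnot(intact_mass > 0)
  if (nrow(ms$matches) == 0L) return(0.0)
  q <- .pf_match_probs(ms, intact_mass, n_residues)
  matched <- match(ms$matches$observed_id, ms_observed_ids(ms))
  sum(-log10(q[matched]))
}

ms_observed_ids <- function(ms) {
  if (!is.null(ms$observed_id_all)) return(ms$observed_id_all)
  rlang::abort("match set lacks observed ids; rebuild with match_fragments()")
}

#' Intact-mass difference
#'
#' @param theoretical Theoretical intact neutral mass (> 0).
#' @param observed Observed intact neutral mass, or `NULL` in theoretical
#'   mode.
#' @return A list with `mass_difference_da` and `mass_difference_ppm`
#'   (observed - theoretical; ppm denominator is the theoretical mass), both
#'   `NA` when `observed` is absent.
#' @export
intact_mass_difference <- function(theoretical, observed = NULL) {
  stopifnot(theoretical > 0)
  if (is.null(observed) || is.na(observed)) {
    return(list(mass_difference_da = NA_real_, mass_difference_ppm = NA_real_))
  }
  d <- observed - theoretical
  list(mass_difference_da = d, mass_difference_ppm = d / theoretical * 1e6)
}

#' Full score report for a characterized proteoform
#'
#' @param p A [proteoform()].
#' @param ms The `pf_match_set` from matching observed masses against the
#'   fragments of `p`.
#' @param intact_observed Optional observed intact neutral mass; omit for
#'   theoretical mode.
#' @return A one-row tibble (class `pf_score_report`): `n_observed`,
#'   `n_matched_observed`, `n_covered_sites`, `coverage_fraction`, `p_score`,
#'   `pcs`, `intact_mass_theoretical`, `intact_mass_observed`,
#'   `mass_difference_da`, `mass_difference_ppm`, `effective_ion_types`.
#' @export
score_report <- function(p, ms, intact_observed = NULL) {
  stopifnot(inherits(p, "pf_proteoform"), inherits(ms, "pf_match_set"))
  n <- proteoform_length(p)
  theo <- intact_mass(p)
  cov <- sequence_coverage(ms, n)
  diff <- intact_mass_difference(theo, intact_observed)
  out <- tibble::tibble(
    n_observed = ms$n_observed,
    n_matched_observed = nrow(ms$matches),
    n_covered_sites = cov$n_covered_sites,
    coverage_fraction = cov$coverage_fraction,
    p_score = p_score(ms, theo, n),
    pcs = pcs(ms, theo, n),
    intact_mass_theoretical = theo,
    intact_mass_observed = if (is.null(intact_observed)) NA_real_ else intact_observed,
    mass_difference_da = diff$mass_difference_da,
    mass_difference_ppm = diff$mass_difference_ppm,
    effective_ion_types = effective_ion_types(ms$config)
  )
  class(out) <- c("pf_score_report", class(out))
  out
}

#' Write a characterization report as TSV and JSON
#'
#' Emits `<prefix>.report.tsv` / `<prefix>.report.json` with all score-report
#' fields plus per-match rows, and echoes the match configuration for
#' provenance.
#'
#' @param report A [score_report()] tibble.
#' @param ms The matching `pf_match_set`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(report, ms, prefix) {
  matches <- dplyr::mutate(ms$matches, series = as.character(.data$series))
  tsv <- paste0(prefix, ".report.tsv")
  json <- paste0(prefix, ".report.json")
  con <- file(tsv, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cfg <- ms$config
  writeLines(c(
    sprintf("# tol_ppm=%g series=%s isotope_shifts=%d isotope_spacing=%g",
            cfg$tol_ppm, paste(cfg$series, collapse = ","),
            cfg$n_isotope_shifts, cfg$isotope_spacing)
  ), con)
  utils::write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("", con)
  utils::write.table(as.data.frame(matches), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(config = list(tol_ppm = cfg$tol_ppm, series = cfg$series,
                       n_isotope_shifts = cfg$n_isotope_shifts,
                       isotope_spacing = cfg$isotope_spacing),
         report = as.list(as.data.frame(report)),
         matches = matches),
    json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv, json))
}
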