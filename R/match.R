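# ppm-tolerance matching of observed deconvoluted neutral masses to
# theoretical fragments, with off-by-n isotope error recovery.

#' Matching configuration
#'
#' @param tol_ppm Positive matching tolerance in parts per million; the ppm
#'   error is always computed against the theoretical fragment mass.
#' @param series Ion series to generate and match.
#' @param n_isotope_shifts Non-negative integer k: observed masses are also
#'   tried after removing s x `isotope_spacing` for every integer
#'   s in -k..k. `k = 0` disables shift recovery. Each enabled shift step adds
#'   2 effective ion types per selected series, which feeds into the P-score
#'   and PCS so that shift recovery cannot artificially improve the scores.
#' @param isotope_spacing Inter-isotopologue spacing in Da (averagine-like
#'   deconvolution errors; default 1.00235).
#' @return A `pf_match_config` list.
#' @export
match_config <- function(tol_ppm = 10, series = c("b", "y", "c", "z"),
                         n_isotope_shifts = 0L, isotope_spacing = 1.00235) {
  stopifnot(tol_ppm > 0, n_isotope_shifts >= 0, isotope_spacing > 0)
  series <- unique(as.character(series))
  bad <- setdiff(series, .pf_series_levels)
  if (length(bad)) {
    rlang::abort(paste0("unknown ion series: ", paste(bad, collapse = ", ")),
                 class = "pf_invalid_config")
  }
  structure(
    list(tol_ppm = as.numeric(tol_ppm), series = series,
         n_isotope_shifts = as.integer(n_isotope_shifts),
         isotope_spacing = as.numeric(isotope_spacing)),
    class = "pf_match_config"
  )
}

#' Effective ion-type count under isotope-shift recovery
#'
#' Each off-by-one shift step adds 2 ion types for every selected ion type,
#' so the effective count is |series| x (1 + 2k).
#'
#' @param cfg A [match_config()].
#' @return Integer.
#' @export
effective_ion_types <- function(cfg) {
  length(cfg$series) * (1L + 2L * cfg$n_isotope_shifts)
}

#' Coerce observed masses to the canonical tibble
#'
#' @param x Numeric vector of neutral masses, or a data frame with a
#'   `neutral_mass` column (optional `intensity`).
#' @return A tibble with `id` (stable input order), `neutral_mass`,
#'   `intensity`.
#' @export
observed_masses <- function(x) {
  if (is.numeric(x)) x <- tibble::tibble(neutral_mass = as.numeric(x))
  x <- tibble::as_tibble(x)
  stopifnot("neutral_mass" %in% names(x))
  if (!"intensity" %in% names(x)) x$intensity <- NA_real_
  x$intensity <- as.numeric(x$intensity)
  if (!"id" %in% names(x)) x$id <- seq_len(nrow(x))
  if (nrow(x) && (!all(is.finite(x$neutral_mass)) || any(x$neutral_mass <= 0))) {
    rlang::abort("observed neutral masses must be finite and positive",
                 class = "pf_invalid_observed")
  }
  x[, c("id", "neutral_mass", "intensity")]
}

#' Read a mass-list file
#'
#' UTF-8 text, one neutral monoisotopic mass per line, optional tab-separated
#' intensity; blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return An [observed_masses()] tibble.
#' @export
read_mass_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(observed_masses(numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  mass <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  intensity <- suppressWarnings(vapply(parts, function(p) {
    if (length(p) >= 2L) as.numeric(p[[2L]]) else NA_real_
  }, numeric(1)))
  if (anyNA(mass)) {
    rlang::abort("mass-list file contains non-numeric mass values",
                 class = "pf_mass_list_error")
  }
  observed_masses(tibble::tibble(neutral_mass = mass, intensity = intensity))
}

#' Write a mass-list file
#'
#' @param observed An [observed_masses()] tibble or numeric vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mass_list <- function(observed, path) {
  obs <- observed_masses(observed)
  lines <- vapply(seq_len(nrow(obs)), function(i) {
    if (is.na(obs$intensity[i])) sprintf("%.6f", obs$neutral_mass[i])
    else sprintf("%.6f\t%.6f", obs$neutral_mass[i], obs$intensity[i])
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Match observed masses to theoretical fragments
#'
#' An observed mass m matches fragment f at shift step s (|s| <= k) iff
#' `|m - s * spacing - f| / f * 1e6 <= tol_ppm`. Every observed mass gets at
#' most one winning match, chosen by smallest |s|, then smallest |ppm_error|,
#' then lowest (series, index); all candidate pairs are retained for
#' diagnostics. Matching is deterministic: permuting the observed input only
#' permutes observed ids.
#'
#' @param observed Numeric vector or [observed_masses()] tibble.
#' @param fragments Fragment tibble from [generate_fragments()].
#' @param cfg A [match_config()]; its `series` filters the fragment table.
#' @return A `pf_match_set`: list with `matches` (winners, one row per matched
#'   observed id: `observed_id`, `observed_mass`, `intensity`, `series`,
#'   `index`, `terminus`, `theoretical_mass`, `shift_steps`, `ppm_error`),
#'   `candidates` (all in-tolerance pairs), `config`, `n_observed`,
#'   `n_theoretical`.
#' @export
match_fragments <- function(observed, fragments, cfg = match_config()) {
  stopifnot(inherits(cfg, "pf_match_config"))
  obs <- observed_masses(observed)
  frag <- fragments[as.character(fragments$series) %in% cfg$series, , drop = FALSE]
  k <- cfg$n_isotope_shifts
  shifts <- seq.int(-k, k)

  empty <- tibble::tibble(
    observed_id = integer(), observed_mass = numeric(), intensity = numeric(),
    series = factor(character(), levels = .pf_series_levels), index = integer(),
    terminus = character(), theoretical_mass = numeric(),
    shift_steps = integer(), ppm_error = numeric()
  )
  cand <- empty
  if (nrow(obs) && nrow(frag)) {
    fm <- frag$neutral_mass
    hits <- purrr::map_dfr(shifts, function(s) {
      adj <- obs$neutral_mass - s * cfg$isotope_spacing      # length n_obs
      ppm <- outer(adj, fm, function(a, f) (a - f) / f * 1e6)
      idx <- which(abs(ppm) <= cfg$tol_ppm, arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      tibble::tibble(
        observed_id = obs$id[idx[, 1L]],
        observed_mass = obs$neutral_mass[idx[, 1L]],
        intensity = obs$intensity[idx[, 1L]],
        series = frag$series[idx[, 2L]],
        index = frag$index[idx[, 2L]],
        terminus = frag$terminus[idx[, 2L]],
        theoretical_mass = fm[idx[, 2L]],
        shift_steps = as.integer(s),
        ppm_error = ppm[idx]
      )
    })
    if (nrow(hits)) cand <- hits
  }
  cand <- dplyr::arrange(cand, .data$observed_id, abs(.data$shift_steps),
                         abs(.data$ppm_error), .data$series, .data$index)
  winners <- dplyr::slice_head(dplyr::group_by(cand, .data$observed_id), n = 1L)
  winners <- dplyr::arrange(dplyr::ungroup(winners), .data$observed_id)
  structure(
    list(matches = winners, candidates = cand, config = cfg,
         n_observed = nrow(obs), n_theoretical = nrow(frag),
         observed_id_all = obs$id, observed_mass_all = obs$neutral_mass),
    class = "pf_match_set"
  )
}

#' @export
print.pf_match_set <- function(x, ...) {
  cat(sprintf(
    "<match set> %d/%d observed masses matched against %d fragments (tol %g ppm, k = %d)\n",
    nrow(x$matches), x$n_observed, x$n_theoretical,
    x$config$tol_ppm, x$config$n_isotope_shifts))
  invisible(x)
}

#' Tidy a match set into its winning matches
#'
#' @param x A `pf_match_set`.
#' @param ... Unused.
#' @return The winners tibble (one row per matched observed mass).
#' @export
tidy.pf_match_set <- function(x, ...) x$matches

#' One-row summary of a match set
#'
#' @param x A `pf_match_set`.
#' @param ... Unused.
#' @return A one-row tibble: counts, configuration, effective ion types.
#' @export
glance.pf_match_set <- function(x, ...) {
  tibble::tibble(
    n_observed = x$n_observed,
    n_theoretical = x$n_theoretical,
    n_matched = nrow(x$matches),
    tol_ppm = x$config$tol_ppm,
    series = paste(x$config$series, collapse = ","),
    n_isotope_shifts = x$config$n_isotope_shifts,
    isotope_spacing = x$config$isotope_spacing,
    effective_ion_types = effective_ion_types(x$config)
  )
}
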