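# Theoretical neutral monoisotopic fragment masses for the a/b/c/x/y/z series.

.pf_series_levels <- c("a", "b", "c", "x", "y", "z")
.pf_nterm_series <- c("a", "b", "c")

#' Generate theoretical fragment masses
#'
#' For an n-residue proteoform each selected series yields n-1 fragments with
#' index i = number of residues in the fragment. All masses are neutral
#' monoisotopic fragment masses (never charged m/z), with N-terminal and
#' in-range localized/fixed modifications applied before summation:
#'
#' * `b_i` = sum of residues 1..i (+ N-terminal mods),
#' * `y_j` = sum of the last j residues + water (+ C-terminal mods),
#' * `a_i = b_i - CO`, `c_i = b_i + NH3`,
#' * `x_j = y_j + CO - H2`, `z_j = y_j - NH3 + H` (the z-radical, z-dot,
#'   standard for ETD/EThcD spectra).
#'
#' @param p A [proteoform()].
#' @param series Character subset of `c("a","b","c","x","y","z")`.
#' @return A tibble sorted by (series, index) with columns `series` (factor),
#'   `index`, `neutral_mass`, `terminus` (`"N"` or `"C"`).
#' @examples
#' generate_fragments(parse_proforma("GG"), c("b", "y"))
#' @export
generate_fragments <- function(p, series = c("b", "y")) {
  stopifnot(inherits(p, "pf_proteoform"))
  if (length(series) == 0L) {
    rlang::abort("at least one ion series must be selected", class = "pf_invalid_config")
  }
  series <- unique(as.character(series))
  bad <- setdiff(series, .pf_series_levels)
  if (length(bad)) {
    rlang::abort(paste0("unknown ion series: ", paste(bad, collapse = ", ")),
                 class = "pf_invalid_config")
  }
  n <- proteoform_length(p)
  if (n < 2L) {
    rlang::abort("proteoform has no cleavage sites (length < 2)",
                 class = "pf_no_cleavage_sites")
  }
  lay <- .pf_mass_layout(p)
  off <- .pf_series_offset()
  prefix <- cumsum(lay$residue)[-n] + lay$nterm              # b_i, i = 1..n-1
  suffix <- rev(cumsum(rev(lay$residue)))[-1] + .pf_water() + lay$cterm # y_j, j = n-1..1
  suffix <- rev(suffix)                                      # y_j, j = 1..n-1
  out <- purrr::map_dfr(sort(factor(series, levels = .pf_series_levels)), function(s) {
    s <- as.character(s)
    base <- if (s %in% .pf_nterm_series) prefix else suffix
    tibble::tibble(
      series = s, index = seq_len(n - 1L),
      neutral_mass = base + off[[s]],
      terminus = if (s %in% .pf_nterm_series) "N" else "C"
    )
  })
  out$series <- factor(out$series, levels = .pf_series_levels)
  dplyr::arrange(out, series, index)
}

#' Write a theoretical fragment table as TSV
#'
#' @param fragments Tibble from [generate_fragments()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(fragments, path) {
  df <- data.frame(series = as.character(fragments$series),
                   index = fragments$index,
                   neutral_mass = sprintf("%.6f", fragments$neutral_mass))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
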