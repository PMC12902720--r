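# Deterministic, self-contained SVG fragment maps. All geometry is integer
# arithmetic and all output is assembled from fixed templates, so identical
# inputs give byte-identical documents. Styling (light/dark) changes only
# style attributes, never geometry.

.pf_svg_cell_w <- 22L
.pf_svg_cell_h <- 30L
.pf_svg_margin <- 24L
.pf_svg_row_gap <- 26L
.pf_svg_legend_lh <- 16L

.pf_theme_palette <- function(theme) {
  if (theme == "dark") {
    list(bg = "#1e1e1e", text = "#e6e6e6", nflag = "#6baed6",
         cflag = "#fc9272", modres = "#c5b0d5", legend = "#bdbdbd")
  } else {
    list(bg = "#ffffff", text = "#1a1a1a", nflag = "#1f77b4",
         cflag = "#d62728", modres = "#7b3294", legend = "#555555")
  }
}

#' Resolve the residues-per-line setting
#'
#' `"auto"` picks the largest allowed count (20, 25, 30, 40, 50) whose row
#' fits within `target_width_px` at the fixed glyph cell width, falling back
#' to 20 when none fits.
#'
#' @param cfg A [render_config()].
#' @return An integer residues-per-line value.
#' @export
resolve_residues_per_line <- function(cfg) {
  if (!identical(cfg$residues_per_line, "auto")) return(cfg$residues_per_line)
  fits <- .pf_allowed_per_line[
    2L * .pf_svg_margin + .pf_allowed_per_line * .pf_svg_cell_w <= cfg$target_width_px]
  if (length(fits)) max(fits) else .pf_allowed_per_line[1L]
}

#' Render a proteoform fragment map as SVG
#'
#' One glyph per residue laid out in rows; covered cleavage sites carry angled
#' tick flags: N-terminal-series evidence as the upper/left flag,
#' C-terminal-series evidence as the lower/right flag (both when both cover
#' the site). Modified residues are highlighted and listed in a legend. The
#' document is SVG 1.1, UTF-8, with no scripts or external references.
#'
#' @param p A [proteoform()].
#' @param ms Optional `pf_match_set`; omit for a coverage-free (theoretical)
#'   map.
#' @param cfg A [render_config()].
#' @return The SVG document as a single character string.
#' @export
render_map <- function(p, ms = NULL, cfg = render_config()) {
  stopifnot(inherits(p, "pf_proteoform"))
  n <- proteoform_length(p)
  if (n < 2L) {
    rlang::abort("proteoform has no cleavage sites (length < 2)",
                 class = "pf_no_cleavage_sites")
  }
  pal <- .pf_theme_palette(cfg$theme)
  rpl <- resolve_residues_per_line(cfg)
  rows <- ceiling(n / rpl)
  res <- strsplit(p$residues, "")[[1]]

  sites <- if (!is.null(ms)) covered_sites(ms, n) else
    tibble::tibble(site = seq_len(n - 1L), n_term = FALSE, c_term = FALSE)

  modded <- tidy.pf_proteoform(p)
  modded <- modded[!is.na(modded$mods), , drop = FALSE]

  width <- 2L * .pf_svg_margin + rpl * .pf_svg_cell_w
  map_h <- rows * .pf_svg_cell_h + (rows - 1L) * .pf_svg_row_gap
  legend_h <- if (nrow(modded)) (nrow(modded) + 1L) * .pf_svg_legend_lh + 8L else 0L
  height <- 2L * .pf_svg_margin + map_h + legend_h

  row_of <- function(i) (i - 1L) %/% rpl
  col_of <- function(i) (i - 1L) %% rpl
  x_mid <- function(i) .pf_svg_margin + col_of(i) * .pf_svg_cell_w + .pf_svg_cell_w %/% 2L
  y_base <- function(i) .pf_svg_margin + row_of(i) * (.pf_svg_cell_h + .pf_svg_row_gap) +
    .pf_svg_cell_h - 8L

  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="%s"/>',
            width, height, pal$bg)
  )
  # residue glyphs
  for (i in seq_len(n)) {
    is_mod <- i %in% modded$pos
    L <- c(L, sprintf(
      paste0('<text x="%d" y="%d" font-family="monospace, Courier" font-size="16" ',
             'text-anchor="middle" fill="%s"%s>%s</text>'),
      x_mid(i), y_base(i), if (is_mod) pal$modres else pal$text,
      if (is_mod) ' font-weight="bold"' else "", res[i]))
  }
  # coverage flags at the inter-residue gap after residue i
  for (i in sites$site) {
    xg <- .pf_svg_margin + (col_of(i) + 1L) * .pf_svg_cell_w
    yt <- .pf_svg_margin + row_of(i) * (.pf_svg_cell_h + .pf_svg_row_gap)
    ym <- yt + .pf_svg_cell_h %/% 2L
    yb <- yt + .pf_svg_cell_h
    if (sites$n_term[i]) {
      L <- c(L, sprintf(
        '<polyline points="%d,%d %d,%d %d,%d" fill="none" stroke="%s" stroke-width="2"/>',
        xg - 7L, yt, xg, yt, xg, ym, pal$nflag))
    }
    if (sites$c_term[i]) {
      L <- c(L, sprintf(
        '<polyline points="%d,%d %d,%d %d,%d" fill="none" stroke="%s" stroke-width="2"/>',
        xg, ym, xg, yb, xg + 7L, yb, pal$cflag))
    }
  }
  # modification legend
  if (nrow(modded)) {
    y0 <- 2L * .pf_svg_margin + map_h
    L <- c(L, sprintf(
      '<text x="%d" y="%d" font-family="sans-serif" font-size="12" fill="%s">Modifications</text>',
      .pf_svg_margin, y0, pal$legend))
    for (j in seq_len(nrow(modded))) {
      L <- c(L, sprintf(
        '<text x="%d" y="%d" font-family="sans-serif" font-size="12" fill="%s">%s%d: %s</text>',
        .pf_svg_margin, y0 + j * .pf_svg_legend_lh, pal$modres,
        modded$residue[j], modded$pos[j], .pf_xml_escape(modded$mods[j])))
    }
  }
  paste(c(L, "</svg>"), collapse = "\n")
}

#' Write SVG text to a file
#'
#' @param svg Character scalar from [render_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(svg, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
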