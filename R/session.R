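# Session container and .pcml (XML) round-trip, plus a portable share blob.
# The .pcml dialect is this package's own versioned schema (the lineage's
# closed format is not published); files are written in a canonical byte-
# deterministic form: fixed element and attribute order, masses with 6
# decimals, so identical sessions produce byte-identical files.

.pf_pcml_version <- "1.0"

#' Fragment-map render settings
#'
#' @param residues_per_line `"auto"` or one of 20, 25, 30, 40, 50. `"auto"`
#'   resolves to the largest allowed count whose row fits `target_width_px`.
#' @param theme `"light"` or `"dark"`; affects only style attributes, never
#'   geometry.
#' @param target_width_px Positive integer, used by `"auto"`.
#' @return A `pf_render_config` list.
#' @export
render_config <- function(residues_per_line = "auto", theme = c("light", "dark"),
                          target_width_px = 900L) {
  theme <- match.arg(theme)
  rpl <- residues_per_line
  if (!identical(rpl, "auto")) {
    rpl <- suppressWarnings(as.integer(rpl))
    if (is.na(rpl) || !rpl %in% .pf_allowed_per_line) {
      rlang::abort(paste0("residues_per_line must be one of ",
                          paste(.pf_allowed_per_line, collapse = ", "), ", auto"),
                   class = "pf_invalid_config")
    }
  }
  stopifnot(target_width_px > 0)
  structure(list(residues_per_line = rpl, theme = theme,
                 target_width_px = as.integer(target_width_px)),
            class = "pf_render_config")
}

.pf_allowed_per_line <- c(20L, 25L, 30L, 40L, 50L)

#' Build a session
#'
#' A session is the unit persisted as `.pcml` and as a share blob: the
#' proteoform, the observed deconvoluted masses (possibly empty, for
#' theoretical mode), an optional observed intact mass, and the match and
#' render settings.
#'
#' @param proteoform A [proteoform()].
#' @param observed Numeric vector or [observed_masses()] tibble (may be
#'   empty).
#' @param observed_intact Optional observed intact neutral mass in Da.
#' @param config A [match_config()].
#' @param render A [render_config()].
#' @return A `pf_session` object.
#' @export
session <- function(proteoform, observed = numeric(), observed_intact = NULL,
                    config = match_config(), render = render_config()) {
  stopifnot(inherits(proteoform, "pf_proteoform"),
            inherits(config, "pf_match_config"),
            inherits(render, "pf_render_config"))
  structure(
    list(proteoform = proteoform, observed = observed_masses(observed),
         observed_intact = observed_intact, config = config, render = render,
         schema_version = .pf_pcml_version, extensions = character()),
    class = "pf_session"
  )
}

#' @export
print.pf_session <- function(x, ...) {
  cat(sprintf("<session> %d-residue proteoform, %d observed masses%s\n",
              proteoform_length(x$proteoform), nrow(x$observed),
              if (nrow(x$observed) == 0) " (theoretical mode)" else ""))
  invisible(x)
}

.pf_xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.pf_comp_string <- function(comp) {
  paste0(names(comp), as.integer(comp), collapse = "")
}

.pf_mod_attrs <- function(mod, pos = NULL) {
  a <- character()
  if (!is.null(pos)) a <- c(a, sprintf('position="%d"', pos))
  a <- c(a, sprintf('name="%s"', .pf_xml_escape(mod$name)),
         sprintf('category="%s"', mod$category))
  if (length(mod$targets)) {
    a <- c(a, sprintf('targets="%s"', .pf_xml_escape(paste(mod$targets, collapse = ","))))
  }
  if (!is.null(mod$mass_shift)) {
    a <- c(a, sprintf('massShift="%.6f"', mod$mass_shift))
  } else if (!is.null(mod$formula)) {
    a <- c(a, sprintf('formula="%s"', .pf_comp_string(mod$formula)))
  } else {
    a <- c(a, sprintf('glycan="%s"', .pf_comp_string(mod$glycan)))
  }
  paste(a, collapse = " ")
}

.pf_pcml_text <- function(s) {
  stopifnot(inherits(s, "pf_session"))
  p <- s$proteoform
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         sprintf('<pcml schemaVersion="%s">', s$schema_version),
         "  <proteoform>",
         sprintf("    <sequence>%s</sequence>", p$residues))
  if (!is.null(p$n_term_mod)) {
    L <- c(L, sprintf("    <nTermMod %s/>", .pf_mod_attrs(p$n_term_mod)))
  }
  if (!is.null(p$c_term_mod)) {
    L <- c(L, sprintf("    <cTermMod %s/>", .pf_mod_attrs(p$c_term_mod)))
  }
  if (length(p$localized)) {
    L <- c(L, "    <localizedMods>",
           vapply(p$localized, function(e) {
             sprintf("      <mod %s/>", .pf_mod_attrs(e$mod, pos = e$pos))
           }, ""),
           "    </localizedMods>")
  }
  if (length(p$fixed_mods)) {
    L <- c(L, "    <fixedMods>",
           vapply(p$fixed_mods, function(m) sprintf("      <mod %s/>", .pf_mod_attrs(m)), ""),
           "    </fixedMods>")
  }
  L <- c(L, "  </proteoform>")
  intact_attr <- if (!is.null(s$observed_intact)) {
    sprintf(' intactMass="%.6f"', s$observed_intact)
  } else ""
  if (nrow(s$observed)) {
    L <- c(L, sprintf("  <observed%s>", intact_attr),
           vapply(seq_len(nrow(s$observed)), function(i) {
             v <- sprintf('value="%.6f"', s$observed$neutral_mass[i])
             if (!is.na(s$observed$intensity[i])) {
               v <- paste0(v, sprintf(' intensity="%.6f"', s$observed$intensity[i]))
             }
             sprintf("    <mass %s/>", v)
           }, ""),
           "  </observed>")
  } else {
    L <- c(L, sprintf("  <observed%s/>", intact_attr))
  }
  cfg <- s$config
  L <- c(L, sprintf(
    '  <matchConfig tolPpm="%.6f" series="%s" isotopeShifts="%d" isotopeSpacing="%.6f"/>',
    cfg$tol_ppm, paste(cfg$series, collapse = ","), cfg$n_isotope_shifts,
    cfg$isotope_spacing))
  r <- s$render
  L <- c(L, sprintf(
    '  <render residuesPerLine="%s" theme="%s" targetWidthPx="%d"/>',
    as.character(r$residues_per_line), r$theme, r$target_width_px))
  if (length(s$extensions)) L <- c(L, paste0("  ", s$extensions))
  c(L, "</pcml>")
}

#' Write a session as a .pcml file
#'
#' Output is canonical and deterministic: identical sessions produce
#' byte-identical files, and write-read-write is byte-stable.
#'
#' @param s A [session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pcml <- function(s, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(.pf_pcml_text(s), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.pf_parse_mod_node <- function(node) {
  at <- xml2::xml_attrs(node)
  src <- intersect(c("massShift", "formula", "glycan"), names(at))
  if (length(src) != 1L) {
    rlang::abort("mod element needs exactly one of massShift/formula/glycan",
                 class = "pf_pcml_schema_error")
  }
  targets <- if ("targets" %in% names(at)) {
    strsplit(at[["targets"]], ",", fixed = TRUE)[[1]]
  } else character()
  modification(
    name = at[["name"]],
    category = if ("category" %in% names(at)) at[["category"]] else "custom",
    targets = targets,
    mass_shift = if (src == "massShift") as.numeric(at[["massShift"]]) else NULL,
    formula = if (src == "formula") at[["formula"]] else NULL,
    glycan = if (src == "glycan") at[["glycan"]] else NULL
  )
}

.pf_parse_pcml_xml <- function(doc) {
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pcml") {
    rlang::abort("not a pcml document (root element is not <pcml>)",
                 class = "pf_pcml_schema_error")
  }
  ver <- xml2::xml_attr(root, "schemaVersion")
  if (is.na(ver) || ver != .pf_pcml_version) {
    rlang::abort(paste0("unsupported pcml schema version: ", ver),
                 class = "pf_pcml_version_error")
  }
  pnode <- xml2::xml_find_first(root, "./proteoform")
  if (inherits(pnode, "xml_missing")) {
    rlang::abort("missing required element: proteoform", class = "pf_pcml_schema_error")
  }
  seqnode <- xml2::xml_find_first(pnode, "./sequence")
  if (inherits(seqnode, "xml_missing")) {
    rlang::abort("missing required element: sequence", class = "pf_pcml_schema_error")
  }
  nmod <- xml2::xml_find_first(pnode, "./nTermMod")
  cmod <- xml2::xml_find_first(pnode, "./cTermMod")
  locnodes <- xml2::xml_find_all(pnode, "./localizedMods/mod")
  fixnodes <- xml2::xml_find_all(pnode, "./fixedMods/mod")
  p <- proteoform(
    xml2::xml_text(seqnode),
    n_term_mod = if (!inherits(nmod, "xml_missing")) .pf_parse_mod_node(nmod) else NULL,
    c_term_mod = if (!inherits(cmod, "xml_missing")) .pf_parse_mod_node(cmod) else NULL,
    localized = lapply(locnodes, function(nd) {
      list(pos = as.integer(xml2::xml_attr(nd, "position")),
           mod = .pf_parse_mod_node(nd))
    }),
    fixed_mods = lapply(fixnodes, .pf_parse_mod_node)
  )
  onode <- xml2::xml_find_first(root, "./observed")
  if (inherits(onode, "xml_missing")) {
    rlang::abort("missing required element: observed", class = "pf_pcml_schema_error")
  }
  intact <- xml2::xml_attr(onode, "intactMass")
  massnodes <- xml2::xml_find_all(onode, "./mass")
  obs <- tibble::tibble(
    neutral_mass = as.numeric(xml2::xml_attr(massnodes, "value")),
    intensity = as.numeric(xml2::xml_attr(massnodes, "intensity"))
  )
  cnode <- xml2::xml_find_first(root, "./matchConfig")
  if (inherits(cnode, "xml_missing")) {
    rlang::abort("missing required element: matchConfig", class = "pf_pcml_schema_error")
  }
  cfg <- match_config(
    tol_ppm = as.numeric(xml2::xml_attr(cnode, "tolPpm")),
    series = strsplit(xml2::xml_attr(cnode, "series"), ",", fixed = TRUE)[[1]],
    n_isotope_shifts = as.integer(xml2::xml_attr(cnode, "isotopeShifts")),
    isotope_spacing = as.numeric(xml2::xml_attr(cnode, "isotopeSpacing"))
  )
  rnode <- xml2::xml_find_first(root, "./render")
  if (inherits(rnode, "xml_missing")) {
    rlang::abort("missing required element: render", class = "pf_pcml_schema_error")
  }
  rnd <- render_config(
    residues_per_line = xml2::xml_attr(rnode, "residuesPerLine"),
    theme = xml2::xml_attr(rnode, "theme"),
    target_width_px = as.integer(xml2::xml_attr(rnode, "targetWidthPx"))
  )
  known <- c("proteoform", "observed", "matchConfig", "render")
  extras <- xml2::xml_children(root)
  extras <- extras[!xml2::xml_name(extras) %in% known]
  s <- session(p, observed = obs,
               observed_intact = if (is.na(intact)) NULL else as.numeric(intact),
               config = cfg, render = rnd)
  s$extensions <- vapply(extras, function(nd) as.character(nd), "")
  s
}

#' Read a .pcml session file
#'
#' Unknown extension elements under the root are preserved opaquely and
#' re-emitted by [write_pcml()].
#'
#' @param path File path.
#' @return A `pf_session`.
#' @export
read_pcml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    rlang::abort(paste0("malformed pcml XML: ", conditionMessage(e)),
                                 class = "pf_pcml_parse_error")
                  })
  .pf_parse_pcml_xml(doc)
}

# ---- share blob -------------------------------------------------------------

.pf_blob_prefix <- "pfm1"

#' Export a session as a portable share blob
#'
#' A single-line URL-safe encoding of the canonical .pcml serialization plus
#' an integrity checksum; a local, service-free replacement for cloud share
#' links. `import_share_state(export_share_state(s))` round-trips exactly.
#'
#' @param s A [session()].
#' @return A single-line character blob.
#' @export
export_share_state <- function(s) {
  text <- paste(.pf_pcml_text(s), collapse = "\n")
  body <- gsub("[\r\n[:space:]]", "", jsonlite::base64url_enc(charToRaw(text)))
  paste(.pf_blob_prefix, body, substr(rlang::hash(text), 1, 16), sep = ".")
}

#' Import a session from a share blob
#'
#' @param blob A blob from [export_share_state()].
#' @return A `pf_session`.
#' @export
import_share_state <- function(blob) {
  blob <- trimws(blob)
  parts <- strsplit(blob, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3L || parts[1] != .pf_blob_prefix) {
    rlang::abort("not a recognizable share blob", class = "pf_blob_integrity_error")
  }
  text <- tryCatch(rawToChar(jsonlite::base64url_dec(parts[2])),
                   error = function(e) {
                     rlang::abort("share blob is corrupted (undecodable body)",
                                  class = "pf_blob_integrity_error")
                   })
  if (substr(rlang::hash(text), 1, 16) != parts[3]) {
    rlang::abort("share blob failed its integrity check (checksum mismatch)",
                 class = "pf_blob_integrity_error")
  }
  .pf_parse_pcml_xml(xml2::read_xml(text))
}
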