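# Proteoform objects and the supported ProForma subset.

#' Construct a proteoform
#'
#' A proteoform is a sequence over the 20-letter amino-acid alphabet plus its
#' full set of modifications: optional N-/C-terminal modifications, localized
#' modifications at 1-based residue positions, and fixed modifications applied
#' to every residue in their target set.
#'
#' @param residues Character scalar over the canonical one-letter alphabet.
#' @param n_term_mod,c_term_mod Optional [modification()] objects.
#' @param localized Named list mapping 1-based position (as names, or a list of
#'   `list(pos =, mod =)` entries) to modifications; a position may carry
#'   several modifications.
#' @param fixed_mods List of `"fixed"`-category modifications.
#' @return A `pf_proteoform` object.
#' @examples
#' p <- proteoform("PEPTIDE",
#'   localized = list(list(pos = 4, mod = lookup_modification("Phospho"))))
#' intact_mass(p)
#' @export
proteoform <- function(residues, n_term_mod = NULL, c_term_mod = NULL,
                       localized = list(), fixed_mods = list()) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  residue_mass(strsplit(residues, "")[[1]]) # validates the alphabet
  n <- nchar(residues)
  loc <- list()
  for (entry in localized) {
    if (inherits(entry, "pf_mod")) rlang::abort(
      "localized entries must be list(pos =, mod =)", class = "pf_invalid_proteoform")
    pos <- as.integer(entry$pos)
    if (is.na(pos) || pos < 1L || pos > n) {
      rlang::abort(sprintf("localized position %s outside 1..%d", entry$pos, n),
                   class = "pf_invalid_proteoform")
    }
    stopifnot(inherits(entry$mod, "pf_mod"))
    loc[[length(loc) + 1L]] <- list(pos = pos, mod = entry$mod)
  }
  ord <- order(vapply(loc, `[[`, 0L, "pos"))
  structure(
    list(residues = residues, n_term_mod = n_term_mod, c_term_mod = c_term_mod,
         localized = loc[ord], fixed_mods = fixed_mods),
    class = "pf_proteoform"
  )
}

#' @export
print.pf_proteoform <- function(x, ...) {
  cat(sprintf("<proteoform> %d residues, intact %0.6f Da\n",
              nchar(x$residues), intact_mass(x)))
  cat("  ", write_proforma(x), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a proteoform
#' @param p A `pf_proteoform`.
#' @return Integer length.
#' @export
proteoform_length <- function(p) nchar(p$residues)

# Per-residue masses with localized and fixed modifications folded in, plus
# terminal mod masses. The basis for both intact mass and fragment generation.
.pf_mass_layout <- function(p) {
  res <- strsplit(p$residues, "")[[1]]
  m <- residue_mass(res)
  for (entry in p$localized) {
    m[entry$pos] <- m[entry$pos] + resolve_modification_mass(entry$mod)
  }
  nterm <- if (!is.null(p$n_term_mod)) resolve_modification_mass(p$n_term_mod) else 0
  cterm <- if (!is.null(p$c_term_mod)) resolve_modification_mass(p$c_term_mod) else 0
  for (fm in p$fixed_mods) {
    dm <- resolve_modification_mass(fm)
    hit <- res %in% fm$targets
    m[hit] <- m[hit] + dm
    if ("N-term" %in% fm$targets) nterm <- nterm + dm
    if ("C-term" %in% fm$targets) cterm <- cterm + dm
  }
  list(residue = m, nterm = nterm, cterm = cterm)
}

#' Theoretical intact neutral monoisotopic mass
#'
#' Sum of residue masses plus one water plus all resolved modification masses.
#'
#' @param p A `pf_proteoform`.
#' @return Mass in Da.
#' @export
intact_mass <- function(p) {
  stopifnot(inherits(p, "pf_proteoform"))
  lay <- .pf_mass_layout(p)
  sum(lay$residue) + .pf_water() + lay$nterm + lay$cterm
}

# ---- ProForma ---------------------------------------------------------------

.pf_resolve_tag <- function(tag) {
  tag <- trimws(tag)
  if (grepl("^[+-]?\\d+(\\.\\d+)?$", tag)) {
    shift <- as.numeric(tag)
    return(modification(sprintf("%+.6f", shift), "custom", mass_shift = shift))
  }
  if (grepl("^formula:", tag, ignore.case = TRUE)) {
    f <- sub("^[Ff]ormula:", "", tag)
    return(modification(tag, "custom", formula = parse_formula(f)))
  }
  if (grepl("^glycan:", tag, ignore.case = TRUE)) {
    g <- sub("^[Gg]lycan:", "", tag)
    return(modification(tag, "custom", glycan = glycan_composition(g)))
  }
  lookup_modification(tag)
}

#' Parse a ProForma string (supported subset)
#'
#' Supports a bare sequence, localized bracketed tags after a residue
#' (`PEPT[+79.966331]IDE`, `[Phospho]`, `[Formula:HPO3]`,
#' `[Glycan:HexNAc4Hex4Fuc1]`), and single N-/C-terminal tags with the
#' standard delimiters (`[Acetyl]-PEPTIDE`, `PEPTIDE-[+14.015650]`). Named tags
#' resolve against the local catalogue only.
#'
#' Unsupported ProForma features are rejected with an error naming the
#' feature: unlocalized tags (`[...]?SEQ`), labile tags (`{...}`), and range
#' tags (`(...)[...]`).
#'
#' @param text A ProForma string.
#' @return A [proteoform()].
#' @examples
#' parse_proforma("PEPT[+79.966331]IDE")
#' @export
parse_proforma <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) rlang::abort("empty ProForma string", class = "pf_proforma_error")
  if (grepl("[{}]", text)) {
    rlang::abort("labile modifications ({...}) are not supported",
                 class = "pf_unsupported_proforma_feature")
  }
  if (grepl("[()]", text)) {
    rlang::abort("range modifications ((...)) are not supported",
                 class = "pf_unsupported_proforma_feature")
  }
  if (grepl("^(\\[[^\\]]*\\])+(\\^\\d+)?\\?", text, perl = TRUE)) {
    rlang::abort("unlocalized modifications ([...]?) are not supported",
                 class = "pf_unsupported_proforma_feature")
  }
  n_term_mod <- NULL
  c_term_mod <- NULL
  m <- regmatches(text, regexec("^\\[([^\\]]*)\\]-", text, perl = TRUE))[[1]]
  if (length(m)) {
    n_term_mod <- .pf_resolve_tag(m[2])
    text <- substr(text, nchar(m[1]) + 1L, nchar(text))
  }
  m <- regmatches(text, regexec("-\\[([^\\]]*)\\]$", text, perl = TRUE))[[1]]
  if (length(m)) {
    c_term_mod <- .pf_resolve_tag(m[2])
    text <- substr(text, 1L, nchar(text) - nchar(m[1]))
  }
  chars <- strsplit(text, "")[[1]]
  residues <- character()
  localized <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(close)) rlang::abort("unterminated '[' tag", class = "pf_proforma_error")
      tag <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (length(residues) == 0L) {
        rlang::abort("tag before any residue (terminal tags use '[...]-' / '-[...]')",
                     class = "pf_unsupported_proforma_feature")
      }
      localized[[length(localized) + 1L]] <-
        list(pos = length(residues), mod = .pf_resolve_tag(tag))
      i <- close + 1L
    } else {
      residue_mass(ch) # errors on illegal residue
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  if (length(residues) == 0L) {
    rlang::abort("ProForma string contains no residues", class = "pf_proforma_error")
  }
  proteoform(paste(residues, collapse = ""), n_term_mod = n_term_mod,
             c_term_mod = c_term_mod, localized = localized)
}

.pf_write_tag <- function(mod) {
  chem <- .pf_chem()
  if (tolower(mod$name) %in% names(chem$catalogue)) return(mod$name)
  sprintf("%+.6f", resolve_modification_mass(mod))
}

#' Write a proteoform as ProForma text
#'
#' Canonical form: catalogue modifications are emitted by name, everything
#' else as a signed mass delta with 6 decimals. `parse_proforma(write_proforma(p))`
#' reproduces the resolved masses of a canonically-built proteoform exactly.
#' Fixed modifications, which ProForma has no slot for, are expanded to
#' localized tags at each target residue.
#'
#' @param p A `pf_proteoform`.
#' @return A ProForma string.
#' @export
write_proforma <- function(p) {
  stopifnot(inherits(p, "pf_proteoform"))
  res <- strsplit(p$residues, "")[[1]]
  tags <- vector("list", length(res))
  for (entry in p$localized) {
    tags[[entry$pos]] <- c(tags[[entry$pos]], .pf_write_tag(entry$mod))
  }
  for (fm in p$fixed_mods) {
    for (pos in which(res %in% fm$targets)) {
      tags[[pos]] <- c(tags[[pos]], .pf_write_tag(fm))
    }
  }
  body <- vapply(seq_along(res), function(i) {
    if (is.null(tags[[i]])) res[i]
    else paste0(res[i], paste0("[", tags[[i]], "]", collapse = ""))
  }, "")
  nterm_fixed <- Filter(function(fm) "N-term" %in% fm$targets, p$fixed_mods)
  cterm_fixed <- Filter(function(fm) "C-term" %in% fm$targets, p$fixed_mods)
  nterm <- c(if (!is.null(p$n_term_mod)) .pf_write_tag(p$n_term_mod),
             vapply(nterm_fixed, .pf_write_tag, ""))
  cterm <- c(if (!is.null(p$c_term_mod)) .pf_write_tag(p$c_term_mod),
             vapply(cterm_fixed, .pf_write_tag, ""))
  paste0(
    if (length(nterm)) paste0("[", nterm, "]", collapse = "") else "",
    if (length(nterm)) "-" else "",
    paste(body, collapse = ""),
    if (length(cterm)) "-" else "",
    if (length(cterm)) paste0("[", cterm, "]", collapse = "") else ""
  )
}

#' Tidy a proteoform into a per-residue tibble
#'
#' @param x A `pf_proteoform`.
#' @param ... Unused.
#' @return A tibble with one row per residue: `pos`, `residue`, `mass`
#'   (with localized/fixed modifications folded in), `mods` (comma-joined
#'   modification names, `NA` if none).
#' @export
tidy.pf_proteoform <- function(x, ...) {
  lay <- .pf_mass_layout(x)
  res <- strsplit(x$residues, "")[[1]]
  mods <- rep(NA_character_, length(res))
  add <- function(pos, nm) {
    mods[pos] <<- if (is.na(mods[pos])) nm else paste(mods[pos], nm, sep = ",")
  }
  for (entry in x$localized) add(entry$pos, entry$mod$name)
  for (fm in x$fixed_mods) for (pos in which(res %in% fm$targets)) add(pos, fm$name)
  tibble::tibble(pos = seq_along(res), residue = res, mass = lay$residue, mods = mods)
}
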