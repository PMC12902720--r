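# Elemental compositions, monoisotopic masses, residues, modifications, glycans.
# All masses in the package are neutral monoisotopic Da derived from the bundled
# atomic-mass table; residue and glycan masses are computed from compositions at
# load time so there is a single source of truth.

.pf <- new.env(parent = emptyenv())

.pf_data_file <- function(name, pkgname = "proformatch") {
  path <- system.file("extdata", name, package = pkgname)
  if (!nzchar(path)) {
    # during development (pkgload) extdata may sit under inst/
    path <- system.file("inst", "extdata", name, package = pkgname)
  }
  if (!nzchar(path)) rlang::abort(paste0("bundled data file not found: ", name))
  path
}

.pf_read_table <- function(name, pkgname = "proformatch") {
  utils::read.delim(.pf_data_file(name, pkgname), comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = NULL)
}

.pf_load_chem <- function(pkgname = "proformatch") {
  at <- .pf_read_table("atomic_masses.tsv", pkgname)
  .pf$atomic <- stats::setNames(as.numeric(at$monoisotopic_mass), at$symbol)

  rc <- .pf_read_table("residue_compositions.tsv", pkgname)
  .pf$residue_comp <- stats::setNames(lapply(rc$formula, parse_formula), rc$code)
  .pf$residue_mass <- vapply(.pf$residue_comp, mass_of_composition, numeric(1))

  gl <- .pf_read_table("glycan_tokens.tsv", pkgname)
  .pf$glycan_comp <- stats::setNames(lapply(gl$formula, parse_formula), gl$token)
  .pf$glycan_mass <- vapply(.pf$glycan_comp, mass_of_composition, numeric(1))

  .pf$water <- mass_of_composition(parse_formula("H2O"))
  .pf$proton_mass <- .pf$atomic[["H"]]          # H atom, not proton; used in z* offset
  # ion-series offsets relative to the b / y backbone sums
  co  <- mass_of_composition(parse_formula("CO"))
  nh3 <- mass_of_composition(parse_formula("NH3"))
  h2  <- mass_of_composition(parse_formula("H2"))
  .pf$series_offset <- c(
    a = -co, b = 0, c = nh3,
    x = co - h2, y = 0, z = -(nh3 - .pf$atomic[["H"]])
  )

  cat <- .pf_read_table("ptm_catalogue.tsv", pkgname)
  mods <- lapply(seq_len(nrow(cat)), function(i) {
    row <- cat[i, ]
    modification(
      name     = row$name,
      category = row$category,
      targets  = strsplit(row$targets, ",", fixed = TRUE)[[1]],
      formula  = if (nzchar(row$formula)) row$formula else NULL,
      glycan   = if (nzchar(row$glycan)) row$glycan else NULL
    )
  })
  .pf$catalogue <- stats::setNames(mods, tolower(vapply(mods, `[[`, "", "name")))
  invisible()
}

.onLoad <- function(libname, pkgname) {
  .pf_load_chem(pkgname)
}

.pf_chem <- function() {
  if (is.null(.pf$atomic)) .pf_load_chem()
  .pf
}

#' Parse a Hill-style elemental formula
#'
#' Accepts element+count tokens such as `"C2H3NO"`, `"HO3P"`, `"H-1N-1O"`, or
#' isotope-prefixed symbols such as `"13C2"`. Counts may be negative (useful
#' for loss-type modifications); an omitted count means 1.
#'
#' @param text A formula string.
#' @return A named integer vector (element symbol to signed count), normalized:
#'   zero counts dropped, symbols sorted.
#' @examples
#' parse_formula("H2O")
#' parse_formula("H-1N-1O") # deamidation
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) return(composition())
  m <- gregexpr("(\\d+)?[A-Z][a-z]?(-?\\d+)?", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    rlang::abort(paste0("cannot parse formula: '", text, "'"),
                 class = "pf_formula_error")
  }
  sym <- sub("(-?\\d+)$", "", tokens)
  cnt <- suppressWarnings(as.integer(sub("^.*?[A-Za-z]", "", tokens)))
  cnt[is.na(cnt)] <- 1L
  composition(stats::setNames(cnt, sym))
}

#' Build a normalized elemental composition
#'
#' @param counts Named integer vector of element symbol to signed count.
#' @return Named integer vector with zero entries removed and symbols sorted;
#'   composition addition is [comp_add()].
#' @export
composition <- function(counts = integer()) {
  if (length(counts) == 0L) return(stats::setNames(integer(), character()))
  counts <- vapply(split(as.integer(counts), names(counts)), sum, integer(1))
  counts <- counts[counts != 0L]
  counts[order(names(counts))]
}

#' Add or subtract elemental compositions
#'
#' @param a,b Compositions as returned by [composition()] or [parse_formula()].
#' @return The normalized sum (or difference) composition.
#' @export
comp_add <- function(a, b) composition(c(a, b))

#' @rdname comp_add
#' @export
comp_sub <- function(a, b) composition(c(a, -b))

#' Monoisotopic mass of an elemental composition
#'
#' @param comp A composition (named signed integer vector).
#' @return Mass in Da: the sum of count times the bundled monoisotopic atomic
#'   mass of each element.
#' @examples
#' mass_of_composition(parse_formula("H2O")) # 18.010565
#' @export
mass_of_composition <- function(comp) {
  chem <- .pf_chem()
  if (length(comp) == 0L) return(0)
  unknown <- setdiff(names(comp), names(chem$atomic))
  if (length(unknown)) {
    rlang::abort(paste0("unknown element symbol: ", paste(unknown, collapse = ", ")),
                 class = "pf_unknown_element")
  }
  sum(chem$atomic[names(comp)] * as.numeric(comp))
}

#' Monoisotopic mass of an amino-acid residue
#'
#' Residue (dehydrated) masses, derived at load time from the bundled residue
#' compositions.
#'
#' @param code One-letter code(s) for the 20 canonical amino acids.
#' @return Numeric vector of residue masses in Da.
#' @examples
#' residue_mass("G") # 57.02146
#' @export
residue_mass <- function(code) {
  chem <- .pf_chem()
  code <- as.character(code)
  bad <- setdiff(unique(code), names(chem$residue_mass))
  if (length(bad)) {
    rlang::abort(paste0("unsupported residue: ", paste(bad, collapse = ", "),
                        " (only the 20 canonical one-letter codes are supported)"),
                 class = "pf_unsupported_residue")
  }
  unname(chem$residue_mass[code])
}

#' Residue monoisotopic mass table
#'
#' @return A tibble with columns `code`, `mass`.
#' @export
residue_masses <- function() {
  chem <- .pf_chem()
  tibble::tibble(code = names(chem$residue_mass), mass = unname(chem$residue_mass))
}

#' Parse a glycan composition string
#'
#' @param text Token+count string over `Hex`, `HexNAc`, `Fuc`, `NeuAc`,
#'   `NeuGc`, `Pent`, e.g. `"HexNAc4Hex4Fuc1"` (the G1F glycan).
#' @return Named non-negative integer vector of monosaccharide counts.
#' @export
glycan_composition <- function(text) {
  chem <- .pf_chem()
  if (is.numeric(text) || (is.character(text) && length(names(text)))) {
    counts <- text
  } else {
    stopifnot(is.character(text), length(text) == 1L)
    text <- gsub("[[:space:]]", "", text)
    # greedy token scan: try longest known token names first
    counts <- integer()
    rest <- text
    tok_names <- names(chem$glycan_comp)[order(-nchar(names(chem$glycan_comp)))]
    while (nzchar(rest)) {
      hit <- NULL
      for (tk in tok_names) {
        if (startsWith(rest, tk)) { hit <- tk; break }
      }
      if (is.null(hit)) {
        rlang::abort(paste0("unknown glycan token at: '", rest, "'"),
                     class = "pf_unknown_glycan_token")
      }
      rest <- substr(rest, nchar(hit) + 1L, nchar(rest))
      n <- regmatches(rest, regexpr("^\\d+", rest))
      if (length(n)) {
        rest <- substr(rest, nchar(n) + 1L, nchar(rest))
        n <- as.integer(n)
      } else n <- 1L
      counts[hit] <- (if (hit %in% names(counts)) counts[[hit]] else 0L) + n
    }
  }
  bad <- setdiff(names(counts), names(chem$glycan_comp))
  if (length(bad)) {
    rlang::abort(paste0("unknown glycan token: ", paste(bad, collapse = ", ")),
                 class = "pf_unknown_glycan_token")
  }
  if (any(counts < 0)) rlang::abort("glycan counts must be non-negative",
                                    class = "pf_unknown_glycan_token")
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[out != 0L]
  out[order(names(out))]
}

#' Monoisotopic mass of a glycan composition
#'
#' Uses residue (dehydrated) monosaccharide masses, i.e. the mass added when
#' the glycan is attached through a glycosidic bond.
#'
#' @param glycan A composition string or named count vector
#'   (see [glycan_composition()]).
#' @return Mass in Da.
#' @export
glycan_mass <- function(glycan) {
  chem <- .pf_chem()
  g <- glycan_composition(glycan)
  if (length(g) == 0L) return(0)
  sum(chem$glycan_mass[names(g)] * as.numeric(g))
}

#' Define a modification
#'
#' A modification carries exactly one mass source: a numeric `mass_shift` in
#' Da, an elemental `formula`, or a `glycan` composition. Categories follow
#' common usage: `"PTM"`, `"fixed"` (applied to every target residue),
#' `"N-glycan"`, `"custom"`.
#'
#' @param name Display name (used when writing ProForma if the name is in the
#'   catalogue).
#' @param category One of `"PTM"`, `"fixed"`, `"N-glycan"`, `"custom"`.
#' @param targets Character vector of residue codes and/or `"N-term"`,
#'   `"C-term"`. Required (non-empty) for `"fixed"` modifications.
#' @param mass_shift Numeric mass shift in Da.
#' @param formula Formula string or composition.
#' @param glycan Glycan composition string or named count vector.
#' @return A `pf_mod` object.
#' @examples
#' modification("Phospho", "PTM", c("S", "T", "Y"), formula = "HO3P")
#' modification("acetyl-like", "custom", mass_shift = 42.010565)
#' @export
modification <- function(name, category = "custom", targets = character(),
                         mass_shift = NULL, formula = NULL, glycan = NULL) {
  n_src <- sum(!is.null(mass_shift), !is.null(formula), !is.null(glycan))
  if (n_src != 1L) {
    rlang::abort("a modification needs exactly one of mass_shift, formula, glycan",
                 class = "pf_invalid_modification")
  }
  category <- match.arg(category, c("PTM", "fixed", "N-glycan", "custom"))
  if (category == "fixed" && length(targets) == 0L) {
    rlang::abort("fixed modifications require a non-empty target set",
                 class = "pf_invalid_modification")
  }
  if (!is.null(formula) && is.character(formula) && is.null(names(formula))) {
    formula <- parse_formula(formula)
  }
  if (!is.null(glycan)) glycan <- glycan_composition(glycan)
  if (!is.null(mass_shift) && !is.finite(mass_shift)) {
    rlang::abort("mass_shift must be finite", class = "pf_invalid_modification")
  }
  structure(
    list(name = as.character(name), category = category,
         targets = as.character(targets),
         mass_shift = mass_shift, formula = formula, glycan = glycan),
    class = "pf_mod"
  )
}

#' @export
print.pf_mod <- function(x, ...) {
  cat(sprintf("<modification> %s [%s] %+0.6f Da", x$name, x$category,
              resolve_modification_mass(x)))
  if (length(x$targets)) cat(" @", paste(x$targets, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Resolve a modification to its monoisotopic mass shift
#'
#' Numeric shifts are returned verbatim; formulas and glycans are routed
#' through [mass_of_composition()] / [glycan_mass()], so repeated resolution is
#' bit-identical.
#'
#' @param mod A `pf_mod` object.
#' @return Mass shift in Da.
#' @export
resolve_modification_mass <- function(mod) {
  if (!inherits(mod, "pf_mod")) rlang::abort("not a pf_mod",
                                             class = "pf_invalid_modification")
  if (!is.null(mod$mass_shift)) return(as.numeric(mod$mass_shift))
  if (!is.null(mod$formula)) return(mass_of_composition(mod$formula))
  glycan_mass(mod$glycan)
}

#' The bundled modification catalogue
#'
#' A starter set of PTMs, fixed modifications and named N-glycans; extensible
#' for the current session with [register_modification()].
#'
#' @return A tibble with one row per catalogue entry: `name`, `category`,
#'   `targets` (comma-joined), `mass_shift` (resolved Da).
#' @export
pf_modifications <- function() {
  chem <- .pf_chem()
  mods <- chem$catalogue
  tibble::tibble(
    name = vapply(mods, `[[`, "", "name"),
    category = vapply(mods, `[[`, "", "category"),
    targets = vapply(mods, function(m) paste(m$targets, collapse = ","), ""),
    mass_shift = vapply(mods, resolve_modification_mass, numeric(1))
  )
}

#' Look up a modification by name
#'
#' Name matching is case-insensitive. Only the local catalogue is consulted;
#' there are no online ontology lookups.
#'
#' @param name Modification name.
#' @return A `pf_mod` object.
#' @export
lookup_modification <- function(name) {
  chem <- .pf_chem()
  key <- tolower(name)
  if (!key %in% names(chem$catalogue)) {
    rlang::abort(paste0("unknown modification: '", name, "'"),
                 class = "pf_unknown_modification")
  }
  chem$catalogue[[key]]
}

#' Register a modification in the session catalogue
#'
#' @param mod A `pf_mod` object; afterwards resolvable by name in ProForma
#'   input for the rest of the session.
#' @return `mod`, invisibly.
#' @export
register_modification <- function(mod) {
  stopifnot(inherits(mod, "pf_mod"))
  resolve_modification_mass(mod) # validate
  chem <- .pf_chem()
  chem$catalogue[[tolower(mod$name)]] <- mod
  invisible(mod)
}

.pf_water <- function() .pf_chem()$water
.pf_series_offset <- function() .pf_chem()$series_offset
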