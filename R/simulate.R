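# Synthetic observed-mass lists with ground truth: emulates a deconvolution
# output (a flat list of neutral monoisotopic masses) for a known proteoform,
# with Gaussian ppm noise, optional off-by-one isotope corruption, and
# uniform decoy masses.

.pf_restore_seed <- function() {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate an observed mass list with ground truth
#'
#' Samples a fraction of the theoretical fragments, perturbs each by Gaussian
#' ppm noise (instrument error scales with mass, matching the ppm tolerance
#' model), shifts a chosen number of them by one isotope spacing with random
#' sign (emulating off-by-one deconvolution errors), adds uniform decoy masses
#' in (100, intact mass), and shuffles. Fully deterministic for a fixed seed.
#'
#' @param p A [proteoform()].
#' @param series Ion series to draw true fragments from.
#' @param frac_matched Fraction of fragments planted, in `[0, 1]`.
#' @param ppm_sigma Gaussian ppm noise sigma.
#' @param n_decoys Number of uniform decoy masses.
#' @param n_isotope_corrupted Number of planted fragments additionally shifted
#'   by one isotope spacing (random sign); must not exceed the planted count.
#' @param spacing Isotope spacing in Da.
#' @param seed Integer RNG seed.
#' @return A list with `observed` (an [observed_masses()] tibble) and `truth`
#'   (a tibble: `observed_id`, `kind` `"fragment"`/`"decoy"`, `series`,
#'   `index`, `theoretical_mass`, `true_shift`).
#' @export
simulate_observed <- function(p, series = c("b", "y"), frac_matched = 0.5,
                              ppm_sigma = 1, n_decoys = 0L,
                              n_isotope_corrupted = 0L, spacing = 1.00235,
                              seed = 1L) {
  stopifnot(inherits(p, "pf_proteoform"))
  if (frac_matched < 0 || frac_matched > 1) {
    rlang::abort("frac_matched must be in [0, 1]", class = "pf_invalid_config")
  }
  stopifnot(ppm_sigma >= 0, n_decoys >= 0, spacing > 0)
  restore <- .pf_restore_seed()
  on.exit(restore())
  set.seed(as.integer(seed))

  frags <- generate_fragments(p, series)
  n_pick <- round(frac_matched * nrow(frags))
  if (n_isotope_corrupted > n_pick) {
    rlang::abort("n_isotope_corrupted exceeds the number of planted fragments",
                 class = "pf_invalid_config")
  }
  picked <- frags[sample.int(nrow(frags), n_pick), , drop = FALSE]
  true_shift <- integer(n_pick)
  if (n_isotope_corrupted > 0) {
    corrupt <- sample.int(n_pick, n_isotope_corrupted)
    true_shift[corrupt] <- sample(c(-1L, 1L), n_isotope_corrupted, replace = TRUE)
  }
  mass <- picked$neutral_mass *
    (1 + stats::rnorm(n_pick, 0, ppm_sigma) * 1e-6) +
    true_shift * spacing
  truth <- tibble::tibble(
    kind = rep("fragment", n_pick),
    series = as.character(picked$series), index = picked$index,
    theoretical_mass = picked$neutral_mass, true_shift = true_shift,
    neutral_mass = mass
  )
  if (n_decoys > 0) {
    decoys <- stats::runif(n_decoys, 100, intact_mass(p))
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      kind = "decoy", series = NA_character_, index = NA_integer_,
      theoretical_mass = NA_real_, true_shift = NA_integer_,
      neutral_mass = decoys
    ))
  }
  truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
  truth$observed_id <- seq_len(nrow(truth))
  observed <- observed_masses(truth$neutral_mass)
  list(
    observed = observed,
    truth = truth[, c("observed_id", "kind", "series", "index",
                      "theoretical_mass", "true_shift", "neutral_mass")]
  )
}

#' Write a simulated ground-truth table as TSV
#'
#' @param truth Truth tibble from [simulate_observed()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' A synthetic glycoprotein demo proteoform
#'
#' A fabricated 70-residue sequence (not any database protein) carrying the
#' biantennary G1F N-glycan (HexNAc4Hex4Fuc1) at its single NxT sequon
#' asparagine, N61 — the modification setting typical of antibody Fc
#' subunit characterization. The sequence was chosen once so that no two
#' theoretical b/y/c/z fragments lie within 10 ppm of each other at 0 or
#' +/-1 isotope-spacing offsets, which makes planted-fragment recovery in
#' simulations unambiguous.
#'
#' @param glycan Name of the catalogue glycan to attach (default `"G1F"`).
#' @return A [proteoform()].
#' @export
demo_proteoform <- function(glycan = "G1F") {
  proteoform(
    .pf_demo_sequence,
    localized = list(list(pos = 61L, mod = lookup_modification(glycan)))
  )
}

# frozen synthetic sequence; single N at position 61 in an N-S-T sequon
.pf_demo_sequence <-
  "IQGKRTYEETDKDHADVFAEHIKPIRETPRFAPSIQRTQDQEEHSMWQPWDKMMDQPSHINSTLYGPCFH"
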