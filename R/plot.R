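# ggplot2 views of match results. The publication figure is the SVG fragment
# map (render_map); these plots are quick diagnostics.

#' Plot a match set
#'
#' Scatter of signed ppm error against theoretical fragment mass for the
#' winning matches, coloured by ion series and shaped by applied isotope
#' shift; dashed lines mark the matching tolerance.
#'
#' @param object A `pf_match_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_match_set <- function(object, ...) {
  m <- dplyr::mutate(object$matches,
                     series = as.character(.data$series),
                     shift = factor(.data$shift_steps))
  tol <- object$config$tol_ppm
  ggplot2::ggplot(m, ggplot2::aes(x = .data$theoretical_mass,
                                  y = .data$ppm_error,
                                  colour = .data$series,
                                  shape = .data$shift)) +
    ggplot2::geom_hline(yintercept = c(-tol, tol), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "theoretical fragment mass (Da)",
                  y = "ppm error (observed vs theoretical)",
                  colour = "series", shape = "isotope\nshift") +
    ggplot2::theme_minimal()
}

#' Plot per-site coverage
#'
#' Cleavage-site coverage along the backbone, split by evidencing terminus.
#'
#' @param ms A `pf_match_set`.
#' @param n_residues Proteoform length.
#' @return A ggplot object.
#' @export
plot_coverage <- function(ms, n_residues) {
  sites <- covered_sites(ms, n_residues)
  long <- tidyr::pivot_longer(sites, c("n_term", "c_term"),
                              names_to = "terminus", values_to = "covered")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$terminus,
                                     fill = .data$covered)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "#1f77b4")) +
    ggplot2::labs(x = "cleavage site", y = NULL, fill = "covered") +
    ggplot2::theme_minimal()
}
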