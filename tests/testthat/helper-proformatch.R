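# shared helpers: random proteoform generation and an independent brute-force
# matching oracle (nested loops, explicit comparator) used to cross-check the
# vectorized matcher.

series_rank <- c(a = 1, b = 2, c = 3, x = 4, y = 5, z = 6)

rand_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# a random modified proteoform; custom masses at 6-decimal precision (the
# canonical ProForma printing precision)
rand_proteoform <- function(n = sample(5:30, 1), n_mods = sample(0:3, 1),
                            terminal = TRUE) {
  loc <- lapply(seq_len(n_mods), function(i) {
    if (stats::runif(1) < 0.5) {
      list(pos = sample(n, 1), mod = lookup_modification(
        sample(c("Phospho", "Acetyl", "Oxidation", "Methyl", "G1F"), 1)))
    } else {
      list(pos = sample(n, 1),
           mod = modification(
             sprintf("%+.6f", round(stats::runif(1, -100, 300), 6)),
             "custom",
             mass_shift = as.numeric(sprintf("%.6f", stats::runif(1, -100, 300)))))
    }
  })
  nt <- if (terminal && stats::runif(1) < 0.3) lookup_modification("Acetyl") else NULL
  ct <- if (terminal && stats::runif(1) < 0.3) {
    modification("+14.015650", "custom", mass_shift = 14.01565)
  } else NULL
  proteoform(rand_sequence(n), n_term_mod = nt, c_term_mod = ct, localized = loc)
}

# independent oracle: all pairs, all shifts, explicit winner comparator
brute_force_match <- function(observed, fragments, cfg) {
  obs <- observed_masses(observed)
  frag <- fragments[as.character(fragments$series) %in% cfg$series, , drop = FALSE]
  k <- cfg$n_isotope_shifts
  cand <- list()
  winners <- list()
  for (i in seq_len(nrow(obs))) {
    best <- NULL
    for (j in seq_len(nrow(frag))) {
      for (s in seq.int(-k, k)) {
        f <- frag$neutral_mass[j]
        ppm <- (obs$neutral_mass[i] - s * cfg$isotope_spacing - f) / f * 1e6
        if (abs(ppm) <= cfg$tol_ppm) {
          row <- list(observed_id = obs$id[i], series = as.character(frag$series[j]),
                      index = frag$index[j], shift_steps = as.integer(s), ppm = ppm)
          cand[[length(cand) + 1L]] <- row
          better <- is.null(best) ||
            abs(s) < abs(best$shift_steps) ||
            (abs(s) == abs(best$shift_steps) && abs(ppm) < abs(best$ppm)) ||
            (abs(s) == abs(best$shift_steps) && abs(ppm) == abs(best$ppm) &&
               (series_rank[[row$series]] < series_rank[[best$series]] ||
                  (series_rank[[row$series]] == series_rank[[best$series]] &&
                     row$index < best$index)))
          if (better) best <- row
        }
      }
    }
    if (!is.null(best)) winners[[length(winners) + 1L]] <- best
  }
  list(candidates = cand, winners = winners)
}

triple_string <- function(id, series, index, shift) {
  paste(id, series, index, shift, sep = "/")
}

match_set_triples <- function(ms) {
  m <- ms$matches
  sort(triple_string(m$observed_id, as.character(m$series), m$index, m$shift_steps))
}

oracle_triples <- function(br) {
  sort(vapply(br$winners, function(w)
    triple_string(w$observed_id, w$series, w$index, w$shift_steps), ""))
}

count_rows_in_svg <- function(svg) {
  # residue glyphs are the monospace text elements; rows = distinct y values
  ys <- regmatches(svg, gregexpr('<text x="[0-9]+" y="([0-9]+)" font-family="monospace[^>]*', svg))[[1]]
  length(unique(sub('.* y="([0-9]+)".*', "\\1", ys)))
}

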