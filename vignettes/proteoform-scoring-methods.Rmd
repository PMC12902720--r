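---
title: "Proteoform fragment matching and scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteoform fragment matching and scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proformatch)
```

## Scope and assumptions

`proformatch` scores one candidate proteoform at a time against a flat list
of deconvoluted **neutral monoisotopic** fragment masses. It deliberately
lives downstream of deconvolution: charge states, isotope envelopes and peak
picking are assumed already resolved by tools such as THRASH-style
deconvolution, whose characteristic failure mode — reporting the
monoisotopic mass off by an integer number of isotopologue spacings — is the
one artifact we model explicitly. Nothing in the package touches m/z.

All masses derive from a single bundled monoisotopic atomic-mass table
(`inst/extdata/atomic_masses.tsv`); residue and monosaccharide masses are
computed from their elemental compositions at load time. This single-source
rule is tested (`residue_mass()` must equal `mass_of_composition()` of the
bundled composition bit-for-bit) so a table edit cannot silently desynchronize
chemistry.

## The fragment model

For an `n`-residue proteoform, each selected series contributes `n - 1`
fragments. `b` prefixes and `y` suffixes carry the backbone sums (plus
terminal modifications and water, respectively); the other series are fixed
offsets computed from compositions, not hard-coded decimals: `a = b - CO`,
`c = b + NH3`, `x = y + CO - H2`, `z = y - NH3 + H`. The `z` series is
emitted as the z-radical (z•), the species actually observed in ETD/EThcD
data; an even-electron variant would be a one-line offset change but is not
the default. Two invariants pin the chemistry down and are enforced to
1e-9 Da in the tests: `b_i + y_{n-i}` equals the intact mass exactly, and a
localized modification at position `p` shifts exactly the N-terminal
fragments with index ≥ `p` and the C-terminal fragments with index
≥ `n - p + 1`.

Cysteine carries **no** implicit fixed modification: top-down samples are
frequently unalkylated, so carbamidomethylation must be requested explicitly
as a fixed modification. Glycan masses use dehydrated (residue)
monosaccharide masses, matching standard N-glycan accounting for
glycosidic-bond attachment.

## Matching and the off-by-n isotope model

An observed mass `m` matches fragment `f` at integer shift `s` in `[-k, k]`
iff `|m - s*spacing - f| / f * 1e6 <= tol_ppm`. Parameter choices:

* `tol_ppm` (default 10 ppm): the working tolerance of well-calibrated FTMS
  fragment data. The denominator is always the **theoretical** mass; this is
  an arbitrary but consequential convention, fixed and documented so errors
  are reproducible.
* `isotope_spacing` (default 1.00235 Da): the averagine inter-isotopologue
  spacing, the natural constant for deconvolution off-by-one errors. It is a
  parameter, not a constant, because other spacings (e.g. pure ¹³C−¹²C) are
  defensible.
* `n_isotope_shifts` `k` (default 0): symmetric integer shifts. Every enabled
  step adds two ion types per selected series (one for `+s`, one for `-s`),
  giving the effective ion-type count `|series| * (1 + 2k)` that feeds the
  scores below.

Each observed mass receives at most one winning match, chosen by smallest
`|s|`, then smallest `|ppm|`, then lowest (series, index) in the fixed order
a, b, c, x, y, z. The shift-0 preference is load-bearing: a mass that
matches anything without a shift must never be reported as isotope-corrected.
All in-tolerance candidates are retained in a diagnostics table. Whether an
interactive tool would instead report every observed mass hitting a fragment
is an open design choice; the one-winner rule was chosen because the scores
need a deduplicated matched count, and the candidate table preserves the
rest. The matcher is validated against an exhaustive all-pairs brute-force
oracle (written first, nested loops, explicit comparator) on 200 random
instances.

## The P-score and PCS

Proteoform characterization tools in this lineage report a Poisson-flavoured
P-score and a cumulative characterization score (PCS), but their exact
formulas are not published. This package therefore defines both fully, so
results are self-contained and testable; they are a reimplementation in
spirit, **not** a bit-compatible clone of any closed implementation. The one
externally fixed requirement — isotope-shift recovery must inflate the
ion-type count by `(1 + 2k)` and thereby worsen both scores for an unchanged
match list — is honoured and tested.

Under the null that observed masses are uniform on `(0, M)` (`M` = intact
mass), observed mass `m_i` with half-window `delta_i = m_i * tol * 1e-6`
hits one of the `F = (n-1) * |series| * (1+2k)` fragment windows with
probability `q_i = min(1, F * 2*delta_i / M)`. With `lambda = sum(q_i)` over
**all** observed masses (matched or not):

* `p_score = P(X >= n_matched)`, `X ~ Poisson(lambda)`, computed as the
  regularized lower incomplete gamma function `pgamma(lambda, n_matched)`
  rather than by naive summation, for stability at large `lambda`; the
  identity with `ppois()` is itself cross-checked in a test. Zero matches
  give 1.0.
* `pcs = sum over matched i of -log10(q_i)`: each matched mass contributes
  its information content, so many precise matches on a large proteoform
  score high, and the `(1+2k)` inflation of `q_i` lowers PCS exactly as it
  raises the P-score. Per-observed windows (rather than one averaged window)
  were chosen because they make `lambda` exact under the stated null with no
  further approximation.

The window model is honest in expectation for complementary series: since
`b_i + y_{n-i} = M`, the mean b/y fragment mass is exactly `M/2`, so
`E[lambda]` equals the true expected number of uniform-decoy matches. The
Monte-Carlo calibration (below) exploits this: it is run with series
`{b, y}`; for non-complementary series subsets the model remains a
first-order approximation.

## What the simulator does and does not emulate

`simulate_observed()` emulates the *output* of deconvolution: a shuffled
flat list of neutral masses, built from a known proteoform by sampling a
fraction of its fragments, applying Gaussian **ppm** noise (instrument error
scales with mass — which is why noise is ppm, not Da), shifting a chosen
number by ±1 isotope spacing, and adding uniform decoys on (100 Da, intact
mass) — the 100 Da floor avoids physically silly decoys below the smallest
fragments. Ground truth (which observed id came from which fragment, with
which shift) is returned alongside.

It does **not** simulate raw spectra, isotope envelopes, correlated or
heavy-tailed mass errors, intensity structure, internal fragments or neutral
losses. Passing tests therefore demonstrate algorithmic correctness of
matching, accounting and scoring under the stated error model — not
instrument-level realism on real data.

The bundled `demo_proteoform()` is a fabricated 70-residue sequence (not any
database protein) with a single NxT sequon at N61 carrying the G1F glycan
(HexNAc₄Hex₄Fuc₁) — the typical antibody-Fc characterization setting. The
sequence was drawn once under a fixed seed and frozen, subject to one
constraint: no two theoretical b/y/c/z fragments lie within 10 ppm of each
other at 0 or ±1 isotope offsets. Without that constraint, "was the planted
fragment recovered?" would be ill-posed whenever two theoretical fragments
collide inside the tolerance.

## Numerical and format choices

* **Indexing** is 1-based everywhere — internal structures, user-facing
  reports and `.pcml` ("N61" style positions). A 0-based internal convention
  was considered and rejected: in a 1-based language it invites exactly the
  off-by-one errors it is meant to prevent.
* **Canonical 6-decimal masses.** ProForma mass deltas and every mass in
  `.pcml` print with 6 decimals (1 μDa, three orders below any matching
  tolerance). This makes write→parse round-trips exact for canonically
  constructed objects and `.pcml`/share-blob output byte-deterministic;
  masses with more than 6 decimals are canonicalized on first write.
* **`.pcml` dialect.** The schema (fixed element and attribute order,
  `schemaVersion="1.0"`) is this package's own versioned dialect; legacy
  closed-format files are out of scope. Unknown extension elements under the
  root are preserved opaquely and re-emitted. The share blob is the canonical
  XML, base64url-encoded on one line with an xxHash checksum — a local,
  service-free stand-in for cloud share links.
* **SVG determinism.** The fragment map uses integer-only geometry and fixed
  string templates, so identical inputs give byte-identical SVG 1.1 with no
  scripts or external assets. `residues_per_line = "auto"` resolves to the
  largest of {20, 25, 30, 40, 50} whose row fits `target_width_px` at the
  fixed 22 px cell, falling back to 20. Themes (light/dark) change only
  style attributes, never geometry — tested by string-comparing the geometry
  attributes of both renderings.
* **Degenerate inputs.** Length-1 proteoforms (no cleavage sites), empty
  series sets, non-canonical residues (B, J, O, U, X, Z), modifications with
  zero or two mass sources, and out-of-range localized positions all raise
  typed errors; an empty observed list is *not* an error — it is theoretical
  mode, where only the intact mass is reported.

## Problem sizes

The test suite validates the matcher against the brute-force oracle on 200
random instances of ~50 observed × ~200 fragments, runs the isotope-recovery
experiment over 100 seeded replicates (7 corrupted fragments each), and
calibrates the P-score with 10,000 Monte-Carlo decoy replicates of 400
observed masses (the acceptance script uses 4,000). These sizes give
Monte-Carlo standard errors comfortably below the tested tolerances while
keeping a full run in a few minutes on one CPU.

## Known limitations

* One winning fragment per observed mass; many-to-one evidence appears only
  in the candidates table.
* No internal fragments, neutral losses, intensity weighting, or
  localization scores (C-score-style), and no FDR across candidate sets.
* ProForma support is the documented subset: localized tags (mass delta,
  `Formula:`, `Glycan:`, catalogue names) and single terminal tags;
  unlocalized, labile and range tags are rejected loudly by design.
* The Poisson null assumes non-overlapping fragment windows and uniform
  decoys; at very wide tolerances or for heavily repetitive sequences the
  P-score becomes approximate.
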