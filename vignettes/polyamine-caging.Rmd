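---
title: "Methods: polyamine caging analysis between parallel DNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyamine caging analysis between parallel DNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnacage)
```

## The problem

When DNA is compacted — in nucleosomes, viral capsids, or polyamine-induced
condensates — double helices sit a few nanometres apart and their
counterions occupy the confined space between them. `dnacage` quantifies
how a flexible trivalent polyamine (spermidine-like: nitrogens N1, N5, N10
with three and four methylene carbons between them) behaves in that
geometry: where it sits relative to the grooves and phosphates, whether it
is *caged* between the helices, how long it resides there, and which
conformations and phosphate-bridging geometries it adopts.

The package has two halves: an analysis layer that operates on any
structure + trajectory with the right topology, and a synthetic generator
that produces idealized systems with known ground truth. The generator is
what makes the analysis testable end to end: every classifier can be
checked against the states the generator actually used.

## Analyses and their definitions

**RDF and coordination numbers.** The pair distribution is
g(r) = p(r) / (4πr²Δr) / (N_p/V): p(r) is the time-averaged number of
selected pairs in the shell (r, r+Δr], N_p = |A|·|B| (minus self pairs for
identical selections), and V the box volume (instantaneous box volume
averaged over frames; for aperiodic fixtures the bounding-box volume is
used and flagged). Δr defaults to 0.1 Å. Distances use the minimum-image
convention whenever a box is present; stored coordinates are never
wrapped. The coordination number is the direct integral of the shell
counts up to a cutoff, per reference atom. Shells are closed on the upper
edge and the shell containing the cutoff is included, so a pair at exactly
the cutoff counts inside; this makes the integral agree with direct pair
counting to bin resolution, which matters because the conventional cutoffs
(4.55, 6.4, 6.5 Å) do not fall on 0.1 Å bin edges.

Region selections are name-based within a duplex: minor groove N3/N2/O2,
major groove C8/N7/C5/O6/N4/C6, phosphate O1P/O2P. The major-groove list
is conventionally quoted with C5 twice (purine and pyrimidine C5); the
selection is the union over base types, so both are picked up wherever
they exist. Per-base-pair coordination profiles average the per-duplex
profiles position-wise when two duplexes are analyzed (a mean of profiles,
not a pooled selection). The inter-duplex phosphate RDF averages the two
directions (duplex 1 against 2 and vice versa) and keeps two separate
cutoffs — 6.4 Å for the total contact coordination number, 6.5 Å for the
per-nucleotide profile — because both conventions are in use and
reconciling them silently would change reported values.

**Groove widths.** For base pair *i* the minor-groove width is the
shortest cross-strand P–P distance with the strand-II partner offset
0…6 bp (window centered at +3, half-width 3); the major-groove register
uses offsets −8…−2 (centered at −5). The centers are the offsets a uniform
B-DNA fiber model selects; the windows never overlap, so the two grooves
can never pick the same pair. A width is reported only where the central
offset of its register exists — otherwise terminal base pairs, whose
truncated windows would yield spuriously large minima, are marked `NA`
rather than zero. Raw P–P distances are reported by default because the
canonical plotted ranges for this problem (minor 8–15 Å, major 15–22 Å)
correspond to raw distances; `subtract_vdw = TRUE` applies the −5.8 Å
phosphate van der Waals correction. Periodicity detection smooths the
minor-width series with a centered moving average (default 3 bp), then
takes strict local minima with a 0.2 Å prominence floor; a profile whose
total range is below the floor reports "no minima", not a spacing of zero.

**Caging.** A molecule is caged at a sample when the distance from its
central nitrogen to the nearest base-pair center of *each* of the two
duplexes is strictly below the threshold; ties go uncaged, per the
"smaller than" reading of the criterion. Base-pair centers are the purine
N1 of each pair (the purine N1 lies near the pair centroid for both A·T
and G·C; the geometric midpoint of the two glycosidic nitrogens is
available as an alternative in principle, and the builder places the
glycosidic nitrogens for that purpose). The per-system default thresholds
are 15, 19, 23 Å for axis separations 20, 25, 30 Å and 22 Å for the
nucleosome-like duplex; for other separations the package exposes the
linear rule `0.8·separation − 1`, which reproduces all four tabulated
values, as a configurable convenience, since no physical derivation of the
thresholds is available. For a single long superhelical duplex the two
parallel gyres (base pairs 1–67 and 80–146, the connecting bend excluded)
play the role of the two duplexes.

State sampling includes t = 0 (so 500 ns sampled every 25 ns gives 21
samples; `include_t0 = FALSE` gives 20 — both conventions appear in
practice and the choice is exposed). The summary classifies molecules over
samples with t ≥ `t_start` (default 0; plateau analyses customarily use
100 ns, so the burn-in is a parameter rather than a constant) as
always-caged, always-uncaged, or mixed, and reports
(always-caged + always-uncaged)/mixed — 0 when the numerator is zero, NA
with an explicit flag when no molecule is mixed. Counts can be divided by
a normalization factor (3 for comparing the 146-bp duplex against the
22-bp systems, matching the threefold length).

**Conformations and bridges.** The end-to-end distance is measured between
the terminal nitrogens (the chain termini are nitrogens; terminal heavy
atom vs terminal nitrogen is ambiguous in common usage, and terminal N is
the choice here). Folded means EE < 7 Å, elongated EE > 9 Å, intermediate
between. Bridges are detected on heavy atoms: an amino nitrogen within
3.5 Å (a standard N⋯O hydrogen-bond heavy-atom distance) of at least one
phosphate oxygen on each duplex is a single-N bridge — the geometric
signature of an O–HNH–O contact — and two nitrogens of one molecule
contacting different duplexes form a molecule-level bridge. Hydrogen
positions are deliberately not used: synthetic fixtures and many
trajectory formats lack reliable hydrogens, and the heavy-atom criterion
is the standard proxy. Mode labels: a bridging, folded molecule is
`c_shape`; a bridging, elongated molecule whose principal axis (leading
eigenvector of the heavy-atom covariance) is within 30° of one duplex's
local backbone tangent (P two steps before to P two steps after the
nearest phosphate) and at least 60° from the other's is `pp`; everything
else is `other`. The 30°/60° gates are package conventions — the
parallel-perpendicular motif is described qualitatively in the literature
— so they are parameters and are reported with every label.

## The synthetic generator

The generator produces the *statistical* structure the analyses assume,
not physical realism: no forces, energies, solvent structure, or sequence-
dependent fine structure.

* **Fiber-model B-DNA**: rise 3.38 Å and twist 36°/bp (canonical B-form
  values; the generator exposes both). Each residue carries only the
  analysis-relevant atoms — P/O1P/O2P (absent on 5′ termini, so a 22-bp
  duplex has 21 phosphates per strand), the glycosidic nitrogen, the
  purine N1, and the groove reference atoms — placed at schematic
  cylindrical positions (P radius 9.0 Å, backbone azimuthal half-gap 50°
  across the minor groove). These constants give a uniform helix with raw
  minor/major widths of about 11.0 and 17.8 Å, inside the canonical B-DNA
  ranges.
* **Two-duplex assembly**: axes along z separated along x, the second
  duplex azimuthally offset by 18° so the backbones interleave;
  separations down to 20 Å then build without steric clash (< 1.5 Å
  contacts are an error). A requested fraction of spermidine molecules is
  placed at caged sites — central N within (threshold − margin) of a
  base-pair center of both duplexes — and the rest at sites violating the
  criterion by the same margin (default 2 Å), so ground-truth states are
  unambiguous under positional noise up to ~1 Å. Ions and water are
  bookkeeping counts chosen to make the reference compositions exactly
  charge neutral (84 phosphates vs 30×(+3) + 84 − 90; 290 vs 100×(+3) +
  156 − 166); they are never instantiated because no analysis here uses
  them.
* **Dynamics**: each molecule carries a two-state Markov chain
  (`p_enter`, `p_exit`) per frame; on a state change it is translated to a
  freshly sampled site of the new kind, otherwise it stays put, and
  independent Gaussian noise (default σ = 0.5 Å) is added to every atom of
  every frame. Defaults are 21 frames at 25 ns — the sampling grid of a
  500 ns production run read every 25 ns. The generator returns the true
  state matrix alongside the trajectory; the classifier agrees with it on
  ≥ 99 % of entries at σ ≤ 1 Å (in practice 100 % at the defaults, since
  the 2 Å margin dominates the noise).
* **Superhelix**: the duplex is bent onto a helical path (defaults radius
  42 Å, pitch 26 Å, matching nucleosome-like gyre separations of
  25–28 Å). Path curvature alone induces a width oscillation with the
  helical repeat — the physically expected in/out alternation of the
  minor groove on bent DNA — so the requested modulation cannot simply be
  added on top. Instead the generator calibrates the per-bp backbone gap
  angle iteratively against the package's own groove-width analyzer until
  the profile matches `W0 − A·cos(2π(bp−1)/period)` to 0.05 Å. This
  cancels the curvature distortion and makes `amplitude = 0` genuinely
  flat; it also means generator and analyzer close exactly by
  construction, which is the property the tests rely on.

What passing tests on these fixtures show — and do not show. They
establish that the estimators implement their definitions (against
brute-force oracles), that normalizations are correct (ideal-gas g → 1),
that the classifier inverts the generator, and that printed derived
statistics follow exactly from printed counts. They do not validate the
analyses against real MD data: real trajectories have correlated DNA
breathing, sequence-dependent groove modulation, and exchange kinetics far
from Markovian, none of which the generator emulates.

## Numerical choices and degenerate inputs

* Bin edges `(r, r+Δr]`; self-pairs removed for identical selections; an
  identical selection with fewer than 2 atoms is an error.
* `r_max` must not exceed half the shortest box edge under periodicity.
* Groove analysis requires ≥ 6 bp (registers undefined below that);
  empty per-bp regions (e.g. terminal phosphates) report CN 0 and are
  flagged rather than dropped.
* Sampling intervals must be commensurate with the frame interval; the
  error suggests the nearest valid value.
* All randomness flows through R's RNG from a single seed; identical spec
  + seed reproduces identical files byte for byte.
* Problem sizes used throughout the test suite — 22-bp duplexes, ≤ 60
  frames, ≤ 2000-atom ideal-gas fixtures, one 146-bp superhelix — keep a
  full run under a minute or two on one CPU while leaving every binomial
  check at least ~30 effective draws per estimate.

## Known limitations

* The fiber model is schematic: sugar atoms, full base geometry and
  sequence-dependent structure are absent, so absolute RDF peak positions
  from synthetic systems are not meaningful — only the properties the
  tests assert (normalization, locality, closure) are.
* Groove widths use a fixed register window; strongly distorted or melted
  duplexes could shift the true register outside it.
* The threshold-vs-separation rule is an interpolation of four tabulated
  values, not a derived quantity.
* Mode classification depends on invented angle gates (30°/60°) and on a
  principal axis that is ill-conditioned for nearly isotropic (tightly
  folded) conformers; labels should be read together with the reported
  angles.
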