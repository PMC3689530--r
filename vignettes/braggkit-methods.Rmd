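---
title: "braggkit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{braggkit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggkit)
```

braggkit bundles two computational cores that meet in serial
crystallography practice: a direct-summation structure-factor engine for
simulating diffraction from finite crystallites, and a per-image Bragg
spotfinding / hit-rate monitoring pipeline for triaging detector frames.
This vignette records the models behind both, the conventions that had to
be fixed, and the reasoning behind the tunable defaults.

## The direct summation model

The macromolecular structure factor is evaluated as the triple sum

$$
F_H \;=\; \sum_{\Delta U} e^{2\pi i H\cdot \Delta U}
     \sum_{S} \sum_{n}\;
     w_n\, f_n(d^*_H)\; e^{-2\pi^2 u_{\mathrm{iso},n} d^{*2}_H}\;
     e^{2\pi i H\cdot (R_S x_n + T_S)} ,
$$

where $H=(h,k,l)$ may be fractional, $d^*_H$ is the reciprocal-lattice
spacing from the reciprocal metric tensor, $f_n$ is the atomic form factor
(4-Gaussian + constant parametrization, $s = d^*/2$), $w_n$ the occupancy,
$u_{\mathrm{iso},n}$ the isotropic displacement, $(R_S, T_S)$ the
space-group operators, and $\Delta U$ runs over the `N1 x N2 x N3` integer
lattice offsets of the crystallite.  Conventions fixed here:

* **Displacement.** The attenuation is $e^{-2\pi^2 u\, d^{*2}}$,
  equivalently $e^{-B s^2}$ with $B = 8\pi^2 u$; the PDB B column converts
  through `b_to_u_iso()`.  This is the standard isotropic convention.
* **Lattice offsets** run over $\{0..N-1\}$ per axis (not centered); the
  origin choice only contributes an overall phase and never affects
  amplitudes.
* **Fractional coordinates** are reduced to $[0,1)$ on input, giving one
  canonical representation for comparisons and round-trips.
* **Space groups.** The operator table is minimal and explicit — P1,
  P2~1~, C2, P2~1~2~1~2~1~, P6~3~ — each stored as literal triplets.  A
  full symmetry engine is out of scope; `expand_to_p1()` provides the
  orbit expansion that doubles as the symmetry oracle in the tests
  (symmetry-aware F must equal P1-expanded F).  Special positions are not
  merged on expansion: the sum runs over operators verbatim, and
  occupancies are taken as given.
* **Form factors** cover H, C, N, O, P, S, Fe from the standard 4-Gaussian
  tables; other elements must be supplied as explicit coefficients.

### The Laue interference factor and its integer-index limit

For a finite block of cells the lattice sum factorizes per axis into a
geometric series,
$\sum_{u=0}^{N-1} e^{2\pi i h u} = e^{i\pi h(N-1)}\sin(\pi N h)/\sin(\pi h)$,
with $N-1$ zeros and $N-2$ subsidiary fringe maxima between adjacent
integers — the fringe pattern of nanocrystals.  The closed form is
singular at integer $h$; `laue_interference()` switches to the smooth
limit $N e^{i\pi(h-\mathrm{round}(h))(N-1)}$ whenever
$|\sin \pi h| < 10^{-9}$, so at exact integers the axis factor is exactly
$N$ (real and positive, matching the term-by-term sum) and the
integer-index intensity law $\|F\|^2 = (N_1N_2N_3)^2\|F_{\mathrm{cell}}\|^2$
holds to rounding.  `sf_finite_crystal()` keeps a brute-force "explicit"
path (every $\Delta U$ summed term by term, capped at $10^6$ cells) purely
as an oracle for the factorized path.

### Precision switch

`sf_batch()` computes through a compiled kernel templated on the working
precision.  With `precision = "single"` every inner operation — metric,
form factors, displacement factors, phases, trigonometry and the
accumulation — runs in IEEE 32-bit arithmetic; `"double"` uses 64-bit
throughout.  The accumulation order is fixed (scatterers innermost,
operators outer) and the single-precision path uses Kahan compensated
summation, which makes results independent of the caller's chunking and
keeps the 32-bit error well-behaved as atom counts grow.  On the package's
benchmark structure (500 random C/N/O/S atoms, $u$ uniform in
$[0.02, 0.05]$ Å², 40 x 50 x 60 Å orthorhombic P1 cell, all ~16 000
unique reflections to 2.5 Å) the mean relative amplitude discrepancy
between the two precisions is about $3\times10^{-4}$ % — orders of
magnitude below the ~0.8 % error conventionally associated with the FFT
approximation, which is the acceptance bound the test suite asserts.

### FFT reference

`fft_reference_sf()` is the cross-check, not the product: it samples each
scatterer's analytic real-space density (the Fourier mate of the Gaussian
form-factor sum, with the displacement folded in as $b' = b + 8\pi^2 u$)
on a grid of spacing at most `d_min / grid_factor` and reads F off a
discrete Fourier transform.  Two numerical choices matter:

* Sharp terms — above all the constant $c$, a delta function in real
  space — cannot be point-sampled.  Every term is therefore broadened by
  an artificial $b_\mathrm{extra} = 8\pi^2(0.8\,\Delta)^2$ ($\Delta$ = grid
  spacing) and the transform is rescaled by $e^{+b_\mathrm{extra}(d^*/2)^2}$
  afterwards — an exact reciprocal-space correction that leaves only
  residual aliasing and truncation error.  The same trick is what makes
  production FFT structure-factor engines accurate.
* Each atom's density is truncated where it falls below $10^{-6}$ of its
  peak, and grid dimensions are rounded up to 7-smooth sizes of at least
  $2 h_{\max} + 2$ per axis so distinct reflections never alias onto the
  same transform bin.

Accuracy improves monotonically with `grid_factor` (the tests check the
2 → 3 → 4 trend) because both the broadening and the sampling error shrink
with the spacing; at the default `grid_factor = 3` the mean relative
amplitude error against direct summation is a few times $10^{-4}$ on the
benchmark structure.

Amplitude comparisons exclude reflections below a floor of
$10^{-8}\times\max\|F\|$: near-extinct reflections (systematic absences)
would otherwise dominate a relative-error statistic through division.

## The spotfinding pipeline

`signal_strength_report()` runs the per-frame sequence: classify pixels,
identify spots, eliminate rings, apply quality heuristics, summarize.

* **Background model.** Per-tile (default 64 px) median with a
  MAD-derived sigma, floored at $\sqrt{\max(\mathrm{median},1)}$ so a flat
  Poisson background can never report a spread of zero.  Robust statistics
  stand in for proprietary dispersion heuristics; every threshold is an
  exposed parameter.  A pixel is signal iff it is active and exceeds
  `median + n_sigma * sigma`.
* **Threshold choice.** The default `n_sigma = 3.5` suits interactive
  triage.  For campaigns that demand *exact* precision/recall — the
  50-frame recovery experiment in the acceptance tests — the threshold is
  a matched design-time choice: on a Poisson(10) background the
  probability of a single pixel exceeding the threshold is $p_1 \approx
  7\times10^{-4}$ at 3.5 σ but $1.8\times10^{-5}$ at 5 σ, and since a
  detection needs `min_pixels = 2` adjacent excursions, the expected
  number of false spots over 50 frames of $256^2$ pixels drops from ~26
  to ~0.02.  The recovery campaign therefore runs at `n_sigma = 5`; with
  planted signal-to-noise of at least 10 the recall analysis is
  unaffected.
* **Spots** are 8-connected components (a small union-find over signal
  pixels) of at least `min_pixels = 2` pixels — pixel-array detector spots
  are nearly point-like.  Centroids are intensity-weighted with pixel
  centers at half-integers, coordinates 0-based in (slow, fast) order;
  these conventions are pinned because the text report is required to be
  byte-stable.  Resolution per spot uses
  $d = \lambda / (2\sin(\tfrac12\arctan(r/D)))$ at the centroid radius,
  plus an intensity-weighted mean pixel $d^*$ (`d_star_mean`) used for
  ring membership — for an azimuthally extended component the centroid
  degenerates toward the beam center while the mean pixel $d^*$ stays on
  the ring.
* **Rings** are found as $d^*$ shells (width 0.002 Å⁻¹) whose
  signal-pixel occupancy exceeds 0.25, merged when adjacent; a shell must
  contain at least `min_shell_pixels = 128` active pixels to be
  flaggable, since the few-pixel shells right at the beam center cannot
  carry an azimuthally meaningful ring and a single compact spot there
  would otherwise dominate its shell.  A built-in hexagonal-ice list
  (3.90, 3.67, 3.44 Å) can pre-seed intervals.
* **Quality heuristics**: pixel-count cap (200), peak-concentration bound
  (peak pixel at most 0.98 of the total), bounding-box elongation bound
  (4).  These are this package's documented re-interpretation of published
  step names; no output parity with any historical tool is claimed.
* **Resolution limit** of an image is the 80th-percentile $d^*$ of
  accepted spots, reported in Å — a deliberate convention (no published
  formula exists): it is stable and responds monotonically when
  high-resolution spots are added.  An optional resolution annulus
  (`d_limits`) restricts the spots that enter the statistics, since "within
  a defined area" is otherwise unspecified.

## Hit-rate monitoring

A frame is a hit when its strong-spot count reaches the threshold
(default 16).  The sliding window is causal, `(t - window, t]` with a 5 s
default, anchored at each record's timestamp; the denominator is the
number of frames actually observed in the window, not a nominal cadence —
an empty window simply cannot occur because the window always contains its
own record.  Totals are additive over stream concatenation, and
`merge_hit_chunks()` guarantees the parallel-processing contract: any
contiguous chunking, processed independently and merged, reproduces the
serial summaries exactly.

## The synthetic frame generator

`generate_frame()` is the test bed standing in for beamline data:
Poisson background, planted 2-D Gaussian spots integrated per pixel by
error-function differences (so the planted integrated intensity is the
ground truth to sub-count accuracy), optional azimuthal Gaussian ring
profiles in $d^*$, rectangular inactive regions, and a saturation cap.
One random source per frame is seeded once, with draws in documented order
(background first), so identical specs give byte-identical frames and
byte-identical SMV files.  The default stream conditions mirror serial
femtosecond crystallography monitoring: 120 Hz timestamps $i/120$ s, hit
threshold 16, and per-frame planted spot counts chosen to straddle the
threshold deterministically (20 for hits, 4 for misses) so ground-truth
labels are unambiguous.

What the generator does *not* emulate: partiality of still reflections,
detector point spread and charge sharing, mosaic spot shapes, non-Poisson
readout noise, and multi-panel metrology.  Passing the recovery tests
therefore demonstrates the pipeline's bookkeeping and statistical logic on
idealized frames, not performance on real beamline images.

SMV (ASCII header + unsigned 16-bit little-endian payload) is the single
real-world image format, chosen because it can be specified bit-exactly;
the two-lattice generator projects reflections of two randomly oriented
cells onto the detector through a thin Ewald-sphere tolerance band
(0.002 Å⁻¹) — a geometric stand-in adequate for exercising the overlap
taxonomy (`overlapping` within one integration-box half-width, `close`
within two).

## Problem sizes in the test suite

The suite fixes seeds everywhere and scales experiments to desk size: the
benchmark precision and FFT comparisons use the 500-atom structure at
2.5 Å (~16 000 reflections); spot recovery uses 50 frames of 256² pixels
with 20–40 planted spots each; the monitoring experiment uses a 2 000
frame, 96²-pixel stream processed end to end through the spotfinder.

## Interfaces and scope

The R functions are the primary interface; `run_command()` plus the
installed `exec/braggkit` script expose the same operations as shell
commands (`fsim`, `fringe`, `spotfind`, `monitor`, `simulate`) with
stable text, XML and JSON reports and conventional exit codes.  An HTTP
front end was considered and omitted: the correctness contract —
byte-stable, order-independent per-image reports — lives entirely in
`run_command()`, and base R offers no production-grade server.  Fringe
sections are rendered on fixed-$l$ planes of reciprocal space (not
Ewald-sphere projections), and the P6~3~ fringe demonstration uses a small
synthetic fixture rather than any external coordinate file, keeping the
package download-free.
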