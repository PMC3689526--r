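---
title: "Models and methods behind serialx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serialx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

serialx implements a desk-scale processing pipeline for serial femtosecond
crystallography (SFX): still diffraction patterns, one per crystal, recorded
with single X-ray free-electron-laser pulses and merged Monte-Carlo style.
This vignette explains the models the package implements, the parameters
that matter, and the design decisions taken where more than one reasonable
choice existed. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## Geometry

The lab frame is right-handed with the beam along +z and a flat detector
normal to the beam at camera length $D$. Pixel indices are 0-based with
pixel centres at integer coordinates. A pixel at radial distance $r$ from
the beam centre maps to reciprocal space through the Ewald construction

$$\mathbf{q} = \frac{\hat{\mathbf{s}} - \hat{\mathbf{z}}}{\lambda},
\qquad |\mathbf{q}| = \frac{2\sin\theta}{\lambda},$$

with $\hat{\mathbf{s}}$ the unit scattered-ray direction and $2\theta =
\arctan(r/D)$. Every mapped pixel therefore lies on the Ewald sphere
($|\mathbf{q} + \hat{\mathbf{z}}/\lambda| = 1/\lambda$, a tested
invariant), and `predict_spot_position()` is the exact inverse. The
reference simulation detector is a 76.8 mm square at 70 mm, which at
$\lambda = 1.3776$ Å resolves 2.8 Å at the edge midpoint and 2.1 Å at the
corner. The configuration quotes a 900 eV photon energy alongside these
resolutions; they are geometrically inconsistent (the printed resolutions
require $\lambda \approx 1.38$ Å, i.e. ~9.0 keV), so the package adopts
9.0 keV for the reference geometry and notes the discrepancy here rather
than silently reinterpreting it elsewhere.

Energy converts to wavelength with the constant 12398.42 eV·Å.

## Frame preparation

Detector corrections run in the standard order: dark subtraction
(per-pixel mean over dark frames; the per-pixel SD is kept as the "spread"),
per-segment offset correction, bad-pixel flagging (inclusive thresholds,
defaults 65534 and −500 detector units), then background subtraction.

*Common mode and coupled drifts.* Shot-to-shot inter-segment offsets and
offsets proportional to the total segment signal are corrected together by
one robust per-frame, per-segment estimator: the median of that segment's
signal-free pixels, where "signal-free" means below three times the dark
spread (or three robust frame sigmas without a dark model). The upstream
description names the two effects without giving estimators; a single
robust median captures both at desk scale. Segments with fewer than 16
usable pixels are left uncorrected with a warning.

*Median background.* The local background at each pixel is the median of
the unmasked pixels in a box (default 5 px, configurable) centred on it,
with truncated boxes at the frame edges — shrinking the box avoids
inventing data beyond the frame. Because Bragg peaks are small compared
with the box, the median is fixed by background pixels: a 2-pixel-diameter
peak inside a 5×5 box leaves about 21 of 25 pixels at background level.
Masked pixels never enter any median, offset or statistic.

## Peak search and hit classification

Peaks are 8-connected components above an intensity threshold (default
4× the robust frame sigma). Components must have between `min_pix` (2,
rejecting single-pixel outliers) and `max_pix` (40, rejecting diffuse ice
blobs) pixels, and must pass a local signal-to-noise gate (default 6). The
SNR numerator is the *mean* above-threshold intensity per peak pixel — the
source material does not fix whether the summed or per-pixel peak intensity
is meant, and the per-pixel form keeps the criterion independent of peak
size. The noise is the SD of the surrounding window (the same size as the
median box), omitting pixels that belong to any peak.

A frame is a *hit* when at least 25 peaks are found; the hit rate is
averaged over blocks of 3600 frames (30 s at 120 Hz), with a final partial
block reported over its own denominator. The per-pattern resolution
estimate is the spatial frequency at the radius containing 80% of the
peaks, using the ceiling-rank convention (smallest radius containing at
least 80%).

## Known-cell autoindexing

Peaks are mapped to exact reciprocal positions under the still-pattern
assumption (nominal wavelength, zero convergence and mosaicity). The
indexer then searches for real-space lattice vectors directly:

1. **Direction search.** ~7300 quasi-uniform hemisphere directions
   (Fibonacci spiral, ~1.7° spacing). For each direction the reciprocal
   points are projected onto it; the projected density of points generated
   by a real axis $\mathbf{a}$ is periodic with period $1/|\mathbf{a}|$, so
   its magnitude spectrum peaks at the real-space length $|\mathbf{a}|$.
   The spectrum is evaluated only at periodicities within ±10% of the
   reference axis lengths, by direct summation with a per-point phase
   recurrence — identical values to a zero-padded FFT at those bins,
   without computing the thousands of out-of-window bins. Directions whose
   projections span fewer than three periods are skipped: with no spread,
   every frequency sums coherently and the magnitude is meaningless.
2. **Polish.** The coarse angular grid is marginal for long axes: the
   spectral peak decoheres within $\sim 1/(q_\mathrm{span} L)$ radians,
   about 1.3° for a 108 Å axis. Each retained candidate (top 150 by
   spectral magnitude) is polished by two shrinking 5×5 tangent-plane
   grids around its direction.
3. **Squashing.** Greedy de-duplication by descending figure of merit,
   treating $\mathbf{v}$ and $-\mathbf{v}$ as equal (the projection
   spectrum cannot distinguish them).
4. **Refinement.** Iterative single-step least squares: peaks whose
   projections lie within `inlier_tol` (0.2) of an integer are fitted to
   those integers via the normal equations, iterating until the inlier set
   is stable. The gate is annealed (0.2 → 0.1 → 0.05) so spurious peaks
   that slip through the loose gate are shed once the genuine peaks have
   pulled the vector into place. Fits collapse to zero if all accepted
   projections round to the same integer, so refinement requires three
   distinct integer indices and rejects steps that halve the vector length.
5. **Assembly.** Triples of candidates (both signs each) whose pairwise
   angles and lengths match the reference cell within tolerances (defaults
   1.5° and 5–10%) are scored by the number of peaks indexed
   ($\lVert A^{\mathsf T}\mathbf{q} - \mathrm{round}(\cdot)\rVert_\infty
   \le 0.25$); ties break on the summed fractional residual. Only
   right-handed triples are accepted, and near-coplanar triples (normalized
   determinant ≤ 0.05) are rejected before any cell reconstruction.
   Success additionally requires the found cell to match the reference
   under some proper signed axis permutation and at least half the peaks
   indexed.

Candidates are represented as real-space vectors (Å): that is what the
projection spectrum determines, and what cell assembly needs; the
reciprocal basis is obtained at the end by matrix inversion. The indexing
tests run the 200-pattern recovery at 3000 sampled directions, which with
the polish step matches the accuracy of the denser default at this problem
size.

## Three-ring integration

Intensities are measured by summation over three concentric circles
(defaults 3, 4, 5 px; strict pixel-centre membership). The background is
the mean of the outer annulus, excluding masked pixels and pixels inside
any other reflection's peak region; the middle annulus is an unused buffer
against small prediction errors. The background-subtracted sum over the
inner circle is the intensity; negative intensities are retained, as
required for unbiased Monte-Carlo merging. No solid-angle correction is
applied to summed totals.

The reported error combines the background variance over the peak region,
the uncertainty of the subtracted background mean, and Poisson counting:

$$\sigma^2(I) = N\,\sigma^2_\mathrm{bg}\left(1 + \frac{N}{M}\right) +
k\,\max(I, 0),$$

with $N$ peak pixels, $M$ background pixels and $k$ detector units per
photon. The $N/M$ term is required for a calibrated error model: without
it, the empirical scatter of repeated measurements exceeds the reported
sigma by $\sqrt{1 + N/M} \approx 1.4$ at the default rings, and the
package's calibration test (empirical SD / reported sigma within
[0.8, 1.2]) enforces the full form. Annuli with fewer than five usable
pixels flag the measurement and fall back to the counting term.

## Indexing ambiguities and merging

The chiral point groups 1, 2, 222, 4, 422, 3 (hexagonal or rhombohedral
setting), 312, 321, 32, 6, 622, 23 and 432 are represented as integer
rotation matrices in the conventional lattice basis, generated from
generators and verified closed, identity-containing and of determinant +1
at construction. The proper holohedry of each lattice system is the
merging symmetry an orientation-blind indexer cannot see beyond; when the
structure's true point group is a proper subgroup of it, indexing is
ambiguous and the data merge as if twinned under the holohedry. Left coset
decomposition of the holohedry with respect to the true group lists the
ambiguity operators. Metric-accidental ambiguities (a cell that only
accidentally looks more symmetric) are detected numerically as proper
signed axis permutations preserving the cell parameters within the
indexing tolerances.

Merging maps every observation to a canonical unique reflection — the
lexicographically greatest image under the group, with Friedel expansion
unless anomalous pairs are kept — and takes the plain mean. The half-data-set
agreement statistic is

$$R_\mathrm{split} = 2^{-1/2}\,
\frac{\sum |I_\mathrm{even} - I_\mathrm{odd}|}
     {\tfrac12 \sum (I_\mathrm{even} + I_\mathrm{odd})},$$

over reflections present in both halves (the equation is stated here
because the source text renders it as an image; this is the standard
definition). It is scale-invariant and zero on identical halves, both
tested.

Because an ambiguity operator never maps a reflection onto its Friedel
mate, 50/50 ambiguity mixing does not destroy anomalous differences but
averages each with an unrelated partner's: the merged difference
$((1-p)\Delta_i + p\Delta_j)$ at $p = 1/2$ has half the variance, i.e. the
RMS anomalous signal drops by $\sqrt 2$. The simulation
(`anomalous_mixing_factor()`) implements exactly this pattern-level model
with a finite number of observations per reflection.

## Partiality model

Each reflection's profile is a sphere of radius $R = 3\times10^{-4}$ Å⁻¹.
A flat-top spectrum of fractional full width $b$ and a convergent beam of
full angle $c$ bound an excited slab of reciprocal space between two
limiting Ewald spheres: the short-wavelength sphere tilted by $c/2$ about
the origin towards the reflection's azimuth ($r_\mathrm{low}$) and the
long-wavelength sphere tilted away ($r_\mathrm{high}$), with excitation
errors positive inside a sphere. The partiality is the fraction of the
profile volume inside the slab, via spherical-cap volumes: with
$u_i = \mathrm{clip}\big((r_i + R)/2R\big)$ and $f(u) = 3u^2 - 2u^3$,

$$p = f(u_\mathrm{low}) - f(u_\mathrm{high}) \in [0, 1].$$

The Lorentz factor of a still exposure is the slab-to-profile thickness
ratio $\Lambda = (r_\mathrm{low} - r_\mathrm{high})/2R$, normalized so
$\Lambda = 1$ when the slab exactly spans the profile. It grows with
scattering angle as the limiting spheres separate.

**How the Lorentz factor enters the recorded intensity.** The recorded
partial intensity is modelled as

$$I = s \cdot \frac{p}{\Lambda} \cdot I_\mathrm{full} + \varepsilon,$$

with $s$ the per-pattern scale and $\varepsilon$ the additive noise. The
division is flux conservation: a flat-top spectrum spreads a fixed pulse
energy over the whole excited slab, so the flux available per unit slab
thickness — and hence to any one reflection's profile — falls as the slab
thickens, and the partiality enters per unit thickness. For a thin slab
$p/\Lambda \to \tfrac32\!\left(1 - \bar u^2\right)$ stays bounded in
$[0, 3/2]$. The one-line verbal description in the source reads as a
multiplication by a factor proportional to the slab thickness; taken
literally it makes recorded partial intensities grow without bound with
bandwidth (up to tens of times the fully integrated intensity at 4%
bandwidth) and fails to reproduce any of the reported convergence
landmarks in the convergence-dominated regime (the 10% crossing lands at
~2.7× the reported pattern count). The flux-conserving direction, which is
also how the reference software applies its still-pattern Lorentz factor,
reproduces every reported landmark within ~10%; the package adopts it.
`lorentz_factor()` itself returns $\Lambda$ exactly as defined above.

*Scale and noise.* Per-pattern scales are Gaussian with mean 1 and SD 0.3
(about 0.04% of draws are negative and are deliberately not clipped — at
these settings they model occasional pathological patterns and have no
measurable effect on the statistics). Noise is additive Gaussian with SD
10 detector units, applied after scaling so its absolute level is constant,
matching the stated constant noise SD.

*Synthetic intensities.* True structure-factor intensities are replaced by
a calibrated Wilson-like model: per unique reflection under the crystal's
point group (Friedel-symmetric), $I \sim \mathrm{Exp}(\mu(s))$ with
$\mu(s) = 500\,e^{-b s^2}$ and $b$ fixed so $\mu = 100$ at the corner-shell
resolution. This anchors the noise SD of 10 at 2% of the low-order shell
mean and 10% of the corner-shell mean, the stated calibration. The
absolute level (500/100) is the one free choice; only the ratio of noise
to intensity affects any scale-invariant statistic.

*Convergence experiments.* `convergence_experiment()` simulates random
orientations (uniform quaternions), applies the model above to every
lattice point inside the detector resolution sphere whose predicted
position falls on the detector, accumulates odd/even half-data-set sums
per unique reflection under point group 422, and reports R_split at the
requested pattern counts. The hot loop is compiled (Rcpp) with an exact
prefilter that skips points that cannot intersect the grown slab; it uses
R's RNG stream, so a single `set.seed()` reproduces a whole run. The
sequential single-threaded RNG replaces the counter-based per-pattern
substream design sometimes used for threaded simulators — execution here
is single-threaded by construction, so sequential draws are already
deterministic, and one seed governs everything.

Crossings of a given R_split level are read off the (essentially monotone)
curve by log-log interpolation between the bracketing grid points.

## Synthetic frames

The fixture generator renders the partiality model into pixels: spots are
isotropic Gaussians (σ = 0.8 px) integrating to their partial intensity,
added to a smooth radial water-ring background plus flat base, and
Poisson-sampled at the configured gain; dark offsets and per-segment
shifts can be injected for the frame-preparation stage. The fixture
configuration uses the reference conditions on a coarse 256-pixel detector
(0.3 mm pixels) with 2% bandwidth and only the brightest ~60–80 spots
rendered per frame, keeping frames sparse like real patterns. A noise-free
switch enables exact conservation tests (total rendered signal equals the
summed truth list).

What the generator does *not* emulate: coherent speckle from the liquid
column, shape transforms / truncation fringes of finite crystals,
per-pixel gain variation, and non-Gaussian detector artefacts. Passing
tests therefore demonstrate the pipeline's correctness under the stated
statistical model of SFX data, not robustness to every artefact of a real
detector.

## Problem sizes and determinism

The shipped tests use problem sizes chosen as a reasonable desk-scale
rendition of the study: the full 0.1%-bandwidth series to 40 000 patterns,
the 4% series to ~9000, the 3 mrad series to 20 000, 200 patterns for
indexing recovery, and 6–10 rendered frames for the end-to-end pipeline
checks. All randomness flows through R's RNG under fixed seeds; the
acceptance script takes its seed on the command line and derives one
sub-seed per condition.

## Known limitations

- Single flat panel normal to the beam; no tilted or curved panels, no
  per-pixel distortion maps.
- The indexer requires a reference cell (that is its design point); there
  is no ab initio or multi-lattice mode.
- No 2-D/3-D profile fitting in integration and no post-refinement of
  scales or partialities; ambiguity *resolution* (as opposed to detection
  and apparent-symmetry bookkeeping) is out of scope.
- The partiality simulator bypasses autoindexing by design, isolating the
  contribution of partialities to Monte-Carlo convergence.
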