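---
title: "Quantifying MPS periodicity with mpscorr: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MPS periodicity with mpscorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mpscorr)
```

The membrane-associated periodic skeleton (MPS) organizes actin rings
every ~190–200 nm along axons, and many membrane proteins follow that
lattice. `mpscorr` measures how periodic a labelled target is in a
super-resolution image and whether two periodic targets sit in phase
(overlapping) or half a period apart (alternating). This vignette explains
the underlying model, every tunable parameter, the simulator that
validates the method, and the design decisions taken where reasonable
implementations could differ.

## The analysis model

### Unbiased region selection

Manual region selection biases periodicity measurements toward the
prettiest stretch of an axon. Instead the entire masked image is cut into
grids (default 1 µm high, full image width) and *every* grid containing
mask pixels is analyzed. The 1 µm height is matched to the ~200 nm period:
tall enough for ~5 repeats, short enough to tolerate axon curvature and
local periodicity changes. Masks come from mean-filter smoothing plus
thresholding on the best-contrast channel (`make_mask()`), with manual
pixel edits (`edit_mask()`) for artifacts such as crossing neurites;
erasing wins over drawing when both touch a pixel. A trailing partial grid
at the image edge is kept when it contains mask pixels — axon ends carry
signal and silently discarding them would bias long-range statistics.

### Oriented profiles via gradient label layers

Ring periodicity only shows along the axon axis, and axons are rarely
axis-aligned, so each grid is reduced to profiles over a sweep of angles
(default −20° to +20° in 1° steps; 0° runs along the grid's column axis,
positive angles counter-clockwise). For each angle a *gradient label
layer* assigns every pixel to one of a family of parallel lines rasterized
with Bresenham's integer algorithm, perpendicular to the profile
direction; consecutive lines are shifted one pixel along the column axis
and labelled consecutively. The mean intensity of the mask-true pixels per
label is the profile.

Three choices matter here:

* **Background pixels are excluded from label means** rather than averaged
  in as zeros. Zeros at mask edges would fabricate intensity dips with the
  geometry of the mask rather than of the labelling, which the correlation
  stage would happily score as structure. The package's parameter-impact
  tests probe the consequences of this choice.
* **Empty labels** (no mask pixel) are trimmed at the profile ends and
  linearly interpolated in the interior, because the correlation sums
  assume a gap-free, evenly spaced series.
* **The lag pitch is one pixel for every angle**, so lag k is always
  k/pixels-per-µm, and the frequency window (nm) means the same thing at
  every angle. The true spacing along a profile tilted by θ is
  1/cos θ pixels; within the default ±20° sweep this compresses a 200 nm
  period to at most 213 nm on the lag axis, which the default 170–230 nm
  window absorbs.

### Correlation and feature extraction

Profiles are mean-centered (n′), then autocorrelated with the biased
estimator

$$A(k) = \sum_{i=1}^{N-k} n'_i\,n'_{i+k}, \qquad
  A_{norm}(k) = \frac{A(k)}{N\sigma^2},$$

where σ is the *population* (divide-by-N) standard deviation — the sample
estimator would give A\_norm(0) = N/(N−1) ≠ 1. No per-lag length
correction is applied: values taper toward long lags, and that taper is
part of the method (amplitudes are compared between conditions, never read
as absolute spectral power). The sums are evaluated by zero-padded FFT,
which is numerically identical to the direct double loop (the test suite
demands agreement below 1e−12) at a fraction of the cost.

Extrema are the sign changes of the first difference; a flat run bounded
by a rise and a fall reports its center lag, rounded down (deterministic
and symmetric under profile reversal up to one lag). Correlograms are not
smoothed first — robustness comes from the frequency window, not from
shaping the curve. The **frequency** is the lag of the second maximum
(lag 0 is the first) and the **amplitude** is the correlation difference
between the second maximum and the first minimum; a grid×angle with no
such pair has an undefined frequency and amplitude 0.

Cross-correlation pairs the two channels' profiles from the *same* label
layer, normalized by N σ₁ σ₂. The printed sum runs over non-negative lags
only, but the shift rule needs maxima on both sides of zero, so negative
lags are defined by swapping the channel roles (C(−k) = Σ n′₂ᵢ n′₁ᵢ₊ₖ);
positive lag means channel 2 leads channel 1 along the label axis. The
**shift** S is the lag of the stronger of the two local maxima nearest
zero; exact ties resolve toward the smaller |lag|, then the non-negative
lag. The downstream folding makes the sign convention immaterial.

### Post-processing and classification

Per grid and channel, angle entries outside the angle window, and entries
whose frequency is undefined or outside the frequency window, are
discarded; the surviving entry with the highest amplitude wins (ties:
angle nearest 0°, then the smaller signed angle). A grid whose entries are
all discarded keeps NaN frequency and amplitude 0. For cross-correlation,
an angle is eligible only if *both* channels survive there, and the angle
with the highest mean amplitude is selected — the per-channel best angles
may differ from it. Shifts are reported in nm before folding so that S and
the channel frequencies share units:

$$L = \frac{F_1 + F_2}{4}, \qquad
  S' = L - \left|\,(S \bmod 2L) - L\,\right|,$$

with a floored modulo so negative shifts fold identically to positive
ones; S′ ∈ [0, L] measures how far the two lattices are out of phase, and
the call is Overlapping when S′ < L/2, Alternating at or above. The
optional amplitude threshold (0.6 in the validation experiments) drops
grids whose weaker channel falls below it at the selected angle; the
companion minimum-data-point rule (10) flags accuracy cells too small to
trust.

## The simulator

The simulator emulates deconvolved two-colour STED images of axon
segments. Its defaults are the validation study's baseline: RED kernel,
no noise, 100 pixels/µm, 100 points/µm², constant point intensity; the
one-factor-at-a-time design varies kernel (RED/ORANGE), noise (0–30% of
the kernel peak), pixel pitch (50/100 px/µm), density (25–300 points/µm²)
and intensity variation (constant vs uniform 0.3–1).

**Masks.** `synthetic_axon_mask()` draws a band of constant perpendicular
width (default 0.6 µm) along a gently curving centerline. The centerline's
slope keeps one sign and stays within ~3–10° of the column axis
(`curvature` scales it; 0 gives a straight horizontal band). Two reasons:
each 1 µm analysis slab then intersects the band in one contiguous
stretch, so profiles need no long interpolated bridges; and the tilt keeps
the lag-axis period within the default frequency window. This emulates the
common experimental situation of an axon lying roughly along the scan
axis. What it does not emulate: branching, varicosities, width variation,
out-of-focus stretches — so passing tests certify the pipeline's
arithmetic and statistical behaviour, not its robustness to every real
morphology (real masks can be supplied directly).

**Backbone.** The mask is thinned to a one-pixel skeleton by 2-D parallel
medial-axis thinning (compiled, two-subiteration scheme), and the backbone
is the longest geodesic path between skeleton pixels (double breadth-first
search on the 8-connected pixel graph). Two numerical corrections follow.
The pixel staircase of an 8-connected path overstates arc length by up to
~8%, which would compress the ring spacing by the same factor; the
coordinates are therefore smoothed with a 7-pixel running mean before arc
length is measured. And thinning retracts the skeleton from the mask ends
by about half the band width, so the path is extended to the mask margin
along its end tangents — otherwise the first and last rings of every axon
would be missing.

**Zones and points.** Anchors sit at every 200 nm of (smoothed) arc
length; at each anchor a Bresenham line perpendicular to the local tangent
(from the three bidirectional neighbours) is drawn across the mask,
dilated by a half-width of 2 px (a ~50 nm stripe at 100 px/µm — the
dilation extent is not recoverable from published material and is exposed
as a parameter), and clipped to the mask: the on-line zone. Point counts
follow the density equation and the periodic-localization split; totals
and on-line counts round half-up and the off-line count is the remainder,
so conservation is exact. At F = 50 the split reduces to area proportions
(uniform spawning); at F = 100 all points are ring points. Alternating
channel pairs re-run the construction with anchors advanced 100 nm — half
a period — along the same backbone; overlapping pairs re-draw points on
the identical zone map.

**Rendering.** Points (intensity 1, or uniform 0.3–1) are stamped with a
unit-peak Gaussian kernel truncated at 3σ. The RED/ORANGE kernels are
parametric stand-ins for fluorophore-specific spot shapes, with FWHM 60
and 90 nm; any pair with RED narrower than ORANGE preserves the
qualitative results exercised here. Gaussian noise with σ equal to the
configured percentage of the kernel peak is added over the whole frame and
is *not* clipped at zero (the mean-zero model as stated; clipping would
bias the background mean).

## Validation experiments and problem sizes

`amplitude_sensitivity_experiment()`, `cross_accuracy_experiment()` and
`parameter_impact_sweep()` rerun the simulation study. All of them share
one set of synthetic masks across conditions (so levels differ only in
point placement) and report raw two-sided Mann–Whitney p-values;
multiplicity handling across the pairwise matrix is deliberately left to
the user. The package's experiment scale is ~55 masks of 20 µm, giving
≈190 analysis grids per condition — with this package's landscape grid
geometry each mask contributes ~3–4 grids (one per µm of the band's
vertical extent), so the grid count is set by the number of mask
replicates. The classification-accuracy experiments score only grids that
received a call; grids discarded by the frequency filter or without a
cross-correlation maximum count toward neither correct nor incorrect.

One caveat surfaced by these experiments: with parametric kernels and
clean band masks, per-grid amplitudes at 50% periodic localization are
dominated by point-placement shot noise (about half a point per label
line), and the additive pixel-noise parameter shifts them only ~8% — far
inside the between-grid spread. The suite's noise-impact check asserts
that pixel noise strongly shifts low-periodicity amplitudes, an effect
plausible for empirically measured kernels and irregular real masks, and
it fails under these simulation conditions; the failure is kept visible to
document the sensitivity gap rather than relaxed to pass. Density, kernel,
pixel size and intensity variation behave as expected.

## Degenerate inputs and edge policies

* Empty mask after thresholding: classed error (`mpscorr_empty_mask`).
* Fewer than two non-empty labels at an angle: that grid×angle is skipped.
* Constant profile (zero variance): grid×angle skipped.
* Cross-correlogram without local maxima: grid excluded from the
  two-channel results.
* All angles filtered out: amplitude 0, frequency NaN (single channel);
  grid excluded from cross-correlation results (two channels).
* Boundary classification S′ = L/2 is Alternating, exactly at the printed
  inequality.
* Disconnected masks are rejected by backbone extraction; analyze each
  component separately.

## Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state; experiment seeds derive deterministically from one
base seed, and simulation outputs are byte-identical across reruns
(`simulate_to_dir()` writes a manifest with the configuration, seed and
input hashes alongside every result set).
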