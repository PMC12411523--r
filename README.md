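# mpscorr

Correlation-based quantification of membrane-associated periodic skeleton
(MPS) periodicity in super-resolution microscopy images.

The MPS is the actin/spectrin lattice under the axonal membrane, with actin
rings spaced roughly 190–200 nm apart. Many ion channels and adhesion
molecules follow this lattice, either co-localizing with the rings or
sitting between them. `mpscorr` gives microscopists an unbiased, whole-image
way to answer two questions about STED/STORM-scale images:

1. **How periodic is a target?** — quantified per image grid as an
   autocorrelation amplitude at a detected frequency.
2. **Do two periodic targets overlap or alternate?** — classified per grid
   from the cross-correlation shift between the two channels.

It also ships the full image simulator used to validate the method, so the
entire validation study (sensitivity, parameter impact, classification
accuracy) can be rerun from scratch without any microscope data.

## Method

An image is masked (thresholding ± manual edits), divided into grids
(default: 1 µm high, full image width; background-only grids dropped), and
each grid is reduced to 1-D intensity profiles over a sweep of angles
(default −20°…+20°) using *gradient label layers*: families of parallel
Bresenham lines perpendicular to the profile direction, one integer label
per line. Each mean-centered profile *n′* is autocorrelated:

    A(k) = Σ_{i=1}^{N−k} n′_i · n′_{i+k},   k = 0 … N−1
    A_norm(k) = A(k) / (N σ²)

with σ the population standard deviation, so `A_norm(0) = 1`. The
**frequency** is the lag of the second maximum of `A_norm` (in nm) and the
**amplitude** is `A_norm(second maximum) − A_norm(first minimum)`. Per grid,
angles outside the configured angle/frequency windows (defaults ±20°,
170–230 nm) are discarded and the max-amplitude angle is kept.

For two channels the per-angle profile pair is cross-correlated,

    C(k) = Σ_{i=1}^{N−k} n′_{1,i} · n′_{2,i+k},
    C_norm(k) = C(k) / (N σ₁ σ₂)

(two-sided; negative lags by channel-role swap), and the **shift** S is the
lag of the stronger of the two local maxima nearest lag zero, taken at the
angle with the highest mean autocorrelation amplitude of the two channels.
The shift is folded onto half a period using

    L  = (F₁ + F₂) / 4
    S′ = L − |(S mod 2L) − L|

and the grid is called **Overlapping** if `S′ < L/2`, otherwise
**Alternating**. An optional autocorrelation amplitude threshold (0.6 in the
validation study) can be applied to both channels before classification.

The simulator paints periodic "on-line" zones across a mask: the mask's
backbone is extracted by medial-axis thinning plus the longest geodesic
path, anchors are placed every 200 nm of arc length, and Bresenham lines
perpendicular to the local tangent are dilated and clipped to the mask.
Points are spawned with density *D* and a *periodic localization
percentage* F (50 = uniform over the mask, 100 = rings only):

    P_total = D (A_on + A_off) / PPM²
    P_on    = P_total · A_on F / (A_on F + A_off (100 − F))

then convolved with a Gaussian point-spread kernel (RED 60 nm FWHM /
ORANGE 90 nm FWHM) and optionally overlaid with Gaussian noise.

## Worked example

```r
library(mpscorr)

# Simulate a two-channel image: both targets periodic (plp 90%),
# generated in alternating zones 100 nm apart along the axon backbone.
sim <- simulate_pair(
  simulation_config(),        # RED kernel, no noise, 100 px/um, D = 100
  pattern  = "alternating",
  plp_ch1  = 90, plp_ch2 = 90,
  seed     = 11
)

res <- analyze_image(sim$image, analysis_config())
res$per_grid
#>   grid_index best_angle_deg amp_ch1 freq_ch1_nm amp_ch2 freq_ch2_nm shift_nm
#> 1          1             -5   1.012         200   0.961         200     -110
#> 2          2             -7   0.863         200   0.983         200     -100
#> 3          3             -8   0.804         200   0.731         200      100
#>   norm_shift_nm       class
#> 1            90 Alternating
#> 2           100 Alternating
#> 3           100 Alternating
```

Each row is one 1 µm grid. Both channels show strong periodicity
(amplitudes ≈ 0.7–1.0) at the generated 200 nm spacing; the
cross-correlation shift folds to ≈ 100 nm — half a period — so every grid
is correctly called Alternating. For real images, start from
`analyze_image_file()` (TIFF in, CSV out); thin command-line wrappers live
in `inst/cli/`.

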