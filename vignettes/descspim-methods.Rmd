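---
title: "Models and methods behind descspim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind descspim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(descspim)
```

This vignette explains the models the toolkit implements, the choices
made where the underlying procedures were ambiguous, and what the
synthetic phantoms do and do not establish about real data.

## Acquisition geometry

A chamberless SPIM images a cleared sample inside a cuvette, so the
detection path is part clearing medium (refractive index $n$), part air.
The effective focal condition is a refractive path sum
$f = \sum_i D_i / n_i$. When the sample stage moves by
$dz_\mathrm{sample}$ the in-medium segment shortens and the in-air
segment lengthens; solving the invariance of $f$ gives the synchronous
speed correction

$$ dz_\mathrm{detect} = \frac{n - 1}{n}\, dz_\mathrm{sample}, $$

equal to 0.342 at $n = 1.52$ (CUBIC-type media) and 0 in air.
`focal_invariance_residual()` evaluates the off-manifold focus error
directly and is zero, to rounding, exactly on this line — the property
tests quantify this over randomized geometries.

Actuator load and host-PC timing make the *practical* correction deviate
from theory (e.g. a calibrated 0.346 instead of 0.342). Every function
that derives a correction from $n$ therefore accepts a user-supplied
`correction` override; the theoretical value is the default and the
override is never applied silently. All lengths are micrometres
internally; the CLI accepts `--units mm` for stage quantities.

Two consequences used throughout: a physical translation $d$ of the
sheet-forming lens displaces the focus by $d \cdot n$ inside the medium,
and effective numerical apertures of cylindrical lenses scale inversely
with focal length, $\mathrm{NA} = \mathrm{NA}_\mathrm{ref} \cdot
f_\mathrm{ref} / f$.

A note on bookkeeping: a continuous scan of $N$ frames at stage velocity
$v$ and exposure $t$ covers exactly $N v t$; the toolkit reports that
product as the z-range rather than any independently quoted travel
figure, which keeps `z_range = n_frames * z_interval` an identity.

## Stack conventions

Stacks are `(z, y, x)` arrays, 1-based, z increasing with stage travel;
movies are `(t, y, x)`. Conversion from movie to stack is pure
re-indexing — bit-exact, no resampling — with the z spacing taken from
the plan. Opposite-direction acquisitions are brought into the reference
frame by reversing z and mirroring x, an involution. 8-bit arithmetic
clamps to $[0, 255]$ after any operation (clamping, not rescaling,
preserves saturated voxels and matches integer acquisition semantics).
Registration downsizing uses a block-mean in xy (an area filter, the
natural anti-aliasing choice for factor-of-two reductions) and plain
subsampling in z (keep one slice in every $k$), matching how large
stacks are actually decimated before deformable registration.

## Flat-field correction

The one-sided sheet illumination falls off along y roughly as a
Gaussian. A reference image of a homogeneous dye solution is reduced to
per-row medians $m(y)$ — the median is the noise suppression; no extra
smoothing is applied by default — and the gain
$c(y) = \max_y m / m(y) \ge 1$ multiplies every voxel in row $y$.
Because the coefficients are dimensionless ratios, a 12-bit reference
corrects an 8-bit stack without rescaling. On a phantom shaded
multiplicatively by a generated illumination profile the corrected
per-row medians have a coefficient of variation below 2%.

## Tiling light-sheet fusion

Two stacks acquired with the sheet focus at different x positions are in
focus on opposite sides of the volume. The seam is found on x–z
reslices: a difference-of-Gaussians band-pass (structure sizes 3–40 px
by default; the original macro's filter settings are not recorded, so
these are exposed in the interface), then the standard deviation of each
non-overlapping 50 × 100 px kernel (x × z). Kernels tile rather than
slide — the cheaper reading of a per-"kernel area" statistic — and
kernels in an x column are averaged into one curve value. The split is
the window boundary where the two curves' difference changes sign,
tie-broken toward the midpoint of the two argmaxes; fusion takes each
stack on its own side with a linear 100 px ramp (or a hard combine).
Multi-tile sets fuse pairwise left to right. The full reslice is used by
default; a y sub-range is a parameter.

## Beam-shape and PSF metrology

All widths are full widths at half maximum from least-squares Gaussian
fits $a\,e^{-(i - m)^2/2s^2} + c$ of 1-D intensity profiles
(`minpack.lm` Levenberg–Marquardt, moment-based starts); a fit whose
centre leaves the window, or a profile without a strict interior
maximum, is rejected. Sheet thickness versus propagation distance is fit
with an unconstrained fifth-order polynomial — measured profiles are
asymmetric through spherical aberration, so no symmetry is imposed. The
focal width is the polynomial's minimum inside the data range; each
one-sided Rayleigh length is where the fitted width first crosses
$\sqrt{2}$ times that minimum (bracketing plus bisection on the fitted
curve), the reported $z_R$ is the mean of the two sides, and
$\mathrm{eFOV} = 2 z_R$ identically. A medium of index $n$ elongates
$z_R$ by $n$; `efov_in_medium()` applies that as an explicit conversion
only.

PSF summaries follow the smallest-$N$ rule: of the per-punctum FWHM
values in a region, the $N = 10$ smallest are kept and their mean and
*sample* (n−1) standard deviation reported — the selection guards
against widths inflated by overlapping emitters or off-focus positions.
Profile windows are six expected FWHMs long (configurable). Puncta are
3×3×3 local maxima; any pair closer than the minimum separation is
discarded entirely, since both profiles are contaminated. Quantized
plateaus (adjacent equal maxima) are merged before that rule so a
single bright bead is not discarded against its own plateau twin.

`psf_pipeline()` adds one step the individual operations do not have: a
bright-punctum gate keeping detections whose peak reaches 75% of the
brightest one. A sub-resolution bead centred between lateral pixels is
sampled down its lateral flank, which leaves the axial width estimate
unbiased but much noisier; feeding such low-precision values to a
smallest-10 selection drags the summary low, so metrology is restricted
to bright, well-centred beads (the standard practice when beads are
hand-picked from a region of interest). Setting `peak_frac = 0`
disables the gate.

## Registration quality metrics

Per corresponding z-slice: mutual information
$MI = H(X) + H(Y) - H(X,Y)$ from a 256 × 256 joint histogram (bins
aligned to 8-bit levels; each image binned over its own range, making
the score invariant to affine intensity rescaling up to binning),
normalized by $\sqrt{H(X) H(Y)}$; entropies in bits, a cosmetic choice
since the normalized score is base-invariant. Constant slices have zero
entropy; they are flagged and excluded from summaries rather than
scored. ZNCC is implemented with the square root in the denominator,
$\sum (X-\mu_X)(Y-\mu_Y) / \sqrt{\sum (X-\mu_X)^2 \sum (Y-\mu_Y)^2}$ —
the normalization a correlation score requires (without it the
self-score would not be 1). Metrics are computed per slice, matching
their use on corresponding slice pairs. Replicate-stack start-timing
offsets are corrected by the integer z-shift maximizing mean ZNCC over
the overlap; ties go to the smallest absolute shift, and the optimum's
score is attached so callers can gate on anti-correlated degenerate
matches.

## Vessel-to-drug distances

Per channel: rolling-ball background subtraction — grayscale opening by
a non-flat ball structuring element of the stated radius (4 px vessel,
50 px drug customary); this is the classical formulation, not a
re-implementation of any specific GUI tool's paraboloid shortcut — then
maximum projections over consecutive groups of 10 slices, and one Otsu
threshold computed on a chosen reference MIP (the volume centre
customary; it is a required parameter, since "central" depends on the
dataset) applied to *all* slices of the channel.

Distances are contour-to-contour: contours are the outer boundary
pixels (a foreground pixel with a 4-neighbour outside the mask) of
8-connected components — pixel-set contours keep the distances exactly
comparable to a brute-force oracle, which sub-pixel tracing would not.
Each drug-contour point queries a 2-D kd-tree of vessel-contour points
(median-split, exact, ties to the lowest point index so results are
deterministic and identical to an all-pairs scan). The straight segment
between the pair is rasterized with Bresenham's algorithm and every
pixel must lie inside the drug mask, else the line is omitted — a line
crossing tissue the drug never reached is not a delivery distance.
Valid distances sharing a nearest vessel point are averaged into that
point's record. Summaries give per-slice quartiles and whiskers, a
pooled histogram, and the pooled 95th percentile by linear
interpolation.

## Virtual H&E

Nuclear and general-protein channels are normalized to $[0,1]$ by bit
depth and mapped through Beer–Lambert attenuation of a white
background: $RGB_c = \mathrm{bg}_c \exp(-k^{nuc}_c g_n I_n -
k^{cyt}_c g_p I_p)$. The default absorption triplets are the published
virtual-H&E literature values (hematoxylin-like (0.860, 1.000, 0.300),
eosin-like (0.050, 1.000, 0.544)); they live in the colour-model object
so measured coefficients can be substituted. The mapping is monotone
non-increasing in each channel and multiplicative across channels, both
of which the tests assert exactly.

## The phantom generator

Phantoms exist to give every pipeline a ground truth. Beads and nuclei
are rendered as Gaussian-equivalent emitters: the PSF variance plus the
sphere's per-axis variance $r^2/5$ (exact in second moments; for 1 µm
beads under a 7.2 µm PSF the approximation error is below 0.1%). The
axial width follows the Gaussian-beam law
$\mathrm{FWHM}(x) = \mathrm{FWHM}_0 \sqrt{1 + ((x - x_0)/z_R)^2}$, and
axial defocus conserves flux — a defocused blob dims by the width
ratio, which is what makes focus-contrast curves invert at the true
midpoint. Defaults emulate the fine-axial imaging regime: 3.45 µm
lateral pixels, 3 µm z-steps, 1 µm beads, 7.2 µm axial and 4.4 µm
lateral FWHM at focus, 445 µm Rayleigh length (half the ~890 µm
effective field of view of that regime).

Noise is Poisson shot noise plus Gaussian read noise on a camera
baseline offset of 10 counts; `snr` is the exact peak-to-total-noise
ratio, with the variance budget split 3:1 shot:read. The baseline
matters: without it read noise clips at zero and the clipped tails bias
profile fits. The default SNR of 20 reflects a bright-bead calibration
acquisition; recovery is also exercised at SNR 10, where per-fit
scatter is larger and the smallest-10 rule is expected to sit a few
percent low. Problem sizes were chosen so the whole suite exercises
every pipeline on a laptop in well under a minute: bead stacks of
40 × 48 × 48 voxels with ~30 beads, tiling pairs of 100 × 16 × 400
voxels with 120 nuclei, 128 × 128 mask pairs.

Vessel/drug phantoms draw random polylines, dilate them to tubes, and
dilate further by per-vessel halo radii for the drug mask, so the true
contour-to-contour distance *is* the halo radius; the recovered pooled
95th percentile lands within the disc-discretization error (~6% for an
8 px halo) of that truth. All generators are deterministic under a
seed, to the byte, including their TIFF serializations.

What passing phantoms does not show: real acquisitions have stripe
shadows (an optional multiplicative artifact here, off by default, and
no device removes them in the basic instrument), scattering-induced
depth attenuation, aberration-asymmetric PSFs, and autofluorescent
background structure, none of which the generator models. Parameter
recovery on phantoms validates the estimators' correctness, not the
instrument's performance on tissue.

## Numerical choices and limitations

* Gaussian fits reject centre-out-of-window and non-positive-amplitude
  solutions rather than returning them; pipeline callers drop such
  puncta.
* The beam-fit polynomial is evaluated on centred, scaled abscissae for
  conditioning; the √2 crossings are bisected to $10^{-10}$ relative.
* Otsu maximizes between-class variance over all 255 cut points on a
  256-level histogram; exhaustive search in the tests is the oracle.
* kd-tree tie-breaks, plateau merging, and crossing tie-breaks are all
  deterministic by construction; there is no RNG outside the phantom
  generator.
* The rolling-ball opening is $O(N r^2)$; the 50 px drug-channel radius
  is practical on MIP-sized images but not on full volumes (the
  analysis is per-MIP 2-D by design).
* Distances are 2-D per MIP slice, not 3-D: halos extending axially
  between slices are attributed to their slice's projection, consistent
  with the boxplot-per-slice presentation the pipeline feeds.
* The effective-NA to eFOV relation used to *extrapolate* instrument
  values is an empirical literature curve, not a formula; the toolkit
  scales NA between lenses and converts eFOV between media but does not
  predict eFOV from NA.
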