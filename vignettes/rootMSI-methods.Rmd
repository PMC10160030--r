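---
title: "Methods: DESI-MSI analysis along the root developmental axis"
author: "rootMSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DESI-MSI analysis along the root developmental axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootMSI)
```

# The measurement and its data model

DESI-MSI raster-scans a tissue section with a charged solvent spray. The
moving stage sweeps one horizontal line per acquisition file while the mass
spectrometer free-runs, so one full scan corresponds to one pixel and the
pixel width is fixed by kinematics:

$$ w_{\mathrm{px}} = v_{\mathrm{stage}} \cdot t_{\mathrm{cycle}}, $$

while the pixel height is the vertical step between rows. `RasterGeometry`
stores both and its validity method enforces the kinematic identity to a
relative tolerance of $10^{-6}$; the two geometries used throughout are
114.6 × 130 µm (stage at 120.37 µm/s) and the higher-resolution
72.6 × 80 µm (53.69 µm/s), the latter being the simulator default.

`MSIDataset` holds a dense rectangular raster of centroided spectra,
0-based `(row, col)`, row-major; imzML's 1-based positions map as
`x = col + 1`, `y = row + 1`. Empty spectra are legal (off-tissue glass
pixels) and contribute a total ion current (TIC) of zero. Continuous-mode
input (one shared m/z axis) is accepted and passed through without
re-centroiding: every downstream operation is a window sum, which is
insensitive to the representation, though window sums over profile data may
differ slightly from sums over centroids of the same spectra.

The imzML reader/writer is implemented in the package (XML via `xml2`,
binary arrays via `readBin`/`writeBin`): m/z arrays are stored as 64-bit
floats — a ±5 ppm window at m/z 117 is ±0.0006 Th, beyond 32-bit
resolution — and intensities as 32-bit floats; uncompressed and
zlib-compressed arrays are read, uncompressed written. A non-rectangular
coordinate set, a missing ibd companion or an unsorted m/z array is
rejected with a diagnostic naming the offending coordinate or file.

# Target masses

Negative-mode DESI of organic acids is dominated by the singly deprotonated
ion, so the registry computes

$$ m/z\,[\mathrm{M{-}H}]^- = \textstyle\sum_i n_i M_i - m_{\mathrm{p}}, $$

with tabulated monoisotopic masses and the proton mass
$m_\mathrm{p} = 1.00727646$ Da. Using the proton mass (rather than the
hydrogen-atom mass, i.e. keeping the electron with the anion) is the
standard high-resolution convention; the two differ by ~0.0005 Da, well
inside a ±5 ppm window at these masses. Citrate and isocitrate are isomers
and indistinguishable by mass alone, so they share one registry entry. The
default registry covers the TCA intermediates plus quinate, hexose and
MBOA; the disaccharide entry is flagged `verified = FALSE` because its
adduct is assumed.

# Ion images, %TIC normalization and ratios

`extractWindow` sums centroid intensities in the inclusive window
$[\,m/z\,(1-\mathrm{ppm}\cdot10^{-6}),\; m/z\,(1+\mathrm{ppm}\cdot10^{-6})]$,
located by binary search; inclusive ends make boundary behavior
deterministic. The default tolerance is ±5 ppm, matching orbitrap mass
accuracy. A target outside the acquired range warns and returns zero so
batch extraction over a target list proceeds.

The TIC of a pixel is the sum over its full acquired mass range, not over a
target list — the convention of %TIC imaging software — and
`normalization = "tic_percent"` reports $100\cdot\text{window}/\text{TIC}$
per pixel (zero where the TIC is zero). TIC normalization is susceptible to
matrix effects, so the unnormalized mode is first-class and the two can be
compared image by image.

Ratio images divide two same-raster images elementwise. Pixels whose
denominator falls below a floor (default 0, i.e. only non-positive
denominators) are masked rather than inflated by an epsilon: masking is
transparent, an epsilon would bias the stored values. Stored ratios are
never clipped; the display maximum (default 11) is a rendering concern
only. Numeric grids exported as delimited text (`writeGrid`) are the
contract surface; rendered images are decorative side-products.

# Axis profiles and per-position statistics

`sampleBand` averages nearest-pixel values across a band perpendicular to a
user-drawn line, at equally spaced sample points. A "ten-pixel" band is
realized as the line point plus five raster pixels on each side with no
interpolation — this mirrors line-width averaging in raster image tools and
keeps the operation brute-forceable in tests. Bands truncated at the image
border are averaged over their surviving pixels and counted in a warning.

Each section's profile is scaled to its own maximum (so sections and ions
share a common [0, 1] axis), linearly resampled onto a common grid as long
as the longest section — sections differ slightly in length and linear
interpolation is the minimal assumption — and aggregated as the pointwise
mean and sample standard deviation ($n-1$ denominator) over sections
(default study size: ten sections).

`compareProfiles` runs a two-sample, two-tailed, *equal-variance* Student
t-test per position (Student rather than Welch, because that is the named
test for both the profile and the resolution comparisons this package
reproduces). Raw p-values are flagged at α = 0.05 with no multiple-testing
correction, matching the per-point-asterisk convention; a Bonferroni option
is available. Whether such per-point tests should compare the two
metabolites to each other or each to a baseline is ambiguous in the source
material; the implementation compares the two groups directly. Degenerate
zero-variance positions are handled explicitly ($t = 0, p = 1$ when means
agree; $p \to 0$ otherwise).

# Lateral resolution: the 80–20% rule

A single-ion chromatogram along one raster row (time converted to distance
via the stage speed) crosses the tissue edge. After subtracting a baseline
(mean of the eight leading off-tissue points, the same off-tissue
convention as the background spectra; configurable) and referencing to the
chromatogram maximum, the edge is localized at its 50% crossing (first
upward crossing for rising, last downward for falling — a deterministic
tie-break), and the maximal consecutive run of points strictly between 20%
and 80% is collected. An ordinary least squares line is fit to those
points — "a straight line fit to measured data points", plural, hence OLS
over all interior points rather than a two-point secant; if only one
interior point exists its two bracketing points are included, and if none
exists the two points bracketing the crossing carry the whole rise, which
bounds the resolution by the pixel pitch. The fitted line is solved via the
point-slope formula for the x-coordinates of the exact 20% and 80% levels;
resolution is $|x_{80} - x_{20}|$.

Closed forms used as oracles: a linear ramp of width $L$ gives $0.6L$
exactly; a Gaussian-blurred edge of width σ gives
$(z_{0.8}-z_{0.2})\,\sigma = 1.6832\,\sigma$ (the OLS chord through the
central sigmoid underestimates this by ~4%, inside the 10% test envelope).
Estimates are invariant to global intensity scaling and distance
translation. Any biological gradient in the chosen ion broadens the
estimate, so calibration runs use the simulator with gradients disabled;
per-study aggregation follows the four-rows × ten-sections design
($n = 40$ per edge) with a two-tailed equal-variance t-test between rising
and falling means.

# Zone-averaged spectra

Scans across one row of one tissue are averaged per developmental zone and
the background — averaged from eight scans on the adjacent glass of the
same row (which side is user-specified) — is subtracted. Centroid positions
jitter at the ppm scale from pixel to pixel, so averaging requires binning
onto a shared axis: peaks are clustered greedily along the sorted m/z axis
with a 5 ppm bin width, consistent with the imaging tolerance (this
approximates whatever profile-domain averaging a vendor browser performs).
Negative differences are floored at zero by default (average-intensity
semantics; the floor can be disabled for diagnostics). Two contracts are
tested: a peak present on- and off-tissue at equal level vanishes, and a
peak present only off-tissue never rises above zero.

# Expression enrichment

From a zone × gene FPKM table (meristem / elongation / differentiation,
replicated), expression is transformed as
$\log_{10}(3 \cdot \max(\mathrm{FPKM}, 1/3))$ — the floor of 1/3 maps
zero-FPKM genes to a transformed value of exactly 0. The enrichment of a
gene is the mean transformed meristem expression divided by the mean
transformed differentiation-zone expression. Because a ratio of logarithms
changes with the base and with the zero-handling, both are explicit,
configurable parameters rather than hidden conventions, and a raw-FPKM
ratio mode is one flag away. A zero differentiation-zone mean makes the
ratio undefined; it is reported as `NA` with an `undefined` flag rather
than as infinity.

# The synthetic-data generator

`simulateRoot` emulates the features of a real acquisition that the
pipeline must withstand, with defaults chosen once as the study conditions:

* **Raster**: 40 × 150 pixels at 72.6 × 80 µm (the high-resolution
  geometry), m/z 50–1000.
* **Tissue**: a tapered capsule — the root enters at 6% of the scan axis,
  tapers to a half-width of 12 rows over the first 18% of its length, and
  leaves the field at 97% — whose boundary is convolved with a Gaussian of
  σ = 110 µm (≈1.5 pixel widths), emulating the desorption-spot blur.
* **Chemistry**: succinate as a Gaussian bump centered at axis fraction
  0.15 (meristem), aconitate and fumarate as logistic gradients rising
  toward differentiation (centers 0.5 and 0.55), malate constant and
  dominant (amplitude 50 000 counts, so %TIC normalization is non-trivially
  exercised), a strong constant lipid (PG(16:0/18:2), the edge-resolution
  ion), and one off-tissue matrix peak at m/z 283.26. Amplitudes are
  arbitrary counts, matching DESI's arbitrary intensity scale.
* **Noise**: Poisson counting noise (default), per-pixel multiplicative
  lognormal TIC drift (sd 0.15), and uniform m/z jitter within ±2 ppm —
  comfortably inside the ±5 ppm windows, as orbitrap accuracy is.
* **Reproducibility**: per-pixel RNG streams are split from the master seed
  through a prefix-stable sequence, so appending raster rows leaves earlier
  pixels' draws untouched, and a fixed seed reproduces the dataset
  byte-for-byte. Poisson intensities are integers, hence exactly
  representable as the 32-bit floats imzML stores — the write/read
  round-trip preserves every intensity and TIC exactly.

Ground truth records the noiseless expected intensity of every species at
every pixel, the blurred tissue factor and mask, the per-column axis
fraction, and the expected and emitted TIC, so tests can assert pipeline
identity (noise off) and correlation bounds (noise on) rather than
hand-picked values.

What the generator does *not* emulate: chimeric/overlapping isobars,
profile-mode peak shapes, spray-direction asymmetry, intensity-dependent
mass error, or the full chemical complexity (20–30 species per zone) of
real sections. Tests passing on synthetic data therefore demonstrate the
correctness of the computations, not instrument-level robustness.

# Problem sizes and numerical choices

The test suite runs ten simulated sections (40 × 150 pixels each) for
profile recovery, 2 000 replicates for the type-I error of the
per-position test (rate required in [0.03, 0.07] at α = 0.05), 100
replicates for the rising-vs-falling null acceptance (≥ 90 accepted), and
1 000 random spectra for window-oracle equivalence — sizes at which the
whole suite completes in about a minute on one CPU. Ties at window
boundaries are included (inclusive interval semantics); all intensity
accumulations are plain double-precision sums over at most a few dozen
centroids per pixel, so no compensated summation is needed.

# Known limitations

* Line profiles are straight; strongly curved roots would need a spline
  axis, which is out of scope (the source workflow draws the line
  manually).
* The root axis is not auto-detected; coordinates are supplied numerically.
* Vendor raw files are not read; conversion to mzML/imzML is assumed
  upstream. Per-row plain mzML import is not implemented.
* Brightfield co-registration and overlay are cosmetic steps outside the
  numeric contract and are omitted.
* %TIC uses the per-pixel TIC (the standard convention); a per-image
  variant is not provided.
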