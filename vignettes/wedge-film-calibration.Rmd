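---
title: "Calibrating radiochromic film from a physical-wedge dose gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating radiochromic film from a physical-wedge dose gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wedgecal)
```

## Overview

Radiochromic film dosimetry needs a per-batch calibration curve from net
optical density (netOD) to absorbed dose. This package implements two
routes and their comparison:

* **Benchmark calibration (BC)** — the conventional protocol: ten film
  strips exposed to uniform 6 MV fields at 1–5.5 Gy in 0.5 Gy steps, one
  (netOD, dose) point per strip.
* **Physical-wedge (PW) calibration** — a single strip exposed under a 60°
  physical wedge captures the wedge's lateral dose gradient; pairing the
  film's netOD profile with the independently measured, normalized wedge
  dose profile yields hundreds of calibration points from one exposure.

Because no public film-scan data exist for this setup, the package ships a
first-class synthetic generator that replicates the study conditions, and
all validation claims are made on that generator.

## Scan model and reduction chain

Scans are RGB TIFFs; only the red channel is used (the most dose-sensitive
channel for EBT3 in this dose range). Each strip is represented by three
stacks of repeat scans: the film before exposure, after exposure, and a
zero-light background strip. The reduction chain per stack is

1. per-scan 3 × 3 median filter (impulse/dust removal),
2. pixel-wise mean across the repeat scans (floating point),
3. adaptive Wiener filter, 7 × 7 window.

The Wiener window is part of the protocol; the median window is not
specified by it, and we use the smallest impulse-removing window (3 × 3)
applied per scan before averaging. Both filters use reflect padding so
that strip borders are not darkened, which would bias edge segmentation.
The adaptive Wiener filter estimates a local mean and variance in each
window, takes the mean local variance of the raster as the noise power,
and applies the gain `max(v − noise, 0) / max(v, noise)` to the deviation
from the local mean: uniform regions collapse to their local mean while
strong structure (field edges, the wedge gradient) passes through nearly
untouched.

netOD and its uncertainty follow the standard transmission formalism:

$$\mathrm{netOD} = \log_{10}\frac{PV_{unexp}-PV_{bckg}}{PV_{exp}-PV_{bckg}},$$

with first-order propagation of the three pixel-value spreads for
$\sigma_{netOD}$. Pixels violating the log domain (saturated film, bad
background) are masked, not fatal — wedge extraction only needs the
central band of the map.

**Where the spreads are measured.** The uncertainty convention is
deliberately conservative: $\sigma_{PV}$ is the sd of the pixels in the
1 × 1 mm ROI itself, not the standard error of its mean. The spreads are
taken on the median-filtered *average* raster, i.e. before the Wiener
step, while ROI means come from the fully reduced raster. Measured after
Wiener filtering, an ROI sd understates the ROI-mean error, because the
filter removes precisely the within-window variation that the sd
measures; empirically that choice drops the 3-sigma coverage of the
generator round-trip from ≥ 99 % to about 94 %, while the pre-Wiener
spread restores it. The alternative (sd of repeat-scan means) would be
smaller by roughly $1/\sqrt{n_{scans}}$ and is not used.

One practical note on metadata: scan resolution is read from the TIFF
resolution tags when present; files written by this package carry the dpi
in the study manifest instead (the TIFF writer in the `tiff` package does
not expose resolution tags), and readers fall back to the configured dpi.

## Calibration function and uncertainty budget

The dose response is $D = a\,\mathrm{netOD} + b\,\mathrm{netOD}^n$ with
$n = 2.5$ held fixed; $a$ and $b$ are fitted by Levenberg–Marquardt
(`minpack.lm::nlsLM`, `ftol = ptol = 1e-12`, up to 1000 iterations),
initialized deterministically at $a_0$ = the dose/netOD secant through the
two lowest-netOD points and $b_0 = 0$. Residuals are unweighted in dose —
$\sigma_{netOD}$ is carried for uncertainty budgets only — and a weighted
mode ($1/\sigma_{netOD}^2$) is available. Because the model is linear in
$(a, b)$ at fixed $n$, an exact zero-residual optimum (noiseless data) can
make the iterative fitter's gradient test degenerate; in that case the
closed-form linear least-squares solution is used, which is the same
minimizer. Parameter uncertainties come from the fit covariance. The
inverse map (netOD from dose) is obtained by bisection on the monotone
forward map to 1e-10 in netOD.

Relative dose uncertainty splits into the experimental component
$|a + n b\,\mathrm{netOD}^{n-1}|\,\sigma_{netOD}/D \times 100$ and the fit
component $\sqrt{\mathrm{netOD}^2\sigma_a^2 +
\mathrm{netOD}^{2n}\sigma_b^2}/D \times 100$, summed in quadrature.
Deviations between calibrations are reported as
$|D_{BC} - D_{PW}|/D_{BC} \times 100$ at the benchmark measurement netODs,
with $D_{BC}$ the benchmark *fit* evaluated there, so the statistic
compares the two curves rather than echoing benchmark measurement noise.

## Wedge profile extraction

Per wedge exposure: the netOD map is reduced as above; the 25 central
lines along the gradient axis are averaged (the per-position uncertainty
kept is the transverse sd of those lines — again the conservative
convention); field edges are located at the maximum gradient magnitude in
each half of a lightly pre-smoothed copy (moving mean, window 5), subject
to a noise floor of 3 × the median absolute gradient of the outer 10 % of
samples; the segmented span is checked against the divergence-scaled
aperture, `field_size × (SSD + depth)/SSD` (157.5 mm here), within 5 %; the
central 20–80 % of the segmented profile is kept; an 11-sample moving mean
(about 2.2 mm at 127 dpi — wide enough to suppress pixel noise, far too
narrow to flatten a 60° gradient) smooths the profile with a symmetrically
shrinking window at the boundaries; and the longest strictly monotone run
is extracted. Profiles are mirrored if needed so netOD decreases with
increasing position. Edge-width asymmetry beyond 50 % raises a
film-rotation warning (detection only; no correction is attempted).

**Registration.** Film and reference profiles live in the same
measurement plane (SSD 100 cm, depth 5 cm), so positions are compared
directly once both are centered. The film profile is centered at the
midpoint of its detected edges. That midpoint, however, is measured in
netOD space, and the nonlinearity of the dose response displaces the netOD
inflection of the high-dose edge more than that of the low-dose edge — for
a 5 mm penumbra the midpoint sits 0.4–0.6 mm off the dose-space CAX, worth
about 0.5 % in dose on a 60° gradient. `wedgeCalibration` therefore
refines the registration: it maps the reference dose profile into netOD
space through the current fitted curve, locates *its* edge midpoint with
the same gradient operator, aligns the film midpoint to it, and refits
(two iterations; the correction is second order after the first). The
displacement is common to both profiles and cancels. Gradient peaks are
interpolated to sub-sample precision with a parabola for registration
only; cropping stays on whole samples. With this registration the
noiseless single-gradient curve agrees with the truth and with the
benchmark curve to better than 0.03 %; without it the agreement is limited
to about 0.5 % by the penumbra physics, not by noise.

Dose profiles are self-similar: the profile at CAX dose $D_{CAX}$ is the
normalized reference profile times $D_{CAX}$ (linear interpolation at film
positions; positions outside the reference support are an error).
Monitor-unit bookkeeping uses the wedge transmission at the CAX
(0.2654 for this wedge at 100 cm SSD, 5 cm depth):
$MU = D_{CAX}/(\text{output} \times \text{attenuation})$.

Extrapolation is not a separate fitting mode: a curve fitted on a narrow
netOD range is simply evaluated outside its fitted domain, and every
result carries an `extrapolated` flag per point. Multi-gradient
calibration concatenates the points of several exposures without
per-gradient weighting and fits once.

## The synthetic generator

`simulateStudy()` renders complete studies: ten uniform-field strip
triplets (1–5.5 Gy), five wedge triplets ($D_{CAX}$ = 1–5 Gy), the
reference profile, and a manifest. The wedge field is separable: along the
gradient axis an exponential lateral factor $f(x)$ with $f(0) = 1$
(exponential in the linearly varying wedge thickness), spanning a dynamic
range of 3 across the central 60 % of the field — chosen so a single 5 Gy
exposure covers roughly 2.9–8.7 Gy, wide enough to exercise trimming,
monotone extraction and extrapolation; a logistic border rolloff with a
5 mm 80–20 penumbra; and a 2 % out-of-field scatter floor; flat
transversely (the strip lies well inside the field). The identical lateral
profile is emitted as the reference, so pipeline tests are self-consistent
by construction; the real wedge profile is a measurement, and no claim is
made that the parametric stand-in matches it — it is declared synthetic
throughout.

Scans are rendered as: unexposed film at mean PV 40000 (16-bit scale)
modulated by a low-frequency multiplicative nonuniformity field (Gaussian,
0.3 % relative sd, 50 mm correlation length, bilinearly upsampled from a
coarse grid); exposed film attenuated by $10^{-\mathrm{netOD(dose)}}$ using
the inverse of the true response (bisection), sharing the film's
nonuniformity realization — it is the same physical film, so the base
nonuniformity largely cancels in netOD, as it does in practice for
pre/post scan protocols; zero-light background at mean PV 1000. Each of
the five repeat scans adds independent Gaussian noise with sd
0.5 % of the pixel value, clipped to the 16-bit range and rounded. The
noise defaults were chosen so the benchmark uncertainty budget lands in
the sub-2 % regime reported for careful EBT3 protocols at these doses.
All randomness flows through one seed; equal seeds give byte-identical
studies.

**Quantization.** A zero-noise render returns the analytic expectation
maps unquantized; rounding to integers is part of the noisy scanner model
and of any raster written to disk (16-bit TIFF). This keeps noiseless
round-trips exact (netOD to 1e-6, parameter recovery to 1e-5, tested on
the in-memory path), while the disk path is additionally limited by PV
quantization (about 2e-5 in netOD, hence about 1e-4 in fitted parameters,
tested at that bound).

What the generator does **not** emulate: scanner lateral-response
artifacts, film curvature, active-layer thickness maps of real EBT3,
energy dependence, film rotation on the scanner bed. Passing tests
therefore demonstrate the correctness and internal consistency of the
numerical pipeline under realistic noise, not the dosimetric accuracy of
any particular film/scanner system.

## Problem sizes and numerical choices

The validation suite and the reproduction script use benchmark strip
rasters of 48 × 48 px and wedge rasters of 60 × 989 px at 127 dpi (the
field span at depth, 157.5 mm, plus 20 mm margins); one wedge gradient
yields about 470 calibration points after trimming, and the replicated
analyses run 20 independent study replicates. The 3-sigma coverage check
uses 36 × 36 px benchmark rasters over 200 replicates. These sizes keep a
complete replicate around ten seconds without changing any study
condition (dose levels, noise, scan counts, dpi, geometry are the
defaults above).

Other numerical conventions, fixed package-wide: positions are
`index × 25.4/dpi` with 0-based indices from the raster corner; mm→pixel
conversions round half away from zero with a 1 × 1 px minimum; ROI
rectangles are anchored on the nearest pixel center (at 127 dpi a
1 × 1 mm ROI is exactly 5 × 5 px); trimming keeps 0-based indices
`floor(0.2 L) ≤ i < floor(0.8 L)`; monotone-run ties resolve toward the
run containing the profile midpoint, then to the earliest; bisection
inversions stop at 1e-10 in netOD.

## Known limitations

* The registration refinement assumes the reference profile's shape is
  trustworthy near the field edges; a reference measured only across the
  central region would force plain midpoint registration and its
  penumbra-dependent bias (about 0.5 % here).
* Rotation of the film relative to the gradient axis is detected (edge
  width asymmetry) but not corrected.
* The per-pixel netOD uncertainty map uses local spreads of the reduced
  rasters and is informative rather than rigorous after Wiener filtering;
  strip-level uncertainties (the quantities entering the budgets) use the
  pre-Wiener convention described above.
* Single-channel (red) dosimetry only; no multi-channel correction model.
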