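---
title: "Quantifying membrane fluorescence, surface density and curvature sorting on GUVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane fluorescence, surface density and curvature sorting on GUVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvquant)
```

## Scope

Giant unilamellar vesicles (GUVs) are the workhorse model membrane for
studying how peripheral proteins bind, crowd, and reshape lipid
bilayers. A typical experiment images an equatorial confocal section of
a GUV — a bright ring over a dark background — and turns ring intensity
into physical quantities: how many molecules sit on a square micrometre
of membrane, what fraction of the surface they cover, how strongly they
enrich on a highly curved tether, how mobile they are (FRAP), and how
effectively they convert spherical vesicles into tubules. `guvquant`
implements that measurement chain end to end, together with synthetic
image generators that render every input with known ground truth, so
each stage is testable without instrument data.

## Gaussian-ring quantification

An equatorial section of a fluorescently labeled GUV is modeled, along
each radial ray at angle $\theta_i$, as

$$I_i(r) = B + A_i \exp\!\left(-\frac{(r - \rho_i)^2}{2\sigma^2}\right),$$

with the background $B$ and apparent ring width $\sigma$ shared across
angles, and a per-angle amplitude $A_i$ and radius $\rho_i$. Sharing
$B$ and $\sigma$ stabilizes low-SNR fits; freeing $A_i$ and $\rho_i$
per angle accommodates intensity heterogeneity and slightly non-circular
contours. The membrane intensity reported per GUV is the mean of the
included $A_i$ (peak amplitude, not integrated area): experiments
compare intensities across channels and conditions at fixed optics, for
which the peak is a consistent proxy. The integrated alternative
$\bar A\,\sigma\sqrt{2\pi}$ is available via `summary = "integrated"`.

Fitting alternates three closed-form or one-dimensional steps: per-angle
matched-filter updates of $\rho_i$, an exact arrowhead-structured linear
solve for $(B, A_1 \ldots A_n)$, and a line search in $\log\sigma$; the
sub-pixel center is refined from the first angular Fourier mode of
$\rho(\theta)$. Radial profiles are sampled every 0.25 px at 360 angles
over a ±10 px window by default. Sampling uses Catmull–Rom cubic
interpolation: bilinear sampling broadens a ring of effective width
$\sigma \approx 2$ px enough to bias the fitted amplitude by about 2%,
which cubic interpolation reduces to below 0.2% (bilinear remains
available via `interpolation = "bilinear"`). Angular sectors can be
excluded from both fit and summary — used to drop the aspirated region
of a pipette-held GUV, and the tether attachment point in sorting
scenes. Sectors covering three quarters of the circle or more are
rejected.

Degenerate inputs: a constant image raises a "no GUV found" detection
error; angular fits with non-positive amplitude or a radius pinned to
the window edge are marked failed, and more than 50% failures aborts
the fit.

```{r ring}
truth <- scene_ground_truth(guv_center = c(6.4, 6.4), guv_radius = 4,
                            membrane_intensity = c(A488 = 1000),
                            background = 50)
scene <- make_guv_image(truth)
fit <- fit_gaussian_ring(scene$image, "A488",
                         detect_guv_contour(scene$image, "A488"))
fit
```

## From intensity to surface density

The calibration chain converts a membrane intensity into a surface
density in four documented steps.

1. **Calibration slope.** GUVs doped with $x$ mol% of a reference lipid
   dye (0.1–0.75 mol% is the usual range) are imaged at fixed settings
   and fit to $\text{Intensity} = s\,x$ through the origin. GUV-to-GUV
   scatter scales with mean intensity (constant CV), so the default fit
   weights observations by $1/x^2$; with unweighted least squares the
   reported slope SE understates the true slope variability roughly
   twofold under multiplicative noise. `weighting = "ols"` restores the
   plain fit.
2. **Reference conversion factor.** With headgroup area
   $a_L = 0.7\ \text{nm}^2$, one mol% of dye in a single leaflet is
   $10^6/a_L/100 \approx 14{,}286$ molecules/µm², so
   $k_{\mathrm{ref}} = s\,a_L\,10^{-4}$ intensity units per
   molecule/µm². Only single-leaflet counting reproduces the published
   factor of 14 from a slope of 201,334, so it is the default;
   `leaflet_mode = "both"` (halving $k$) covers symmetric labeling.
3. **Target-dye factor.** A target fluorophore $\beta$ times brighter
   than the reference has $k_{\mathrm{dye}} = \beta\,k_{\mathrm{ref}}$;
   $\beta$ is applied as a scalar brightness ratio.
4. **Species density.** For labeling efficiency $e$,
   $\text{density} = I/(k_{\mathrm{dye}}\,e)$. The GUV-to-GUV intensity
   SD propagates to the density SD; the conversion-factor uncertainty is
   reported alongside rather than folded in, and reported values are
   additionally rounded to the nearest 100 molecules/µm², the working
   precision of the chain.

```{r density}
k_ref <- conversion_factor(calibration_model(slope = 201334,
                                             slope_se = 14039))
k_dye <- target_dye_factor(k_ref, brightness_ratio = 2)
round(c(k_ref$k, k_dye$k), 2)
labeled_species_density(19117, 7997, k_dye, efficiency = 0.5)
```

## Footprint and membrane coverage of a disordered peptide

For an intrinsically disordered chain, the hydrodynamic radius follows
the Marsh–Forman-Kay scaling law

$$R_h = (A\,P_{\mathrm{pro}} + B)(C\,|Q| + D)\,S_{\mathrm{His}}\,R_0\,N^{\nu},$$

with the published coefficients ($A = 1.24$, $B = 0.904$, $C = 0.00759$,
$D = 0.963$, $R_0 = 2.49$ Å, $\nu = 0.509$; $S_{\mathrm{His}} = 1$
without a His tag) as defaults in `rh_constants()`. The membrane
footprint is the projected disk $\pi R_h^2$ and coverage is density ×
footprint, flagged against the ~20% coverage where steric crowding
alone can bend membranes. Descriptors can be typed in directly or
derived from a sequence; the sequence path uses the package convention
$|Q| = |(\#K + \#R) - (\#D + \#E)|$ with histidine neutral and termini
ignored, and is advisory — published descriptor values take precedence
when available.

```{r coverage}
d <- peptide_descriptor(n_residues = 80, p_pro = 0.2, abs_net_charge = 13)
rh <- idp_hydrodynamic_radius(d)
c(rh = round(rh, 1), footprint_um2 = signif(footprint_area(rh), 3),
  percent = round(area_coverage(1400, footprint_area(rh))$percent, 1))
```

## Tether sorting and aspiration tension

Curvature preference is quantified on a membrane tether pulled from a
micropipette-aspirated GUV. The sorting coefficient

$$S = \frac{(I_{\mathrm{tether}}/I_{\mathrm{GUV}})_{\mathrm{protein}}}
           {(I_{\mathrm{tether}}/I_{\mathrm{GUV}})_{\mathrm{lipid}}}$$

normalizes by a lipid dye so channel gains and tether geometry cancel;
$S = 1$ means no preference. $I_{\mathrm{GUV}}$ is the Gaussian-ring
membrane intensity with the aspirated sector excluded;
$I_{\mathrm{tether}}$ is the mean over a narrow rectangular ROI along
the tether. Background subtraction for the tether ROI defaults to none,
matching the bare ratio definition, but a measured background can be
supplied — diffraction-limited tethers over nonzero background otherwise
bias $S$ toward 1. Channels whose tether signal falls below a
configurable floor are flagged `low_signal` rather than suppressed.
Membrane tension from the aspiration geometry is
$T = \Delta P\,R_p / [2(1 - R_p/R_v)]$, with pressures in Pa, radii in
µm, and tension reported in mN/m.

```{r tension}
membrane_tension(delta_p = 100, r_p = 2.5, r_v = 10)
```

## FRAP

Traces are normalized frame-by-frame against an unbleached reference
ROI (cancelling acquisition bleaching), averaged over all pre-bleach
frames, and fit to a single-exponential recovery
$I(t) = I_\infty - (I_\infty - I_0)\,e^{-(t - t_b)/\tau}$ with the
documented initializer ($I_0$ = first post-bleach point, $I_\infty$ =
last, $\tau$ = span/3). A one-$\tau$ model is the minimal faithful
summary of normalized recovery profiles; the fit function is pluggable
if a diffusion-equation model is ever needed. Mobile fraction is
$(I_\infty - I_0)/(I_{\mathrm{pre}} - I_0)$ clipped to [0, 1];
half-time is $\tau \ln 2$. Flat post-bleach traces short-circuit to
mobile fraction 0, and exact (zero-residual) traces fall back from
Levenberg–Marquardt to direct SSE minimization from the same start.

## Tubule morphometry

Micrograph-style images are thresholded (Otsu, refined by an isodata
step so anti-aliased edges split at half coverage), labeled, and each
component is skeletonized by Zhang–Suen thinning. Length is the
geodesic length of the longest skeleton path, measured on a 5-px
subsampled polyline to undo the ~7% staircase inflation of 8-connected
chains; diameter is twice the mean distance-transform value along the
path minus one pixel (the half-pixel boundary offset on each side).
Objects with length/width ≥ 3 are classified tubulated — the published
analyses classified by eye, so the threshold is an explicit, logged
parameter — and border-touching objects are flagged and excluded from
summaries to avoid truncation bias. Tubulation percentages aggregate
per group (micrograph or trial) and are then summarized as mean ± SD
across groups, mirroring trial-wise reporting.

## The synthetic generators

The generators define the study conditions and return their ground
truth alongside every image; recovery tests compare only against that
record.

* **GUV scenes** (`make_guv_image`): ring amplitude 1000 a.u. over
  background 50 at radius 4 µm; intrinsic ring width 0.1 µm and PSF
  width 0.15 µm combine in quadrature, so the noiseless radial peak
  equals the ground-truth membrane intensity exactly. Pixel size
  defaults to 0.1 µm/px; pixel size and PSF are package choices typical
  of a 60×/1.1 NA confocal, as the source imaging parameters are not
  published. Poisson noise at gain 1 gives peak SNR ≈ √1000 ≈ 30.
* **Tether scenes** (`make_tether_scene`): a Gaussian line of FWHM 3 px
  attached radially, with per-channel amplitude = enrichment × ring
  amplitude × a shared geometric factor, so the ground-truth sorting
  coefficient is exactly the enrichment ratio.
* **FRAP stacks** (`make_frap_stack`): closed-form recovery in a bleach
  ROI against a constant reference region, 2.6 s frame interval.
* **Calibration series** (`make_calibration_series`): five levels over
  0.1–0.75 mol%, ten GUVs per level, 10% CV multiplicative noise.
* **Micrographs** (`make_tubule_micrograph`, `random_tubule_scene`):
  dark disks and constant-width capsules on a bright background at
  5 nm/px, diameters 40–80 nm and lengths 0.2–1 µm, placed without
  overlap.

What the generators deliberately omit: 3-D sectioning and defocus,
optical aberrations and PSF anisotropy, membrane fluctuations, stain
texture and uneven illumination, overlapping or aggregated objects.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated image model, not robustness to every
artifact of real data; on real images the Gaussian-ring model and the
isodata threshold remain applicable, but accuracy claims must be
re-established per dataset.

## Numerical choices and problem sizes

Tests and examples run on 128–640 px images, 360 fit angles, 50-replicate
noise ensembles, a 12-cell × 20-replicate FRAP grid, and 20 random
micrographs — sizes chosen so the full suite exercises every stage at
meaningful statistics while remaining quick on a laptop. Seeds enter
only through generator ground-truth records and are restored after use;
identical seed and parameters give bit-identical outputs. TIFF output
quantizes intensities to 16-bit against a recorded scale (integer data
in [0, 65535] round-trips exactly); ground truth and manifests are JSON.

## Known limitations

* Tether radius estimation from lipid intensity, tether force, and
  pulling kinematics are out of scope.
* The classifier operates on connected components; a vesicle with an
  attached tubule is one object and is classified by its overall
  aspect, as the component-level split is not defined by the source
  analyses.
* Sequence-derived net charge ignores pH and His protonation; it is a
  counting convention, not a titration model.
* The single-exponential FRAP model does not estimate a diffusion
  coefficient from ROI geometry and cannot represent two-component
  recoveries.
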