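# guvquant

Quantitative fluorescence and morphometry analysis for membrane
biophysics on giant unilamellar vesicles (GUVs).

Peripheral membrane proteins are studied by conjugating or binding them
to GUVs and imaging equatorial confocal sections: a bright membrane
ring over a dark background. Getting from those rings to physical
quantities — molecules per µm², fractional surface coverage, curvature
sorting on pulled tethers, lateral mobility, tubulation statistics —
requires a chain of measurements that is usually scattered across
ImageJ macros and one-off scripts. `guvquant` implements that chain as
a tested R package, aimed at membrane biophysicists and microscopists:

* **Gaussian-ring quantification** — detect a GUV contour and fit, per
  angle θ, `I(r) = B + A_i exp(−(r − ρ_i)²/2σ²)` with shared
  background B and width σ, giving a sub-pixel center, radius, and a
  per-GUV membrane intensity with angular spread; the aspirated sector
  of a pipette-held GUV can be excluded.
* **Density calibration** — from the slope *s* of intensity vs mol% of
  a reference lipid dye and headgroup area *a_L*:
  `k_ref = s · a_L · 10⁻⁴` intensity units per molecule/µm² (single
  leaflet), `k_dye = β · k_ref` for a target dye β times brighter, and
  `density = I / (k_dye · e)` at labeling efficiency *e*.
* **Footprint and coverage of disordered peptides** — the
  Marsh–Forman-Kay scaling law
  `Rh = (A·Ppro + B)(C·|Q| + D)·S_His·R0·N^ν`, footprint `π·Rh²`, and
  coverage = density × footprint, flagged against the ~20% crowding
  threshold.
* **Tether sorting and tension** — sorting coefficient
  `S = (I_tether/I_GUV)_protein / (I_tether/I_GUV)_lipid` and
  aspiration tension `T = ΔP·Rp / [2(1 − Rp/Rv)]` in mN/m.
* **FRAP** — reference-normalized traces and single-exponential
  recovery fits (mobile fraction, τ, half-time).
* **Tubule morphometry** — segmentation, Zhang–Suen skeletonization,
  geodesic length and distance-transform diameter, intact/tubulated
  classification, trial-wise summaries.
* **Synthetic generators** — GUV rings, tether scenes, FRAP stacks,
  calibration series, and vesicle/tubule micrographs, each returned
  with its ground truth, so the whole chain is testable without
  instrument data.

## Worked example

Quantify a shot-noise-limited synthetic GUV and push its intensity
through the density chain:

```r
library(guvquant)

truth <- scene_ground_truth(guv_center = c(6.4, 6.4), guv_radius = 4,
                            membrane_intensity = c(A488 = 1000),
                            background = 50,
                            noise = noise_model("poisson", gain = 1),
                            seed = 1)
scene <- make_guv_image(truth)
fit <- fit_gaussian_ring(scene$image, "A488",
                         detect_guv_contour(scene$image, "A488"))
fit
#> <ring_fit> center (64.00, 64.00) px, radius 40.00 px, sigma 1.81 px
#>   background 49.90, membrane intensity 995.5 +/- 14.9 a.u. (360 angles)
```

The fitted amplitude recovers the ground-truth 1000 a.u. within 0.5%
at peak SNR ≈ 30, and the radius (4 µm at 0.1 µm/px) to 0.01 px.
Converting a measured GUV intensity of 19,117 ± 7,997 a.u. with a
calibration slope of 201,334 a.u./mol%, a 2× brighter target dye, and
50% labeling efficiency:

```r
k_ref <- conversion_factor(calibration_model(slope = 201334,
                                             slope_se = 14039))
k_dye <- target_dye_factor(k_ref, brightness_ratio = 2)
round(c(k_ref$k, k_dye$k), 2)
#> [1] 14.09 28.19
labeled_species_density(19117, 7997, k_dye, efficiency = 0.5)
#> <density_estimate> 1356.5 +/- 567.4 molecules/um2 (1400 +/- 600 after rounding)
```

i.e. 14 ± 1 intensity units per reference-dye molecule/µm², 28 ± 2 for
the target dye, and a surface density of 1400 ± 600 molecules/µm².
The footprint and coverage of an 80-residue disordered loop with
proline fraction 0.2 and net charge 13:

```r
d <- peptide_descriptor(n_residues = 80, p_pro = 0.2, abs_net_charge = 13)
rh <- idp_hydrodynamic_radius(d)    # 28.3 Angstrom
footprint_area(rh)                  # 2.52e-5 um2
area_coverage(1400, footprint_area(rh))$percent   # ~3.5 (%)
membrane_tension(delta_p = 100, r_p = 2.5, r_v = 10)  # 0.167 mN/m
```

So at 1400 molecules/µm² the loop covers ~3.5% of the membrane — far
below the ~20% where steric crowding alone bends membranes.

`run_pipeline(run_config(seed = 7, output_dir = "out"))` runs every
stage on generated fixtures and writes CSV/JSON results plus a manifest
that makes the run byte-reproducible.

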