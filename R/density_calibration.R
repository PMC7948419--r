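#' Fit the intensity-vs-mol% calibration line
#'
#' Least-squares line through the origin relating GUV membrane intensity
#' to the mole percent of a calibration lipid dye, the one-parameter
#' relation `Intensity = slope * mol_percent`.  An intercept mode exists
#' for background-contaminated data but is not the default.
#'
#' GUV-to-GUV intensity scatter scales with the mean intensity
#' (constant coefficient of variation), so the default fit weights
#' observations by `1 / mol_percent^2`, which makes the reported slope
#' standard error honest under multiplicative noise.  Unweighted
#' least squares is available via `weighting = "ols"`.
#'
#' @param series data.frame with columns `mol_percent` and `intensity`.
#' @param through_origin fit without intercept (default TRUE).
#' @param weighting `"cv"` (weights 1/x^2, default) or `"ols"`.
#' @return list of class `calibration_fit` with `slope`, `slope_se`,
#'   `intercept` (0 in origin mode) and the underlying `stats::lm` fit.
#' @export
fit_calibration <- function(series, through_origin = TRUE,
                            weighting = c("cv", "ols")) {
  weighting <- match.arg(weighting)
  if (!all(c("mol_percent", "intensity") %in% names(series)))
    stop("series must have columns 'mol_percent' and 'intensity'")
  x <- series$mol_percent; y <- series$intensity
  if (any(x <= 0)) stop("all mol% levels must be > 0")
  if (length(unique(x)) < 2)
    stop("calibration needs at least two distinct mol% levels")
  w <- if (weighting == "cv") 1 / x^2 else rep(1, length(x))
  fm <- if (through_origin) stats::lm(y ~ 0 + x, weights = w) else
    stats::lm(y ~ x, weights = w)
  co <- suppressWarnings(summary(fm)$coefficients)  # exact fits warn
  slope_row <- if (through_origin) 1L else 2L
  se <- co[slope_row, 2]
  if (!is.finite(se)) se <- 0
  structure(list(slope = unname(stats::coef(fm)[slope_row]),
                 slope_se = unname(se),
                 intercept = if (through_origin) 0 else
                   unname(stats::coef(fm)[1]),
                 through_origin = through_origin, fit = fm),
            class = "calibration_fit")
}

#' Calibration model for the intensity-to-density chain
#'
#' @param slope fitted calibration slope, a.u. per mol% of reference dye.
#' @param slope_se standard error of the slope.
#' @param headgroup_area_nm2 area per lipid headgroup (default 0.7 nm2).
#' @param leaflet_mode `"single"` counts dye in the outer leaflet only
#'   (the default; conjugated species sit on one face), `"both"` counts
#'   both leaflets, which halves the conversion factor.
#' @param brightness_ratio per-molecule brightness of the reference dye
#'   relative to the target dye (2 when the target is twice as bright).
#' @param labeling_efficiency fraction of target molecules carrying a dye
#'   (0-1].
#' @return list of class `calibration_model`.
#' @export
calibration_model <- function(slope, slope_se = 0, headgroup_area_nm2 = 0.7,
                              leaflet_mode = c("single", "both"),
                              brightness_ratio = 1,
                              labeling_efficiency = 1) {
  leaflet_mode <- match.arg(leaflet_mode)
  stopifnot(slope >= 0, slope_se >= 0, headgroup_area_nm2 > 0,
            brightness_ratio > 0,
            labeling_efficiency > 0, labeling_efficiency <= 1)
  structure(list(slope = slope, slope_se = slope_se,
                 headgroup_area_nm2 = headgroup_area_nm2,
                 leaflet_mode = leaflet_mode,
                 brightness_ratio = brightness_ratio,
                 labeling_efficiency = labeling_efficiency),
            class = "calibration_model")
}

#' Intensity units per reference-dye molecule per um2
#'
#' One mol% of dye in a leaflet with headgroup area `a` nm2 corresponds
#' to `1e6 / a / 100` molecules per um2, so the calibration slope divided
#' by that count converts intensity into reference-dye surface density:
#' `density = intensity / k`.
#'
#' @param model a [calibration_model()].
#' @return list of class `conversion_factor` with `k` (a.u. per molecule
#'   per um2), `k_se` propagated from the slope SE, and
#'   `molecules_per_um2_per_molpct`.
#' @export
conversion_factor <- function(model) {
  stopifnot(inherits(model, "calibration_model"))
  per_leaflet <- 1e6 / model$headgroup_area_nm2      # lipids per um2
  n_leaflets <- if (model$leaflet_mode == "both") 2 else 1
  mol_per_um2_per_pct <- per_leaflet * n_leaflets / 100
  structure(list(k = model$slope / mol_per_um2_per_pct,
                 k_se = model$slope_se / mol_per_um2_per_pct,
                 molecules_per_um2_per_molpct = mol_per_um2_per_pct,
                 leaflet_mode = model$leaflet_mode),
            class = "conversion_factor")
}

#' Rescale the conversion factor to a different fluorophore
#'
#' A target dye `beta` times brighter than the reference emits the same
#' intensity at `1/beta` the density, so intensity units per molecule
#' scale by `beta`.
#'
#' @param k_ref a [conversion_factor()] or a bare numeric factor.
#' @param brightness_ratio `beta`, target brightness over reference
#'   brightness.
#' @return a `conversion_factor` for the target dye.
#' @export
target_dye_factor <- function(k_ref, brightness_ratio) {
  stopifnot(brightness_ratio > 0)
  if (is.numeric(k_ref)) k_ref <- structure(
    list(k = k_ref, k_se = 0, molecules_per_um2_per_molpct = NA,
         leaflet_mode = NA), class = "conversion_factor")
  k_ref$k <- k_ref$k * brightness_ratio
  k_ref$k_se <- k_ref$k_se * brightness_ratio
  k_ref
}

#' Surface density of a labeled species from membrane intensity
#'
#' `density = intensity / (k_dye * e)` where `e` is the labeling
#' efficiency.  The GUV-to-GUV intensity spread propagates to the density
#' SD; the conversion-factor uncertainty is carried alongside, not folded
#' in.  Reported values are also rounded to the nearest hundred
#' molecules per um2, the working precision of the chain.
#'
#' @param intensity_mean,intensity_sd membrane intensity mean and SD
#'   across GUVs (a.u.).
#' @param k_dye a [conversion_factor()] for the target dye, or numeric.
#' @param efficiency labeling efficiency `e` in (0, 1].
#' @return list of class `density_estimate` with `density_mean`,
#'   `density_sd`, `rounded_mean`, `rounded_sd` (molecules/um2) and the
#'   `k` used.
#' @export
labeled_species_density <- function(intensity_mean, intensity_sd = 0, k_dye,
                                    efficiency = 1) {
  if (efficiency <= 0 || efficiency > 1)
    stop("labeling efficiency must be in (0, 1]")
  k <- if (inherits(k_dye, "conversion_factor")) k_dye$k else k_dye
  stopifnot(k > 0, intensity_mean >= 0, intensity_sd >= 0)
  d <- intensity_mean / (k * efficiency)
  s <- intensity_sd / (k * efficiency)
  structure(list(density_mean = d, density_sd = s,
                 rounded_mean = round(d / 100) * 100,
                 rounded_sd = round(s / 100) * 100,
                 k = k, efficiency = efficiency),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> %.1f +/- %.1f molecules/um2 (%.0f +/- %.0f after rounding)\n",
              x$density_mean, x$density_sd, x$rounded_mean, x$rounded_sd))
  invisible(x)
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Composition descriptor of a disordered peptide
#'
#' Either give the counts directly or derive them from a sequence with
#' [descriptor_from_sequence()].  Net charge follows the package
#' convention `|Q| = |(#K + #R) - (#D + #E)|` (histidine neutral,
#' termini ignored).
#'
#' @param n_residues chain length N.
#' @param n_prolines number of prolines (alternative to `p_pro`).
#' @param p_pro proline fraction.
#' @param abs_net_charge absolute net charge |Q| in elementary charges.
#' @param has_his_tag whether the construct carries a His tag.
#' @return list of class `peptide_descriptor`.
#' @export
peptide_descriptor <- function(n_residues, n_prolines = NULL, p_pro = NULL,
                               abs_net_charge, has_his_tag = FALSE) {
  stopifnot(n_residues >= 1, abs_net_charge >= 0)
  if (is.null(p_pro)) {
    if (is.null(n_prolines)) stop("give n_prolines or p_pro")
    p_pro <- n_prolines / n_residues
  } else if (is.null(n_prolines)) n_prolines <- round(p_pro * n_residues)
  if (p_pro < 0 || p_pro > 1) stop("p_pro must be in [0, 1]")
  structure(list(n_residues = n_residues, n_prolines = n_prolines,
                 p_pro = p_pro, abs_net_charge = abs_net_charge,
                 has_his_tag = isTRUE(has_his_tag)),
            class = "peptide_descriptor")
}

#' Derive a peptide descriptor from an amino-acid sequence
#'
#' @param sequence one-letter amino-acid string (standard 20 residues).
#' @param has_his_tag whether the construct carries a His tag.
#' @return a [peptide_descriptor()].
#' @export
descriptor_from_sequence <- function(sequence, has_his_tag = FALSE) {
  s <- strsplit(gsub("[[:space:]]", "", toupper(sequence)), "")[[1]]
  bad <- setdiff(unique(s), AA_LETTERS)
  if (length(bad) > 0)
    stop("non-standard residue letters: ", paste(bad, collapse = ", "))
  cnt <- function(a) sum(s == a)
  peptide_descriptor(n_residues = length(s), n_prolines = cnt("P"),
                     abs_net_charge = abs((cnt("K") + cnt("R")) -
                                            (cnt("D") + cnt("E"))),
                     has_his_tag = has_his_tag)
}

#' Coefficients of the disordered-chain hydrodynamic-radius scaling law
#'
#' Defaults are the published coefficients of the Marsh--Forman-Kay
#' relation for intrinsically disordered proteins:
#' `Rh = (A*Ppro + B) * (C*|Q| + D) * S_His * R0 * N^nu` (Angstrom).
#'
#' @param A,B proline-fraction coefficients.
#' @param C,D net-charge coefficients.
#' @param S_His His-tag factor (1 for constructs without a tag).
#' @param R0 prefactor in Angstrom.
#' @param nu Flory-like scaling exponent.
#' @return list of class `rh_constants`.
#' @export
rh_constants <- function(A = 1.24, B = 0.904, C = 0.00759, D = 0.963,
                         S_His = 1, R0 = 2.49, nu = 0.509) {
  vals <- c(A, B, C, D, S_His, R0, nu)
  if (any(vals <= 0)) stop("all coefficients must be positive")
  structure(list(A = A, B = B, C = C, D = D, S_His = S_His, R0 = R0,
                 nu = nu), class = "rh_constants")
}

#' Predicted hydrodynamic radius of a disordered peptide
#'
#' @param descriptor a [peptide_descriptor()].
#' @param constants an [rh_constants()].
#' @return Rh in Angstrom.
#' @export
idp_hydrodynamic_radius <- function(descriptor, constants = rh_constants()) {
  stopifnot(inherits(descriptor, "peptide_descriptor"),
            inherits(constants, "rh_constants"))
  s_his <- if (descriptor$has_his_tag) constants$S_His else 1
  with(constants,
       (A * descriptor$p_pro + B) * (C * descriptor$abs_net_charge + D) *
         s_his * R0 * descriptor$n_residues^nu)
}

#' Membrane footprint of one molecule
#'
#' The area occupied on the membrane by a single molecule of
#' hydrodynamic radius Rh, `pi * Rh^2`, converted to um2.
#'
#' @param rh_angstrom hydrodynamic radius in Angstrom.
#' @return footprint area in um2 (1 A2 = 1e-8 um2).
#' @export
footprint_area <- function(rh_angstrom) {
  stopifnot(rh_angstrom >= 0)
  pi * rh_angstrom^2 * 1e-8
}

#' Fractional membrane area covered by a bound species
#'
#' @param density surface density in molecules per um2.
#' @param footprint per-molecule footprint in um2.
#' @param crowding_threshold coverage above which steric crowding alone
#'   can bend membranes (default 0.20).
#' @return list with `fraction`, `percent` and
#'   `above_crowding_threshold`.
#' @export
area_coverage <- function(density, footprint, crowding_threshold = 0.20) {
  stopifnot(density >= 0, footprint >= 0)
  f <- density * footprint
  list(fraction = f, percent = 100 * f,
       above_crowding_threshold = f >= crowding_threshold)
}
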