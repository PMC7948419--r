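test_that("calibration fit is exact on an exact line and errors otherwise", {
  s <- make_calibration_series(noise_cv = 0)
  cal <- fit_calibration(s)
  expect_equal(cal$slope, 201334)
  expect_equal(cal$slope_se, 0)
  expect_error(fit_calibration(data.frame(mol_percent = c(0.5, 0.5),
                                          intensity = c(1, 2))),
               "distinct")
  zero <- data.frame(mol_percent = c(0.1, 0.5), intensity = c(0, 0))
  expect_equal(fit_calibration(zero)$slope, 0)
})

test_that("noisy calibration recovers the true slope within 3 SE", {
  s <- make_calibration_series(noise_cv = 0.1, n_guvs_per_level = 10,
                               seed = 21L)
  cal <- fit_calibration(s)
  expect_lt(abs(cal$slope - 201334), 3 * cal$slope_se)
})

test_that("conversion factor follows the leaflet lipid count", {
  m <- calibration_model(slope = 14286, headgroup_area_nm2 = 0.7)
  expect_equal(conversion_factor(m)$k, 14286 * 0.7 / 1e4)
  expect_equal(conversion_factor(m)$k, 1.00002, tolerance = 1e-4)
  mb <- calibration_model(slope = 14286, headgroup_area_nm2 = 0.7,
                          leaflet_mode = "both")
  expect_equal(conversion_factor(mb)$k, conversion_factor(m)$k / 2)
})

test_that("brightness ratio rescales the conversion factor", {
  k <- conversion_factor(calibration_model(201334, 14039))
  expect_equal(target_dye_factor(k, 1)$k, k$k)
  expect_equal(target_dye_factor(k, 0.5)$k, k$k / 2)
  expect_equal(target_dye_factor(k, 2)$k_se, 2 * k$k_se)
})

test_that("density conversion handles edges and errors", {
  expect_equal(labeled_species_density(0, 0, 28, 0.5)$density_mean, 0)
  expect_equal(labeled_species_density(28, 0, 28, 1)$density_mean, 1)
  expect_error(labeled_species_density(100, 0, 28, 0), "efficiency")
})

test_that("sequence-derived descriptors count composition correctly", {
  d <- descriptor_from_sequence("KKRDE")
  expect_equal(d$n_residues, 5)
  expect_equal(d$p_pro, 0)
  expect_equal(d$abs_net_charge, 1)
  d2 <- descriptor_from_sequence("PPAP")
  expect_equal(d2$n_prolines, 3)
  expect_equal(d2$p_pro, 0.75)
  expect_error(descriptor_from_sequence("KXZ"), "X")
})

test_that("hydrodynamic radius formula matches direct arithmetic", {
  d1 <- peptide_descriptor(n_residues = 1, p_pro = 0, abs_net_charge = 0)
  expect_equal(idp_hydrodynamic_radius(d1), 0.904 * 0.963 * 2.49,
               tolerance = 1e-12)
  # strictly increasing in N, Ppro and |Q|
  base <- peptide_descriptor(n_residues = 80, p_pro = 0.2,
                             abs_net_charge = 13)
  rh0 <- idp_hydrodynamic_radius(base)
  expect_gt(idp_hydrodynamic_radius(
    peptide_descriptor(81, p_pro = 0.2, abs_net_charge = 13)), rh0)
  expect_gt(idp_hydrodynamic_radius(
    peptide_descriptor(80, p_pro = 0.25, abs_net_charge = 13)), rh0)
  expect_gt(idp_hydrodynamic_radius(
    peptide_descriptor(80, p_pro = 0.2, abs_net_charge = 14)), rh0)
})

test_that("footprint geometry behaves like pi r^2", {
  expect_equal(footprint_area(0), 0)
  expect_equal(footprint_area(2) / footprint_area(1), 4)
})

test_that("coverage is linear and flags the crowding threshold", {
  expect_equal(area_coverage(0, 1)$fraction, 0)
  cov <- area_coverage(1400, 2.52e-5)
  expect_false(cov$above_crowding_threshold)
  expect_true(area_coverage(1e4, 2.52e-5)$above_crowding_threshold)
})

test_that("density chain round-trips a known surface density", {
  # synthesize an intensity from a known density, then invert the chain;
  # the error should sit within twice the propagated slope SE for the
  # bulk of noise realizations
  slope_true <- 201334
  dens_true <- 1400
  e <- 0.5
  k_true <- target_dye_factor(
    conversion_factor(calibration_model(slope_true)), 2)$k
  within <- vapply(31:35, function(seed) {
    s <- make_calibration_series(slope_true = slope_true, noise_cv = 0.1,
                                 seed = seed)
    cal <- fit_calibration(s)
    k_dye <- target_dye_factor(
      conversion_factor(calibration_model(cal$slope, cal$slope_se)), 2)
    est <- labeled_species_density(dens_true * k_true * e, 0, k_dye, e)
    rel_se <- cal$slope_se / cal$slope
    abs(est$density_mean - dens_true) < 2 * rel_se * dens_true
  }, logical(1))
  expect_gte(sum(within), 4)
})
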