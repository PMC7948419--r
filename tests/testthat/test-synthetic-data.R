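test_that("zero-signal scene renders a constant background", {
  tr <- default_guv_truth(membrane_intensity = c(A488 = 0))
  sc <- make_guv_image(tr)
  expect_true(all(get_channel(sc$image, "A488") == 50))
})

test_that("noiseless ring peaks at background + membrane intensity", {
  tr <- scene_ground_truth(guv_center = c(12.8, 12.8), guv_radius = 10,
                           membrane_intensity = c(A488 = 1000),
                           background = 50, ring_width_sigma = 0.3,
                           psf_sigma = 0.15)
  sc <- make_guv_image(tr, c(256L, 256L), 0.1)
  m <- get_channel(sc$image, "A488")
  # brightest pixel along the horizontal ray through the center
  ray <- m[129, 129:256]
  expect_lt(abs(max(ray) - 1050) / 1050, 0.01)
  # analytic profile peaks exactly at the ring radius
  expect_equal(guv_radial_profile(tr, 10, "A488"), 1050)
})

test_that("generators are bit-identical for identical seed and parameters", {
  tr <- default_guv_truth(noise = noise_model("poisson", gain = 1), seed = 42L)
  expect_identical(make_guv_image(tr)$image$channels,
                   make_guv_image(tr)$image$channels)
  s1 <- make_frap_stack(0.7, 4, noise_cv = 0.03, seed = 9L)
  s2 <- make_frap_stack(0.7, 4, noise_cv = 0.03, seed = 9L)
  expect_identical(s1$stack, s2$stack)
  expect_identical(make_calibration_series(seed = 5L),
                   make_calibration_series(seed = 5L))
  sc1 <- random_tubule_scene(seed = 3L)
  sc2 <- random_tubule_scene(seed = 3L)
  expect_identical(make_tubule_micrograph(sc1)$image,
                   make_tubule_micrograph(sc2)$image)
})

test_that("a ring that does not fit in the frame is rejected by name", {
  tr <- default_guv_truth()
  expect_error(make_guv_image(tr, c(64L, 128L), 0.1), "margin")
})

test_that("tether ground truth defines the sorting coefficient", {
  sc <- make_tether_scene(default_tether_truth(c(A594 = 1, DiD = 1)))
  expect_equal(unname(sc$truth$sorting_truth), c(1, 1))
  sc2 <- make_tether_scene(default_tether_truth(c(A594 = 3, DiD = 1)))
  expect_equal(sc2$truth$sorting_truth[["A594"]], 3)
  # lipid-channel enrichment must be present
  tr <- default_tether_truth(c(A594 = 3, DiD = 1))
  tr$lipid_channel <- "missing"
  expect_error(make_tether_scene(tr), "lipid channel")
})

test_that("FRAP stack follows the closed-form recovery", {
  # immobile: post-bleach trace flat at the bleach floor
  st <- make_frap_stack(0, 5, bleach_depth = 0.7)
  bmeans <- apply(st$stack, 3, function(f)
    mean(roi_pixels(f, st$truth$bleach_roi)))
  post <- st$truth$bleach_frame:length(st$times)
  expect_true(all(abs(bmeans[post] - st$truth$bleach_floor) < 1e-9))
  # fully mobile: half-recovery at tau * ln 2 after the bleach
  st2 <- make_frap_stack(1, 5, frame_interval = 5 * log(2) / 4,
                         bleach_depth = 0.7)
  t_half <- st2$times[st2$truth$bleach_frame] + 5 * log(2)
  k <- which.min(abs(st2$times - t_half))
  v <- mean(roi_pixels(st2$stack[, , k], st2$truth$bleach_roi))
  midpoint <- (st2$truth$prebleach_intensity + st2$truth$bleach_floor) / 2
  expect_equal(v, midpoint, tolerance = 1e-6)
  expect_error(make_frap_stack(1.2, 5), "mobile_fraction")
})

test_that("calibration series is exact without noise", {
  s <- make_calibration_series(noise_cv = 0)
  expect_equal(s$intensity, 201334 * s$mol_percent)
  s2 <- make_calibration_series(mol_percents = 0.5, slope_true = 201334,
                                n_guvs_per_level = 1, noise_cv = 0)
  expect_equal(s2$intensity, 100667)
})

test_that("tubule scene arithmetic and rendering ground truth", {
  ves <- data.frame(x_um = seq(0.3, 3, length.out = 13),
                    y_um = 0.3, radius_um = 0.1)
  tubs <- replicate(7, list(path = rbind(c(0.5, 1), c(1.1, 1)),
                            diameter_nm = 50), simplify = FALSE)
  tr <- tubule_scene_truth(ves, tubs, pixel_size_nm = 5)
  expect_equal(truth_tubulation_fraction(tr), 35)
  tr0 <- tubule_scene_truth(ves, list(), pixel_size_nm = 5)
  expect_equal(truth_tubulation_fraction(tr0), 0)
  expect_error(
    tubule_scene_truth(ves, list(list(path = rbind(c(0, 0), c(0.04, 0)),
                                      diameter_nm = 50))),
    "diameter")
})

test_that("noiseless generator matches its analytic profile at the ring", {
  for (rho in c(2, 5, 8)) {
    tr <- scene_ground_truth(guv_center = c(10, 10), guv_radius = rho,
                             membrane_intensity = c(A488 = 800),
                             background = 40)
    sc <- make_guv_image(tr, c(200L, 200L), 0.1)
    m <- get_channel(sc$image, "A488")
    # pixel exactly on the ring along +x
    j <- round(100 + rho / 0.1) + 1L
    expect_lt(abs(m[101, j] - guv_radial_profile(tr, rho)) / 800, 0.01)
  }
})
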