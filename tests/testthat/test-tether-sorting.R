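test_that("tether ROI mean subtracts the supplied background", {
  m <- matrix(7, 32, 32)
  img <- multichannel_image(list(A = m), 0.1)
  expect_equal(measure_tether_intensity(img, "A", roi(2, 2, 10, 6)), 7)
  expect_equal(measure_tether_intensity(img, "A", roi(2, 2, 10, 6),
                                        background = 7), 0)
})

test_that("tether ROI intensity matches the rendered line profile", {
  sc <- make_tether_scene(default_tether_truth(c(A594 = 3, DiD = 1)))
  truth <- sc$truth
  est <- detect_guv_contour(sc$image, "A594")
  rr <- roi(round(est$center[1] + est$radius + 10), round(est$center[2] - 2),
            round(est$center[1] + est$radius + 60), round(est$center[2] + 2))
  for (cc in c("A594", "DiD")) {
    got <- measure_tether_intensity(sc$image, cc, rr,
                                    background = truth$background)
    # width-weighted expectation from the analytic Gaussian cross-section
    rows <- (rr[2]:rr[4])
    d <- abs(rows - truth$guv_center[2] / 0.1)
    expected <- mean(truth$tether_amplitude[[cc]] *
                       exp(-d^2 / (2 * truth$tether_sigma_px^2)))
    expect_lt(abs(got - expected) / expected, 0.02)
  }
})

test_that("ROI overlapping the GUV body is flagged", {
  sc <- make_tether_scene(default_tether_truth())
  est <- detect_guv_contour(sc$image, "A594")
  fit <- fit_gaussian_ring(sc$image, "A594", est,
                           excluded_sectors = list(c(-15, 15)))
  expect_warning(
    v <- measure_tether_intensity(sc$image, "A594",
                                  roi(60, 75, 90, 85), guv_fit = fit),
    "overlaps")
  expect_equal(attr(v, "roi_warning"), "roi overlaps GUV disk")
})

test_that("sorting coefficient definition, symmetry and gain invariance", {
  m <- tether_measurement(c(P = 200, L = 100), c(P = 100, L = 100), "L")
  s <- sorting_coefficient(m, "P")
  expect_equal(s$sorting_coefficient[["P"]], 2)
  expect_equal(s$sorting_coefficient[["L"]], 1)
  # all equal -> no sorting
  m1 <- tether_measurement(c(P = 5, L = 5), c(P = 5, L = 5), "L")
  expect_equal(sorting_coefficient(m1)$sorting_coefficient[["P"]], 1)
  # swapping protein and lipid roles inverts S
  m2 <- tether_measurement(c(P = 200, L = 100), c(P = 100, L = 100), "P")
  expect_equal(sorting_coefficient(m2)$sorting_coefficient[["L"]], 0.5)
  # independent per-channel gains cancel
  g <- c(P = 3.7, L = 0.2)
  m3 <- tether_measurement(c(P = 200, L = 100) * g,
                           c(P = 100, L = 100) * g, "L")
  expect_equal(sorting_coefficient(m3)$sorting_coefficient[["P"]], 2,
               tolerance = 1e-12)
  # zero denominators are named
  m4 <- tether_measurement(c(P = 1, L = 1), c(P = 0, L = 1), "L")
  expect_error(sorting_coefficient(m4), "channel 'P'")
})

test_that("end-to-end sorting recovers the enrichment ratio", {
  sc <- make_tether_scene(default_tether_truth(c(A594 = 3, DiD = 1)))
  s <- measure_scene_sorting(sc)
  expect_lt(abs(s$sorting_coefficient[["A594"]] - 3), 0.1)
  expect_equal(s$sorting_coefficient[["DiD"]], 1)
})

test_that("membrane tension formula, units and limits", {
  expect_equal(membrane_tension(100, 2.5, 10), 100 * 2.5e-6 / (2 * 0.75) * 1e3)
  expect_equal(membrane_tension(100, 2.5, 10), 0.1667, tolerance = 1e-3)
  expect_equal(membrane_tension(0, 2.5, 10), 0)
  expect_error(membrane_tension(100, 10, 10), "smaller")
  # monotone in pressure and in Rp/Rv
  expect_gt(membrane_tension(200, 2.5, 10), membrane_tension(100, 2.5, 10))
  expect_gt(membrane_tension(100, 3, 10), membrane_tension(100, 2.5, 10))
  # large-vesicle limit: T -> dP * Rp / 2
  t_lim <- membrane_tension(100, 2.5, 2.5e4)
  expect_lt(abs(t_lim - 100 * 2.5 * 1e-3 / 2) / t_lim, 0.002)
})

test_that("typical aspiration settings fall in the usual tension band", {
  # ~0.1 mN/m order of magnitude for common pipette/GUV geometries
  t1 <- membrane_tension(30, 3, 10)
  t2 <- membrane_tension(60, 2.5, 8)
  expect_true(all(c(t1, t2) > 0.01 & c(t1, t2) < 1))
})
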