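empty_vesicles <- data.frame(x_um = numeric(0), y_um = numeric(0),
                             radius_um = numeric(0))

test_that("blank image segments to zero objects", {
  seg <- segment_objects(matrix(200, 64, 64), 5)
  expect_equal(seg$n_objects, 0)
  expect_equal(nrow(measure_all_objects(seg)), 0)
})

test_that("noiseless micrograph yields one label per object", {
  sc <- random_tubule_scene(n_vesicles = 12, n_tubules = 8,
                            tubule_length_um = c(0.2, 0.6), seed = 2L)
  seg <- segment_objects(make_tubule_micrograph(sc)$image, 5)
  expect_equal(seg$n_objects, 20)
})

test_that("segmentation survives 5% Gaussian noise", {
  sc <- random_tubule_scene(n_vesicles = 12, n_tubules = 8,
                            tubule_length_um = c(0.2, 0.6),
                            noise = noise_model("gaussian", sigma = 7.5),
                            seed = 4L)
  seg <- segment_objects(make_tubule_micrograph(sc)$image, 5)
  expect_gte(seg$n_objects, 19)  # >= 95% of 20 objects
})

test_that("straight-tubule geometry oracle: length and diameter", {
  u <- c(cos(pi / 6), sin(pi / 6))
  tr <- tubule_scene_truth(empty_vesicles,
                           list(list(path = rbind(c(0.3, 0.3),
                                                  c(0.3, 0.3) + u),
                                     diameter_nm = 50)),
                           pixel_size_nm = 5)
  rec <- measure_all_objects(segment_objects(make_tubule_micrograph(tr)$image,
                                             5))
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$length_um - 1) / 1, 0.1)
  expect_lt(abs(rec$diameter_nm - 50) / 50, 0.1)
  expect_equal(rec$classification, "tubulated")
})

test_that("curved tubule geodesic length matches the arc length", {
  th <- seq(0, pi / 2, length.out = 40)
  path <- cbind(0.3 + 0.5 * cos(th), 0.3 + 0.5 * sin(th))
  tr <- tubule_scene_truth(empty_vesicles,
                           list(list(path = path, diameter_nm = 60)),
                           pixel_size_nm = 5)
  rec <- measure_all_objects(segment_objects(make_tubule_micrograph(tr)$image,
                                             5))
  arc <- pi / 2 * 0.5
  expect_lt(abs(rec$length_um - arc) / arc, 0.1)
})

test_that("a filled disk is classified intact with aspect near 1", {
  tr <- tubule_scene_truth(data.frame(x_um = 0.5, y_um = 0.5,
                                      radius_um = 0.15),
                           list(), pixel_size_nm = 5)
  rec <- measure_all_objects(segment_objects(make_tubule_micrograph(tr)$image,
                                             5))
  expect_equal(rec$classification, "intact")
  expect_lt(rec$aspect, 1.5)
})

test_that("classification is monotone in the aspect threshold", {
  sc <- random_tubule_scene(n_vesicles = 5, n_tubules = 5,
                            tubule_length_um = c(0.2, 0.6), seed = 6L)
  seg <- segment_objects(make_tubule_micrograph(sc)$image, 5)
  n_tub <- vapply(c(1.5, 3, 6, 20), function(thr)
    sum(measure_all_objects(seg, aspect_threshold = thr)$classification ==
          "tubulated"), numeric(1))
  expect_true(all(diff(n_tub) <= 0))
})

test_that("length and diameter are stable under pixel-size halving", {
  u <- c(cos(0.4), sin(0.4))
  mk <- function(px) {
    tr <- tubule_scene_truth(empty_vesicles,
                             list(list(path = rbind(c(0.3, 0.3),
                                                    c(0.3, 0.3) + 0.8 * u),
                                       diameter_nm = 60)),
                             pixel_size_nm = px)
    measure_all_objects(segment_objects(make_tubule_micrograph(tr)$image, px))
  }
  r5 <- mk(5); r2.5 <- mk(2.5)
  expect_lt(abs(r5$length_um - r2.5$length_um) / r2.5$length_um, 0.05)
  expect_lt(abs(r5$diameter_nm - r2.5$diameter_nm) / r2.5$diameter_nm, 0.05)
})

test_that("border-touching objects are flagged and excluded from summaries", {
  tr <- tubule_scene_truth(data.frame(x_um = c(0.02, 0.5),
                                      y_um = c(0.02, 0.5),
                                      radius_um = c(0.1, 0.1)),
                           list(), pixel_size_nm = 5)
  img <- make_tubule_micrograph(tr, image_shape = c(130L, 130L))$image
  rec <- measure_all_objects(segment_objects(img, 5))
  expect_true(any(rec$border))
  sm <- summarize_morphometry(rec)
  expect_equal(sm$n_intact + sm$n_tubulated, sum(!rec$border))
})

test_that("summaries aggregate per group like trial-wise statistics", {
  rec <- data.frame(label = 1:20,
                    cx_px = 0, cy_px = 0,
                    length_um = 1, diameter_nm = 50, aspect = 5,
                    classification = rep(c("tubulated", "intact"),
                                         c(7, 13)),
                    border = FALSE, area_px = 100)
  sm <- summarize_morphometry(rec)
  expect_equal(sm$tubulated_percent, 35)
  # groups with 30/35/40% tubulation
  mk_group <- function(n_tub, n_tot) rep(c("tubulated", "intact"),
                                         c(n_tub, n_tot - n_tub))
  cls <- c(mk_group(6, 20), mk_group(7, 20), mk_group(8, 20))
  rec2 <- data.frame(label = seq_along(cls), cx_px = 0, cy_px = 0,
                     length_um = 1, diameter_nm = 50, aspect = 5,
                     classification = cls, border = FALSE, area_px = 100)
  grp <- rep(1:3, each = 20)
  sm2 <- summarize_morphometry(rec2, group = grp)
  expect_equal(sm2$percent_mean, 35)
  expect_equal(sm2$percent_sd, 5)
  # empty input stays defined
  sm0 <- summarize_morphometry(rec2[0, ], group = integer(0))
  expect_equal(sm0$n_intact + sm0$n_tubulated, 0)
})
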