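# Shared fixture builders for the test suite. Everything is generated in
# code; no image files ship with the package.

default_guv_truth <- function(...) {
  args <- utils::modifyList(
    list(guv_center = c(6.4, 6.4), guv_radius = 4,
         membrane_intensity = c(A488 = 1000), background = 50,
         ring_width_sigma = 0.3, psf_sigma = 0.15,
         noise = noise_model("none"), seed = 1L),
    list(...))
  do.call(scene_ground_truth, args)
}

fit_default_scene <- function(truth, shape = c(128L, 128L), ...) {
  sc <- make_guv_image(truth, shape, 0.1)
  est <- detect_guv_contour(sc$image, names(truth$membrane_intensity)[1])
  fit_gaussian_ring(sc$image, names(truth$membrane_intensity)[1], est, ...)
}

default_tether_truth <- function(enrichment = c(A594 = 3, DiD = 1),
                                 noise = noise_model("none"), seed = 1L) {
  scene_ground_truth(guv_center = c(7, 8), guv_radius = 4,
                     membrane_intensity = stats::setNames(
                       rep(1000, length(enrichment)), names(enrichment)),
                     background = 50, ring_width_sigma = 0.3,
                     psf_sigma = 0.15, noise = noise, seed = seed,
                     tether_enrichment = enrichment, tether_angle = 0,
                     lipid_channel = "DiD")
}

# Measure sorting on a rendered tether scene, excluding the attachment
# sector from the ring fit, with the truth background subtracted from the
# tether ROI.
measure_scene_sorting <- function(scene) {
  truth <- scene$truth
  ch <- names(truth$membrane_intensity)
  est <- detect_guv_contour(scene$image, ch[1])
  excl <- list(c(truth$tether_angle - 15, truth$tether_angle + 15))
  i_guv <- vapply(ch, function(cc)
    fit_gaussian_ring(scene$image, cc, est,
                      excluded_sectors = excl)$membrane_intensity,
    numeric(1))
  rr <- roi(round(est$center[1] + est$radius + 10),
            round(est$center[2] - 2),
            round(est$center[1] + est$radius + 60),
            round(est$center[2] + 2))
  i_tet <- vapply(ch, function(cc)
    measure_tether_intensity(scene$image, cc, rr,
                             background = truth$background), numeric(1))
  sorting_coefficient(tether_measurement(i_tet, i_guv,
                                         truth$lipid_channel))
}

bare_ring_fit <- function(amplitudes, sigma = 2) {
  n <- length(amplitudes)
  structure(list(amplitudes = amplitudes, included = rep(TRUE, n),
                 sigma = sigma, summary = "amplitude"),
            class = "ring_fit")
}
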