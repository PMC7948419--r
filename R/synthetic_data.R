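#' Noise model descriptor
#'
#' @param type `"none"`, `"gaussian"` (additive, absolute `sigma`), or
#'   `"poisson"` (shot noise with `gain` photons per intensity unit:
#'   pixel value is `rpois(gain * I) / gain`).
#' @param sigma Gaussian standard deviation in intensity units.
#' @param gain Poisson gain in photons per intensity unit.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(type = c("none", "gaussian", "poisson"),
                        sigma = NULL, gain = NULL) {
  type <- match.arg(type)
  if (type == "gaussian" && (is.null(sigma) || sigma < 0))
    stop("gaussian noise requires sigma >= 0")
  if (type == "poisson" && (is.null(gain) || gain <= 0))
    stop("poisson noise requires gain > 0")
  structure(list(type = type, sigma = sigma, gain = gain),
            class = "noise_model")
}

apply_noise <- function(mat, noise) {
  switch(noise$type,
    none = mat,
    gaussian = mat + stats::rnorm(length(mat), 0, noise$sigma),
    poisson = {
      lam <- pmax(mat, 0) * noise$gain
      matrix(stats::rpois(length(mat), lam) / noise$gain,
             nrow(mat), ncol(mat))
    })
}

#' Ground truth for a synthetic GUV scene
#'
#' Describes an equatorial confocal section of a giant unilamellar
#' vesicle: a bright membrane ring over a dark background, blurred by the
#' microscope point spread function.  All lengths are in micrometres.
#'
#' @param guv_center `(x, y)` of the vesicle center in um.
#' @param guv_radius vesicle radius in um.
#' @param membrane_intensity named vector, peak ring intensity (a.u.) per
#'   channel.
#' @param background camera background level (a.u.), shared by channels.
#' @param ring_width_sigma intrinsic radial Gaussian width of the
#'   membrane ring in um (models undulation/defocus broadening; the
#'   bilayer itself is unresolvable).
#' @param psf_sigma isotropic Gaussian PSF width in um.
#' @param noise a [noise_model()].
#' @param seed integer seed consumed by the noise draw; the same seed and
#'   parameters give a bit-identical image.
#' @param tether_present logical, whether a membrane tether is attached.
#' @param tether_enrichment named vector of tether/GUV enrichment ratios
#'   per channel (dimensionless, > 0).
#' @param tether_angle attachment angle in degrees (0 = +x, increasing
#'   clockwise on screen).
#' @param lipid_channel name of the reference lipid-dye channel.
#' @return list of class `scene_ground_truth`.
#' @export
scene_ground_truth <- function(guv_center = c(6.4, 6.4), guv_radius = 4,
                               membrane_intensity = c(A488 = 1000),
                               background = 50, ring_width_sigma = 0.1,
                               psf_sigma = 0.15,
                               noise = noise_model("none"), seed = 1L,
                               tether_present = FALSE,
                               tether_enrichment = NULL,
                               tether_angle = 0,
                               lipid_channel = NULL) {
  stopifnot(length(guv_center) == 2L, guv_radius > 0,
            all(membrane_intensity >= 0), background >= 0,
            ring_width_sigma > 0, psf_sigma >= 0)
  if (is.null(names(membrane_intensity)))
    stop("'membrane_intensity' must be a named per-channel vector")
  if (!is.null(tether_enrichment) && any(tether_enrichment <= 0))
    stop("tether enrichment ratios must be > 0")
  structure(list(guv_center = guv_center, guv_radius = guv_radius,
                 membrane_intensity = membrane_intensity,
                 background = background,
                 ring_width_sigma = ring_width_sigma,
                 psf_sigma = psf_sigma, noise = noise,
                 seed = as.integer(seed),
                 tether_present = isTRUE(tether_present),
                 tether_enrichment = tether_enrichment,
                 tether_angle = tether_angle,
                 lipid_channel = lipid_channel),
            class = "scene_ground_truth")
}

# Effective radial Gaussian width: intrinsic ring width and PSF combine
# in quadrature for an equatorial section.
effective_ring_sigma <- function(truth) {
  sqrt(truth$ring_width_sigma^2 + truth$psf_sigma^2)
}

#' Analytic radial intensity profile of a synthetic GUV ring
#'
#' @param truth a [scene_ground_truth()].
#' @param r radial distance from the center in um.
#' @param channel channel name.
#' @return intensity in a.u. (background + Gaussian ring).
#' @export
guv_radial_profile <- function(truth, r, channel = NULL) {
  A <- if (is.null(channel)) truth$membrane_intensity[1] else
    truth$membrane_intensity[[channel]]
  se <- effective_ring_sigma(truth)
  truth$background + A * exp(-(r - truth$guv_radius)^2 / (2 * se^2))
}

guv_frame_check <- function(truth, image_shape, pixel_size, extra_um = 0) {
  ext <- truth$guv_radius + 3 * truth$psf_sigma + extra_um
  lim <- (rev(image_shape) - 1) * pixel_size  # (x_max, y_max) in um
  lo <- truth$guv_center - ext
  hi <- truth$guv_center + ext
  ax <- c("x", "y")
  for (k in 1:2) {
    if (lo[k] < 0)
      stop(sprintf("ring exceeds frame: %s margin %.2f um below 0",
                   ax[k], -lo[k]))
    if (hi[k] > lim[k])
      stop(sprintf("ring exceeds frame: %s margin %.2f um beyond %.2f um",
                   ax[k], hi[k] - lim[k], lim[k]))
  }
  invisible(TRUE)
}

#' Render a synthetic equatorial GUV image
#'
#' The noiseless image is `background + A * exp(-(r - rho)^2 / (2 s^2))`
#' with `s` the quadrature sum of ring width and PSF width, so the radial
#' peak equals the ground-truth membrane intensity.  Noise is applied
#' last under the ground-truth seed.
#'
#' @param truth a [scene_ground_truth()].
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @return list with elements `image` (an [multichannel_image()]) and
#'   `truth` (unchanged ground truth).
#' @export
make_guv_image <- function(truth, image_shape = c(128L, 128L),
                           pixel_size = 0.1) {
  guv_frame_check(truth, image_shape, pixel_size)
  base <- guv_ring_channels(truth, image_shape, pixel_size)
  chans <- with_seed(truth$seed, lapply(base, apply_noise, noise = truth$noise))
  list(image = multichannel_image(chans, pixel_size), truth = truth)
}

guv_ring_channels <- function(truth, image_shape, pixel_size) {
  nr <- image_shape[1]; nc <- image_shape[2]
  cx <- truth$guv_center[1] / pixel_size
  cy <- truth$guv_center[2] / pixel_size
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  r <- sqrt((xg - cx)^2 + (yg - cy)^2) * pixel_size
  se <- effective_ring_sigma(truth)
  ring <- exp(-(r - truth$guv_radius)^2 / (2 * se^2))
  lapply(as.list(truth$membrane_intensity), function(A)
    truth$background + A * ring)
}

#' Render a GUV with a membrane tether pulled from its surface
#'
#' A tether of the given length is attached at `truth$tether_angle`,
#' pointing radially outward.  Its cross-section is a Gaussian line whose
#' amplitude in channel c is
#' `tether_enrichment[c] * membrane_intensity[c] * tether_factor`, the
#' geometric factor being shared by all channels so that the ground-truth
#' sorting coefficient of channel c against the lipid channel is exactly
#' `enrichment[c] / enrichment[lipid]`.
#'
#' @inheritParams make_guv_image
#' @param tether_length tether length in um.
#' @param tether_width_px full width (FWHM) of the rendered tether line in
#'   pixels; diffraction-limited tethers are represented by this width,
#'   not by resolved structure.  Must be >= 1.
#' @param tether_factor shared geometric brightness factor of the tether
#'   relative to the equatorial ring.
#' @return list with `image` and `truth`; the truth gains fields
#'   `tether_amplitude`, `tether_sigma_px`, `tether_length` and
#'   `sorting_truth` (per-channel ground-truth sorting coefficients).
#' @export
make_tether_scene <- function(truth, tether_length = 8, tether_width_px = 3,
                              tether_factor = 0.5,
                              image_shape = c(160L, 224L), pixel_size = 0.1) {
  if (is.null(truth$tether_enrichment))
    stop("ground truth has no tether enrichment ratios")
  ch <- names(truth$membrane_intensity)
  if (!all(ch %in% names(truth$tether_enrichment)))
    stop("tether enrichment missing for channel(s): ",
         paste(setdiff(ch, names(truth$tether_enrichment)), collapse = ", "))
  if (is.null(truth$lipid_channel) ||
      !truth$lipid_channel %in% names(truth$tether_enrichment))
    stop("enrichment for the lipid channel is missing (lipid_channel = ",
         if (is.null(truth$lipid_channel)) "NULL" else truth$lipid_channel,
         ")")
  if (tether_width_px < 1) stop("tether_width_px must be >= 1")
  truth$tether_present <- TRUE
  guv_frame_check(truth, image_shape, pixel_size)

  nr <- image_shape[1]; nc <- image_shape[2]
  cx <- truth$guv_center[1] / pixel_size
  cy <- truth$guv_center[2] / pixel_size
  th <- truth$tether_angle * pi / 180
  u <- c(cos(th), sin(th))
  p0 <- c(cx, cy) + (truth$guv_radius / pixel_size) * u
  p1 <- p0 + (tether_length / pixel_size) * u
  if (any(p1 < 0) || p1[1] > nc - 1 || p1[2] > nr - 1)
    stop("tether end exceeds frame")
  sig_t <- tether_width_px / (2 * sqrt(2 * log(2)))  # FWHM -> sigma

  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  # distance of each pixel to the tether segment
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  tpar <- pmin(pmax(((xg - p0[1]) * vx + (yg - p0[2]) * vy) / len2, 0), 1)
  d <- sqrt((xg - (p0[1] + tpar * vx))^2 + (yg - (p0[2] + tpar * vy))^2)
  tprof <- exp(-d^2 / (2 * sig_t^2))

  base <- guv_ring_channels(truth, image_shape, pixel_size)
  amp <- truth$tether_enrichment[ch] * truth$membrane_intensity[ch] *
    tether_factor
  for (i in seq_along(ch))
    base[[i]] <- base[[i]] + amp[[i]] * tprof
  chans <- with_seed(truth$seed, lapply(base, apply_noise, noise = truth$noise))

  truth$tether_amplitude <- amp
  truth$tether_sigma_px <- sig_t
  truth$tether_length <- tether_length
  truth$sorting_truth <- truth$tether_enrichment[ch] /
    truth$tether_enrichment[[truth$lipid_channel]]
  list(image = multichannel_image(chans, pixel_size), truth = truth)
}

#' Synthesize a FRAP bleach/recovery image stack
#'
#' The bleached-ROI mean follows
#' `I(t) = I_inf - (I_inf - I0) * exp(-(t - t_bleach)/tau)` with
#' `I_inf = I0 + mobile_fraction * (I_pre - I0)`; a disjoint reference
#' region stays at the pre-bleach level throughout.
#'
#' @param mobile_fraction recoverable fraction of bleached signal, 0-1.
#' @param tau recovery time constant in seconds.
#' @param n_prebleach,n_recovery number of frames before/after the bleach.
#' @param frame_interval seconds between frames (default 2.6 s, a typical
#'   confocal capture speed for GUV FRAP).
#' @param bleach_depth fraction of signal removed by the bleach pulse
#'   (1 = bleached to zero).
#' @param prebleach_intensity pre-bleach intensity level (a.u.).
#' @param noise_cv per-pixel Gaussian noise as a fraction of the
#'   pre-bleach level.
#' @param seed RNG seed for the noise.
#' @param image_shape `(rows, cols)` of each frame.
#' @return list with `stack` (3D array `[row, col, frame]`), `times`
#'   (seconds), and `truth` (parameters plus `bleach_roi`,
#'   `reference_roi` and `bleach_frame`, the 1-based index of the first
#'   post-bleach frame).
#' @export
make_frap_stack <- function(mobile_fraction, tau, n_prebleach = 5L,
                            n_recovery = 30L, frame_interval = 2.6,
                            bleach_depth = 0.7, prebleach_intensity = 1000,
                            noise_cv = 0, seed = 1L,
                            image_shape = c(64L, 64L)) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must be in [0, 1]")
  stopifnot(tau > 0, n_prebleach >= 1, n_recovery >= 2, bleach_depth >= 0,
            bleach_depth <= 1)
  n <- n_prebleach + n_recovery
  times <- (seq_len(n) - 1) * frame_interval
  bleach_frame <- n_prebleach + 1L
  ipre <- prebleach_intensity
  i0 <- (1 - bleach_depth) * ipre
  iinf <- i0 + mobile_fraction * (ipre - i0)
  nr <- image_shape[1]; nc <- image_shape[2]
  b_roi <- roi(floor(nc * 0.56), floor(nr * 0.3),
               floor(nc * 0.9), floor(nr * 0.7))
  r_roi <- roi(floor(nc * 0.08), floor(nr * 0.3),
               floor(nc * 0.42), floor(nr * 0.7))
  stack <- array(ipre, c(nr, nc, n))
  for (k in bleach_frame:n) {
    t_rel <- times[k] - times[bleach_frame]
    v <- iinf - (iinf - i0) * exp(-t_rel / tau)
    stack[(b_roi[2] + 1):(b_roi[4] + 1), (b_roi[1] + 1):(b_roi[3] + 1), k] <- v
  }
  if (noise_cv > 0)
    stack <- with_seed(seed, stack +
      array(stats::rnorm(length(stack), 0, noise_cv * ipre), dim(stack)))
  truth <- list(mobile_fraction = mobile_fraction, tau = tau,
                prebleach_intensity = ipre, bleach_floor = i0,
                plateau = iinf, bleach_frame = bleach_frame,
                bleach_roi = b_roi, reference_roi = r_roi,
                frame_interval = frame_interval, noise_cv = noise_cv,
                seed = as.integer(seed))
  list(stack = stack, times = times, truth = truth)
}

#' Synthesize an intensity-vs-mol% calibration series
#'
#' Emulates imaging GUVs doped with increasing mol% of a calibration
#' lipid dye under fixed instrument settings: expected intensity is
#' `slope_true * mol_percent` with multiplicative Gaussian noise of the
#' stated coefficient of variation.
#'
#' @param mol_percents dye mole-percent levels (default 0.1-0.75, the
#'   usual calibration range).
#' @param slope_true true intensity per mol% (a.u.).
#' @param n_guvs_per_level replicate GUVs imaged at each level.
#' @param noise_cv GUV-to-GUV coefficient of variation.
#' @param seed RNG seed.
#' @return data.frame with columns `mol_percent`, `intensity`,
#'   `replicate`.
#' @export
make_calibration_series <- function(mol_percents = c(0.1, 0.25, 0.4, 0.5, 0.75),
                                    slope_true = 201334,
                                    n_guvs_per_level = 10L, noise_cv = 0.1,
                                    seed = 1L) {
  stopifnot(all(mol_percents > 0), slope_true >= 0, n_guvs_per_level >= 1,
            noise_cv >= 0)
  x <- rep(mol_percents, each = n_guvs_per_level)
  mult <- if (noise_cv > 0)
    with_seed(seed, 1 + stats::rnorm(length(x), 0, noise_cv)) else 1
  data.frame(mol_percent = x,
             intensity = slope_true * x * mult,
             replicate = rep(seq_len(n_guvs_per_level),
                             times = length(mol_percents)))
}

#' Ground truth for a synthetic vesicle/tubule micrograph
#'
#' @param vesicles data.frame with columns `x_um`, `y_um`, `radius_um`.
#' @param tubules list of records, each `list(path = matrix[n,2] of (x,y)
#'   um, diameter_nm = ...)`.
#' @param pixel_size_nm nm per pixel.
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @return list of class `tubule_scene_truth`.
#' @export
tubule_scene_truth <- function(vesicles, tubules, pixel_size_nm = 5,
                               noise = noise_model("none"), seed = 1L) {
  for (tb in tubules) {
    len_nm <- polyline_length(tb$path) * 1000
    if (tb$diameter_nm <= 0 || tb$diameter_nm >= len_nm)
      stop("tubule diameter must be > 0 and < its length")
  }
  structure(list(vesicles = vesicles, tubules = tubules,
                 pixel_size_nm = pixel_size_nm, noise = noise,
                 seed = as.integer(seed)),
            class = "tubule_scene_truth")
}

polyline_length <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

#' Ground-truth tubulation fraction of a micrograph scene
#'
#' @param truth a [tubule_scene_truth()].
#' @return percent of objects that are tubules, over vesicles + tubules.
#' @export
truth_tubulation_fraction <- function(truth) {
  nv <- nrow(truth$vesicles); nt <- length(truth$tubules)
  if (nv + nt == 0) return(NA_real_)
  100 * nt / (nv + nt)
}

#' Place random non-overlapping vesicles and tubules in a field
#'
#' Rejection-samples object positions so that bounding disks do not
#' overlap; tubules are straight segments with random orientation.
#'
#' @param n_vesicles,n_tubules object counts.
#' @param field_um side length of the square field in um.
#' @param vesicle_radius_um range of vesicle radii (um).
#' @param tubule_length_um range of tubule lengths (um).
#' @param tubule_diameter_nm range of tubule diameters (nm).
#' @param pixel_size_nm nm per pixel of the eventual render.
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @return a [tubule_scene_truth()].
#' @export
random_tubule_scene <- function(n_vesicles = 6L, n_tubules = 4L,
                                field_um = 3.2,
                                vesicle_radius_um = c(0.1, 0.2),
                                tubule_length_um = c(0.2, 1),
                                tubule_diameter_nm = c(40, 80),
                                pixel_size_nm = 5,
                                noise = noise_model("none"), seed = 1L) {
  with_seed(seed, {
    placed <- list()  # bounding disks: (x, y, r) um
    margin <- 0.05
    try_place <- function(r_bound) {
      for (i in 1:500) {
        p <- stats::runif(2, r_bound + margin, field_um - r_bound - margin)
        ok <- TRUE
        for (q in placed)
          if (sqrt(sum((p - q[1:2])^2)) < r_bound + q[3] + margin) {
            ok <- FALSE; break
          }
        if (ok) return(p)
      }
      stop("could not place object without overlap; reduce counts")
    }
    ves <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0))
    for (i in seq_len(n_vesicles)) {
      r <- stats::runif(1, vesicle_radius_um[1], vesicle_radius_um[2])
      p <- try_place(r)
      placed[[length(placed) + 1L]] <- c(p, r)
      ves[i, ] <- c(p, r)
    }
    tubs <- vector("list", n_tubules)
    for (i in seq_len(n_tubules)) {
      len <- stats::runif(1, tubule_length_um[1], tubule_length_um[2])
      dia <- stats::runif(1, tubule_diameter_nm[1], tubule_diameter_nm[2])
      rb <- len / 2 + dia / 2000
      p <- try_place(rb)
      th <- stats::runif(1, 0, pi)
      u <- c(cos(th), sin(th))
      tubs[[i]] <- list(path = rbind(p - u * len / 2, p + u * len / 2),
                        diameter_nm = dia)
      placed[[length(placed) + 1L]] <- c(p, rb)
    }
    tubule_scene_truth(ves, tubs, pixel_size_nm = pixel_size_nm,
                       noise = noise, seed = seed)
  })
}

#' Render a negative-stain-style micrograph of vesicles and tubules
#'
#' Vesicles are drawn as filled dark disks and tubules as constant-width
#' dark capsules (dilated segments) on a bright background, with
#' one-pixel edge anti-aliasing.  The ground-truth record remains
#' authoritative for all object properties.
#'
#' @param truth a [tubule_scene_truth()].
#' @param image_shape `(rows, cols)` px; default covers the scene at the
#'   truth's pixel size.
#' @param background,foreground grey levels of stain background and
#'   objects.
#' @return list with `image` (matrix) and `truth`.
#' @export
make_tubule_micrograph <- function(truth, image_shape = NULL,
                                   background = 200, foreground = 50) {
  px_um <- truth$pixel_size_nm / 1000  # um per pixel
  if (is.null(image_shape)) {
    ext <- 0
    if (nrow(truth$vesicles) > 0)
      ext <- max(ext, truth$vesicles$x_um + truth$vesicles$radius_um,
                 truth$vesicles$y_um + truth$vesicles$radius_um)
    for (tb in truth$tubules)
      ext <- max(ext, tb$path + tb$diameter_nm / 2000)
    n <- ceiling(ext / px_um) + 10L
    image_shape <- c(n, n)
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  img <- matrix(background, nr, nc)
  cover <- matrix(0, nr, nc)
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) * px_um
  yg <- matrix(0:(nr - 1), nr, nc) * px_um
  add_cover <- function(d_um, r_um) {
    # smooth 1-px edge: full inside, zero beyond r + 1 px
    c1 <- pmin(pmax((r_um - d_um) / px_um + 0.5, 0), 1)
    cover <<- pmax(cover, c1)
  }
  if (nrow(truth$vesicles) > 0)
    for (i in seq_len(nrow(truth$vesicles))) {
      v <- truth$vesicles[i, ]
      d <- sqrt((xg - v$x_um)^2 + (yg - v$y_um)^2)
      add_cover(d, v$radius_um)
    }
  for (tb in truth$tubules) {
    r_um <- tb$diameter_nm / 2000
    p <- tb$path
    for (s in seq_len(nrow(p) - 1)) {
      a <- p[s, ]; b <- p[s + 1, ]
      vx <- b[1] - a[1]; vy <- b[2] - a[2]
      l2 <- vx^2 + vy^2
      tpar <- pmin(pmax(((xg - a[1]) * vx + (yg - a[2]) * vy) / l2, 0), 1)
      d <- sqrt((xg - (a[1] + tpar * vx))^2 + (yg - (a[2] + tpar * vy))^2)
      add_cover(d, r_um)
    }
  }
  img <- background + (foreground - background) * cover
  img <- with_seed(truth$seed, apply_noise(img, truth$noise))
  list(image = img, truth = truth)
}
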