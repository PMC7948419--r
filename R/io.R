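#' Write a multichannel image as TIFF plus JSON sidecar
#'
#' Pages are ordered channel-major, then frame.  TIFF stores samples in
#' [0, 1], so intensities are divided by `scale` (recorded in the
#' sidecar) and quantized to the sample depth.  With the default
#' `scale = 65535` and 16-bit samples, integer-valued intensities in
#' [0, 65535] round-trip bit-exactly.
#'
#' @param image an [multichannel_image()].
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @param scale intensity value mapped to full sample range; default
#'   65535, or the next power of two above the data maximum when larger.
#' @param bits_per_sample 8, 16 or 32.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, scale = NULL, bits_per_sample = 16L) {
  stopifnot(inherits(image, "mc_image"))
  mx <- max(vapply(image$channels, max, numeric(1)))
  if (is.null(scale))
    scale <- if (mx <= 65535) 65535 else 2^ceiling(log2(mx))
  pages <- list()
  frames <- NA_integer_
  for (ch in names(image$channels)) {
    a <- image$channels[[ch]]
    if (length(dim(a)) == 3L) {
      frames <- dim(a)[3]
      for (k in seq_len(frames)) pages[[length(pages) + 1L]] <- a[, , k]
    } else {
      frames <- 1L
      pages[[length(pages) + 1L]] <- a
    }
  }
  pages <- lapply(pages, function(p) pmin(pmax(p / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits_per_sample))
  meta <- list(channels = names(image$channels),
               frames_per_channel = frames,
               pixel_size = image$pixel_size, pixel_unit = image$pixel_unit,
               times = image$times, scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel image written by [write_image()] (or a plain
#' TIFF/PNG)
#'
#' Pixel data are restored on their original intensity scale when a
#' sidecar is present and are otherwise returned as stored (8-bit PNGs as
#' 0-255 integers), never rescaled or guessed; pixel size comes from the
#' sidecar or the `pixel_size` argument only.
#'
#' @param path TIFF or PNG file.
#' @param channel_map named integer vector mapping channel labels to page
#'   indices, for TIFFs without a sidecar.
#' @param pixel_size pixel size override when no sidecar exists.
#' @return an [multichannel_image()].
#' @export
read_image <- function(path, channel_map = NULL, pixel_size = NULL) {
  side <- paste0(path, ".json")
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  if (is_png) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package")
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    pages <- list(m * 255)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
    else NULL
  if (!is.null(meta) && !is_png) {
    pages <- lapply(pages, function(p) p * meta$scale)
    fr <- meta$frames_per_channel
    chans <- list()
    for (i in seq_along(meta$channels)) {
      sel <- pages[((i - 1) * fr + 1):(i * fr)]
      chans[[meta$channels[i]]] <- if (fr == 1L) sel[[1]] else
        array(unlist(sel), c(dim(sel[[1]]), fr))
    }
    return(multichannel_image(chans, meta$pixel_size, meta$pixel_unit,
                              times = meta$times))
  }
  if (is.null(channel_map))
    channel_map <- stats::setNames(seq_along(pages),
                                   paste0("ch", seq_along(pages)))
  bad <- channel_map[channel_map > length(pages) | channel_map < 1]
  if (length(bad) > 0)
    stop("channel map points at page(s) ",
         paste(bad, collapse = ", "), " but the file has pages 1..",
         length(pages))
  chans <- lapply(channel_map, function(i) pages[[i]])
  multichannel_image(chans, pixel_size %||% 1, times = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a ground-truth record to JSON
#' @param truth a ground-truth list from a generator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Every parameter that affects a number in the outputs is echoed
#' verbatim into the run manifest; unknown keys are rejected.  A seed is
#' mandatory because all demonstration stages draw synthetic inputs.
#'
#' @param stages character subset of `c("ringfit", "density", "sorting",
#'   "frap", "tubules")`.
#' @param seed integer seed for every stochastic stage.
#' @param output_dir directory for result files (created if missing).
#' @param params named list of per-stage parameter overrides; allowed
#'   keys: `noise`, `brightness_ratio`, `labeling_efficiency`,
#'   `tether_enrichment`, `aspect_threshold`, `mobile_fraction`, `tau`,
#'   `n_micrographs`.
#' @return list of class `run_config`.
#' @export
run_config <- function(stages = c("ringfit", "density", "sorting", "frap",
                                  "tubules"),
                       seed, output_dir, params = list()) {
  known_stages <- c("ringfit", "density", "sorting", "frap", "tubules")
  if (!all(stages %in% known_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, known_stages), collapse = ", "))
  if (missing(seed) || is.null(seed))
    stop("validation error: a seed is required for stochastic stages")
  known_params <- c("noise", "brightness_ratio", "labeling_efficiency",
                    "tether_enrichment", "aspect_threshold",
                    "mobile_fraction", "tau", "n_micrographs")
  if (length(params) > 0 && !all(names(params) %in% known_params))
    stop("unknown parameter key(s): ",
         paste(setdiff(names(params), known_params), collapse = ", "))
  defaults <- list(noise = "poisson", brightness_ratio = 2,
                   labeling_efficiency = 0.5,
                   tether_enrichment = c(A594 = 3, A488 = 1, DiD = 1),
                   aspect_threshold = 3, mobile_fraction = 0.8, tau = 5,
                   n_micrographs = 3L)
  params <- utils::modifyList(defaults, params)
  structure(list(stages = stages, seed = as.integer(seed),
                 output_dir = output_dir, params = params),
            class = "run_config")
}

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the demonstration pipeline over generated fixtures
#'
#' Executes the requested stages in order on synthetic scenes drawn from
#' the configured seed: Gaussian-ring quantification, the
#' intensity-to-density calibration chain, tether curvature sorting,
#' FRAP recovery, and tubule morphometry.  Writes per-stage CSV/JSON
#' results plus `manifest.json` (full configuration, seed, package
#' version); a rerun with the same configuration reproduces the output
#' files byte-identically.
#'
#' @param config a [run_config()].
#' @return named list of per-stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  noise <- switch(p$noise,
                  none = noise_model("none"),
                  poisson = noise_model("poisson", gain = 1),
                  gaussian = noise_model("gaussian", sigma = 10))
  results <- list()
  files <- character(0)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  for (stage in config$stages) {
    if (stage == "ringfit") {
      results$ringfit <- run_stage("ringfit", function() {
        tr <- scene_ground_truth(membrane_intensity = c(A488 = 1000),
                                 noise = noise, seed = config$seed)
        sc <- make_guv_image(tr)
        fit <- fit_gaussian_ring(sc$image, "A488",
                                 detect_guv_contour(sc$image, "A488"))
        df <- data.frame(image = "synthetic_guv", channel = "A488",
                         cx = fit$center[1], cy = fit$center[2],
                         radius_px = fit$mean_radius, sigma_px = fit$sigma,
                         background = fit$background,
                         membrane_intensity = fit$membrane_intensity,
                         intensity_sd = fit$intensity_sd,
                         n_angles_included = fit$n_angles_included)
        files <<- c(files, write_csv_file(
          df, file.path(config$output_dir, "ringfit.csv")))
        list(fit = fit, table = df)
      })
    } else if (stage == "density") {
      results$density <- run_stage("density", function() {
        series <- make_calibration_series(seed = config$seed)
        cal <- fit_calibration(series)
        model <- calibration_model(cal$slope, cal$slope_se,
                                   brightness_ratio = p$brightness_ratio,
                                   labeling_efficiency =
                                     p$labeling_efficiency)
        kd <- target_dye_factor(conversion_factor(model),
                                p$brightness_ratio)
        inten <- if (!is.null(results$ringfit))
          results$ringfit$fit$membrane_intensity else 19117
        isd <- if (!is.null(results$ringfit))
          results$ringfit$fit$intensity_sd else 0
        dens <- labeled_species_density(inten, isd, kd,
                                        p$labeling_efficiency)
        out <- list(slope = cal$slope, slope_se = cal$slope_se,
                    k_dye = kd$k, density_mean = dens$density_mean,
                    density_sd = dens$density_sd,
                    rounded_mean = dens$rounded_mean,
                    rounded_sd = dens$rounded_sd)
        files <<- c(files, write_csv_file(
          series, file.path(config$output_dir, "calibration_series.csv")))
        jsonlite::write_json(out,
                             file.path(config$output_dir, "density.json"),
                             auto_unbox = TRUE, digits = NA)
        files <<- c(files, file.path(config$output_dir, "density.json"))
        out
      })
    } else if (stage == "sorting") {
      results$sorting <- run_stage("sorting", function() {
        enr <- p$tether_enrichment
        tr <- scene_ground_truth(
          guv_center = c(7, 8), guv_radius = 4,
          membrane_intensity = stats::setNames(rep(1000, length(enr)),
                                               names(enr)),
          noise = noise, seed = config$seed,
          tether_enrichment = enr, lipid_channel = "DiD")
        sc <- make_tether_scene(tr)
        ring_ch <- names(enr)[1]
        est <- detect_guv_contour(sc$image, ring_ch)
        excl <- list(c(tr$tether_angle - 15, tr$tether_angle + 15))
        i_guv <- vapply(names(enr), function(cc)
          fit_gaussian_ring(sc$image, cc, est,
                            excluded_sectors = excl)$membrane_intensity,
          numeric(1))
        rr <- roi(round(est$center[1] + est$radius + 10),
                  round(est$center[2] - 2),
                  round(est$center[1] + est$radius + 60),
                  round(est$center[2] + 2))
        i_tet <- vapply(names(enr), function(cc)
          measure_tether_intensity(sc$image, cc, rr,
                                   background = tr$background),
          numeric(1))
        sres <- sorting_coefficient(
          tether_measurement(i_tet, i_guv, "DiD"))
        df <- data.frame(channel = names(sres$sorting_coefficient),
                         tether_to_guv_ratio =
                           as.numeric(sres$tether_to_guv_ratio),
                         sorting_coefficient =
                           as.numeric(sres$sorting_coefficient))
        files <<- c(files, write_csv_file(
          df, file.path(config$output_dir, "sorting.csv")))
        list(result = sres, table = df)
      })
    } else if (stage == "frap") {
      results$frap <- run_stage("frap", function() {
        st <- make_frap_stack(p$mobile_fraction, p$tau,
                              noise_cv = if (p$noise == "none") 0 else 0.02,
                              seed = config$seed)
        trace <- normalize_frap(st$stack, st$times, st$truth$bleach_roi,
                                st$truth$reference_roi,
                                st$truth$bleach_frame)
        fit <- fit_recovery(trace)
        df <- data.frame(time_s = trace$times,
                         normalized_intensity = trace$normalized_intensity)
        files <<- c(files, write_csv_file(
          df, file.path(config$output_dir, "frap_trace.csv")))
        out <- list(mobile_fraction = fit$mobile_fraction, tau = fit$tau,
                    half_time = fit$half_time, fit_rms = fit$fit_rms)
        jsonlite::write_json(out,
                             file.path(config$output_dir, "frap_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        files <<- c(files, file.path(config$output_dir, "frap_fit.json"))
        list(fit = fit, trace = trace)
      })
    } else if (stage == "tubules") {
      results$tubules <- run_stage("tubules", function() {
        recs <- NULL; grp <- integer(0)
        for (i in seq_len(p$n_micrographs)) {
          sc <- random_tubule_scene(
            seed = config$seed + i,
            noise = if (p$noise == "none") noise_model("none") else
              noise_model("gaussian", sigma = 7.5))
          seg <- segment_objects(make_tubule_micrograph(sc)$image,
                                 sc$pixel_size_nm)
          r <- measure_all_objects(seg, p$aspect_threshold)
          recs <- rbind(recs, r)
          grp <- c(grp, rep(i, nrow(r)))
        }
        sm <- summarize_morphometry(recs, group = grp)
        files <<- c(files, write_csv_file(
          cbind(group = grp, recs),
          file.path(config$output_dir, "morphometry.csv")))
        jsonlite::write_json(
          sm[c("n_intact", "n_tubulated", "tubulated_percent",
               "percent_mean", "percent_sd", "length_mean_um",
               "length_sd_um", "diameter_mean_nm", "diameter_sd_nm")],
          file.path(config$output_dir, "morphometry_summary.json"),
          auto_unbox = TRUE, digits = NA)
        files <<- c(files,
                    file.path(config$output_dir, "morphometry_summary.json"))
        list(records = recs, summary = sm)
      })
    }
  }
  manifest <- list(
    package = "guvquant",
    version = as.character(utils::packageVersion("guvquant")),
    stages = config$stages, seed = config$seed,
    output_dir = config$output_dir, params = config$params,
    files = basename(files))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}
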