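#' Mean tether fluorescence in a rectangular ROI
#'
#' The tether signal is the mean pixel intensity within a narrow
#' rectangular ROI laid along the tether, minus an optional background
#' level (default 0, i.e. the raw mean).  If a GUV ring fit is supplied
#' and the ROI overlaps the vesicle disk, the overlap is recorded as a
#' warning attribute on the result (and raised as an R warning).
#'
#' @param image an [multichannel_image()] or matrix.
#' @param channel channel name.
#' @param tether_roi an [roi()] covering the tether.
#' @param background intensity to subtract (a.u.).
#' @param guv_fit optional [fit_gaussian_ring()] result used for the
#'   overlap check.
#' @return numeric tether intensity; attribute `roi_warning` if the ROI
#'   touched the GUV disk.
#' @export
measure_tether_intensity <- function(image, channel = NULL, tether_roi,
                                     background = 0, guv_fit = NULL) {
  m <- get_channel(image, channel)
  v <- mean(roi_pixels(m, tether_roi)) - background
  if (!is.null(guv_fit)) {
    cx <- guv_fit$center[1]; cy <- guv_fit$center[2]
    r <- guv_fit$mean_radius + 2 * guv_fit$sigma
    # closest point of the ROI rectangle to the GUV center
    px <- min(max(cx, tether_roi[1]), tether_roi[3])
    py <- min(max(cy, tether_roi[2]), tether_roi[4])
    if (sqrt((px - cx)^2 + (py - cy)^2) < r) {
      warning("tether ROI overlaps the fitted GUV disk")
      attr(v, "roi_warning") <- "roi overlaps GUV disk"
    }
  }
  v
}

#' Tether/GUV intensity measurement record
#'
#' @param i_tether named vector of tether intensities per channel (a.u.).
#' @param i_guv named vector of GUV membrane intensities per channel
#'   (typically [fit_gaussian_ring()] membrane intensities).
#' @param lipid_channel name of the reference lipid channel.
#' @return list of class `tether_measurement`.
#' @export
tether_measurement <- function(i_tether, i_guv, lipid_channel) {
  if (is.null(names(i_tether)) || is.null(names(i_guv)))
    stop("intensities must be named per-channel vectors")
  if (!lipid_channel %in% names(i_tether) ||
      !lipid_channel %in% names(i_guv))
    stop("lipid channel '", lipid_channel, "' missing from measurements")
  if (any(i_tether < 0) || any(i_guv < 0))
    stop("intensities must be >= 0")
  structure(list(i_tether = i_tether, i_guv = i_guv,
                 lipid_channel = lipid_channel),
            class = "tether_measurement")
}

#' Curvature sorting coefficient
#'
#' `S = (I_tether / I_GUV)_channel / (I_tether / I_GUV)_lipid`: the
#' enrichment of a species on the highly curved tether relative to the
#' flat GUV membrane, normalized by the lipid dye so that geometry and
#' gain cancel.  S = 1 means no curvature preference; the lipid channel
#' is 1 by construction.
#'
#' @param measurement a [tether_measurement()].
#' @param protein_channel channel of primary interest (reported first).
#' @param lipid_channel reference channel; defaults to the measurement's.
#' @param min_tether_intensity channels whose tether intensity falls
#'   below this level are flagged `low_signal` (sorting there is not
#'   detectable, though the value is still reported).
#' @return list of class `sorting_result` with per-channel
#'   `tether_to_guv_ratio`, `sorting_coefficient` and `low_signal` flags.
#' @export
sorting_coefficient <- function(measurement, protein_channel = NULL,
                                lipid_channel = measurement$lipid_channel,
                                min_tether_intensity = 0) {
  stopifnot(inherits(measurement, "tether_measurement"))
  it <- measurement$i_tether; ig <- measurement$i_guv
  ch <- names(it)
  for (cc in ch) {
    if (ig[[cc]] == 0)
      stop("zero GUV intensity in channel '", cc, "'")
  }
  if (it[[lipid_channel]] == 0)
    stop("zero tether intensity in lipid channel '", lipid_channel, "'")
  ratio <- it / ig[ch]
  s <- ratio / ratio[[lipid_channel]]
  if (!is.null(protein_channel)) {
    ord <- c(protein_channel, setdiff(ch, protein_channel))
    ratio <- ratio[ord]; s <- s[ord]
  }
  structure(list(tether_to_guv_ratio = ratio, sorting_coefficient = s,
                 lipid_channel = lipid_channel,
                 protein_channel = protein_channel,
                 low_signal = it[names(s)] < min_tether_intensity),
            class = "sorting_result")
}

#' @export
print.sorting_result <- function(x, ...) {
  cat("<sorting_result> (lipid reference:", x$lipid_channel, ")\n")
  for (cc in names(x$sorting_coefficient))
    cat(sprintf("  %s: tether/GUV %.3f, S = %.3f%s\n", cc,
                x$tether_to_guv_ratio[[cc]], x$sorting_coefficient[[cc]],
                if (isTRUE(x$low_signal[[cc]])) " [low signal]" else ""))
  invisible(x)
}

#' Micropipette-aspiration membrane tension
#'
#' `T = dP * Rp / (2 * (1 - Rp/Rv))` -- the Laplace balance between the
#' aspiration pressure `dP`, the pipette (projection) radius `Rp` and the
#' vesicle radius `Rv`.
#'
#' @param delta_p aspiration pressure in Pa (>= 0).
#' @param r_p pipette/projection radius in um.
#' @param r_v vesicle radius in um; must exceed `r_p`.
#' @return membrane tension in mN/m.
#' @export
membrane_tension <- function(delta_p, r_p, r_v) {
  stopifnot(delta_p >= 0, r_p > 0)
  if (any(r_p >= r_v))
    stop("projection radius must be smaller than vesicle radius")
  # Pa * um = 1e-6 N/m = 1e-3 mN/m
  delta_p * r_p * 1e-3 / (2 * (1 - r_p / r_v))
}
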