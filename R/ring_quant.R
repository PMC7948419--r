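#' Detect the dominant GUV contour in a fluorescence image
#'
#' Smooths the image, thresholds it above background by a contrast
#' factor, labels connected components, and scores each ring candidate by
#' the mean intensity on its estimated circle minus the local background.
#' Tie-breaking is deterministic: the largest radius wins, then the
#' highest score.
#'
#' @param image an [multichannel_image()] or matrix.
#' @param channel channel name.
#' @param contrast_factor candidate pixels must exceed
#'   `background + contrast_factor * (max - background)`.
#' @param smooth_sigma Gaussian pre-smoothing in px (0 disables).
#' @param min_area_px discard components smaller than this.
#' @return list of class `contour_estimate` with `center` (x, y in px,
#'   0-based), `radius` (px) and `detection_score`.
#' @export
detect_guv_contour <- function(image, channel = NULL, contrast_factor = 0.25,
                               smooth_sigma = 1, min_area_px = 25L) {
  m <- get_channel(image, channel)
  sm <- if (smooth_sigma > 0) EBImage::gblur(m, sigma = smooth_sigma) else m
  bg <- stats::median(sm)
  thr <- bg + contrast_factor * (max(sm) - bg)
  mask <- sm > thr
  if (!any(mask)) stop("no GUV found: no pixels exceed the contrast threshold")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  cand <- list()
  for (id in which(sizes >= min_area_px)) {
    idx <- which(lab == id, arr.ind = TRUE)
    cy <- mean(idx[, 1]) - 1; cx <- mean(idx[, 2]) - 1
    rad <- mean(sqrt((idx[, 1] - 1 - cy)^2 + (idx[, 2] - 1 - cx)^2))
    if (rad <= 2) next
    if (cx < 0 || cy < 0 || cx > ncol(m) - 1 || cy > nrow(m) - 1) next
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    ring_mean <- mean(interp_image(sm, cx + rad * cos(th), cy + rad * sin(th),
                                   method = "bilinear"))
    score <- ring_mean - bg
    if (score <= 0) next
    cand[[length(cand) + 1L]] <- list(center = c(cx, cy), radius = rad,
                                      detection_score = score)
  }
  if (length(cand) == 0) stop("no GUV found: no ring-like candidate")
  radii <- vapply(cand, `[[`, numeric(1), "radius")
  scores <- vapply(cand, `[[`, numeric(1), "detection_score")
  best <- order(-radii, -scores)[1]
  structure(cand[[best]], class = "contour_estimate")
}

sector_contains <- function(theta_deg, sector) {
  a <- sector[1] %% 360; b <- sector[2] %% 360; t <- theta_deg %% 360
  if (a <= b) t >= a & t <= b else t >= a | t <= b
}

sector_width <- function(sector) {
  (sector[2] - sector[1]) %% 360
}

sample_ring_profiles <- function(m, cx, cy, theta, r, method) {
  xs <- outer(cos(theta), r) + cx
  ys <- outer(sin(theta), r) + cy
  matrix(interp_image(m, as.vector(xs), as.vector(ys), method = method),
         length(theta), length(r))
}

# Closed-form generalized least squares for the arrowhead system:
# y_ij = B + A_i g_ij with shared B and per-angle amplitudes A_i.
ring_linear_solve <- function(P, D, sigma) {
  G <- exp(-D^2 / (2 * sigma^2))
  Sg <- rowSums(G); Sgg <- rowSums(G^2); Sgy <- rowSums(G * P)
  N <- length(P); Sy <- sum(P)
  denom <- N - sum(Sg^2 / Sgg)
  B <- (Sy - sum(Sgy * Sg / Sgg)) / denom
  A <- (Sgy - B * Sg) / Sgg
  R <- P - B - A * G
  list(A = A, B = B, sse = sum(R^2), G = G)
}

#' Fit a Gaussian ring to a GUV contour
#'
#' For each sampled angle the radial intensity profile is fit to
#' `B + A_i * exp(-(r - rho_i)^2 / (2 sigma^2))` with the background `B`
#' and ring width `sigma` shared across angles and per-angle amplitude
#' `A_i` and radius `rho_i`.  The center is refined to sub-pixel accuracy
#' from the first angular Fourier mode of `rho_i`.  Angles falling in
#' `excluded_sectors` (e.g. the aspirated region of a pipette-held GUV)
#' contribute nothing to the fit or to the intensity summary.
#'
#' @param image an [multichannel_image()] or matrix.
#' @param channel channel name.
#' @param estimate a [detect_guv_contour()] result (or any list with
#'   `center` and `radius` in px).
#' @param n_angles number of equally spaced angles (default 360).
#' @param radial_window half-width of the radial fit window in px.
#' @param excluded_sectors list of `c(start, end)` angle ranges in
#'   degrees (clockwise from +x; ranges may wrap through 360).
#' @param interpolation radial sampling scheme; Catmull-Rom `"cubic"`
#'   (default) or `"bilinear"`.
#' @param summary `"amplitude"` reports the mean per-angle peak amplitude
#'   as membrane intensity; `"integrated"` reports
#'   `mean(A) * sigma * sqrt(2*pi)`.
#' @param max_iter outer refinement iterations.
#' @return object of class `ring_fit` with sub-pixel `center`,
#'   `mean_radius`, per-angle `amplitudes` and `radii` (NA at excluded
#'   angles), shared `background` and `sigma`, `membrane_intensity`,
#'   `intensity_sd`, `included` logical mask, `angles_deg`,
#'   `n_angles_included` and `residual_rms`.
#' @export
fit_gaussian_ring <- function(image, channel = NULL, estimate,
                              n_angles = 360L, radial_window = 10,
                              excluded_sectors = list(),
                              interpolation = c("cubic", "bilinear"),
                              summary = c("amplitude", "integrated"),
                              max_iter = 5L) {
  interpolation <- match.arg(interpolation)
  summary <- match.arg(summary)
  m <- get_channel(image, channel)
  if (length(excluded_sectors) > 0 &&
      sum(vapply(excluded_sectors, sector_width, numeric(1))) >= 270)
    stop("excluded sectors cover >= 75% of the circle")
  theta_deg <- seq(0, 360, length.out = n_angles + 1L)[-(n_angles + 1L)]
  included <- rep(TRUE, n_angles)
  for (s in excluded_sectors)
    included <- included & !sector_contains(theta_deg, s)
  if (sum(included) < 8) stop("fewer than 8 included angles")
  theta <- theta_deg[included] * pi / 180

  cx <- estimate$center[1]; cy <- estimate$center[2]
  rho0 <- estimate$radius
  r <- seq(max(1, rho0 - radial_window), rho0 + radial_window, by = 0.25)

  P <- sample_ring_profiles(m, cx, cy, theta, r, interpolation)
  B <- as.numeric(stats::quantile(P, 0.2))
  rho <- r[max.col(P, ties.method = "first")]
  sigma <- max(1, radial_window / 4)

  for (iter in seq_len(max_iter)) {
    # per-angle radius: vectorized matched-filter sweep + parabolic refine
    deltas <- seq(-2 * sigma, 2 * sigma, length.out = 33)
    H <- matrix(0, length(theta), length(deltas))
    Y <- P - B
    for (j in seq_along(deltas)) {
      D <- outer(-rho - deltas[j], r, `+`)
      G <- exp(-D^2 / (2 * sigma^2))
      H[, j] <- rowSums(G * Y)^2 / rowSums(G^2)
    }
    jb <- max.col(H, ties.method = "first")
    dd <- deltas[2] - deltas[1]
    dbest <- deltas[jb]
    inner <- jb > 1 & jb < length(deltas)
    if (any(inner)) {
      i1 <- which(inner)
      y0 <- H[cbind(i1, jb[i1] - 1L)]
      y1 <- H[cbind(i1, jb[i1])]
      y2 <- H[cbind(i1, jb[i1] + 1L)]
      denom <- y0 - 2 * y1 + y2
      adj <- ifelse(abs(denom) > 0, 0.5 * (y0 - y2) / denom, 0)
      dbest[i1] <- dbest[i1] + pmin(pmax(adj, -1), 1) * dd
    }
    rho <- pmin(pmax(rho + dbest, r[1] + 1), r[length(r)] - 1)

    # sub-pixel center from first Fourier mode of rho(theta)
    if (iter <= 2) {
      X <- cbind(1, cos(theta), sin(theta))
      cf <- stats::lm.fit(X, rho)$coefficients
      cx <- cx + cf[2]; cy <- cy + cf[3]
      rho <- rho - cf[2] * cos(theta) - cf[3] * sin(theta)
      P <- sample_ring_profiles(m, cx, cy, theta, r, interpolation)
    }

    # shared sigma: log-scale sweep with closed-form B, A at each value
    svals <- sigma * exp(seq(-0.5, 0.5, length.out = 21))
    D <- outer(-rho, r, `+`)
    sse <- vapply(svals, function(s) ring_linear_solve(P, D, s)$sse,
                  numeric(1))
    kb <- which.min(sse)
    if (kb > 1 && kb < length(svals)) {
      ls <- log(svals); y0 <- sse[kb - 1]; y1 <- sse[kb]; y2 <- sse[kb + 1]
      den <- y0 - 2 * y1 + y2
      adj <- if (abs(den) > 0) 0.5 * (y0 - y2) / den else 0
      sigma <- exp(ls[kb] + pmin(pmax(adj, -1), 1) * (ls[2] - ls[1]))
    } else sigma <- svals[kb]
    sol <- ring_linear_solve(P, D, sigma)
    B <- sol$B
  }

  sol <- ring_linear_solve(P, outer(-rho, r, `+`), sigma)
  A <- sol$A; B <- sol$B
  ok <- A > 0 & rho > r[1] + 1 & rho < r[length(r)] - 1
  if (mean(!ok) > 0.5)
    stop(sprintf("ring fit failed: %d of %d angular fits did not converge",
                 sum(!ok), length(ok)))
  amp_all <- radius_all <- rep(NA_real_, n_angles)
  amp_all[included] <- A
  radius_all[included] <- rho
  keep <- A[ok]
  mi <- mean(keep)
  if (summary == "integrated") mi <- mi * sigma * sqrt(2 * pi)
  structure(list(
    center = c(x = unname(cx), y = unname(cy)),
    mean_radius = mean(rho[ok]),
    amplitudes = amp_all, radii = radius_all,
    background = B, sigma = sigma,
    membrane_intensity = mi,
    intensity_sd = if (length(keep) > 1) stats::sd(keep) else 0,
    summary = summary,
    included = included & replace(rep(FALSE, n_angles), which(included), ok),
    angles_deg = theta_deg,
    n_angles_included = sum(ok),
    residual_rms = sqrt(sol$sse / length(P)),
    excluded_sectors = excluded_sectors,
    interpolation = interpolation), class = "ring_fit")
}

#' @export
print.ring_fit <- function(x, ...) {
  cat(sprintf(paste0("<ring_fit> center (%.2f, %.2f) px, radius %.2f px, ",
                     "sigma %.2f px\n  background %.2f, membrane intensity ",
                     "%.1f +/- %.1f a.u. (%d angles)\n"),
              x$center[1], x$center[2], x$mean_radius, x$sigma, x$background,
              x$membrane_intensity, x$intensity_sd, x$n_angles_included))
  invisible(x)
}

#' Membrane intensity summary of a ring fit
#'
#' Returns the per-GUV membrane intensity (the `I_GUV` consumed by the
#' density-calibration and curvature-sorting stages) together with the
#' GUV-contour spread, the sample standard deviation (n - 1 denominator)
#' of the included per-angle amplitudes.
#'
#' @param fit a [fit_gaussian_ring()] result.
#' @return list with `intensity` and `spread` (a.u.).
#' @export
measure_guv_intensity <- function(fit) {
  stopifnot(inherits(fit, "ring_fit"))
  a <- fit$amplitudes[fit$included]
  a <- a[is.finite(a)]
  if (length(a) == 0) stop("no included amplitudes")
  mi <- mean(a)
  if (identical(fit$summary, "integrated"))
    mi <- mi * fit$sigma * sqrt(2 * pi)
  list(intensity = mi,
       spread = if (length(a) > 1) stats::sd(a) else 0)
}
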