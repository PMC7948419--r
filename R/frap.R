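#' Normalize a FRAP stack against an unbleached reference region
#'
#' Per frame, the mean intensity of the bleach ROI is divided by the mean
#' intensity of a disjoint reference ROI, which cancels acquisition
#' photobleaching and global intensity drifts.  The pre-bleach frames of
#' that ratio are averaged into `prebleach_level`; with
#' `rescale_prebleach = TRUE` (default) the trace is additionally divided
#' by it so that the pre-bleach level is 1.
#'
#' @param stack 3D array `[row, col, frame]` (or an [multichannel_image()]
#'   holding one).
#' @param times frame times in seconds, strictly increasing.
#' @param bleach_roi,reference_roi [roi()] rectangles; must not overlap.
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @param rescale_prebleach divide the trace by the pre-bleach level.
#' @return list of class `frap_trace` with `times`,
#'   `normalized_intensity`, `bleach_frame_index`, `prebleach_level`.
#' @export
normalize_frap <- function(stack, times, bleach_roi, reference_roi,
                           bleach_frame, rescale_prebleach = TRUE) {
  if (inherits(stack, "mc_image")) stack <- stack$channels[[1]]
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] == length(times))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (bleach_frame < 2 || bleach_frame > length(times))
    stop("bleach_frame out of range")
  if (rois_overlap(bleach_roi, reference_roi))
    stop("bleach and reference ROIs overlap")
  n <- length(times)
  ratio <- vapply(seq_len(n), function(k) {
    fr <- stack[, , k]
    ref <- mean(roi_pixels(fr, reference_roi))
    if (ref <= 0) stop("reference ROI mean is not positive at frame ", k)
    mean(roi_pixels(fr, bleach_roi)) / ref
  }, numeric(1))
  pre <- mean(ratio[seq_len(bleach_frame - 1L)])
  if (rescale_prebleach) {
    ratio <- ratio / pre
    pre <- 1
  }
  structure(list(times = times, normalized_intensity = ratio,
                 bleach_frame_index = bleach_frame, prebleach_level = pre),
            class = "frap_trace")
}

#' Fit a single-exponential recovery to a FRAP trace
#'
#' Least-squares fit of
#' `I(t) = I_inf - (I_inf - I0) * exp(-(t - t_bleach)/tau)` to the
#' post-bleach frames, with the documented initializer I0 = first
#' post-bleach point, I_inf = last point, tau = post-bleach span / 3.
#' The mobile fraction is `(I_inf - I0)/(prebleach - I0)`, clipped to
#' [0, 1]; the half-time is `tau * ln 2`.
#'
#' @param trace a [normalize_frap()] result.
#' @return list of class `frap_fit` with `i0`, `i_inf`, `tau`,
#'   `mobile_fraction`, `half_time`, `fit_rms`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  post <- trace$bleach_frame_index:length(trace$times)
  if (length(post) < 5) stop("need at least 5 post-bleach frames")
  t0 <- trace$times[trace$bleach_frame_index]
  tt <- trace$times[post] - t0
  y <- trace$normalized_intensity[post]
  pre <- trace$prebleach_level
  span <- max(tt)
  start <- list(i0 = y[1], i_inf = y[length(y)], tau = span / 3)
  if (diff(range(y)) < 1e-6 * max(abs(pre), 1)) {
    # flat trace: no measurable recovery
    fit <- list(i0 = mean(y), i_inf = mean(y), tau = NA_real_)
    rms <- stats::sd(y)
  } else {
    fm <- tryCatch(
      minpack.lm::nlsLM(y ~ i_inf - (i_inf - i0) * exp(-tt / tau),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fm)) {
      cf <- stats::coef(fm)
      rms <- sqrt(mean(stats::resid(fm)^2))
    } else {
      # zero-residual traces defeat the Levenberg-Marquardt wrapper;
      # minimize the SSE directly from the same initializer
      sse <- function(p) {
        if (p[3] <= 0) return(Inf)
        sum((y - (p[2] - (p[2] - p[1]) * exp(-tt / p[3])))^2)
      }
      op <- stats::optim(unlist(start), sse, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
      if (!is.finite(op$value))
        stop("recovery fit did not converge (starting values i0=",
             signif(start$i0, 4), ", i_inf=", signif(start$i_inf, 4),
             ", tau=", signif(start$tau, 4), ")")
      cf <- stats::setNames(op$par, c("i0", "i_inf", "tau"))
      rms <- sqrt(op$value / length(y))
    }
    fit <- list(i0 = unname(cf["i0"]), i_inf = unname(cf["i_inf"]),
                tau = unname(cf["tau"]))
  }
  mob <- if (pre - fit$i0 <= 0) 0 else
    min(max((fit$i_inf - fit$i0) / (pre - fit$i0), 0), 1)
  structure(list(i0 = fit$i0, i_inf = fit$i_inf, tau = fit$tau,
                 mobile_fraction = mob,
                 half_time = fit$tau * log(2),
                 fit_rms = rms, prebleach_level = pre),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(paste0("<frap_fit> mobile fraction %.3f, tau %.2f s ",
                     "(half-time %.2f s), floor %.3f, plateau %.3f\n"),
              x$mobile_fraction, x$tau, x$half_time, x$i0, x$i_inf))
  invisible(x)
}
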