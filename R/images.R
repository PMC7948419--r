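#' Multichannel image container
#'
#' Bundles one pixel grid per channel with the physical pixel size and,
#' for time-lapse stacks, the frame acquisition times.  Pixel centers sit
#' at integer coordinates, origin at the top-left pixel, x increasing
#' rightward (columns) and y increasing downward (rows); physical position
#' is pixel coordinate times `pixel_size`.
#'
#' @param channels named list of numeric matrices (one per channel), or a
#'   named list of 3D arrays `[row, col, frame]` for time-lapse data.
#' @param pixel_size physical size of one pixel (micrometres per pixel for
#'   confocal images, nanometres per pixel for micrographs -- stated in
#'   `pixel_unit`).
#' @param pixel_unit unit string for `pixel_size` (default `"um"`).
#' @param times optional numeric vector of frame times in seconds.
#' @return an object of class `mc_image`.
#' @export
multichannel_image <- function(channels, pixel_size, pixel_unit = "um",
                               times = NULL) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of matrices")
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("every channel must be named")
  dims <- lapply(channels, function(m) dim(m)[1:2])
  if (length(unique(dims)) != 1L)
    stop("all channels must share the same pixel grid")
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  if (!is.null(times)) {
    if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 pixel_unit = pixel_unit, times = times),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mc_image> %d x %d px, %g %s/px, channels: %s%s\n",
              d[1], d[2], x$pixel_size, x$pixel_unit,
              paste(names(x$channels), collapse = ", "),
              if (is.null(x$times)) "" else
                sprintf(", %d frames", length(x$times))))
  invisible(x)
}

#' Extract one channel as a matrix (or frame array)
#'
#' @param image an `mc_image` or a plain matrix (returned as is).
#' @param channel channel name; may be omitted for single-channel images.
#' @return numeric matrix (or 3D array for stacks).
#' @export
get_channel <- function(image, channel = NULL) {
  if (is.matrix(image) || (is.array(image) && length(dim(image)) == 3L))
    return(image)
  if (!inherits(image, "mc_image")) stop("not an mc_image or matrix")
  if (is.null(channel)) {
    if (length(image$channels) == 1L) return(image$channels[[1]])
    stop("multi-channel image: specify 'channel' (available: ",
         paste(names(image$channels), collapse = ", "), ")")
  }
  if (!channel %in% names(image$channels))
    stop("channel '", channel, "' not found; available: ",
         paste(names(image$channels), collapse = ", "))
  image$channels[[channel]]
}

#' Rectangular region of interest
#'
#' ROIs are axis-aligned pixel rectangles in the 0-based pixel coordinate
#' convention, inclusive of both corners.
#'
#' @param x0,y0 top-left pixel coordinate (0-based).
#' @param x1,y1 bottom-right pixel coordinate (0-based, inclusive).
#' @return integer vector `c(x0, y0, x1, y1)` of class `roi`.
#' @export
roi <- function(x0, y0, x1, y1) {
  r <- as.integer(round(c(x0, y0, x1, y1)))
  if (r[3] < r[1] || r[4] < r[2]) stop("ROI corners out of order")
  if (any(r[1:2] < 0L)) stop("ROI coordinates must be >= 0")
  structure(r, class = "roi", names = c("x0", "y0", "x1", "y1"))
}

#' Pixels inside an ROI
#'
#' @param mat numeric matrix.
#' @param r an [roi()].
#' @return the submatrix covered by the ROI.
#' @export
roi_pixels <- function(mat, r) {
  if (r[4] + 1L > nrow(mat) || r[3] + 1L > ncol(mat))
    stop("ROI extends beyond the image")
  mat[(r[2] + 1L):(r[4] + 1L), (r[1] + 1L):(r[3] + 1L), drop = FALSE]
}

rois_overlap <- function(a, b) {
  !(a[3] < b[1] || b[3] < a[1] || a[4] < b[2] || b[4] < a[2])
}

# Sub-pixel image interpolation at 0-based coordinates (x, y).
# method "cubic" is a Catmull-Rom spline (local, C1, exact for cubics);
# "bilinear" is the classic 4-neighbour scheme. Edges replicate.
interp_image <- function(mat, x, y, method = c("cubic", "bilinear")) {
  method <- match.arg(method)
  nr <- nrow(mat); nc <- ncol(mat)
  ix <- floor(x); iy <- floor(y)
  tx <- x - ix; ty <- y - iy
  cl <- function(i, n) pmin(pmax(i, 0L), n - 1L) + 1L  # to clamped 1-based
  if (method == "bilinear") {
    v <- 0
    for (a in 0:1) for (b in 0:1) {
      w <- (if (a == 0) 1 - tx else tx) * (if (b == 0) 1 - ty else ty)
      v <- v + w * mat[cbind(cl(iy + b, nr), cl(ix + a, nc))]
    }
    return(v)
  }
  cr <- function(t, k) {
    switch(k,
      `1` = ((-t + 2) * t - 1) * t / 2,
      `2` = (((3 * t - 5) * t) * t + 2) / 2,
      `3` = ((-3 * t + 4) * t + 1) * t / 2,
      `4` = ((t - 1) * t * t) / 2)
  }
  v <- 0
  for (a in -1:2) {
    wx <- cr(tx, as.character(a + 2))
    for (b in -1:2) {
      wy <- cr(ty, as.character(b + 2))
      v <- v + wx * wy * mat[cbind(cl(iy + b, nr), cl(ix + a, nc))]
    }
  }
  v
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  expr
}
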