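#' Segment vesicles and tubules in a micrograph
#'
#' Global threshold (Otsu by default) followed by connected-component
#' labeling; components below `min_area_px` are dropped.  Negative-stain
#' micrographs have dark objects on a bright background, which is the
#' default polarity.
#'
#' @param image grayscale matrix (or single-channel [multichannel_image()]).
#' @param pixel_size_nm physical pixel size in nm.
#' @param threshold_method only `"otsu"` is implemented.
#' @param min_area_px minimum object area in pixels.
#' @param polarity `"dark"` objects below threshold (default) or
#'   `"bright"` above.
#' @return list of class `segmentation` with `labels` (integer matrix,
#'   0 = background), `n_objects`, `threshold`, `pixel_size_nm`.
#' @export
segment_objects <- function(image, pixel_size_nm,
                            threshold_method = "otsu", min_area_px = 20L,
                            polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (threshold_method != "otsu")
    stop("unsupported threshold method: ", threshold_method)
  stopifnot(pixel_size_nm > 0)
  m <- get_channel(image)
  rng <- range(m)
  empty <- function(thr) structure(
    list(labels = matrix(0L, nrow(m), ncol(m)), n_objects = 0L,
         threshold = thr, pixel_size_nm = pixel_size_nm),
    class = "segmentation")
  if (diff(rng) == 0) return(empty(NA_real_))
  thr <- rng[1] + EBImage::otsu((m - rng[1]) / diff(rng),
                                range = c(0, 1)) * diff(rng)
  # isodata refinement: place the cut midway between the class means so
  # that anti-aliased edges split at half coverage
  for (i in 1:50) {
    new <- (mean(m[m < thr]) + mean(m[m >= thr])) / 2
    if (!is.finite(new) || abs(new - thr) < 1e-6 * diff(rng)) break
    thr <- new
  }
  mask <- if (polarity == "dark") m < thr else m > thr
  if (!any(mask)) return(empty(thr))
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(m), ncol(m))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  structure(list(labels = out, n_objects = length(keep), threshold = thr,
                 pixel_size_nm = pixel_size_nm),
            class = "segmentation")
}

# Zhang-Suen binary thinning, vectorized over the whole mask.
thin_mask <- function(mask) {
  M <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  M[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(M); nc <- ncol(M)
  sh <- function(A, dr, dc) {
    B <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    B[rs, cs] <- A[rs - dr, cs - dc]
    B
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- sh(M, -1, 0); p3 <- sh(M, -1, 1); p4 <- sh(M, 0, 1)
      p5 <- sh(M, 1, 1);  p6 <- sh(M, 1, 0);  p7 <- sh(M, 1, -1)
      p8 <- sh(M, 0, -1); p9 <- sh(M, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- M & bsum >= 2 & bsum <= 6 & a == 1
      if (sub == 1)
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(cond)) {
        M[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  M[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

# Longest geodesic path through an 8-connected skeleton.
# Returns path pixel coordinates (row, col) and its length in px.
skeleton_path <- function(skel) {
  pix <- which(skel, arr.ind = TRUE)
  np <- nrow(pix)
  if (np == 0) return(list(length_px = 0, path = pix))
  if (np == 1) return(list(length_px = 0, path = pix))
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[pix] <- seq_len(np)
  edges <- NULL; wts <- NULL
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- pix[, 1] + off[1]; c2 <- pix[, 2] + off[2]
    valid <- r2 >= 1 & r2 <= nrow(skel) & c2 >= 1 & c2 <= ncol(skel)
    j <- integer(np); j[valid] <- id[cbind(r2[valid], c2[valid])]
    hit <- which(j > 0)
    if (length(hit) > 0) {
      edges <- rbind(edges, cbind(hit, j[hit]))
      wts <- c(wts, rep(sqrt(sum(off^2)), length(hit)))
    }
  }
  if (is.null(edges))
    return(list(length_px = 0, path = pix[1, , drop = FALSE]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  if (igraph::vcount(g) < np)
    g <- igraph::add_vertices(g, np - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  d0 <- igraph::distances(g, v = main[1])[1, main]
  v1 <- main[which.max(d0)]
  d1 <- igraph::distances(g, v = v1)[1, main]
  v2 <- main[which.max(d1)]
  sp <- igraph::shortest_paths(g, from = v1, to = v2, output = "vpath")
  vp <- as.integer(sp$vpath[[1]])
  list(length_px = max(d1), path = pix[vp, , drop = FALSE])
}

#' Measure one segmented object
#'
#' The object is skeletonized (Zhang-Suen thinning); its length is the
#' geodesic length of the longest skeleton path plus the end-cap radii
#' (distance-transform values at the two path endpoints), and its width
#' is twice the mean distance-transform value along the path minus one
#' pixel (the half-pixel boundary offset at each side).  Objects with
#' `aspect = length / width >= aspect_threshold` are classified
#' tubulated.  Objects touching the image border are flagged.
#'
#' @param seg a [segment_objects()] result.
#' @param label_id object label.
#' @param aspect_threshold elongation threshold for the tubulated class.
#' @return one-row data.frame with columns `label`, `length_um`,
#'   `diameter_nm`, `aspect`, `classification`, `border`, `area_px`.
#' @export
measure_object <- function(seg, label_id, aspect_threshold = 3) {
  stopifnot(inherits(seg, "segmentation"))
  idx <- which(seg$labels == label_id, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty object label ", label_id)
  border <- any(idx[, 1] == 1L | idx[, 1] == nrow(seg$labels) |
                  idx[, 2] == 1L | idx[, 2] == ncol(seg$labels))
  pad <- 2L
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  nr <- r1 - r0 + 1L + 2L * pad; nc <- c1 - c0 + 1L + 2L * pad
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(idx[, 1] - r0 + 1L + pad, idx[, 2] - c0 + 1L + pad)] <- TRUE
  dm <- EBImage::distmap(mask)
  sk <- thin_mask(mask)
  sp <- skeleton_path(sk)
  px <- seg$pixel_size_nm
  if (nrow(sp$path) < 2) {
    len_px <- 0; wid_px <- 2 * max(dm) - 1
  } else {
    # geodesic length along the skeleton, measured on a subsampled
    # polyline to undo the staircase inflation of 8-connected chains
    n <- nrow(sp$path)
    ii <- unique(c(seq(1L, n, by = 5L), n))
    len_px <- polyline_length(sp$path[ii, , drop = FALSE])
    wid_px <- 2 * mean(dm[sp$path]) - 1
  }
  wid_px <- max(wid_px, 1)
  aspect <- len_px / wid_px
  data.frame(label = label_id,
             cx_px = mean(idx[, 2]) - 1, cy_px = mean(idx[, 1]) - 1,
             length_um = len_px * px / 1000,
             diameter_nm = wid_px * px,
             aspect = aspect,
             classification = if (aspect >= aspect_threshold)
               "tubulated" else "intact",
             border = border,
             area_px = nrow(idx),
             stringsAsFactors = FALSE)
}

#' Measure every object of a segmentation
#'
#' @inheritParams measure_object
#' @return data.frame, one row per object (see [measure_object()]).
#' @export
measure_all_objects <- function(seg, aspect_threshold = 3) {
  if (seg$n_objects == 0)
    return(data.frame(label = integer(0), cx_px = numeric(0),
                      cy_px = numeric(0), length_um = numeric(0),
                      diameter_nm = numeric(0), aspect = numeric(0),
                      classification = character(0), border = logical(0),
                      area_px = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(seg$n_objects), measure_object, seg = seg,
                        aspect_threshold = aspect_threshold))
}

#' Summarize morphometry records
#'
#' Computes the tubulated percentage per group (e.g. per micrograph or
#' per independent trial) and reports the mean and SD of those per-group
#' percentages, plus pooled tubule length and diameter statistics.
#' Border-touching objects are excluded by default to avoid truncation
#' bias.
#'
#' @param records data.frame from [measure_all_objects()] (rows from
#'   several images may be concatenated).
#' @param group optional vector (length `nrow(records)`) of group labels;
#'   a single group is assumed when omitted.
#' @param exclude_border drop border-touching objects first.
#' @return list of class `morphometry_summary` with `n_intact`,
#'   `n_tubulated`, `tubulated_percent` (overall), `percent_by_group`,
#'   `percent_mean`, `percent_sd`, `length_mean_um`, `length_sd_um`,
#'   `diameter_mean_nm`, `diameter_sd_nm`.
#' @export
summarize_morphometry <- function(records, group = NULL,
                                  exclude_border = TRUE) {
  if (is.null(group)) group <- rep(1L, nrow(records))
  stopifnot(length(group) == nrow(records))
  if (exclude_border && nrow(records) > 0) {
    keep <- !records$border
    records <- records[keep, , drop = FALSE]
    group <- group[keep]
  }
  n_tub <- sum(records$classification == "tubulated")
  n_int <- sum(records$classification == "intact")
  pct_by_group <- if (nrow(records) == 0) numeric(0) else
    tapply(records$classification == "tubulated", group,
           function(z) 100 * mean(z))
  tub <- records[records$classification == "tubulated", , drop = FALSE]
  msd <- function(v) if (length(v) == 0) c(NA_real_, NA_real_) else
    c(mean(v), if (length(v) > 1) stats::sd(v) else 0)
  lm_ <- msd(tub$length_um); dm_ <- msd(tub$diameter_nm)
  structure(list(
    n_intact = n_int, n_tubulated = n_tub,
    tubulated_percent = if (n_int + n_tub > 0)
      100 * n_tub / (n_int + n_tub) else NA_real_,
    percent_by_group = pct_by_group,
    percent_mean = if (length(pct_by_group)) mean(pct_by_group) else NA_real_,
    percent_sd = if (length(pct_by_group) > 1) stats::sd(pct_by_group) else
      NA_real_,
    length_mean_um = lm_[1], length_sd_um = lm_[2],
    diameter_mean_nm = dm_[1], diameter_sd_nm = dm_[2]),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_summary> %d intact, %d tubulated ",
                     "(%.1f%%)\n"),
              x$n_intact, x$n_tubulated, x$tubulated_percent))
  if (!is.na(x$length_mean_um))
    cat(sprintf("  tubules: length %.2f +/- %.2f um, diameter %.0f +/- %.0f nm\n",
                x$length_mean_um, x$length_sd_um, x$diameter_mean_nm,
                x$diameter_sd_nm))
  invisible(x)
}
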