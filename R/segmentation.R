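# Threshold segmentation: per-axial-slice iso-contours (marching squares
# with linear interpolation) produce the boundary point cloud to which
# surface models are fitted.  No hole filling or morphology is applied;
# regularization is the registration's job.

#' Point cloud container
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param source_threshold grayscale threshold the cloud was extracted at.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, source_threshold = NA_real_) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  structure(list(points = points, source_threshold = source_threshold),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points (threshold %s)\n", nrow(x$points),
              format(x$source_threshold)))
  invisible(x)
}

#' Extract an iso-threshold boundary cloud from a volume
#'
#' Runs marching squares (with linear interpolation) at the given grayscale
#' threshold on every axial slice and collects the contour vertices in world
#' millimetre coordinates.  Structures other than the target surface are
#' captured too, and boundary stretches whose contrast falls below the
#' threshold are lost; downstream registration must tolerate both.
#'
#' @param vol a `ct_volume`.
#' @param threshold grayscale value within the volume's intensity range.
#' @param roi optional crop box: list with `lo` and `hi` 3-vectors (mm), or
#'   a 2 x 3 matrix `rbind(lo, hi)`.
#' @return A `point_cloud`.
#' @export
extract_threshold_cloud <- function(vol, threshold, roi = NULL) {
  rng <- range(vol$data)
  if (threshold < rng[1] || threshold > rng[2])
    stop(sprintf("empty cloud: threshold %g outside intensity range [%g, %g]",
                 threshold, rng[1], rng[2]))
  ax <- volume_axes(vol)
  d <- dim(vol$data)
  pts <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    sl <- vol$data[, , k]
    if (min(sl) >= threshold || max(sl) <= threshold) next
    cl <- contourLines(ax[[1]], ax[[2]], sl, levels = threshold)
    if (length(cl) == 0) next
    xy <- do.call(rbind, lapply(cl, function(c) cbind(c$x, c$y)))
    pts[[k]] <- cbind(xy, ax[[3]][k])
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0)
    stop(sprintf("empty cloud: no iso-contours at threshold %g", threshold))
  cloud <- point_cloud(pts, threshold)
  if (!is.null(roi)) cloud <- crop_cloud(cloud, roi)
  if (nrow(cloud$points) < 3)
    stop(sprintf("empty cloud: fewer than 3 points at threshold %g after crop",
                 threshold))
  cloud
}

#' Crop a point cloud to a box
#'
#' @param cloud a `point_cloud`.
#' @param roi list with `lo`, `hi` (mm) or a 2 x 3 matrix.
#' @export
crop_cloud <- function(cloud, roi) {
  if (is.matrix(roi)) roi <- list(lo = roi[1, ], hi = roi[2, ])
  p <- cloud$points
  keep <- p[, 1] >= roi$lo[1] & p[, 1] <= roi$hi[1] &
          p[, 2] >= roi$lo[2] & p[, 2] <= roi$hi[2] &
          p[, 3] >= roi$lo[3] & p[, 3] <= roi$hi[3]
  cloud$points <- p[keep, , drop = FALSE]
  cloud
}

# Default ROI: bounding box of the landmark-aligned template, dilated.
template_roi <- function(aligned_vertices, dilate = 2) {
  list(lo = apply(aligned_vertices, 2, min) - dilate,
       hi = apply(aligned_vertices, 2, max) + dilate)
}
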