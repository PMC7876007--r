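# Clinically relevant cochlear measurements on the outer-wall contour:
# reach, outer-wall duct length, basal-plane non-planarity and vertical
# trajectories.  All operate on ordered 3-D polylines; the same definitions
# serve the dense analytic ground-truth curves and the 101-point contours
# traced on fitted surfaces.

.row_norms <- function(m) sqrt(rowSums(m^2))

# Cumulative turning angle (degrees) of an ordered polyline: the running sum
# of angles between consecutive tangent segments, starting at the round
# window end (index 1).  Points 1 and 2 have zero cumulative turning.
cumulative_turning <- function(pts) {
  seg <- diff(pts)
  len <- .row_norms(seg)
  if (any(len == 0)) {
    keep <- len > 0
    seg <- seg[keep, , drop = FALSE]
    len <- len[keep]
  }
  t <- seg / len
  n <- nrow(t)
  if (n < 2) return(rep(0, nrow(pts)))
  d <- rowSums(t[-n, , drop = FALSE] * t[-1, , drop = FALSE])
  ang <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  c(0, 0, cumsum(ang))[seq_len(nrow(pts))]
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to the
#' points (smallest principal direction of the centred point set).  The
#' normal is oriented so that `orient_toward` (when given) has positive
#' signed height.
#'
#' @param points n x 3 matrix, n >= 3 and non-collinear.
#' @param orient_toward optional 3-vector used to orient the normal.
#' @return list with unit `normal`, `offset` (so the plane is
#'   `dot(normal, x) == offset`), and `rms_residual` (mm).
#' @export
fit_basal_plane <- function(points, orient_toward = NULL) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 3)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(1, sv$d[1]))
    stop("degenerate plane: points are collinear")
  n <- sv$v[, 3]
  if (!is.null(orient_toward) && sum((orient_toward - ctr) * n) < 0) n <- -n
  h <- as.numeric(X %*% n)
  list(normal = n, offset = sum(n * ctr),
       rms_residual = sqrt(mean(h^2)), centroid = ctr)
}

# Core measurement routine for an ordered outer-wall polyline running from
# the round window (row 1) to the apex (last row).
measure_polyline <- function(pts, window_deg = 270) {
  pts <- as.matrix(pts)
  seg_len <- .row_norms(diff(pts))
  cum_turn <- cumulative_turning(pts)
  total_turn <- cum_turn[length(cum_turn)]
  if (total_turn < window_deg)
    stop(sprintf("insufficient coiling: total turning %.1f deg < window %.1f deg",
                 total_turn, window_deg))
  k <- max(which(cum_turn <= window_deg))
  win <- pts[1:k, , drop = FALSE]
  plane <- fit_basal_plane(win, orient_toward = pts[nrow(pts), ])
  h_all <- as.numeric(sweep(pts, 2, plane$centroid) %*% plane$normal)
  list(duct_length = sum(seg_len),
       reach = max(.row_norms(sweep(win, 2, pts[1, ]))),
       non_planarity = mean(abs(h_all[1:k])),
       basal_plane = plane,
       window_end = k,
       cum_turning = cum_turn,
       trajectory = data.frame(turning_deg = cum_turn, height_mm = h_all))
}

#' Outer-wall contour container
#'
#' 101 ordered points along the cochlear lateral wall from the round window
#' (index 1) to the apex (index 101), with per-point cumulative arc length
#' (equal increments by construction) and cumulative turning angle.
#'
#' @param points 101 x 3 matrix (mm).
#' @param total_length arc length (mm) of the traced polyline the points were
#'   resampled from; defaults to the chord length of `points`.
#' @return An object of class `outer_wall_contour`.
#' @export
outer_wall_contour <- function(points, total_length = NULL) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == 101, ncol(points) == 3, all(is.finite(points)))
  if (is.null(total_length)) total_length <- sum(.row_norms(diff(points)))
  structure(list(points = points,
                 cum_arc_length = seq(0, total_length, length.out = 101),
                 cum_turning_angle = cumulative_turning(points)),
            class = "outer_wall_contour")
}

#' @export
print.outer_wall_contour <- function(x, ...) {
  cat(sprintf("<outer_wall_contour> 101 points, length %.2f mm, total turning %.0f deg\n",
              max(x$cum_arc_length), max(x$cum_turning_angle)))
  invisible(x)
}

# Resample an ordered polyline to n points at equal arc-length intervals.
resample_polyline <- function(pts, n = 101) {
  pts <- as.matrix(pts)
  s <- c(0, cumsum(.row_norms(diff(pts))))
  keep <- c(TRUE, diff(s) > 0)
  pts <- pts[keep, , drop = FALSE]; s <- s[keep]
  si <- seq(0, s[length(s)], length.out = n)
  out <- sapply(1:3, function(c) approx(s, pts[, c], xout = si)$y)
  list(points = out, total_length = s[length(s)])
}

#' Indices of the basal turning-angle window
#'
#' Returns the contiguous range of contour points whose cumulative turning
#' angle (summed over consecutive tangent segments from the round window)
#' does not exceed `window_deg`.
#'
#' @param contour an `outer_wall_contour`.
#' @param window_deg window size in degrees (default 270, the basal turn
#'   range where most insertion trauma occurs).
#' @return integer vector of point indices.
#' @export
turning_angle_window <- function(contour, window_deg = 270) {
  ct <- contour$cum_turning_angle
  if (window_deg <= 0) stop("window must be positive")
  if (max(ct) < window_deg)
    stop(sprintf("insufficient coiling: total turning %.1f deg < window %.1f deg",
                 max(ct), window_deg))
  seq_len(max(which(ct <= window_deg)))
}

#' Non-planarity of the basal turn
#'
#' Mean absolute distance between the first `window_deg` of the outer-wall
#' contour and its total-least-squares basal plane (mm).
#'
#' @inheritParams turning_angle_window
#' @export
non_planarity <- function(contour, window_deg = 270) {
  measure_polyline(contour$points, window_deg)$non_planarity
}

#' Cochlear reach
#'
#' Maximum distance from the round window to any point within the first
#' `window_deg` of the outer-wall contour (mm); comparable to the clinical
#' A-value.
#'
#' @inheritParams turning_angle_window
#' @export
reach <- function(contour, window_deg = 270) {
  idx <- turning_angle_window(contour, window_deg)
  max(.row_norms(sweep(contour$points[idx, , drop = FALSE], 2,
                       contour$points[1, ])))
}

#' Outer-wall cochlear duct length
#'
#' Total polyline arc length of the 101-point contour, round window to apex
#' (mm).
#'
#' @param contour an `outer_wall_contour`.
#' @export
duct_length <- function(contour) {
  sum(.row_norms(diff(contour$points)))
}

#' Vertical trajectory in basal-plane coordinates
#'
#' Per-point (cumulative turning angle, signed height above the basal plane)
#' pairs over the whole contour.  Heights are signed along the plane normal,
#' oriented so the apex is positive.
#'
#' @param contour an `outer_wall_contour`.
#' @param plane optional basal plane (as returned by [fit_basal_plane()]);
#'   fitted to the 270 degree window when omitted.
#' @export
vertical_trajectory <- function(contour, plane = NULL) {
  if (is.null(plane)) {
    idx <- turning_angle_window(contour, 270)
    plane <- fit_basal_plane(contour$points[idx, , drop = FALSE],
                             orient_toward = contour$points[101, ])
  }
  h <- as.numeric(contour$points %*% plane$normal) - plane$offset
  data.frame(turning_deg = contour$cum_turning_angle, height_mm = h)
}

#' Full measurement report for a contour
#'
#' @param contour an `outer_wall_contour`.
#' @param window_deg basal window in degrees.
#' @return list with `non_planarity`, `reach`, `duct_length` (mm) and the
#'   vertical `trajectory` data frame.
#' @export
measurement_report <- function(contour, window_deg = 270) {
  m <- measure_polyline(contour$points, window_deg)
  list(non_planarity = m$non_planarity, reach = m$reach,
       duct_length = m$duct_length, trajectory = m$trajectory)
}
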