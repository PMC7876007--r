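# Synthetic cochlea phantoms: a logarithmic-spiral duct of ~2.5 turns with
# controllable size, taper and vertical profile, plus a canal-like torus-arc
# appendage carrying the canal-bifurcation landmark.  Every specimen shares
# one vertex topology (same angular sampling), giving native vertex
# correspondence across a cohort.

#' Phantom parameters
#'
#' Parameters of a synthetic cochlea specimen.  The outer (lateral) wall
#' follows the logarithmic spiral `R(theta) = spiral_scale * exp(-decay_rate
#' * theta)` and the duct is a tube of geometrically tapering radius swept
#' along the spiral, with a cubic vertical profile `z(theta)` that starts at
#' zero with slope `base_slope` and rises to `height` at the apex
#' (`base_slope < 0` produces the down-then-up "rollercoaster" shapes).
#'
#' @param spiral_scale outer-wall radius at the round window (mm).
#' @param decay_rate spiral radius decay per radian (dimensionless).
#' @param total_turn total coiling (radians; default 2.5 turns).
#' @param height_profile named vector `c(height, base_slope, apex_slope,
#'   ripple_amp, ripple_freq)`: total rise (mm), initial and apex slopes
#'   (mm/radian), and the amplitude (mm) and angular frequency (1/radian) of
#'   a slow vertical undulation, decaying towards the apex, superimposed on
#'   the cubic trend.  The
#'   undulation is what makes the basal turn genuinely non-planar (a smooth
#'   cubic trend is largely absorbed by the best-fit basal plane); a zero
#'   vector gives a planar spiral.
#' @param duct_radius named vector `c(base, apex)`: tube radius at the two
#'   ends (mm), `base >= apex`.
#' @param ellipticity vector `c(amp, phase)`: relative amplitude and phase
#'   (radians) of an elliptic modulation `1 + amp * cos(2 theta + phase)` of
#'   the spiral radius, emulating the elliptic basal turn of real cochleae;
#'   gives reach a component independent of overall size.
#' @param harmonics optional idiosyncratic shape detail: a list with `freq`
#'   (integer vector of angular frequencies) and 2 x length(freq) coefficient
#'   matrices `radial` (mm, added to the spiral radius) and `vertical` (mm,
#'   added to the height with an apex decay), rows = cosine/sine.  Real
#'   cochleae carry individual wall detail that no low-dimensional family
#'   reproduces; these harmonics give every specimen high-dimensional
#'   identity, which is what makes a leave-one-out shape model genuinely
#'   unable to span a held-out specimen.
#' @param side `"left"` or `"right"` (chirality; left mirrors x).
#' @param canal_offset 3-vector: centre of the canal torus arc (mm).
#' @param rng_seed integer seed recorded with the specimen.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(spiral_scale = 5.4, decay_rate = 0.103,
                           total_turn = 2.45 * 2 * pi,
                           height_profile = c(height = 2.4, base_slope = -0.05,
                                              apex_slope = NA,
                                              ripple_amp = 0.80,
                                              ripple_freq = 1.55),
                           duct_radius = c(base = 0.78, apex = 0.46),
                           ellipticity = c(amp = 0, phase = 0),
                           harmonics = NULL,
                           side = c("right", "left"),
                           canal_offset = c(-3.2, -2.8, 4.2),
                           rng_seed = 1L) {
  side <- match.arg(side)
  if (!is.finite(total_turn) || total_turn <= 0)
    stop("total_turn must be positive")
  hp <- as.numeric(height_profile)
  defaults <- c(0, 0, NA, 0, 1.5)
  if (length(hp) < 5) hp <- c(hp, defaults[(length(hp) + 1):5])
  if (is.na(hp[3])) hp[3] <- 1.5 * hp[1] / total_turn
  names(hp) <- c("height", "base_slope", "apex_slope", "ripple_amp",
                 "ripple_freq")
  dr <- as.numeric(duct_radius)
  names(dr) <- c("base", "apex")
  el <- as.numeric(ellipticity)
  if (length(el) < 2) el <- c(el, 0)
  names(el) <- c("amp", "phase")
  p <- structure(list(spiral_scale = spiral_scale, decay_rate = decay_rate,
                      total_turn = total_turn, height_profile = hp,
                      duct_radius = dr, ellipticity = el,
                      harmonics = harmonics, side = side,
                      canal_offset = as.numeric(canal_offset),
                      rng_seed = as.integer(rng_seed)),
                 class = "phantom_params")
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  num <- c(p$spiral_scale, p$decay_rate, p$total_turn, p$height_profile,
           p$duct_radius, p$canal_offset)
  if (!all(is.finite(num))) stop("non-finite phantom parameter")
  if (p$spiral_scale <= 0) stop("spiral_scale must be positive")
  if (p$total_turn <= 0) stop("total_turn must be positive")
  if (p$decay_rate < 0) stop("decay_rate must be non-negative")
  if (any(p$duct_radius <= 0)) stop("duct radii must be positive")
  if (p$duct_radius["base"] < p$duct_radius["apex"])
    stop("duct base radius must be >= apex radius")
  if (p$ellipticity["amp"] < 0 || p$ellipticity["amp"] > 0.2)
    stop("ellipticity amplitude must be in [0, 0.2]")
  if (!is.null(p$harmonics)) {
    h <- p$harmonics
    if (!all(is.finite(h$freq)) || !all(is.finite(h$radial)) ||
        !all(is.finite(h$vertical)))
      stop("non-finite phantom parameter")
  }
  invisible(p)
}

# --- analytic geometry ------------------------------------------------------

# Outer-wall radius, duct radius and height as functions of theta.
.spiral_R <- function(p, th) {
  e <- if (is.null(p$ellipticity)) c(0, 0) else p$ellipticity
  R <- p$spiral_scale * exp(-p$decay_rate * th) *
    (1 + unname(e[1]) * cos(2 * th + unname(e[2])))
  h <- p$harmonics
  if (!is.null(h))
    for (j in seq_along(h$freq))
      R <- R + h$radial[1, j] * cos(h$freq[j] * th) +
               h$radial[2, j] * sin(h$freq[j] * th)
  R
}
.duct_rho <- function(p, th) {
  b <- p$duct_radius["base"]; a <- p$duct_radius["apex"]
  unname(b * (a / b)^(th / p$total_turn))
}
.height_z <- function(p, th) {
  H <- p$height_profile["height"]; s0 <- p$height_profile["base_slope"]
  sA <- p$height_profile["apex_slope"]; T <- p$total_turn
  ra <- p$height_profile["ripple_amp"]; rf <- p$height_profile["ripple_freq"]
  # cubic trend z = s0 t + a2 t^2 + a3 t^3 with z(T) = H, z'(T) = sA,
  # plus a slow vertical undulation that the basal plane cannot absorb
  A <- matrix(c(T^2, T^3, 2 * T, 3 * T^2), 2, 2, byrow = TRUE)
  ab <- solve(A, c(H - s0 * T, sA - s0))
  z <- s0 * th + ab[1] * th^2 + ab[2] * th^3 +
       ra * sin(rf * th) * exp(-th / 3)
  h <- p$harmonics
  if (!is.null(h))
    for (j in seq_along(h$freq))
      z <- z + (h$vertical[1, j] * cos(h$freq[j] * th) +
                h$vertical[2, j] * sin(h$freq[j] * th)) * exp(-th / 3)
  unname(z)
}

# Analytic outer-wall curve: the laterally extremal locus of the swept tube.
# Cross-sections are circles in the (radial, vertical) plane, so the point
# farthest from the coiling axis at angle theta is exactly at the outer-wall
# spiral radius R(theta).
outer_wall_curve <- function(p, th) {
  R <- .spiral_R(p, th)
  cbind(R * cos(th), R * sin(th), .height_z(p, th))
}

.centerline <- function(p, th) {
  rc <- .spiral_R(p, th) - .duct_rho(p, th)
  cbind(rc * cos(th), rc * sin(th), .height_z(p, th))
}

# --- meshing ----------------------------------------------------------------

# Tube swept along rings: centers k x 3, two unit frame vectors per ring
# (n1 k x 3, n2 k x 3), per-ring radius.  Capped with a fan at both ends.
# aspect < 1 flattens the cross-section along n2 (the cochlear duct is oval,
# not circular; the asymmetry also keeps surface registration from rolling
# the tube about its own centreline).
tube_mesh_parts <- function(centers, n1, n2, radii, n_phi, aspect = 1) {
  k <- nrow(centers)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  V <- matrix(0, k * n_phi + 2, 3)
  for (j in seq_len(k)) {
    ring <- centers[rep(j, n_phi), ] +
      outer(cos(phi), radii[j] * n1[j, ]) +
      outer(sin(phi), aspect * radii[j] * n2[j, ])
    V[(j - 1) * n_phi + seq_len(n_phi), ] <- ring
  }
  V[k * n_phi + 1, ] <- centers[1, ]
  V[k * n_phi + 2, ] <- centers[k, ]
  idx <- function(i, j) (j - 1) * n_phi + ((i - 1) %% n_phi) + 1
  F <- matrix(0L, (k - 1) * n_phi * 2 + 2 * n_phi, 3)
  r <- 0L
  for (j in seq_len(k - 1))
    for (i in seq_len(n_phi)) {
      F[r + 1L, ] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      F[r + 2L, ] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
      r <- r + 2L
    }
  for (i in seq_len(n_phi)) {
    F[r + 1L, ] <- c(k * n_phi + 1L, idx(i + 1, 1), idx(i, 1))
    F[r + 2L, ] <- c(k * n_phi + 2L, idx(i, k), idx(i + 1, k))
    r <- r + 2L
  }
  list(V = V, F = F)
}

# Sampling densities shared by all specimens (native correspondence).
.phantom_mesh_n <- list(duct_rings = 141, duct_phi = 14, flare_rings = 12,
                        canal_rings = 25, canal_phi = 8)

# The duct continues 0.6 rad beyond the round window with a flaring radius,
# emulating the widening where the basal turn joins the vestibule.  The
# flare anchors the basal end of the template during fitting; the measured
# outer-wall curve still starts at theta = 0.
.flare_ext <- 0.6
.flare_gain <- 1.4
# quadratic widening: C1-smooth at the round-window junction so the blur
# of clinical-resolution reconstruction has no crease to round off there
.flare_factor <- function(th) 1 + .flare_gain * pmax(0, -th)^2

.build_phantom_mesh <- function(p) {
  n <- .phantom_mesh_n
  th <- c(seq(-.flare_ext, 0, length.out = n$flare_rings + 1)[1:n$flare_rings],
          seq(0, p$total_turn, length.out = n$duct_rings))
  ctr <- .centerline(p, pmax(th, 0))
  # continue the spiral backwards for the flare segment
  neg <- th < 0
  if (any(neg)) {
    Rn <- .spiral_R(p, th[neg])
    rcn <- Rn - .duct_rho(p, 0)
    ctr[neg, ] <- cbind(rcn * cos(th[neg]), rcn * sin(th[neg]),
                        .height_z(p, 0) + p$height_profile["base_slope"] * th[neg])
  }
  rho <- .duct_rho(p, pmax(th, 0)) * .flare_factor(th)
  er <- cbind(cos(th), sin(th), 0)
  ez <- matrix(rep(c(0, 0, 1), each = length(th)), ncol = 3)
  duct <- tube_mesh_parts(ctr, er, ez, rho, n$duct_phi, aspect = 0.85)
  # canal-like torus arc; its far end is the canal-bifurcation landmark.
  # The canal co-scales with the cochlea so the whole capsule is
  # size-consistent under a single similarity transform.
  sf <- p$spiral_scale / 5.4
  psi <- seq(-95, 95, length.out = n$canal_rings) * pi / 180
  arc_R <- 2.5 * sf; tube_r <- 0.45 * sf
  cc <- p$canal_offset * sf
  n1 <- cbind(cos(psi), 0, sin(psi))
  cctr <- matrix(cc, length(psi), 3, byrow = TRUE) + arc_R * n1
  n2 <- matrix(rep(c(0, 1, 0), each = length(psi)), ncol = 3)
  canal <- tube_mesh_parts(cctr, n1, n2, rep(tube_r, length(psi)), n$canal_phi)
  V <- rbind(duct$V, canal$V)
  F <- rbind(duct$F, canal$F + nrow(duct$V))
  tip <- cc + arc_R * c(cos(psi[length(psi)]), 0, sin(psi[length(psi)]))
  m <- trimesh(V, F)
  if (mesh_volume(m) < 0) m <- flip_faces(m)
  list(mesh = m, canal_tip = tip)
}

# Guard against self-intersecting tube configurations (consecutive turns or
# canal touching the duct), which would corrupt voxel parity.
.check_clearance <- function(p) {
  th <- seq(-.flare_ext, p$total_turn, length.out = 400)
  ctr <- .centerline(p, pmax(th, 0))
  neg <- th < 0
  if (any(neg)) {
    Rn <- .spiral_R(p, th[neg])
    ctr[neg, ] <- cbind((Rn - .duct_rho(p, 0)) * cos(th[neg]),
                        (Rn - .duct_rho(p, 0)) * sin(th[neg]),
                        .height_z(p, 0) + p$height_profile["base_slope"] * th[neg])
  }
  rho <- .duct_rho(p, pmax(th, 0)) * .flare_factor(th)
  dth <- abs(outer(th, th, "-"))
  D <- as.matrix(dist(ctr))
  need <- outer(rho, rho, "+")
  sel <- dth >= pi
  if (any(D[sel] < need[sel] + 0.02))
    stop("phantom self-intersects: consecutive turns of the duct touch")
  sf <- p$spiral_scale / 5.4
  psi <- seq(-95, 95, length.out = 50) * pi / 180
  cctr <- matrix(p$canal_offset * sf, length(psi), 3, byrow = TRUE) +
    2.5 * sf * cbind(cos(psi), 0, sin(psi))
  D2 <- sqrt(outer(rowSums(cctr^2), rep(1, nrow(ctr))) -
             2 * cctr %*% t(ctr) +
             outer(rep(1, nrow(cctr)), rowSums(ctr^2)))
  gap <- sweep(D2, 2, rho + 0.45 * sf)
  if (min(gap) < 0.03)
    stop("phantom self-intersects: canal arc touches the duct")
  invisible(TRUE)
}

#' Generate a synthetic cochlea specimen
#'
#' Builds a watertight tube-around-spiral surface mesh (plus a canal-like
#' appendage) and its analytic ground truth: the dense outer-wall curve, the
#' three registration landmarks, and the gold-standard measurements
#' (non-planarity, reach, duct length) computed from the analytic curve with
#' a dense quadrature sampling of at least 10^4 points.
#'
#' @param params a [phantom_params()] object.
#' @param n_truth number of dense samples of the analytic outer-wall curve.
#' @return list with `mesh` (a `trimesh`), `truth` (ground-truth list) and
#'   `params`.
#' @export
generate_specimen <- function(params = phantom_params(), n_truth = 12001) {
  validate_phantom_params(params)
  .check_clearance(params)
  built <- .build_phantom_mesh(params)
  mesh <- built$mesh
  th <- seq(0, params$total_turn, length.out = n_truth)
  # resample the analytic curve at equal arc-length intervals: the
  # measurement definitions weight the contour uniformly in arc length
  curve <- resample_polyline(outer_wall_curve(params, th), n_truth)$points
  th_ow <- 0.55
  landmarks <- list(
    apex = as.numeric(curve[n_truth, ]),
    oval_window = as.numeric(.centerline(params, th_ow)) +
      c(0, 0, .duct_rho(params, th_ow)),
    canal_bifurcation = as.numeric(built$canal_tip))
  round_window <- as.numeric(curve[1, ])
  axis <- c(0, 0, 1)
  if (params$side == "left") {
    M <- diag(c(-1, 1, 1))
    mesh$vertices <- mesh$vertices %*% M
    mesh <- flip_faces(mesh)
    curve <- curve %*% M
    landmarks <- lapply(landmarks, function(v) as.numeric(v %*% M))
    round_window <- as.numeric(round_window %*% M)
  }
  meas <- measure_polyline(curve, window_deg = 270)
  truth <- list(centerline = curve,
                non_planarity = meas$non_planarity,
                reach = meas$reach,
                duct_length = meas$duct_length,
                landmarks = landmarks,
                round_window = round_window,
                coiling_axis = axis,
                side = params$side)
  structure(list(mesh = mesh, truth = truth, params = params),
            class = "otic_specimen")
}

#' @export
print.otic_specimen <- function(x, ...) {
  cat(sprintf("<otic_specimen> %s side; duct length %.2f mm, reach %.2f mm, non-planarity %.3f mm\n",
              x$truth$side, x$truth$duct_length, x$truth$reach,
              x$truth$non_planarity))
  invisible(x)
}

#' Apply a rigid transform to a specimen
#'
#' Moves the mesh, ground-truth curve and landmarks into a new pose.  Scalar
#' ground-truth measurements are invariant and are carried over (for
#' non-rigid similarity transforms they scale with the transform).
#'
#' @param spec an `otic_specimen`.
#' @param tf a `similarity_transform`.
#' @export
transform_specimen <- function(spec, tf) {
  spec$mesh <- apply_transform(tf, spec$mesh)
  if (tf$reflect) spec$mesh <- flip_faces(spec$mesh)
  spec$truth$centerline <- apply_transform(tf, spec$truth$centerline)
  spec$truth$landmarks <- lapply(spec$truth$landmarks,
                                 function(v) as.numeric(apply_transform(tf, v)))
  spec$truth$round_window <- as.numeric(apply_transform(tf, spec$truth$round_window))
  ax <- tf$rotation %*% (if (tf$reflect) .mirror3 %*% spec$truth$coiling_axis
                         else spec$truth$coiling_axis)
  spec$truth$coiling_axis <- as.numeric(ax)
  for (f in c("non_planarity", "reach", "duct_length"))
    spec$truth[[f]] <- spec$truth[[f]] * tf$scale
  spec
}

#' Sample a phantom cohort
#'
#' Draws `n` specimens with independent parameter draws from documented
#' uniform ranges chosen so that cohort duct length spans several
#' millimetres, and places each specimen in a random rigid pose (rotation up
#' to 20 degrees, translation up to 3 mm per axis).
#'
#' @param n cohort size (>= 2).
#' @param seed integer seed; identical seeds reproduce the cohort exactly.
#' @param pose logical; apply random rigid poses (default TRUE).
#' @return list of `otic_specimen` objects.
#' @export
sample_cohort <- function(n = 18, seed = 1L, pose = TRUE) {
  if (n < 2) stop("cohort size must be at least 2")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    # draw every parameter in a fixed order before constructing, so the
    # RNG stream does not depend on the constructor's evaluation order
    scale_i <- runif(1, 5.0, 5.8)
    decay_i <- runif(1, 0.088, 0.118)
    turn_i <- runif(1, 2.30, 2.60) * 2 * pi
    hp_i <- c(height = runif(1, 2.0, 2.8),
              base_slope = runif(1, -0.25, 0.15),
              apex_slope = NA,
              ripple_amp = runif(1, 0.20, 1.40),
              ripple_freq = runif(1, 1.3, 1.8))
    dr_i <- c(base = runif(1, 0.72, 0.84), apex = runif(1, 0.42, 0.50))
    el_i <- c(amp = runif(1, 0, 0.05), phase = runif(1, 0, 2 * pi))
    freq <- 3:8
    harm_i <- list(freq = freq,
                   radial = rbind(rnorm(6, 0, 0.03 * 3 / freq),
                                  rnorm(6, 0, 0.03 * 3 / freq)),
                   vertical = rbind(rnorm(6, 0, 0.04 * 3 / freq),
                                    rnorm(6, 0, 0.04 * 3 / freq)))
    side_i <- sample(c("left", "right"), 1)
    p <- phantom_params(
      spiral_scale = scale_i, decay_rate = decay_i, total_turn = turn_i,
      height_profile = hp_i, duct_radius = dr_i, ellipticity = el_i,
      harmonics = harm_i, side = side_i, rng_seed = seed + i)
    spec <- generate_specimen(p)
    if (pose) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- runif(1, 0, 20) * pi / 180
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      tf <- similarity_transform(R, 1, runif(3, -3, 3))
      spec <- transform_specimen(spec, tf)
    }
    spec
  })
}
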