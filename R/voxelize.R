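# Rasterization of closed surface meshes into intensity volumes, with
# partial-volume smoothing through a signed-distance ramp one voxel wide.

# Signed distance (negative inside) of every voxel centre to a closed mesh,
# exact within +/- exact_band of the surface, chamfer-propagated out to
# band and clamped beyond.
signed_distance_volume <- function(mesh, spacing, origin, dim, band,
                                   exact_band = band) {
  sdf <- cpp_signed_distance_grid(mesh$vertices, mesh$faces,
                                  as.integer(dim), as.numeric(origin),
                                  spacing, band, exact_band)
  ct_volume(sdf, spacing, origin)
}

.grid_for_mesh <- function(mesh, spacing, margin) {
  lo <- apply(mesh$vertices, 2, min) - margin
  hi <- apply(mesh$vertices, 2, max) + margin
  dim <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(origin = lo, dim = dim)
}

#' Voxelize a closed mesh into an intensity volume
#'
#' Produces a scalar volume whose iso-surface at the mid intensity lies on
#' the input mesh, with partial-volume smoothing via a signed-distance ramp
#' one voxel wide: voxels deeper than half a voxel inside get
#' `intensities["inside"]`, voxels farther than half a voxel outside get
#' `intensities["outside"]`, and the transition is linear in signed
#' distance.
#'
#' @param mesh a closed `trimesh` (mm).
#' @param spacing isotropic voxel spacing (mm); must be smaller than the
#'   finest feature of the mesh.
#' @param intensities named vector `c(inside, outside)` on the working
#'   grayscale (default 230 bone inside, 20 air outside).
#' @param margin padding around the mesh bounding box (mm).
#' @param origin,dim optional explicit grid (world origin of first voxel
#'   centre, and integer dimensions); derived from the mesh otherwise.
#' @return A `ct_volume`.
#' @export
voxelize <- function(mesh, spacing, intensities = c(inside = 230, outside = 20),
                     margin = 3 * spacing, origin = NULL, dim = NULL) {
  stopifnot(spacing > 0)
  bbox <- apply(mesh$vertices, 2, range)
  if (spacing > min(bbox[2, ] - bbox[1, ]) / 2)
    stop("degenerate resolution: spacing larger than the mesh extent")
  if (is.null(origin) || is.null(dim)) {
    g <- .grid_for_mesh(mesh, spacing, margin)
    origin <- g$origin; dim <- g$dim
  }
  sdf <- signed_distance_volume(mesh, spacing, origin, dim, band = 1.5 * spacing)
  frac <- pmin(1, pmax(0, 0.5 - sdf$data / spacing))
  vol <- intensities[["outside"]] +
    (intensities[["inside"]] - intensities[["outside"]]) * frac
  ct_volume(array(vol, dim), spacing, origin)
}

#' Micro-CT-like phantom volume
#'
#' Renders a specimen mesh as a three-zone intensity volume emulating a
#' high-resolution scan of the otic capsule: duct lumen inside the surface,
#' a bone shell of thickness `wall` outside it, and air beyond, each
#' transition smoothed by a one-voxel signed-distance ramp.  On the default
#' 0--255 scale the bone/lumen boundary (the capsule surface being fitted)
#' crosses the mid grayscale 160, so segmentation thresholds of 160--180
#' bracket the capsule boundary within a fraction of a voxel.
#'
#' @param spec an `otic_specimen` (or a `trimesh`).
#' @param spacing isotropic voxel spacing (mm; default 0.05 emulating
#'   micro-CT at synthetic-tractable resolution).
#' @param intensities named vector `c(bone, lumen, air)`.
#' @param wall bone shell thickness (mm).
#' @param margin padding around the mesh bounding box (mm).
#' @return A `ct_volume`.
#' @export
phantom_volume <- function(spec, spacing = 0.05,
                           intensities = c(bone = 230, lumen = 90, air = 20),
                           wall = 1.5, margin = wall + 0.8) {
  mesh <- if (inherits(spec, "trimesh")) spec else spec$mesh
  if (spacing > min(.duct_radius_of(spec)))
    stop("degenerate resolution: spacing exceeds the minimum duct radius")
  g <- .grid_for_mesh(mesh, spacing, margin)
  # exact distances matter only across the capsule-surface ramp; the outer
  # bone/air boundary tolerates chamfer-accurate distances
  sdf <- signed_distance_volume(mesh, spacing, g$origin, g$dim,
                                band = wall + 2 * spacing,
                                exact_band = 2 * spacing)$data
  ramp <- function(s) pmin(1, pmax(0, 0.5 - s / spacing))
  inner <- ramp(sdf)                        # 1 in lumen, 0 in bone/air
  outer <- ramp(sdf - wall)                 # 1 within the bone shell
  vol <- intensities[["air"]] +
    (intensities[["bone"]] - intensities[["air"]]) * outer +
    (intensities[["lumen"]] - intensities[["bone"]]) * inner
  ct_volume(array(vol, g$dim), spacing, g$origin)
}

.duct_radius_of <- function(spec) {
  if (inherits(spec, "otic_specimen")) spec$params$duct_radius else 0.4
}
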