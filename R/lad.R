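# Locally affine deformation (LAD): regularized nonrigid refinement after
# similarity ICP.  Each template vertex carries a neighbourhood of vertices
# within distance d; per iteration a least-squares rigid transform is fitted
# over each neighbourhood's vertex/cloud pairs, and every vertex moves to
# the proximity-weighted average of its images under its neighbours'
# transforms.  d is the algorithm's only shape parameter: small d permits
# local deformation, large d approaches a single global rigid fit.

#' LAD configuration
#'
#' @param d neighbourhood radius in mm (default 5, a high degree of
#'   regularization suited to low-resolution noisy data; use smaller values
#'   for clean high-resolution volumes).
#' @param iters iteration budget (default 50).
#' @param trim_factor drop vertex/cloud pairs farther than this multiple of
#'   the median pair distance (default 3).
#' @param tol early-stop tolerance on the mean vertex step (mm).
#' @return An object of class `lad_config`.
#' @export
lad_config <- function(d = 5, iters = 50, trim_factor = 3, tol = 1e-9) {
  stopifnot(d > 0, iters >= 1, trim_factor > 0)
  structure(list(d = d, iters = iters, trim_factor = trim_factor, tol = tol),
            class = "lad_config")
}

#' Locally affine deformation fit
#'
#' Nonrigid refinement of a pre-aligned template mesh to a boundary point
#' cloud.  Neighbourhoods are Euclidean balls of radius `cfg$d` in the
#' current (deformed) configuration, recomputed every iteration; blending
#' weights are a truncated Gaussian `exp(-r^2 / (d/2)^2)` over the
#' neighbourhood.  Vertices with fewer than 3 surviving neighbour pairs fall
#' back to the nearest vertex's transform (counted in `fallbacks`).
#'
#' @param mesh a `trimesh`, already similarity-aligned to the cloud.
#' @param cloud a `point_cloud` or m x 3 matrix.
#' @param cfg a [lad_config()].
#' @return A `deformed_mesh`: list with `base` (input mesh), `mesh` (fitted
#'   mesh), `displacement` (per-vertex mm offsets), `iterations`,
#'   `fallbacks` and the `mean_pair_distance` trace.
#' @export
lad_fit <- function(mesh, cloud, cfg = lad_config()) {
  stopifnot(inherits(mesh, "trimesh"), inherits(cfg, "lad_config"))
  P <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(P) == 0) stop("empty cloud")
  res <- cpp_lad_fit(mesh$vertices, P, cfg$d, cfg$iters, cfg$trim_factor,
                     cfg$tol)
  fitted <- trimesh(res$vertices, mesh$faces)
  structure(list(base = mesh, mesh = fitted,
                 displacement = res$vertices - mesh$vertices,
                 iterations = res$iterations, fallbacks = res$fallbacks,
                 mean_pair_distance = res$mean_pair_distance),
            class = "deformed_mesh")
}

#' @export
print.deformed_mesh <- function(x, ...) {
  cat(sprintf("<deformed_mesh> %d vertices; mean |displacement| %.4f mm (%d iterations)\n",
              nrow(x$mesh$vertices), mean(sqrt(rowSums(x$displacement^2))),
              x$iterations))
  invisible(x)
}

#' Deformation energy of a displacement field
#'
#' Sum of squared displacement differences across mesh edges; a smoothness
#' measure that decreases as the neighbourhood radius d grows.
#'
#' @param deformed a `deformed_mesh`.
#' @export
deformation_energy <- function(deformed) {
  e <- mesh_edges(deformed$base)
  du <- deformed$displacement[e[, 1], , drop = FALSE] -
        deformed$displacement[e[, 2], , drop = FALSE]
  sum(du^2)
}
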