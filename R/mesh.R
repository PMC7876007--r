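#' Triangulated surface mesh
#'
#' Lightweight container for a triangle mesh in world millimetre
#' coordinates: an n x 3 vertex matrix and an m x 3 face matrix of 1-based
#' vertex indices.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix, 1-based.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            all(is.finite(vertices)),
            min(faces) >= 1, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Area-weighted vertex normals
#'
#' @param mesh a `trimesh`.
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  N <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, c], F[, k])
      N[as.integer(rownames(acc)), c] <- N[as.integer(rownames(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

# Unique undirected edges as a 2-column index matrix.
mesh_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Signed volume via divergence theorem; positive for outward orientation.
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c3 <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# Flip face orientation.
flip_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

mesh_diameter <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Distance from points to a mesh surface
#'
#' Exact point-to-triangle distances, with the closest surface point, the
#' triangle hit and its barycentric coordinates.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a `trimesh`.
#' @return list with `distance`, `point`, `triangle`, `bary`.
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- rbind(points)
  cpp_closest_point_mesh(points, mesh$vertices, mesh$faces)
}

# UV-sphere mesh; used for voxelization checks and small examples.
uv_sphere <- function(radius = 1, center = c(0, 0, 0), n_theta = 24, n_phi = 48) {
  th <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]    # exclude poles
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(phi = ph, theta = th)
  V <- cbind(radius * sin(g$theta) * cos(g$phi),
             radius * sin(g$theta) * sin(g$phi),
             radius * cos(g$theta))
  idx <- function(i, j) (j - 1) * n_phi + ((i - 1) %% n_phi) + 1
  F <- NULL
  for (j in seq_len(n_theta - 2))
    for (i in seq_len(n_phi))
      F <- rbind(F,
                 c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                 c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  top <- nrow(V) + 1; bot <- nrow(V) + 2
  V <- rbind(V, c(0, 0, radius), c(0, 0, -radius))
  for (i in seq_len(n_phi)) {
    F <- rbind(F, c(top, idx(i, 1), idx(i + 1, 1)))
    F <- rbind(F, c(bot, idx(i + 1, n_theta - 1), idx(i, n_theta - 1)))
  }
  m <- trimesh(sweep(V, 2, -center), F)
  if (mesh_volume(m) < 0) m <- flip_faces(m)
  m
}
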