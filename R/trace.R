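# Tracing the cochlear outer-wall contour on a surface mesh.  The contour
# passes through the points where the surface normal is perpendicular to
# the coiling axis, on the laterally outward side, running from the round
# window to the apex.  Traced once on a template, the contour is carried
# through any deformation of the same mesh topology as barycentric anchors.

# Dijkstra over an explicit edge list restricted to a vertex subset.
.dijkstra_path <- function(n_vertices, edges, weights, from, to) {
  adj <- vector("list", n_vertices)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, weights[i]))
    adj[[b]] <- rbind(adj[[b]], c(a, weights[i]))
  }
  dist <- rep(Inf, n_vertices); prev <- rep(NA_integer_, n_vertices)
  done <- rep(FALSE, n_vertices)
  dist[from] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || !is.finite(dist[u])) break
    if (u == to) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      alt <- dist[u] + nb[r, 2]
      if (alt < dist[v]) { dist[v] <- alt; prev[v] <- u }
    }
  }
  if (!is.finite(dist[to])) return(NULL)
  path <- to
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path
}

# Interpolated unit normal at a surface point given triangle + barycentrics.
.interp_normal <- function(mesh, normals, tri, bary) {
  f <- mesh$faces[tri, ]
  n <- bary[1] * normals[f[1], ] + bary[2] * normals[f[2], ] +
       bary[3] * normals[f[3], ]
  n / sqrt(sum(n^2))
}

#' Trace the outer-wall contour on a mesh
#'
#' Finds the lateral-wall band (vertices whose normals are nearly
#' perpendicular to the coiling axis), follows it from the round window to
#' the apex along the mesh edge graph, refines every point so the
#' interpolated surface normal is perpendicular to the axis, and resamples
#' the result to 101 points at equal arc-length intervals.
#'
#' @param mesh a `trimesh`.
#' @param apex,round_window 3-D points within about 1 mm of the surface.
#' @param coiling_axis direction of the cochlear coiling axis (need not be
#'   unit length).
#' @param band_tol maximum |normal . axis| for band membership.
#' @param refine number of refinement passes per contour point.
#' @return list with `contour` (an [outer_wall_contour()]), `points` (the
#'   dense traced polyline) and `anchors` (triangle + barycentric
#'   coordinates, usable on any mesh with the same topology via
#'   [contour_from_anchors()]).
#' @export
trace_outer_wall <- function(mesh, apex, round_window, coiling_axis,
                             band_tol = 0.45, refine = 2) {
  if (sqrt(sum(coiling_axis^2)) == 0) stop("coiling axis must be non-zero")
  a <- coiling_axis / sqrt(sum(coiling_axis^2))
  V <- mesh$vertices
  N <- vertex_normals(mesh)
  # lateral band: normal nearly perpendicular to the coiling axis AND
  # pointing outward from the axis line (anchored at the apex).  The
  # outwardness test removes the inner-wall strip and the end-cap centres,
  # which would otherwise offer a shortcut across the spiral; it is relaxed
  # near the axis, where the apex sits and radial directions degenerate.
  rel <- sweep(V, 2, apex)
  axial <- as.numeric(rel %*% a)
  radial <- rel - outer(axial, a)
  rad <- .row_norms(radial)
  outward <- rowSums((radial / pmax(rad, 1e-9)) * N)
  band <- which(abs(as.numeric(N %*% a)) < band_tol &
                !(rad > 1.8 & outward <= 0.15))
  if (length(band) < 10)
    stop("tracing error: no lateral band found on the mesh")
  inband <- logical(nrow(V)); inband[band] <- TRUE
  e <- mesh_edges(mesh)
  e <- e[inband[e[, 1]] & inband[e[, 2]], , drop = FALSE]
  if (nrow(e) == 0) stop("tracing error: lateral band is disconnected")
  w <- .row_norms(V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])
  near <- function(p) band[which.min(.row_norms(sweep(V[band, , drop = FALSE], 2, p)))]
  from <- near(round_window); to <- near(apex)
  path <- .dijkstra_path(nrow(V), e, w, from, to)
  if (is.null(path))
    stop("tracing error: no path from round window to apex along the band")
  pts <- V[path, , drop = FALSE]
  # refine: slide each point along the surface so that normal . axis == 0
  for (pass in seq_len(refine)) {
    pr <- point_mesh_distance(pts, mesh)
    for (i in seq_len(nrow(pts))) {
      p <- pr$point[i, ]
      n <- .interp_normal(mesh, N, pr$triangle[i], pr$bary[i, ])
      g0 <- sum(n * a)
      u <- a - sum(a * n) * n
      ul <- sqrt(sum(u^2))
      if (ul < 1e-8) { pts[i, ] <- p; next }
      u <- u / ul
      delta <- 0.05
      q <- point_mesh_distance(rbind(p + delta * u), mesh)
      n1 <- .interp_normal(mesh, N, q$triangle[1], q$bary[1, ])
      g1 <- sum(n1 * a)
      slope <- (g1 - g0) / delta
      step <- if (abs(slope) > 1e-6) -g0 / slope else 0
      step <- max(-0.3, min(0.3, step))
      moved <- point_mesh_distance(rbind(p + step * u), mesh)
      pts[i, ] <- moved$point[1, ]
    }
  }
  # anchor the endpoints at the annotated apex / round window projections
  ends <- point_mesh_distance(rbind(round_window, apex), mesh)
  pts <- rbind(ends$point[1, ], pts, ends$point[2, ])
  pr <- point_mesh_distance(pts, mesh)
  anchors <- list(triangle = pr$triangle, bary = pr$bary)
  rs <- resample_polyline(pts, 101)
  list(contour = outer_wall_contour(rs$points, rs$total_length),
       points = pts, anchors = anchors)
}

#' Rebuild a contour from template anchors on a deformed mesh
#'
#' Evaluates stored barycentric anchors on a mesh with the same topology
#' (e.g. the template after LAD or SSM fitting) and resamples to the
#' standard 101 points.
#'
#' @param anchors anchor list from [trace_outer_wall()].
#' @param mesh a `trimesh` sharing the template topology.
#' @return An [outer_wall_contour()].
#' @export
contour_from_anchors <- function(anchors, mesh) {
  F <- mesh$faces[anchors$triangle, , drop = FALSE]
  V <- mesh$vertices
  pts <- anchors$bary[, 1] * V[F[, 1], , drop = FALSE] +
         anchors$bary[, 2] * V[F[, 2], , drop = FALSE] +
         anchors$bary[, 3] * V[F[, 3], , drop = FALSE]
  rs <- resample_polyline(pts, 101)
  outer_wall_contour(rs$points, rs$total_length)
}
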