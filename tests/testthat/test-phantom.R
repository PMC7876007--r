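# Phantom generator: analytic ground truth, invariances, cohort statistics
# and voxelization.

test_that("a flat height profile gives zero non-planarity", {
  # a thinner duct keeps the fully planar spiral self-intersection-free
  p <- phantom_params(height_profile = c(0, 0, 0, 0, 1.5),
                      duct_radius = c(base = 0.55, apex = 0.35))
  s <- generate_specimen(p)
  expect_lt(s$truth$non_planarity, 1e-9)
})

test_that("side reflection mirrors the mesh but preserves all measurements", {
  pr <- phantom_params(side = "right")
  pl <- phantom_params(side = "left")
  sr <- generate_specimen(pr); sl <- generate_specimen(pl)
  expect_equal(sl$mesh$vertices, sr$mesh$vertices %*% diag(c(-1, 1, 1)))
  expect_equal(sl$truth$non_planarity, sr$truth$non_planarity, tolerance = 1e-9)
  expect_equal(sl$truth$reach, sr$truth$reach, tolerance = 1e-9)
  expect_equal(sl$truth$duct_length, sr$truth$duct_length, tolerance = 1e-9)
  # both meshes remain outward-oriented
  expect_gt(oticfit:::mesh_volume(sl$mesh), 0)
})

test_that("ground-truth duct length matches an independent quadrature oracle", {
  p <- phantom_params()
  s <- generate_specimen(p)
  f <- function(th) oticfit:::outer_wall_curve(p, th)
  expect_equal(s$truth$duct_length, quad_arc_length(f, 0, p$total_turn, n = 5e4),
               tolerance = 1e-4 * s$truth$duct_length)
})

test_that("ground truth scales linearly and is rigid-invariant", {
  hp <- c(2.4, -0.05, NA, 0.30, 1.55)
  p1 <- phantom_params(height_profile = hp)
  p2 <- phantom_params(spiral_scale = 5.4 * 1.3,
                       height_profile = c(hp[1:2] * 1.3, NA, hp[4] * 1.3, hp[5]),
                       duct_radius = c(base = 0.78, apex = 0.46) * 1.3)
  s1 <- generate_specimen(p1); s2 <- generate_specimen(p2)
  expect_equal(s2$truth$duct_length, 1.3 * s1$truth$duct_length,
               tolerance = 1e-6 * s1$truth$duct_length)
  expect_equal(s2$truth$reach, 1.3 * s1$truth$reach, tolerance = 1e-6)
  expect_equal(s2$truth$non_planarity, 1.3 * s1$truth$non_planarity,
               tolerance = 1e-6)
  tf <- similarity_transform(rot3(c(1, 2, 3), 0.8), 1, c(4, -2, 7))
  s3 <- transform_specimen(s1, tf)
  expect_equal(s3$truth$duct_length, s1$truth$duct_length)
  expect_equal(s3$truth$reach, s1$truth$reach)
})

test_that("non-planarity is monotone in the ripple amplitude", {
  amps <- seq(0, 0.5, by = 0.1)
  np <- sapply(amps, function(a) {
    s <- generate_specimen(phantom_params(
      height_profile = c(2.4, -0.05, NA, a, 1.5)))
    s$truth$non_planarity
  })
  expect_true(all(diff(np) > 0))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(spiral_scale = -1), "positive")
  expect_error(phantom_params(total_turn = 0), "positive")
  expect_error(phantom_params(duct_radius = c(base = 0.4, apex = 0.6)), ">=")
  expect_error(phantom_params(spiral_scale = NaN), "finite")
})

test_that("cohorts are reproducible, distinct, and span the expected duct-length range", {
  a <- sample_cohort(6, seed = 42)
  b <- sample_cohort(6, seed = 42)
  expect_identical(lapply(a, function(s) s$mesh$vertices),
                   lapply(b, function(s) s$mesh$vertices))
  dl <- sapply(a, function(s) s$truth$duct_length)
  expect_gt(length(unique(round(dl, 6))), 5)
  full <- sample_cohort(18, seed = 1)
  dl18 <- sapply(full, function(s) s$truth$duct_length)
  expect_gte(diff(range(dl18)), 4)
  expect_error(sample_cohort(1, seed = 1), "at least 2")
})

test_that("voxelized sphere volume matches the analytic value within 1%", {
  sph <- oticfit:::uv_sphere(radius = 2, n_theta = 32, n_phi = 64)
  vol <- voxelize(sph, spacing = 0.05)
  count <- sum(vol$data > (230 + 20) / 2)
  expect_equal(count * 0.05^3, 4 / 3 * pi * 8, tolerance = 0.01 * 4 / 3 * pi * 8)
})

test_that("voxelization is translation-equivariant on a shared grid", {
  sph <- oticfit:::uv_sphere(radius = 1, n_theta = 16, n_phi = 32)
  g <- list(origin = c(-2, -2, -2), dim = c(50L, 50L, 50L))
  v0 <- voxelize(sph, 0.1, origin = g$origin, dim = g$dim)
  sph2 <- sph
  sph2$vertices <- sweep(sph$vertices, 2, -c(0.1, 0, 0))   # +1 voxel in x
  v1 <- voxelize(sph2, 0.1, origin = g$origin, dim = g$dim)
  expect_equal(v1$data[2:50, , ], v0$data[1:49, , ], tolerance = 1e-12)
})

test_that("phantom volume iso-surface at 170 lies within a voxel of the mesh", {
  s <- generate_specimen()
  vol <- phantom_volume(s, spacing = 0.15)
  cl <- extract_threshold_cloud(vol, 170)
  set.seed(1)
  idx <- sample(nrow(cl$points), 2000)
  d <- point_mesh_distance(cl$points[idx, ], s$mesh)$distance
  # capsule-boundary points sit on the mesh; bone/air shell points sit a
  # wall-thickness away and are expected clutter
  capsule <- d < 0.5
  expect_gt(mean(capsule), 0.2)
  expect_lt(mean(d[capsule]), 0.15)
  expect_error(phantom_volume(s, spacing = 1.0), "degenerate")
})
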