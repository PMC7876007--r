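# Locally affine deformation: limiting cases and regularization behaviour.

lad_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_template()$mesh
    cache
  }
})

test_that("fitting a mesh to its own vertices produces zero displacement", {
  mesh <- lad_mesh()
  f <- lad_fit(mesh, mesh$vertices, lad_config(d = 5, iters = 3))
  expect_lt(max(abs(f$displacement)), 1e-9)
})

test_that("a globally rigidly moved cloud is recovered to sub-0.01 mm surface error", {
  mesh <- lad_mesh()
  tf <- similarity_transform(rot3(c(0.2, 1, 0.4), 0.04), 1, c(0.3, -0.1, 0.2))
  target <- apply_transform(tf, mesh)
  f <- lad_fit(mesh, target$vertices, lad_config(d = 5, iters = 50))
  d <- point_mesh_distance(f$mesh$vertices, target)$distance
  expect_lt(mean(d), 0.01)
})

test_that("d at least the mesh diameter reduces LAD to the global rigid fit", {
  mesh <- lad_mesh()
  set.seed(7)
  noisy <- mesh$vertices + matrix(rnorm(length(mesh$vertices), 0, 0.3), ncol = 3)
  diam <- sqrt(sum((apply(mesh$vertices, 2, max) -
                    apply(mesh$vertices, 2, min))^2))
  iters <- 6
  f <- lad_fit(mesh, noisy, lad_config(d = 1.1 * diam, iters = iters,
                                       trim_factor = 1e9))
  # oracle: iterated pairing + closed-form Kabsch applied globally
  Vc <- mesh$vertices
  for (it in seq_len(iters)) {
    nn <- oticfit:::cpp_nn(noisy, Vc)
    fit <- kabsch_fit(Vc, noisy[nn$index, ])
    Vc <- sweep(Vc %*% t(fit$R), 2, -fit$t)
  }
  expect_lt(max(abs(f$mesh$vertices - Vc)), 1e-6)
})

test_that("deformation energy is non-increasing in the neighbourhood radius", {
  mesh <- lad_mesh()
  set.seed(8)
  noisy <- mesh$vertices + matrix(rnorm(length(mesh$vertices), 0, 0.25), ncol = 3)
  en <- sapply(c(2.5, 5, 10), function(d)
    deformation_energy(lad_fit(mesh, noisy, lad_config(d = d, iters = 10))))
  expect_true(all(diff(en) <= 0))
})

test_that("LAD displacement fields are smooth at d = 5", {
  mesh <- lad_mesh()
  set.seed(9)
  noisy <- mesh$vertices + matrix(rnorm(length(mesh$vertices), 0, 0.2), ncol = 3)
  f <- lad_fit(mesh, noisy, lad_config(d = 5, iters = 20))
  e <- oticfit:::mesh_edges(mesh)
  dd <- sqrt(rowSums((f$displacement[e[, 1], ] - f$displacement[e[, 2], ])^2))
  expect_lt(max(dd), 25 * mean(dd) + 1e-12)
})

test_that("re-running LAD from a converged state moves vertices negligibly", {
  mesh <- lad_mesh()
  tf <- similarity_transform(rot3(c(0, 0, 1), 0.03), 1, c(0.1, 0.2, 0))
  cloud <- apply_transform(tf, mesh$vertices)
  f1 <- lad_fit(mesh, cloud, lad_config(d = 5, iters = 60, tol = 1e-10))
  f2 <- lad_fit(f1$mesh, cloud, lad_config(d = 5, iters = 5, tol = 0))
  expect_lt(max(abs(f2$mesh$vertices - f1$mesh$vertices)), 1e-4)
})

test_that("empty clouds are rejected", {
  expect_error(lad_fit(lad_mesh(), matrix(0, 0, 3), lad_config()), "empty cloud")
})
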