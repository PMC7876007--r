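# Similarity-transform ICP registration.

make_test_mesh <- function() build_template()$mesh

test_that("ICP on identical point sets keeps the identity", {
  mesh <- make_test_mesh()
  tf <- icp_similarity(mesh, mesh$vertices, iters = 10)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(abs(tf$scale - 1), 1e-9)
  expect_lt(max(abs(tf$translation)), 1e-9)
  expect_lt(tail(attr(tf, "mean_pair_distance"), 1), 1e-12)
})

test_that("ICP recovers a small similarity perturbation exactly", {
  mesh <- make_test_mesh()
  tf_true <- similarity_transform(rot3(c(1, 2, 0.5), 0.05), 1.02,
                                  c(0.3, -0.2, 0.4))
  cloud <- apply_transform(tf_true, mesh$vertices)
  tf <- icp_similarity(mesh, cloud, iters = 50)
  expect_lt(abs(tf$scale - tf_true$scale) / tf_true$scale, 1e-3)
  ang <- acos(min(1, (sum(diag(t(tf$rotation) %*% tf_true$rotation)) - 1) / 2))
  expect_lt(ang * 180 / pi, 0.1)
  expect_lt(max(abs(tf$translation - tf_true$translation)), 0.01)
  err <- apply_transform(tf, mesh$vertices) - cloud
  expect_lt(mean(sqrt(rowSums(err^2))), 0.01)
})

test_that("ICP mean pair distance is non-increasing", {
  mesh <- make_test_mesh()
  set.seed(11)
  cloud <- apply_transform(similarity_transform(rot3(c(0, 0, 1), 0.06), 1.01,
                                                c(0.2, 0.1, -0.1)),
                           mesh$vertices)
  cloud <- cloud + matrix(rnorm(length(cloud), 0, 0.05), ncol = 3)
  tf <- icp_similarity(mesh, cloud, iters = 30)
  tr <- attr(tf, "mean_pair_distance")
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("ICP is equivariant under a rigid motion of the cloud", {
  mesh <- make_test_mesh()
  tf0 <- similarity_transform(rot3(c(1, 0, 1), 0.04), 1.01, c(0.2, 0, 0.1))
  cloud <- apply_transform(tf0, mesh$vertices)
  S <- similarity_transform(rot3(c(0, 1, 0), 0.5), 1, c(5, -3, 2))
  tf_a <- icp_similarity(mesh, cloud, iters = 40)
  tf_b <- icp_similarity(mesh, apply_transform(S, cloud),
                         init = compose_transform(S, tf_a), iters = 40)
  expected <- compose_transform(S, tf_a)
  expect_lt(max(abs(tf_b$rotation - expected$rotation)), 1e-6)
  expect_lt(abs(tf_b$scale - expected$scale), 1e-6)
  expect_lt(max(abs(tf_b$translation - expected$translation)), 1e-5)
})

test_that("empty clouds are rejected", {
  mesh <- make_test_mesh()
  expect_error(icp_similarity(mesh, matrix(0, 0, 3)), "empty cloud")
})
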