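# Statistical shape model: Procrustes standardization, PCA construction,
# and SSM-constrained ICP fitting.

ssm_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tpl <- build_template()
      co <- sample_cohort(6, seed = 5)
      train <- lapply(co, function(s) {
        V <- s$mesh$vertices
        if (s$truth$side != tpl$side) V <- V %*% diag(c(-1, 1, 1))
        V
      })
      cache <<- list(tpl = tpl, co = co, train = train,
                     model = build_ssm(train, tpl$mesh$vertices,
                                       faces = tpl$mesh$faces))
    }
    cache
  }
})

test_that("Procrustes standardization gives unit centroid size and undoes similarities", {
  fx <- ssm_fixture()
  ref <- fx$tpl$mesh$vertices
  std <- procrustes_standardize(fx$train, ref)
  for (s in std)
    expect_equal(oticfit:::centroid_size(s), 1, tolerance = 1e-12)
  # a similarity-transformed copy standardizes to the same shape
  tf <- similarity_transform(rot3(c(3, 1, 2), 1.2), 1.7, c(10, 20, -5))
  a <- procrustes_standardize(list(ref), ref)[[1]]
  b <- procrustes_standardize(list(apply_transform(tf, ref)), ref)[[1]]
  expect_lt(max(abs(a - b)), 1e-9)
  expect_error(procrustes_standardize(list(ref[-1, ]), ref), "correspondence")
})

test_that("identical training shapes give zero eigenvalues and the mean equals the shape", {
  fx <- ssm_fixture()
  ref <- fx$tpl$mesh$vertices
  m <- build_ssm(list(ref, ref, ref), ref)
  expect_lt(max(abs(m$eigenvalues)), 1e-20)
  std <- procrustes_standardize(list(ref), ref)[[1]]
  expect_lt(max(abs(oticfit:::.shape_to_matrix(m$mean_shape) - std)), 1e-12)
})

test_that("three distinct shapes give exactly two nonzero eigenvalues and exact reconstruction", {
  fx <- ssm_fixture()
  m3 <- build_ssm(fx$train[1:3], fx$tpl$mesh$vertices)
  ev <- m3$eigenvalues
  expect_equal(length(ev), 2)
  expect_true(all(ev > 0))
  expect_true(all(diff(ev) <= 0))
  for (i in 1:3) {
    S <- ssm_project(m3, fx$train[[i]])
    rec <- ssm_shape(m3, S)
    std <- procrustes_standardize(fx$train[i], fx$tpl$mesh$vertices)[[1]]
    expect_lt(max(abs(rec - std)), 1e-8)
  }
  expect_error(build_ssm(fx$train[1], fx$tpl$mesh$vertices), "at least 2")
})

test_that("eigenvalue sum equals the total variance of the standardized data", {
  fx <- ssm_fixture()
  m <- fx$model
  std <- procrustes_standardize(fx$train, fx$tpl$mesh$vertices)
  X <- do.call(rbind, lapply(std, function(v) as.numeric(t(v))))
  total_var <- sum(sweep(X, 2, colMeans(X))^2) / (nrow(X) - 1)
  expect_equal(sum(m$eigenvalues), total_var, tolerance = 1e-10 * total_var)
  expect_lt(max(abs(crossprod(m$modes) - diag(ncol(m$modes)))), 1e-8)
})

test_that("fitting the mean shape yields near-zero coefficients", {
  fx <- ssm_fixture()
  cs <- oticfit:::centroid_size(fx$tpl$mesh$vertices)
  cloud <- oticfit:::.shape_to_matrix(fx$model$mean_shape) * cs
  fit <- ssm_fit(fx$model, cloud, iters = 30)
  expect_lt(sqrt(sum(fit$coefficients^2)),
            0.01 * sqrt(sum(fx$model$eigenvalues)))
})

test_that("a densely sampled training shape is recovered below 0.02 mm surface error", {
  fx <- ssm_fixture()
  spec <- fx$co[[2]]
  cloud <- spec$mesh$vertices
  init <- landmark_similarity(fx$tpl$landmarks, spec$truth$landmarks,
    reflect = if (spec$truth$side != fx$tpl$side) "force" else "never")
  icp_tf <- icp_similarity(fx$tpl$mesh, cloud, init, iters = 50)
  fit <- ssm_fit(fx$model, cloud, icp_tf, iters = 150)  # run to convergence
  d <- point_mesh_distance(fit$mesh$vertices, spec$mesh)$distance
  expect_lt(mean(d), 0.02)
  # trimmed objective decreases overall; the pair-trimming subset changes
  # between iterations, which permits small transient increases
  tr <- fit$mean_pair_distance
  expect_lt(tail(tr, 1), head(tr, 1))
  expect_true(all(diff(tr) <= 1e-6 + 5e-2 * head(tr, -1)))
})

test_that("a leave-one-out model fits the held-out shape no better than the full model", {
  fx <- ssm_fixture()
  for (i in c(1, 4)) {
    spec <- fx$co[[i]]
    cloud <- spec$mesh$vertices
    init <- landmark_similarity(fx$tpl$landmarks, spec$truth$landmarks,
      reflect = if (spec$truth$side != fx$tpl$side) "force" else "never")
    icp_tf <- icp_similarity(fx$tpl$mesh, cloud, init, iters = 50)
    full <- ssm_fit(fx$model, cloud, icp_tf, iters = 50)
    loo_model <- build_ssm(fx$train[-i], fx$tpl$mesh$vertices,
                           faces = fx$tpl$mesh$faces)
    loo <- ssm_fit(loo_model, cloud, icp_tf, iters = 50)
    d_full <- mean(point_mesh_distance(full$mesh$vertices, spec$mesh)$distance)
    d_loo <- mean(point_mesh_distance(loo$mesh$vertices, spec$mesh)$distance)
    expect_gte(d_loo, d_full)
  }
})
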