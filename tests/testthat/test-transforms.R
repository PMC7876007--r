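test_that("similarity transforms compose and invert exactly", {
  set.seed(1)
  for (i in 1:10) {
    a <- similarity_transform(rot3(rnorm(3), runif(1, 0, pi)),
                              runif(1, 0.5, 2), rnorm(3, 0, 5),
                              reflect = i %% 2 == 0)
    b <- similarity_transform(rot3(rnorm(3), runif(1, 0, pi)),
                              runif(1, 0.5, 2), rnorm(3, 0, 5),
                              reflect = i %% 3 == 0)
    x <- matrix(rnorm(30), 10, 3)
    expect_equal(apply_transform(compose_transform(b, a), x),
                 apply_transform(b, apply_transform(a, x)), tolerance = 1e-12)
    expect_lt(max(abs(apply_transform(invert_transform(a),
                                      apply_transform(a, x)) - x)), 1e-9)
  }
})

test_that("landmark similarity recovers a known transform", {
  src <- list(apex = c(1, 2, 3), oval_window = c(4, -1, 0),
              canal_bifurcation = c(-2, 5, 1))
  tf_true <- similarity_transform(rot3(c(1, 1, 0), 0.7), 1.4, c(10, -3, 2))
  dst <- lapply(src, function(p) as.numeric(apply_transform(tf_true, p)))
  tf <- landmark_similarity(src, dst)
  expect_lt(abs(tf$scale - 1.4) / 1.4, 1e-9)
  expect_lt(max(abs(tf$rotation - tf_true$rotation)), 1e-9)
  expect_lt(max(abs(tf$translation - tf_true$translation)), 1e-8)
  expect_lt(attr(tf, "rms_residual"), 1e-9)
  # identity case
  tf0 <- landmark_similarity(src, src)
  expect_lt(attr(tf0, "rms_residual"), 1e-12)
  expect_equal(tf0$scale, 1, tolerance = 1e-12)
})

test_that("reflection handling: triads are chirality-ambiguous, 4+ points are not", {
  src3 <- rbind(c(1, 2, 3), c(4, -1, 0), c(-2, 5, 1))
  mir3 <- src3 %*% diag(c(-1, 1, 1))
  # a labelled triad and its mirror image are congruent via a proper
  # rotation, so both the proper and mirrored solutions fit exactly
  tf_never <- landmark_similarity(src3, mir3, reflect = "never")
  expect_lt(attr(tf_never, "rms_residual"), 1e-9)
  tf_force <- landmark_similarity(src3, mir3, reflect = "force")
  expect_true(tf_force$reflect)
  expect_lt(attr(tf_force, "rms_residual"), 1e-9)
  # with four non-planar points the mirrored solution is required
  src4 <- rbind(src3, c(0.5, 0.5, 8))
  mir4 <- src4 %*% diag(c(-1, 1, 1))
  tf4 <- landmark_similarity(src4, mir4, reflect = "auto")
  expect_true(tf4$reflect)
  expect_lt(attr(tf4, "rms_residual"), 1e-9)
  tf4n <- landmark_similarity(src4, mir4, reflect = "never")
  expect_gt(attr(tf4n, "rms_residual"), 0.1)
})

test_that("collinear landmark triads are rejected", {
  src <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  dst <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(landmark_similarity(src, dst), "collinear")
})

test_that("landmark residual is invariant to joint rigid motion", {
  set.seed(3)
  src <- matrix(rnorm(9), 3, 3)
  dst <- src + matrix(rnorm(9, 0, 0.1), 3, 3)
  r0 <- attr(landmark_similarity(src, dst), "rms_residual")
  Q <- rot3(c(0, 1, 2), 1.1)
  move <- function(m) sweep(m %*% t(Q), 2, -c(5, 6, 7))
  r1 <- attr(landmark_similarity(move(src), move(dst)), "rms_residual")
  expect_equal(r0, r1, tolerance = 1e-9)
})
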