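# Outer-wall contour measurements checked against closed forms and
# brute-force dense-curve oracles.

circle_contour <- function(R = 1, turns = 1.2, n = 101, z = function(th) 0 * th) {
  th <- seq(0, turns * 2 * pi, length.out = n)
  outer_wall_contour(cbind(R * cos(th), R * sin(th), z(th)))
}

test_that("reach of a unit circle over 270 degrees is its diameter", {
  ct <- circle_contour(R = 1)
  expect_equal(reach(ct), 2, tolerance = 1e-3)
})

test_that("270-degree window of a planar circle selects three quarters of the turn", {
  th <- seq(0, 2 * pi, length.out = 101)
  ct <- outer_wall_contour(cbind(cos(th), sin(th), 0))
  idx <- turning_angle_window(ct, 270)
  # the window endpoint sits at polar angle 270 degrees within one sample
  end_angle <- atan2(ct$points[max(idx), 2], ct$points[max(idx), 1]) %% (2 * pi)
  expect_lt(abs(end_angle * 180 / pi - 270), 360 / 100 + 1e-6)
  expect_equal(max(idx) / 101, 0.75, tolerance = 0.02)
})

test_that("duct length of a circle matches the closed form at 101 points", {
  ct <- circle_contour(R = 3, turns = 1)
  expect_equal(duct_length(ct), 2 * pi * 3, tolerance = 2 * pi * 3 * 1e-3)
})

test_that("log-spiral measurements agree with the dense brute-force oracle", {
  zf <- function(th) 0.08 * th + 0.25 * sin(1.4 * th)
  dense <- log_spiral(A = 5, b = 0.1, theta_max = 4.6 * pi, n = 4e4, z = zf)
  oracle <- brute_measures(dense)
  rs <- oticfit:::resample_polyline(dense, 101)
  ct <- outer_wall_contour(rs$points, rs$total_length)
  expect_equal(duct_length(ct), oracle$duct_length,
               tolerance = 0.005 * oracle$duct_length)
  # reach endpoint within one sample spacing of the dense-oracle value
  spacing <- max(ct$cum_arc_length) / 100
  expect_lt(abs(reach(ct) - oracle$reach), spacing)
  expect_lt(abs(non_planarity(ct) - oracle$non_planarity), 0.02)
})

test_that("turning-angle window endpoint matches quadrature on a log spiral", {
  dense <- log_spiral(A = 5, b = 0.1, theta_max = 3 * pi, n = 4e4)
  oracle <- brute_measures(dense, 270)
  rs <- oticfit:::resample_polyline(dense, 101)
  ct <- outer_wall_contour(rs$points, rs$total_length)
  idx <- turning_angle_window(ct, 270)
  end_101 <- ct$points[max(idx), ]
  end_dense <- dense[oracle$window_end, ]
  spacing <- max(ct$cum_arc_length) / 100
  expect_lt(sqrt(sum((end_101 - end_dense)^2)), spacing)
})

test_that("window wider than total coiling raises an error; 360 on 2.5 turns is interior", {
  ct <- circle_contour(turns = 0.5)
  expect_error(turning_angle_window(ct, 270), "insufficient")
  sp <- log_spiral(A = 5, b = 0.1, theta_max = 5 * pi, n = 3001)
  rs <- oticfit:::resample_polyline(sp, 101)
  ct2 <- outer_wall_contour(rs$points, rs$total_length)
  idx <- turning_angle_window(ct2, 360)
  expect_lt(max(idx), 101)
})

test_that("basal plane fit recovers a known plane with symmetric offsets", {
  set.seed(7)
  n0 <- c(1, 2, 2) / 3
  u <- c(2, -1, 0) / sqrt(5); v <- c(2, 4, -5) / sqrt(45)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  base <- outer(cos(th), u) + outer(sin(th), v)
  h <- 0.05
  pts <- base + outer(rep(c(1, -1), 20), h * n0)
  pl <- fit_basal_plane(pts, orient_toward = n0)
  expect_lt(acos(min(1, abs(sum(pl$normal * n0)))), 1e-6)
  d <- abs(as.numeric(pts %*% pl$normal) - pl$offset)
  expect_equal(mean(d), h, tolerance = 1e-9)
  # coplanar points give zero residual
  pl0 <- fit_basal_plane(base)
  expect_lt(pl0$rms_residual, 1e-12)
  # order invariance and rigid equivariance
  pl1 <- fit_basal_plane(pts[sample(nrow(pts)), ], orient_toward = n0)
  expect_equal(abs(sum(pl1$normal * pl$normal)), 1, tolerance = 1e-9)
  Q <- rot3(c(1, 0, 1), 0.9); tvec <- c(3, -2, 1)
  pl2 <- fit_basal_plane(sweep(pts %*% t(Q), 2, -tvec),
                         orient_toward = as.numeric(Q %*% n0) + tvec)
  expect_equal(abs(sum(pl2$normal * as.numeric(Q %*% pl$normal))), 1,
               tolerance = 1e-9)
  expect_error(fit_basal_plane(cbind(1:5, 1:5, 1:5)), "collinear")
})

test_that("measurements are invariant under rigid motion and reflection, linear in scale", {
  zf <- function(th) 0.1 * th + 0.2 * sin(1.5 * th)
  dense <- log_spiral(A = 5, b = 0.1, theta_max = 4.6 * pi, n = 3001, z = zf)
  rs <- oticfit:::resample_polyline(dense, 101)
  ct <- outer_wall_contour(rs$points, rs$total_length)
  m0 <- measurement_report(ct)
  Q <- rot3(c(1, 2, 3), 1.3)
  moved <- sweep(rs$points %*% t(Q), 2, -c(4, 5, -6))
  m1 <- measurement_report(outer_wall_contour(moved))
  refl <- rs$points %*% diag(c(-1, 1, 1))
  m2 <- measurement_report(outer_wall_contour(refl))
  for (f in c("non_planarity", "reach", "duct_length")) {
    expect_equal(m1[[f]], m0[[f]], tolerance = 1e-9)
    expect_equal(m2[[f]], m0[[f]], tolerance = 1e-9)
  }
  m3 <- measurement_report(outer_wall_contour(rs$points * 2.5))
  for (f in c("non_planarity", "reach", "duct_length"))
    expect_equal(m3[[f]], 2.5 * m0[[f]], tolerance = 1e-6)
})

test_that("vertical trajectory heights vanish for planar contours and centre on the window", {
  ct <- circle_contour(R = 4, turns = 1.2)
  tr <- vertical_trajectory(ct)
  expect_lt(max(abs(tr$height_mm)), 1e-9)
  zf <- function(th) 0.15 * th - 0.3 * sin(th)
  dense <- log_spiral(A = 5, b = 0.1, theta_max = 4.6 * pi, n = 3001, z = zf)
  rs <- oticfit:::resample_polyline(dense, 101)
  ct2 <- outer_wall_contour(rs$points, rs$total_length)
  idx <- turning_angle_window(ct2, 270)
  tr2 <- vertical_trajectory(ct2)
  # least-squares plane residuals over the window have zero mean
  expect_lt(abs(mean(tr2$height_mm[idx])), 1e-9)
})

test_that("contour container enforces equal arc-length increments", {
  sp <- log_spiral(n = 5001)
  rs <- oticfit:::resample_polyline(sp, 101)
  ct <- outer_wall_contour(rs$points, rs$total_length)
  inc <- diff(ct$cum_arc_length)
  expect_lt(diff(range(inc)) / mean(inc), 1e-6)
  expect_true(all(diff(ct$cum_turning_angle) >= 0))
})
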