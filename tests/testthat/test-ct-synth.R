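# Pseudo-clinical degradation: downsampling, projection, detector noise and
# filtered backprojection.

test_that("downsampling preserves constants, identity spacing, and block means", {
  v <- ct_volume(array(7, c(12, 12, 12)), 0.15)
  expect_equal(downsample(v, 0.15)$data, v$data)
  d <- downsample(v, 0.3)
  expect_true(all(abs(d$data - 7) < 1e-12))
  set.seed(2)
  r <- ct_volume(array(runif(12^3), c(12, 12, 12)), 0.15)
  d2 <- downsample(r, 0.3)
  x <- r$data
  dim(x) <- c(2, 6, 2, 6, 2, 6)
  oracle <- apply(x, c(2, 4, 6), mean)
  expect_equal(d2$data, oracle, tolerance = 1e-12)
  expect_equal(mean(d2$data), mean(r$data), tolerance = 0.005 * mean(r$data))
  expect_error(downsample(r, 0.1), "upsampling")
})

test_that("projection geometry: zeros, disc symmetry, point-mass sinusoid", {
  z <- matrix(0, 32, 32)
  expect_true(all(project_slice(z, n_angles = 12)$data == 0))
  n <- 63
  x <- outer(seq_len(n), rep(1, n)); y <- t(x); c0 <- (n + 1) / 2
  disc <- 1 * ((x - c0)^2 + (y - c0)^2 < 100)
  s <- project_slice(disc, n_angles = 36)
  # every projection of a centred disc is identical up to sampling error
  pm <- rowMeans(s$data)
  expect_lt(mean(abs(s$data - pm)), 0.02 * max(s$data))
  pm <- matrix(0, n, n); pm[c0 + 10, c0] <- 1
  sp <- project_slice(pm, n_angles = 90)
  peak <- apply(sp$data, 2, which.max)
  amp_bins <- max(abs(peak - (nrow(sp$data) + 1) / 2))
  os <- sp$pixel_spacing / sp$det_spacing
  expect_equal(amp_bins / os, 10, tolerance = 0.1)
  expect_error(project_slice(disc, n_angles = 1), "at least 2")
  expect_error(project_slice(matrix(0, 3, 4)), "square")
})

test_that("detector noise scales with sigma and is seed-deterministic", {
  set.seed(9)
  s <- project_slice(matrix(runif(48^2), 48, 48), n_angles = 60)
  expect_identical(add_detector_noise(s, 0)$data, s$data)
  n1 <- add_detector_noise(s, 0.01, seed = 4)
  n2 <- add_detector_noise(s, 0.02, seed = 4)
  expect_equal(sd(n2$data - s$data) / sd(n1$data - s$data), 2, tolerance = 0.05)
  expect_identical(n1$data, add_detector_noise(s, 0.01, seed = 4)$data)
  r <- diff(range(s$data))
  expect_equal(sd(n1$data - s$data), 0.01 * r, tolerance = 0.05 * 0.01 * r)
  expect_error(add_detector_noise(s, -1), "non-negative")
})

test_that("filtered backprojection round trip recovers a smooth slice within 2%", {
  n <- 47
  x <- outer(seq_len(n), rep(1, n)); y <- t(x); c0 <- (n + 1) / 2
  # smoothed disc emulating a bone cross-section with partial-volume edges
  r <- sqrt((x - c0)^2 + (y - c0)^2)
  img <- 20 + 210 * matrix(pmin(1, pmax(0, 14 - r)), n, n)
  sino <- project_slice(img, spacing = 0.3)
  rec <- reconstruct_slice(sino)
  m <- 5
  interior <- matrix(FALSE, n, n); interior[m:(n - m), m:(n - m)] <- TRUE
  rmse <- sqrt(mean((rec - img)[interior]^2))
  expect_lt(rmse, 0.02 * diff(range(img)))
  # zero sinogram reconstructs to zero
  z <- project_slice(matrix(0, 32, 32), n_angles = 20)
  expect_lt(max(abs(reconstruct_slice(z))), 1e-12)
  # disc boundary recovered within one pixel
  disc <- 20 + 200 * matrix(as.numeric(r < 10), n, n)
  rd <- reconstruct_slice(project_slice(disc, spacing = 1))
  rec_r <- range(r[rd > 120])
  expect_lt(abs(rec_r[2] - 10), 1)
})

test_that("degradation is linear, unbiased, and preset noise is ordered", {
  sph <- oticfit:::uv_sphere(radius = 1.5, n_theta = 16, n_phi = 32)
  vol <- voxelize(sph, spacing = 0.15, margin = 2)
  cfg0 <- degrade_config("mdct", noise_sigma = 0)
  d1 <- degrade_volume(vol, cfg0)
  vol2 <- ct_volume(vol$data * 2.5, vol$spacing, vol$origin)
  d2 <- degrade_volume(vol2, cfg0)
  expect_equal(d2$data, 2.5 * d1$data, tolerance = 1e-9)
  # identity-spacing, zero-noise degradation approximates the input
  cfgid <- degrade_config(NULL, target_spacing = 0.15, noise_sigma = 0)
  did <- degrade_volume(vol, cfgid)
  expect_lt(sqrt(mean((did$data - vol$data)^2)), 0.02 * diff(range(vol$data)))
  # noise ordering cbct < mdct < poor_mdct in the image domain
  sds <- sapply(c("cbct", "mdct", "poor_mdct"), function(p) {
    cfg <- degrade_config(p, target_spacing = 0.3, rng_seed = 5)
    cfgz <- degrade_config(p, target_spacing = 0.3, noise_sigma = 0)
    sd(degrade_volume(vol, cfg)$data - degrade_volume(vol, cfgz)$data)
  })
  expect_true(sds[1] < sds[2] && sds[2] < sds[3])
  # image-domain noise is essentially zero-mean
  cfg <- degrade_config("mdct", target_spacing = 0.3, rng_seed = 5)
  cfgz <- degrade_config("mdct", target_spacing = 0.3, noise_sigma = 0)
  nz <- degrade_volume(vol, cfg)$data - degrade_volume(vol, cfgz)$data
  expect_lt(abs(mean(nz)), 3 * sd(nz) / sqrt(length(nz)) + 1e-3)
})
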