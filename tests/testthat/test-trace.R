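# Outer-wall contour tracing on phantom meshes.

test_that("the traced contour follows the analytic outer-wall curve", {
  tpl <- build_template()
  nn <- oticfit:::cpp_nn(tpl$truth$centerline, tpl$contour$points)
  expect_lt(mean(nn$distance), 0.1)
  m <- measurement_report(tpl$contour)
  expect_equal(m$duct_length, tpl$truth$duct_length,
               tolerance = 0.005 * tpl$truth$duct_length)
  expect_lt(abs(m$reach - tpl$truth$reach), 0.05)
})

test_that("tracing a reflected mesh with reflected inputs mirrors the contour", {
  s <- generate_specimen(phantom_params(side = "right"))
  tr_r <- trace_outer_wall(s$mesh, s$truth$landmarks$apex, s$truth$round_window,
                           s$truth$coiling_axis)
  M <- diag(c(-1, 1, 1))
  sm <- generate_specimen(phantom_params(side = "left"))
  tr_l <- trace_outer_wall(sm$mesh, sm$truth$landmarks$apex,
                           sm$truth$round_window, sm$truth$coiling_axis)
  expect_equal(max(tr_l$contour$cum_arc_length),
               max(tr_r$contour$cum_arc_length), tolerance = 1e-6)
  d <- tr_l$contour$points - tr_r$contour$points %*% M
  expect_lt(max(abs(d)), 1e-6)
})

test_that("anchors reproduce the contour on the same mesh and track deformations", {
  tpl <- build_template()
  ct2 <- contour_from_anchors(tpl$anchors, tpl$mesh)
  expect_lt(max(abs(ct2$points - tpl$contour$points)), 1e-9)
  tf <- similarity_transform(rot3(c(1, 1, 1), 0.5), 1.2, c(3, 2, 1))
  ct3 <- contour_from_anchors(tpl$anchors, apply_transform(tf, tpl$mesh))
  m2 <- measurement_report(ct2); m3 <- measurement_report(ct3)
  expect_equal(m3$duct_length, 1.2 * m2$duct_length, tolerance = 1e-6)
  expect_equal(m3$reach, 1.2 * m2$reach, tolerance = 1e-6)
})

test_that("degenerate tracing inputs raise errors", {
  tpl <- build_template()
  expect_error(trace_outer_wall(tpl$mesh, tpl$truth$landmarks$apex,
                                tpl$truth$round_window, c(0, 0, 0)),
               "non-zero")
})
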