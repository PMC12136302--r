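# small synthetic trajectory helper: prescribe ve(t, x) directly
synth_traj <- function(ve_mat, times, grid) {
  structure(list(times = times, ve = ve_mat,
                 vi = ve_mat, k = matrix(0.5, nrow(ve_mat), grid$N),
                 grid = grid, params = NULL,
                 settings = integration_settings(dt = 0.01,
                                                 t_final = max(max(times), 0.01)),
                 stimulus = NULL),
            class = "csd_trajectory")
}

test_that("wavefront detection returns the outermost suprathreshold node", {
  g <- build_grid(5, 21)
  ctr <- (21 + 1) %/% 2
  snap <- rep(-1, 21)
  expect_true(is.na(detect_wavefront(snap, 0, g)))
  snap[ctr:(ctr + 5)] <- 1
  expect_equal(detect_wavefront(snap, 0, g), ctr + 5)
  # mirror-symmetric snapshot: rightward front mirrors the leftward one
  snap2 <- rep(-1, 21)
  snap2[(ctr - 3):(ctr + 3)] <- 1
  d <- detect_wavefront(snap2, 0, g) - ctr
  expect_equal(snap2[ctr - d], snap2[ctr + d])
  expect_equal(d, 3)
  expect_error(detect_wavefront(rep(0, 5), 0, g), "length")
})

test_that("the speed estimator reproduces hand-computable fronts", {
  g <- build_grid(10, 21)   # hx = 1
  ctr <- 11
  times <- seq(0, 10, by = 1)
  # front advancing one node per time unit up to node ctr+10 at t=10
  ve <- matrix(-1, length(times), 21)
  for (i in seq_along(times))
    ve[i, ctr:(ctr + times[i])] <- 1
  traj <- synth_traj(ve, times, g)
  cal <- unit_calibration(1, 1)
  sp <- propagation_speed(traj, 0, cal)
  expect_equal(sp$nth, ctr + 10)
  expect_equal(sp$speed_model_units, 1)            # hx * 10 / 10
  expect_equal(sp$speed_mm_per_min, 60)            # 1 unit/s * 60
  expect_equal(sp$front_slope_model_units, 1, tolerance = 1e-10)
  # zero displacement at tF
  ve0 <- matrix(-1, 2, 21); ve0[, ctr] <- 1
  sp0 <- propagation_speed(synth_traj(ve0, c(0, 5), g), 0, cal)
  expect_equal(sp0$speed_model_units, 0)
  # no front at all -> measurement error
  expect_error(
    propagation_speed(synth_traj(matrix(-1, 2, 21), c(0, 5), g), 0, cal),
    "did not form")
})

test_that("node extrema match a brute-force scan and handle transients", {
  g <- build_grid(5, 11)
  times <- seq(0, 2 * pi, length.out = 400)
  ve <- matrix(rep(sin(times), 11), ncol = 11)
  traj <- synth_traj(ve, times, g)
  ex <- node_extrema(traj, 4, discard_fraction = 0)
  expect_equal(unname(ex["max_ve"]), 1, tolerance = 1e-3)
  expect_equal(unname(ex["min_ve"]), -1, tolerance = 1e-3)
  # constant trajectory
  cx <- node_extrema(synth_traj(matrix(0.3, 5, 11), 0:4, g), 2)
  expect_equal(unname(cx), c(0.3, 0.3))
  # brute force comparison with discard
  keep <- times >= 0.25 * max(times)
  ex2 <- node_extrema(traj, 7, 0.25)
  expect_equal(unname(ex2["max_ve"]), max(ve[keep, 7]))
  expect_equal(unname(ex2["min_ve"]), min(ve[keep, 7]))
  expect_error(node_extrema(traj, 99), "out of range")
})

test_that("regime classification is monotone in the reach fraction", {
  g <- build_grid(10, 21)
  ctr <- 11
  ve <- matrix(-1, 3, 21)
  ve[3, ctr:(ctr + 6)] <- 1   # front covers 6 of 10 half-axis nodes
  traj <- synth_traj(ve, 0:2, g)
  expect_equal(classify_regime(traj, 0, reach_fraction = 0.5), "propagating")
  expect_equal(classify_regime(traj, 0, reach_fraction = 0.6), "propagating")
  expect_equal(classify_regime(traj, 0, reach_fraction = 0.7), "quiescent")
  expect_equal(classify_regime(traj, 0, reach_fraction = 1), "quiescent")
  # quiescent trajectory has no measurable speed (consistency of the views)
  qt <- synth_traj(matrix(-1, 3, 21), 0:2, g)
  expect_equal(classify_regime(qt, 0, 0.5), "quiescent")
  expect_error(propagation_speed(qt, 0, unit_calibration(1)), "did not form")
})

test_that("space-time matrix is the raw field with labels", {
  g <- build_grid(3, 7)
  ve <- matrix(rnorm(21), 3, 7)
  traj <- synth_traj(ve, c(0, 0.5, 1), g)
  m <- space_time_matrix(traj, "ve")
  expect_equal(dim(m), c(3, 7))
  expect_equal(unname(m[2, 5]), ve[2, 5])
  expect_equal(rownames(m), format(c(0, 0.5, 1), trim = TRUE))
  expect_error(space_time_matrix(traj, "nope"))
  # single snapshot
  one <- synth_traj(matrix(1:7, 1, 7), 0, g)
  expect_equal(dim(space_time_matrix(one, "k")), c(1, 7))
})

test_that("unit calibration converts speeds linearly and round-trips", {
  cal <- calibrate_units(control_speed_model_units = 1.4,
                         target_mm_per_min = 2.2)
  expect_equal(speed_to_mm_per_min(1.4, cal), 2.2, tolerance = 1e-12)
  cal2 <- calibrate_units(1.4, 4.4)
  expect_equal(cal2$mm_per_grid_unit, 2 * cal$mm_per_grid_unit)
  # idempotence: calibrating from an already-converted speed is stable
  cal3 <- calibrate_units(1.4, speed_to_mm_per_min(1.4, cal))
  expect_equal(cal3$mm_per_grid_unit, cal$mm_per_grid_unit)
  expect_error(calibrate_units(0, 2.2), "control")
  expect_error(unit_calibration(-1), "mm_per_grid_unit")
})
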