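test_that("simulation is deterministic under a fixed seed", {
  p <- swimmer_params(n_cells = 8L, duration_frames = 50L)
  expect_identical(simulate_swimmers(p, 7), simulate_swimmers(p, 7))
  expect_false(identical(simulate_swimmers(p, 7)$x_um,
                         simulate_swimmers(p, 8)$x_um))
  g <- growth_sim_params()
  expect_identical(simulate_growth_curves(g, 3), simulate_growth_curves(g, 3))
  expect_identical(simulate_pigment_absorbances(1, 1, seed = 5, noise_sd = 0.01),
                   simulate_pigment_absorbances(1, 1, seed = 5, noise_sd = 0.01))
})

test_that("noise-free swimmers move on straight lines at constant speed", {
  p <- swimmer_params(n_cells = 5L, duration_frames = 40L, sigma_rot = 0,
                      jitter_sd = 0, stall_rate_0 = 0, ag_conc = 0,
                      field_um = 1e5)  # large field: no boundary reflections
  tr <- truth_tracks(p, 1)
  st <- step_velocities(tr, DT)
  by_cell <- split(st, st$track_id)
  for (s in by_cell) {
    expect_lt(diff(range(s$speed)), 1e-9)          # constant speed
    expect_lt(diff(range(atan2(s$vy, s$vx))), 1e-9) # constant heading
  }
  an <- directional_changes(tr, DT)
  expect_lt(max(an$dtheta), 1e-6)
})

test_that("swimmer parameter validation rejects degenerate inputs", {
  expect_error(swimmer_params(dt = 0), "dt")
  expect_error(swimmer_params(n_cells = 0), "n_cells")
  expect_error(swimmer_params(v_shape = 1), "v_shape")
})

test_that("positions stay inside the field and states are well-formed", {
  p <- stressed_params(n_cells = 15L, duration_frames = 200L)
  tr <- simulate_swimmers(p, 3)
  expect_true(all(tr$x_um >= 0 & tr$x_um <= p$field_um))
  expect_true(all(tr$y_um >= 0 & tr$y_um <= p$field_um))
  expect_true(all(tr$state %in% c("swimming", "stalled")))
  expect_identical(nrow(tr), p$n_cells * p$duration_frames)
  # stalling is absorbing: no stalled -> swimming transitions
  per_cell <- split(tr$state == "stalled", tr$cell_id)
  expect_true(all(vapply(per_cell, function(s) all(diff(s) >= 0), logical(1))))
})

test_that("silver exposure increases the stalled fraction", {
  frac <- function(ag, expo) {
    p <- swimmer_params(n_cells = 30L, duration_frames = 300L,
                        ag_conc = ag, exposure_min = expo)
    mean(simulate_swimmers(p, 11)$state == "stalled")
  }
  expect_equal(frac(0, 60), 0)
  expect_gt(frac(2.35, 60), frac(0, 60))
  expect_gt(frac(2.35, 60), frac(2.35, 15))  # exposure ramp
})

test_that("speed mode is recovered within one histogram bin across v_mode", {
  for (vm in c(20, 45, 60)) {
    p <- swimmer_params(n_cells = 40L, duration_frames = 500L, v_mode = vm,
                        sigma_rot = 0.3)
    st <- step_velocities(truth_tracks(p, 21), DT)
    h <- speed_histogram(st)
    mode_mid <- h$bin_mid[which.max(h$count)]
    expect_lte(abs(mode_mid - vm), 5)
  }
})

test_that("growth simulation reproduces the closed-form curve without noise", {
  p <- growth_sim_params(noise_sd = 0, p_no_growth = 0)
  cur <- simulate_growth_curves(p, 1)
  expected <- p$od0 + gompertz(cur$time_hr, p$A, p$mu_m, p$lag)
  expect_equal(cur$od, expected, tolerance = 1e-12)
})

test_that("no-growth replicates stay at baseline plus noise", {
  p <- growth_sim_params(p_no_growth = 1, noise_sd = 0.005)
  cur <- simulate_growth_curves(p, 2)
  expect_lt(max(abs(cur$od - p$od0)), 0.03)
})

test_that("replicate failure inflates the spread of per-replicate lag fits", {
  lag_sd <- function(p_ng, seed) {
    cur <- simulate_growth_curves(growth_sim_params(p_no_growth = p_ng), seed)
    sd(fit_gompertz(cur)$fits$lag, na.rm = TRUE)
  }
  het <- mean(vapply(1:3, function(s) lag_sd(0.5, s), numeric(1)))
  hom <- mean(vapply(1:3, function(s) lag_sd(0, s), numeric(1)))
  expect_gte(het, 3 * hom)
})

test_that("pigment absorbance synthesis inverts the chlorophyll equations", {
  # hand-solved 2x2 system: chl_a = 1.0975, chl_b = 0.5245 at volume 1
  # corresponds to E663 = 0.1, E645 = 0.05
  ab <- simulate_pigment_absorbances(1.0975, 0.5245, volume_ml = 1,
                                     noise_sd = 0, seed = 1, e750 = 0.02)
  expect_equal(ab$A663 - ab$A750, 0.1, tolerance = 1e-12)
  expect_equal(ab$A645 - ab$A750, 0.05, tolerance = 1e-12)
  # zero pigment: baseline-only absorbances
  ab0 <- simulate_pigment_absorbances(0, 0, noise_sd = 0, seed = 1)
  expect_equal(ab0$A663, ab0$A750)
  expect_equal(ab0$A645, ab0$A750)
})

test_that("rendering places resolvable spots and returns matching truth", {
  p <- swimmer_params(n_cells = 1L, duration_frames = 5L, v_mode = 1,
                      field_um = 25.6)
  tr <- simulate_swimmers(p, 4)
  vid <- render_video(tr, render_params(field_px = 64, snr = 100), seed = 5)
  for (f in names(vid$frames)) {
    img <- vid$frames[[f]]
    pk <- which(img == max(img), arr.ind = TRUE)[1, ]
    cell <- vid$truth[vid$truth$frame == as.integer(f), ]
    expect_lt(abs((pk["col"] - 1) - cell$x_um / 0.4), 1.5)
    expect_lt(abs((pk["row"] - 1) - cell$y_um / 0.4), 1.5)
  }
  expect_error(render_params(cell_sigma = 0.1), "cell_sigma")
})
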