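test_that("step velocities follow the finite-difference definition", {
  tr <- make_track(cbind(c(0, 1, 2), c(0, 0, 0)))
  st <- step_velocities(tr, DT)
  expect_identical(nrow(st), 2L)
  expect_equal(st$speed, rep(1 / DT, 2))  # 25.2525... um/s
  expect_equal(st$vx, rep(1 / DT, 2))
  expect_equal(st$vy, rep(0, 2))
  # static track
  st0 <- step_velocities(make_track(cbind(rep(1, 5), rep(2, 5))), DT)
  expect_true(all(st0$speed == 0))
  expect_error(step_velocities(tr, 0), "dt")
})

test_that("gap frames contribute no steps", {
  tr <- make_track(cbind(0:3, 0:3), frames = c(0L, 1L, 5L, 6L))
  st <- step_velocities(tr, DT)
  expect_identical(nrow(st), 2L)
  expect_identical(st$frame, c(0L, 5L))
})

test_that("directional changes follow the arccos definition with signed cross", {
  # steps (1,0) then (0,1): quarter turn, positive cross product
  tr <- make_track(cbind(c(0, 1, 1), c(0, 0, 1)))
  an <- directional_changes(tr, DT)
  expect_equal(an$dtheta, pi / 2)
  expect_equal(an$dtheta_signed, pi / 2)
  # straight continuation: zero
  an0 <- directional_changes(make_track(cbind(c(0, 1, 2), c(0, 0, 0))), DT)
  expect_equal(an0$dtheta, 0)
  # exact reversal: pi with the positive tie-break
  anr <- directional_changes(make_track(cbind(c(0, 1, 0), c(0, 0, 0))), DT)
  expect_equal(anr$dtheta, pi)
  expect_equal(anr$dtheta_signed, pi)
  # clockwise quarter turn: negative sign
  anc <- directional_changes(make_track(cbind(c(0, 1, 1), c(0, 0, -1))), DT)
  expect_equal(anc$dtheta_signed, -pi / 2)
})

test_that("zero-length steps are dropped from angle computation", {
  tr <- make_track(cbind(c(0, 1, 1, 2), c(0, 0, 0, 0)))
  an <- directional_changes(tr, DT)  # middle step has zero length
  expect_identical(nrow(an), 0L)
})

test_that("angle pairs require a shared middle frame", {
  tr <- make_track(cbind(c(0, 1, 5, 6, 7), c(0, 0, 0, 0, 0)),
                   frames = c(0L, 1L, 4L, 5L, 6L))
  an <- directional_changes(tr, DT)
  expect_identical(nrow(an), 1L)  # only steps 4->5 and 5->6 are consecutive
  expect_identical(an$frame, 5L)
})

test_that("speeds and unsigned angles are rotation invariant", {
  p <- control_params(n_cells = 10L, duration_frames = 100L)
  tr <- truth_tracks(p, 5)
  rot <- pi / 7
  tr2 <- tr |>
    dplyr::mutate(x_new = cos(rot) * x_um - sin(rot) * y_um,
                  y_new = sin(rot) * x_um + cos(rot) * y_um,
                  x_um = x_new, y_um = y_new) |>
    dplyr::select(track_id, frame, x_um, y_um)
  s1 <- step_velocities(tr, DT); s2 <- step_velocities(tr2, DT)
  expect_equal(s1$speed, s2$speed, tolerance = 1e-9)
  a1 <- directional_changes(tr, DT); a2 <- directional_changes(tr2, DT)
  expect_equal(a1$dtheta, a2$dtheta, tolerance = 1e-9)
})

test_that("arccos clamping never produces NaN", {
  # steps engineered so the normalized dot product drifts past 1 by float error
  x <- cumsum(rep(c(0.1, 0.1 + 1e-16), 50))
  tr <- make_track(cbind(x, x * (1 + 1e-16)))
  an <- directional_changes(tr, DT)
  expect_false(any(is.nan(an$dtheta)))
  expect_false(any(is.nan(an$dtheta_signed)))
})

test_that("signed angles are symmetric for unbiased turning", {
  for (p in list(control_params(n_cells = 30L, duration_frames = 400L),
                 stressed_params(n_cells = 30L, duration_frames = 400L))) {
    an <- directional_changes(truth_tracks(p, 23), DT)
    se <- sd(an$dtheta_signed) / sqrt(nrow(an))
    expect_lt(abs(mean(an$dtheta_signed)), 3 * se)
    pos <- an$dtheta_signed[an$dtheta_signed > 0]
    neg <- -an$dtheta_signed[an$dtheta_signed < 0]
    ks <- suppressWarnings(stats::ks.test(pos, neg))
    expect_lt(unname(ks$statistic), 0.1)
  }
})

test_that("percent change reproduces worked examples and rejects zero baseline", {
  expect_equal(percent_change(59, 12), -100 * 47 / 59)
  expect_equal(percent_change(0.81, 1.8), 100 * (1.8 - 0.81) / 0.81)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "before")
})

test_that("histograms use fixed left-closed bins and normalize to one", {
  h <- motility_histogram(c(0, 4.9, 5, 7, 150), bin_width = 5, range = c(0, 150))
  expect_identical(nrow(h), 30L)
  expect_identical(h$count[1], 2L)   # 0 and 4.9
  expect_identical(h$count[2], 2L)   # 5 and 7
  expect_identical(h$count[30], 1L)  # top edge falls in last bin
  expect_equal(sum(h$freq), 1)
  expect_identical(nrow(motility_histogram(numeric(0), 5, c(0, 150))), 0L)
  expect_error(motility_histogram(1:5, 0, c(0, 1)), "bin_width")
})

test_that("averaging hierarchy pools steps, then replicates, then conditions", {
  steps <- dplyr::bind_rows(
    tibble::tibble(ag_conc = 0, exposure_min = 0, replicate = 1,
                   track_id = 1L, speed = c(10, 20)),
    tibble::tibble(ag_conc = 0, exposure_min = 0, replicate = 2,
                   track_id = 2L, speed = c(40, 40, 40, 40))
  )
  s <- summarize_condition(steps)
  # replicate means are 15 and 40; the condition mean weighs replicates
  # equally regardless of their step counts
  expect_equal(s$mean_speed, (15 + 40) / 2)
  expect_equal(s$sd_speed_across_reps, sd(c(15, 40)))
  expect_identical(s$n_reps, 2L)
  expect_identical(s$n_steps, 6L)
  # identical replicates give zero dispersion
  steps2 <- dplyr::mutate(steps, speed = 30)
  expect_equal(summarize_condition(steps2)$sd_speed_across_reps, 0)
  # missing replicates trigger a warning when the acquisition count is known
  expect_warning(summarize_condition(steps, expected_reps = 5), "zero steps")
})

test_that("silver stress lowers mean speed and raises directional change", {
  speeds <- numeric(0); angles <- numeric(0)
  gains <- c(0, 0.03, 0.06)
  for (i in seq_along(gains)) {
    res <- lapply(1:3, function(s) {
      p <- swimmer_params(n_cells = 15L, duration_frames = 250L,
                          ag_conc = 2.35, exposure_min = 60,
                          stall_gain = gains[i])
      tr <- truth_tracks(p, 100 * i + s)
      list(v = mean(step_velocities(tr, DT)$speed),
           a = mean(directional_changes(tr, DT)$dtheta))
    })
    speeds[i] <- mean(vapply(res, `[[`, numeric(1), "v"))
    angles[i] <- mean(vapply(res, `[[`, numeric(1), "a"))
  }
  expect_true(all(diff(speeds) < 0))
  expect_true(all(diff(angles) > 0))
})

test_that("smoothing preserves straight lines and converges to raw data", {
  line <- make_track(cbind(0:19 * 1.5, 0:19 * 0.5))
  for (reg in c(0.1, 1, 10)) {
    sm <- smooth_track(line, reg)
    expect_lt(max(abs(sm$x_um - line$x_um)), 1e-6)
    expect_lt(max(abs(sm$y_um - line$y_um)), 1e-6)
  }
  set.seed(41)
  noisy <- make_track(cbind(0:19 + rnorm(20, 0, 0.2), rnorm(20, 0, 0.2)))
  sm0 <- smooth_track(noisy, 1e-12)
  expect_lt(max(abs(sm0$x_um - noisy$x_um)), 1e-3)
  expect_error(smooth_track(noisy, -1), "reg")
  short <- make_track(cbind(1:3, 1:3))
  expect_identical(smooth_track(short, 1)$x_um, short$x_um)
})

test_that("stress-response ordering is robust to spline smoothing", {
  ctrl <- truth_tracks(control_params(), 51)
  trt <- truth_tracks(stressed_params(), 52)
  for (reg in c(0, 0.1, 1, 10)) {
    sc <- smooth_track(ctrl, reg); st <- smooth_track(trt, reg)
    expect_lt(mean(step_velocities(st, DT)$speed),
              mean(step_velocities(sc, DT)$speed))
    expect_gt(mean(directional_changes(st, DT)$dtheta),
              mean(directional_changes(sc, DT)$dtheta))
  }
})

test_that("heading uniformity flags drift and passes isotropic motion", {
  # uniform headings on a fine grid: resultant length ~ 0
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  steps <- tibble::tibble(vx = cos(th), vy = sin(th))
  h <- heading_uniformity(steps)
  expect_lt(h$R, 1e-10)
  expect_gt(h$p_value, 0.99)
  # all steps due east: R = 1
  east <- tibble::tibble(vx = rep(1, 50), vy = 0)
  he <- heading_uniformity(east)
  expect_equal(he$R, 1)
  expect_lt(he$p_value, 1e-6)
  # drift injected into an isotropic control fixture
  st <- step_velocities(truth_tracks(control_params(), 61), DT)
  expect_gt(heading_uniformity(st)$p_value, 0.01)
  drift <- dplyr::mutate(st, vx = vx + 10)
  expect_lt(heading_uniformity(drift)$p_value, 0.01)
  expect_error(heading_uniformity(tibble::tibble(vx = 1, vy = 1)), "10")
})
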