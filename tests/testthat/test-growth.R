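test_that("the Gompertz curve has the documented closed-form properties", {
  A <- 0.54; mu <- 0.0084; lag <- 45.6
  # asymptote
  expect_equal(gompertz(1e7, A, mu, lag), A, tolerance = 1e-12)
  # value at t = lag is A * exp(-e)
  expect_equal(gompertz(lag, A, mu, lag), A * exp(-exp(1)), tolerance = 1e-12)
  # maximum slope equals mu_m (numerical derivative on a fine grid)
  t <- seq(0, 400, by = 0.01)
  y <- gompertz(t, A, mu, lag)
  expect_equal(max(diff(y) / 0.01), mu, tolerance = 1e-4)
  # monotone non-decreasing
  expect_true(all(diff(y) >= 0))
  expect_error(gompertz(1, -1, mu, lag), "A")
})

test_that("noiseless curves are recovered exactly", {
  p <- growth_sim_params(noise_sd = 0)
  fit <- fit_gompertz(simulate_growth_curves(p, 1))
  expect_true(all(fit$fits$converged))
  expect_equal(fit$aggregate$A_mean, p$A, tolerance = 1e-6)
  expect_equal(fit$aggregate$mu_m_mean, p$mu_m, tolerance = 1e-6)
  expect_equal(fit$aggregate$lag_mean, p$lag, tolerance = 1e-6)
})

test_that("noisy replicates recover the generating parameters", {
  # control-like condition
  f1 <- fit_gompertz(simulate_growth_curves(growth_sim_params(), 2))
  expect_lt(abs(f1$aggregate$lag_mean - 45.6) / 45.6, 0.10)
  expect_lt(abs(f1$aggregate$A_mean - 0.54) / 0.54, 0.05)
  # hormetic low-dose condition
  p2 <- growth_sim_params(A = 0.87, mu_m = 0.0096, lag = 82.6)
  f2 <- fit_gompertz(simulate_growth_curves(p2, 3))
  expect_lt(abs(f2$aggregate$A_mean - 0.87) / 0.87, 0.05)
})

test_that("parameter recovery holds across a grid of conditions", {
  errs <- NULL
  for (A in c(0.3, 0.54, 0.9)) for (mu in c(0.005, 0.01)) for (lag in c(40, 100)) {
    p <- growth_sim_params(A = A, mu_m = mu, lag = lag)
    f <- fit_gompertz(simulate_growth_curves(p, round(1000 * A + 1e4 * mu + lag)))
    a <- f$aggregate
    errs <- rbind(errs, c(abs(a$A_mean - A) / A, abs(a$mu_m_mean - mu) / mu,
                          abs(a$lag_mean - lag) / lag))
  }
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
  expect_lt(median(errs[, 3]), 0.10)
})

test_that("flat curves are flagged no-growth and excluded from the aggregate", {
  p <- growth_sim_params(p_no_growth = 1, noise_sd = 0.005)
  f <- fit_gompertz(simulate_growth_curves(p, 4))
  expect_true(all(f$fits$no_growth))
  expect_identical(f$aggregate$n_fit, 0L)
})

test_that("fits are invariant to time-unit rescaling", {
  cur <- simulate_growth_curves(growth_sim_params(), 5)
  f_hr <- fit_gompertz(cur)
  f_min <- fit_gompertz(dplyr::mutate(cur, time_hr = time_hr * 60))
  expect_equal(f_min$aggregate$lag_mean / 60, f_hr$aggregate$lag_mean,
               tolerance = 1e-6)
  expect_equal(f_min$aggregate$mu_m_mean * 60, f_hr$aggregate$mu_m_mean,
               tolerance = 1e-6)
  expect_equal(f_min$aggregate$A_mean, f_hr$aggregate$A_mean, tolerance = 1e-6)
})

test_that("fitting requires enough time points", {
  cur <- tibble::tibble(time_hr = rep(c(0, 12, 24, 36), 2),
                        replicate = rep(1:2, each = 4), od = 0.1)
  expect_error(fit_gompertz(cur), "5 time points")
})

test_that("hormesis comparison flags raised asymptotes and longer lags", {
  mk <- function(A, mu, lag, label, p_ng = 0, seed) {
    dplyr::mutate(
      simulate_growth_curves(
        growth_sim_params(A = A, mu_m = mu, lag = lag, p_no_growth = p_ng),
        seed),
      condition = label)
  }
  curves <- dplyr::bind_rows(
    mk(0.54, 0.0084, 45.6, "0", seed = 11),
    mk(0.87, 0.0096, 82.6, "0.29", seed = 12),
    mk(0.60, 0.0070, 142.7, "0.88", seed = 13),
    mk(0.20, 0.0050, 100, "1.18", p_ng = 1, seed = 14)
  )
  fits <- fit_growth_conditions(curves)
  rep_tbl <- compare_conditions(fits, control = "0")
  r <- function(cond) rep_tbl[rep_tbl$condition == cond, ]
  expect_false(r("0")$hormetic_asymptote)
  expect_true(r("0.29")$hormetic_asymptote)
  expect_true(r("0.29")$elongated_lag)
  expect_false(r("0.88")$hormetic_asymptote)
  expect_true(r("0.88")$elongated_lag)
  expect_true(r("1.18")$no_growth)
  expect_false(r("1.18")$hormetic_asymptote)
  expect_error(compare_conditions(fits, control = "nope"), "control")
})

test_that("identical conditions raise no hormesis flags", {
  cur <- simulate_growth_curves(growth_sim_params(), 21)
  fits <- list("0" = fit_gompertz(cur), t = fit_gompertz(cur))
  rep_tbl <- compare_conditions(fits, control = "0")
  expect_false(any(rep_tbl$hormetic_asymptote))
  expect_false(any(rep_tbl$elongated_lag))
})

test_that("broom-style accessors expose per-replicate and aggregate results", {
  f <- fit_gompertz(simulate_growth_curves(growth_sim_params(), 31))
  td <- tidy(f)
  expect_identical(nrow(td), 18L)  # 6 replicates x 3 terms
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  au <- augment(f)
  expect_identical(nrow(au), nrow(f$data))
  expect_true(".fitted" %in% names(au))
  expect_lt(max(abs(au$.fitted - au$od)), 0.1)
})
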