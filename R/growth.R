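#' Gompertz growth curve
#'
#' The lag-time parameterization of the Gompertz model,
#' `y(t) = A * exp(-exp(mu_m * e / A * (lag - t) + 1))`, in which `A` is the
#' stationary-phase asymptote, `mu_m` the maximum growth rate (the slope at
#' the inflection point), and `lag` the time-axis intercept of the tangent
#' at the inflection (the lag time). Monotone non-decreasing in `t`.
#'
#' @param t time (hr), vectorized.
#' @param A asymptote (OD750 above baseline), > 0.
#' @param mu_m maximum growth rate (1/hr).
#' @param lag lag time (hr).
#' @return OD750 above baseline at `t`.
#' @export
gompertz <- function(t, A, mu_m, lag) {
  check_positive(A, "A")
  A * exp(-exp(mu_m * exp(1) / A * (lag - t) + 1))
}

#' Simulation parameters for replicated growth curves
#'
#' Defaults are the untreated-control condition of the growth assay:
#' asymptote 0.54 OD750, maximum growth rate 0.0084 per hr, lag 45.6 hr,
#' initial OD750 0.01, six replicates sampled every 12 h out to 188 h, and
#' measurement noise of 0.02 OD750.
#'
#' @param A asymptote above baseline (OD750).
#' @param mu_m maximum growth rate (1/hr).
#' @param lag lag time (hr).
#' @param noise_sd OD750 measurement noise SD, independent per time point.
#' @param n_reps number of replicates.
#' @param t_grid strictly increasing sampling times (hr).
#' @param od0 initial (baseline) OD750.
#' @param p_no_growth probability that a replicate fails to grow and stays
#'   at `od0` plus noise, mimicking heterogeneous responses near lethal
#'   concentrations.
#' @return a list of class `growth_sim_params`.
#' @export
growth_sim_params <- function(A = 0.54, mu_m = 0.0084, lag = 45.6,
                              noise_sd = 0.02, n_reps = 6L,
                              t_grid = seq(0, 188, by = 12), od0 = 0.01,
                              p_no_growth = 0) {
  check_positive(A, "A")
  check_positive(mu_m, "mu_m")
  check_nonneg(lag, "lag")
  check_nonneg(noise_sd, "noise_sd")
  check_positive(n_reps, "n_reps")
  check_nonneg(od0, "od0")
  if (A <= od0) abort("`A` must exceed `od0`")
  check_scalar(p_no_growth, "p_no_growth", function(v) v >= 0 && v <= 1,
               "must be a probability")
  if (any(diff(t_grid) <= 0)) abort("`t_grid` must be strictly increasing")
  structure(list(A = A, mu_m = mu_m, lag = lag, noise_sd = noise_sd,
                 n_reps = as.integer(n_reps), t_grid = t_grid, od0 = od0,
                 p_no_growth = p_no_growth),
            class = "growth_sim_params")
}

#' Simulate replicated OD750 growth curves
#'
#' Each replicate is `od0 + gompertz(t) + N(0, noise_sd)` independently per
#' time point; with probability `p_no_growth` a replicate stays at `od0`
#' plus noise (no growth).
#'
#' @param p a [growth_sim_params()] object.
#' @param seed integer seed.
#' @return long tibble with `time_hr`, `replicate`, `od`, with `p` attached
#'   as attribute `"params"`.
#' @export
simulate_growth_curves <- function(p = growth_sim_params(), seed) {
  stopifnot(inherits(p, "growth_sim_params"))
  withr::with_seed(as.integer(seed), {
    grew <- runif(p$n_reps) >= p$p_no_growth
    out <- purrr::map_dfr(seq_len(p$n_reps), function(r) {
      mu <- if (grew[r]) gompertz(p$t_grid, p$A, p$mu_m, p$lag) else 0
      tibble(time_hr = p$t_grid, replicate = r,
             od = p$od0 + mu + rnorm(length(p$t_grid), 0, p$noise_sd))
    })
    attr(out, "params") <- p
    out
  })
}

fit_gompertz_one <- function(t, od, baseline, t_max) {
  y <- od - baseline
  A0 <- max(y)
  if (A0 <= 0) A0 <- 1e-3
  slopes <- diff(y) / diff(t)
  k <- which.max(slopes)
  mu0 <- max(slopes[k], 1e-4)
  t_mid <- (t[k] + t[k + 1]) / 2
  y_mid <- (y[k] + y[k + 1]) / 2
  lag0 <- min(max(t_mid - y_mid / mu0, 0), max(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-exp(mu_m * exp(1) / A * (lag - tt) + 1)),
      data = data.frame(tt = t, y = y),
      start = list(A = A0, mu_m = mu0, lag = lag0),
      lower = c(A = 1e-6, mu_m = 1e-8, lag = 0),
      upper = c(A = 2 * max(max(y), 1e-3), mu_m = Inf, lag = t_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble(A = NA_real_, mu_m = NA_real_, lag = NA_real_,
                  se_A = NA_real_, se_mu = NA_real_, se_lag = NA_real_,
                  rss = NA_real_, converged = FALSE))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  tibble(A = cf[["A"]], mu_m = cf[["mu_m"]], lag = cf[["lag"]],
         se_A = se[["A"]], se_mu = se[["mu_m"]], se_lag = se[["lag"]],
         rss = sum(stats::resid(fit)^2), converged = TRUE)
}

#' Fit the Gompertz model to replicated growth curves
#'
#' Nonlinear least squares on `od - baseline`, fitted per replicate and
#' aggregated as mean and SD across replicates. Initialization: the
#' asymptote starts at the maximum observed OD, the rate at the maximum
#' discrete slope, and the lag at the time-axis intercept of the
#' maximum-slope tangent. Replicates whose OD never rises more than
#' `no_growth_threshold` above baseline are flagged `no_growth` and
#' excluded from the aggregate (their "lag" is unidentified within the
#' assay window). Non-convergence is reported via `converged = FALSE`, not
#' as an error.
#'
#' @param curves long tibble with `time_hr`, `replicate`, `od` (as produced
#'   by [simulate_growth_curves()] or [read_growth_csv()]).
#' @param baseline initial OD750 subtracted before fitting.
#' @param no_growth_threshold minimum rise above baseline (OD750) for a
#'   replicate to count as grown.
#' @return an object of class `gompertz_fit`: a list with `fits` (one row
#'   per replicate), `aggregate` (one row: means and SDs over grown,
#'   converged replicates), `data`, `baseline`.
#' @export
fit_gompertz <- function(curves, baseline = 0.01, no_growth_threshold = 0.05) {
  check_nonneg(baseline, "baseline")
  check_positive(no_growth_threshold, "no_growth_threshold")
  check_columns(curves, c("time_hr", "replicate", "od"), "curves")
  if (length(unique(curves$time_hr)) < 5L) {
    abort("need at least 5 time points to fit the Gompertz model")
  }
  t_max <- max(curves$time_hr)
  fits <- curves |>
    group_by(.data$replicate) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$time_hr)
      res <- fit_gompertz_one(d$time_hr, d$od, baseline, t_max)
      res$no_growth <- max(d$od) - baseline < no_growth_threshold
      res
    }) |>
    ungroup()
  used <- fits |> filter(.data$converged, !.data$no_growth)
  aggregate <- tibble(
    n_fit = nrow(used), n_no_growth = sum(fits$no_growth),
    A_mean = mean(used$A), A_sd = sd(used$A),
    mu_m_mean = mean(used$mu_m), mu_m_sd = sd(used$mu_m),
    lag_mean = mean(used$lag), lag_sd = sd(used$lag)
  )
  structure(list(fits = fits, aggregate = aggregate, data = curves,
                 baseline = baseline),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  a <- x$aggregate
  cat("Gompertz fit:", a$n_fit, "replicate(s) aggregated,",
      a$n_no_growth, "flagged no-growth\n")
  cat(sprintf("  A    = %.3f +- %.3f OD750\n", a$A_mean, a$A_sd))
  cat(sprintf("  mu_m = %.5f +- %.5f 1/hr\n", a$mu_m_mean, a$mu_m_sd))
  cat(sprintf("  lag  = %.1f +- %.1f hr\n", a$lag_mean, a$lag_sd))
  invisible(x)
}

#' Fit Gompertz curves for several conditions
#'
#' @param curves long tibble with `condition`, `time_hr`, `replicate`, `od`.
#' @inheritParams fit_gompertz
#' @return named list of `gompertz_fit` objects, one per condition.
#' @export
fit_growth_conditions <- function(curves, baseline = 0.01,
                                  no_growth_threshold = 0.05) {
  check_columns(curves, c("condition", "time_hr", "replicate", "od"), "curves")
  curves |>
    split(curves$condition) |>
    purrr::map(fit_gompertz, baseline = baseline,
               no_growth_threshold = no_growth_threshold)
}

#' Hormesis comparison across conditions
#'
#' Compares each treated condition to the control: `hormetic_asymptote` is
#' flagged when the treated asymptote exceeds the control's by more than
#' the combined SD `sqrt(sd_t^2 + sd_c^2)`; `elongated_lag` analogously for
#' the lag time. Conditions in which no replicate grew (or in which flat
#' replicates outnumber grown ones) are reported with `no_growth = TRUE`
#' and unset flags.
#'
#' @param fits named list of `gompertz_fit` objects (names are condition
#'   labels), e.g. from [fit_growth_conditions()].
#' @param control name of the control condition in `fits`.
#' @return tibble with one row per condition: aggregated parameters and the
#'   hormesis flags.
#' @export
compare_conditions <- function(fits, control) {
  if (!control %in% names(fits)) {
    abort(sprintf("control condition `%s` is missing from `fits`", control))
  }
  agg <- purrr::imap_dfr(fits, function(f, cond) {
    mutate(f$aggregate, condition = cond, .before = 1L)
  })
  # a condition counts as no-growth when no replicate grew, or when the
  # flat replicates outnumber the grown ones (majority rule, so one noisy
  # flat curve sneaking past the per-replicate threshold cannot promote a
  # lethal condition to "grown")
  agg <- mutate(agg, no_growth = .data$n_fit == 0 |
                  .data$n_no_growth > .data$n_fit)
  ctrl <- agg[agg$condition == control, , drop = FALSE]
  sd0 <- function(x) ifelse(is.na(x), 0, x)
  agg |>
    mutate(
      is_control = .data$condition == control,
      hormetic_asymptote = !.data$is_control & !.data$no_growth &
        (.data$A_mean - ctrl$A_mean >
           sqrt(sd0(.data$A_sd)^2 + sd0(ctrl$A_sd)^2)),
      elongated_lag = !.data$is_control & !.data$no_growth &
        (.data$lag_mean - ctrl$lag_mean >
           sqrt(sd0(.data$lag_sd)^2 + sd0(ctrl$lag_sd)^2))
    ) |>
    select("condition", "n_fit", "n_no_growth", "A_mean", "A_sd",
           "mu_m_mean", "mu_m_sd", "lag_mean", "lag_sd", "no_growth",
           "is_control", "hormetic_asymptote", "elongated_lag")
}
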