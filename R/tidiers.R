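#' Tidy a Gompertz fit
#'
#' One row per replicate and parameter, broom-style.
#'
#' @param x a `gompertz_fit` object.
#' @param ... unused.
#' @return tibble with `replicate`, `term`, `estimate`, `std.error`,
#'   `converged`, `no_growth`.
#' @method tidy gompertz_fit
#' @export
tidy.gompertz_fit <- function(x, ...) {
  x$fits |>
    tidyr::pivot_longer(
      cols = c("A", "mu_m", "lag"),
      names_to = "term", values_to = "estimate"
    ) |>
    mutate(std.error = dplyr::case_when(
      .data$term == "A" ~ .data$se_A,
      .data$term == "mu_m" ~ .data$se_mu,
      TRUE ~ .data$se_lag
    )) |>
    select("replicate", "term", "estimate", "std.error", "converged",
           "no_growth")
}

#' Glance at a Gompertz fit
#'
#' One-row aggregate summary (means and SDs across grown, converged
#' replicates).
#'
#' @param x a `gompertz_fit` object.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance gompertz_fit
#' @export
glance.gompertz_fit <- function(x, ...) {
  x$aggregate
}

#' Augment growth data with fitted Gompertz curves
#'
#' @param x a `gompertz_fit` object.
#' @param ... unused.
#' @return the input data with a `.fitted` column (`NA` for replicates
#'   without a converged fit).
#' @method augment gompertz_fit
#' @export
augment.gompertz_fit <- function(x, ...) {
  fits <- x$fits
  x$data |>
    left_join(select(fits, "replicate", "A", "mu_m", "lag", "converged"),
              by = "replicate") |>
    mutate(.fitted = ifelse(
      .data$converged,
      x$baseline + gompertz_vec(.data$time_hr, .data$A, .data$mu_m, .data$lag),
      NA_real_
    )) |>
    select(-"A", -"mu_m", -"lag", -"converged")
}

# vectorized-in-parameters Gompertz (gompertz() validates a scalar A)
gompertz_vec <- function(t, A, mu_m, lag) {
  A * exp(-exp(mu_m * exp(1) / A * (lag - t) + 1))
}
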