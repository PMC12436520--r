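# Spectrophotometric chlorophyll coefficients (80% acetone / 20% methanol
# extracts, absorbances at 663/645 nm baseline-corrected by 750 nm).
CHL_COEF <- c(a663 = 12.25, a645 = -2.55, b663 = -4.91, b645 = 20.31)

#' Chlorophyll a, b and total concentrations from absorbance triplets
#'
#' Baseline-corrects the 663 nm and 645 nm absorbances by the 750 nm
#' reading (`E663 = A663 - A750`, `E645 = A645 - A750`) and applies the
#' two-wavelength equations: `chl_a = (12.25 E663 - 2.55 E645) / volume`,
#' `chl_b = (20.31 E645 - 4.91 E663) / volume`, and
#' `chl_total = (17.76 E645 + 7.34 E663) / volume`. The total coefficients
#' are exactly the sums of the a and b coefficients, so
#' `chl_a + chl_b = chl_total` holds identically. Negative computed
#' concentrations are flagged (`qc_negative`), never clipped, since
#' clipping would silently break the additivity identity.
#'
#' @param samples tibble with columns `A663`, `A645`, `A750`, `volume_ml`
#'   (and optionally `sample_id` and others, carried through).
#' @return the input with added columns `E663`, `E645`, `chl_a`, `chl_b`,
#'   `chl_total` (ug/mL) and `qc_negative`.
#' @export
chlorophyll_concentrations <- function(samples) {
  check_columns(samples, c("A663", "A645", "A750", "volume_ml"), "samples")
  if (any(samples$volume_ml <= 0)) abort("`volume_ml` must be positive")
  if (any(!is.finite(as.matrix(samples[c("A663", "A645", "A750")])))) {
    abort("absorbances must be finite")
  }
  samples |>
    mutate(
      E663 = .data$A663 - .data$A750,
      E645 = .data$A645 - .data$A750,
      chl_a = (CHL_COEF[["a663"]] * .data$E663 +
                 CHL_COEF[["a645"]] * .data$E645) / .data$volume_ml,
      chl_b = (CHL_COEF[["b645"]] * .data$E645 +
                 CHL_COEF[["b663"]] * .data$E663) / .data$volume_ml,
      chl_total = .data$chl_a + .data$chl_b,
      qc_negative = .data$chl_a < 0 | .data$chl_b < 0
    )
}

#' Per-cell chlorophyll content from culture density
#'
#' Converts a bulk chlorophyll concentration (ug/mL) to per-cell content
#' using the optical-density-to-cell-count rule of thumb
#' `1 OD750 ~ 1e7 cells/mL`: `cells_per_ml = od750 * 1e7` and
#' `pg/cell = chl * 1e6 / cells_per_ml`.
#'
#' @param chl chlorophyll concentration (ug/mL), vectorized.
#' @param od750 culture optical density at 750 nm (> 0), vectorized.
#' @return tibble with `cells_per_ml` and `chl_per_cell_pg`.
#' @export
per_cell_content <- function(chl, od750) {
  if (any(od750 <= 0)) abort("`od750` must be positive")
  cells <- od750 * 1e7
  tibble(cells_per_ml = cells, chl_per_cell_pg = chl * 1e6 / cells)
}

#' Simulate absorbance triplets for known chlorophyll concentrations
#'
#' Inverts the two-wavelength chlorophyll equations: solves the 2x2 linear
#' system for the baseline-corrected absorbances (`E663`, `E645`) that
#' reproduce the requested concentrations exactly, sets the 750 nm baseline
#' to `e750`, and adds independent Gaussian noise of SD `noise_sd` to each
#' absorbance. With `noise_sd = 0`, [chlorophyll_concentrations()] recovers
#' the inputs to machine precision.
#'
#' @param chl_a,chl_b target concentrations (ug/mL), vectorized, >= 0.
#' @param volume_ml sample volume (mL), > 0.
#' @param noise_sd absorbance noise SD (AU).
#' @param seed integer seed.
#' @param e750 baseline absorbance at 750 nm.
#' @return tibble with `sample_id`, `A663`, `A645`, `A750`, `volume_ml`.
#' @export
simulate_pigment_absorbances <- function(chl_a, chl_b, volume_ml = 1,
                                         noise_sd = 0, seed = 1,
                                         e750 = 0.02) {
  if (any(chl_a < 0) || any(chl_b < 0)) abort("concentrations must be >= 0")
  if (any(volume_ml <= 0)) abort("`volume_ml` must be positive")
  check_nonneg(noise_sd, "noise_sd")
  n <- max(length(chl_a), length(chl_b), length(volume_ml))
  chl_a <- rep_len(chl_a, n); chl_b <- rep_len(chl_b, n)
  volume_ml <- rep_len(volume_ml, n)
  a <- chl_a * volume_ml
  b <- chl_b * volume_ml
  det <- CHL_COEF[["a663"]] * CHL_COEF[["b645"]] -
    CHL_COEF[["a645"]] * CHL_COEF[["b663"]]
  E663 <- (CHL_COEF[["b645"]] * a - CHL_COEF[["a645"]] * b) / det
  E645 <- (CHL_COEF[["a663"]] * b - CHL_COEF[["b663"]] * a) / det
  withr::with_seed(as.integer(seed), {
    tibble(
      sample_id = paste0("s", seq_len(n)),
      A663 = E663 + e750 + rnorm(n, 0, noise_sd),
      A645 = E645 + e750 + rnorm(n, 0, noise_sd),
      A750 = e750 + rnorm(n, 0, noise_sd),
      volume_ml = volume_ml
    )
  })
}
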