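#' Parameters of the synthetic swimmer model
#'
#' Builds a validated parameter set for [simulate_swimmers()]. The generative
#' model is a two-state (swimming / stalled) active particle: each cell draws
#' a cruising speed once from a Gamma distribution parameterized by its mode
#' and shape (positive support, single peak, as observed for untreated
#' populations), swims with rotational diffusion of the heading, and under
#' Ag+ stress enters an absorbing stalled state at a rate that grows with
#' concentration and with time since exposure. Stalled cells show no directed
#' displacement, only Gaussian positional jitter about their stall point.
#'
#' @param n_cells number of cells in the field.
#' @param v_mode mode of the per-cell cruising-speed distribution (um/s).
#' @param v_shape Gamma shape of the speed distribution (dimensionless,
#'   must exceed 1 so the mode is positive); larger values give a narrower
#'   single-peaked distribution.
#' @param sigma_rot rotational diffusion: SD of the wrapped-Gaussian heading
#'   increment per frame (rad).
#' @param stall_rate_0 baseline stall-entry rate (1/s), applying even without
#'   silver.
#' @param stall_gain increment of the stall-entry rate per uM of Ag+ at full
#'   exposure ramp (1/s/uM).
#' @param ag_conc Ag+ concentration (uM).
#' @param exposure_min minutes since Ag+ addition; the effective stall rate
#'   ramps up linearly and saturates at `ramp_min` minutes.
#' @param ramp_min saturation time of the exposure ramp (minutes).
#' @param jitter_sd positional jitter SD of stalled cells (um).
#' @param duration_frames number of frames to simulate.
#' @param dt frame interval (s).
#' @param field_um side length of the square field (um); the default matches
#'   a 512-pixel field at 0.4 um/pixel.
#' @return a list of class `swimmer_params`.
#' @export
swimmer_params <- function(n_cells = 40L, v_mode = 45, v_shape = 60,
                           sigma_rot = 0.2, stall_rate_0 = 0,
                           stall_gain = 0.06, ag_conc = 0, exposure_min = 0,
                           ramp_min = 45, jitter_sd = 0.1,
                           duration_frames = 1000L, dt = 0.0396,
                           field_um = 512 * 0.4) {
  check_positive(n_cells, "n_cells")
  check_positive(v_mode, "v_mode")
  check_scalar(v_shape, "v_shape", function(v) v > 1,
               "must exceed 1 so the speed mode is positive")
  check_nonneg(sigma_rot, "sigma_rot")
  check_nonneg(stall_rate_0, "stall_rate_0")
  check_nonneg(stall_gain, "stall_gain")
  check_nonneg(ag_conc, "ag_conc")
  check_nonneg(exposure_min, "exposure_min")
  check_positive(ramp_min, "ramp_min")
  check_nonneg(jitter_sd, "jitter_sd")
  check_positive(duration_frames, "duration_frames")
  check_positive(dt, "dt")
  check_positive(field_um, "field_um")
  structure(list(
    n_cells = as.integer(n_cells), v_mode = v_mode, v_shape = v_shape,
    sigma_rot = sigma_rot, stall_rate_0 = stall_rate_0,
    stall_gain = stall_gain, ag_conc = ag_conc, exposure_min = exposure_min,
    ramp_min = ramp_min, jitter_sd = jitter_sd,
    duration_frames = as.integer(duration_frames), dt = dt,
    field_um = field_um
  ), class = "swimmer_params")
}

# Effective stall-entry rate (1/s): baseline plus a concentration term scaled
# by a monotone saturating exposure ramp f(T) = min(T / ramp_min, 1).
stall_rate <- function(p) {
  ramp <- min(p$exposure_min / p$ramp_min, 1)
  p$stall_rate_0 + p$stall_gain * p$ag_conc * ramp
}

#' Simulate ground-truth swimming microalgae
#'
#' Generates per-frame true positions and motility states for `n_cells`
#' cells over `duration_frames` frames under the two-state swim/stall model
#' described in [swimmer_params()]. Boundaries are reflective, so tracks are
#' never truncated at the field edge. Identical seed and parameters give
#' bit-identical output.
#'
#' @param params a [swimmer_params()] object.
#' @param seed integer seed for reproducibility.
#' @return a tibble with columns `cell_id`, `frame` (0-based), `x_um`,
#'   `y_um`, and `state` (`"swimming"` or `"stalled"`), with `params`
#'   attached as attribute `"params"`.
#' @export
simulate_swimmers <- function(params, seed) {
  stopifnot(inherits(params, "swimmer_params"))
  p <- params
  withr::with_seed(as.integer(seed), {
    n <- p$n_cells
    T <- p$duration_frames
    L <- p$field_um
    speed <- rgamma(n, shape = p$v_shape, scale = p$v_mode / (p$v_shape - 1))
    x <- runif(n, 0, L)
    y <- runif(n, 0, L)
    heading <- runif(n, -pi, pi)
    stalled <- rep(FALSE, n)
    anchor_x <- x
    anchor_y <- y
    p_stall <- 1 - exp(-stall_rate(p) * p$dt)

    X <- matrix(0, nrow = T, ncol = n)
    Y <- matrix(0, nrow = T, ncol = n)
    S <- matrix(FALSE, nrow = T, ncol = n)
    X[1L, ] <- x; Y[1L, ] <- y; S[1L, ] <- stalled

    for (f in seq_len(T - 1L)) {
      # state transitions: swimming cells may stall (absorbing)
      enter <- !stalled & (runif(n) < p_stall)
      anchor_x[enter] <- x[enter]
      anchor_y[enter] <- y[enter]
      stalled <- stalled | enter

      sw <- !stalled
      if (any(sw)) {
        heading[sw] <- heading[sw] + rnorm(sum(sw), 0, p$sigma_rot)
        x[sw] <- x[sw] + speed[sw] * p$dt * cos(heading[sw])
        y[sw] <- y[sw] + speed[sw] * p$dt * sin(heading[sw])
      }
      if (any(stalled)) {
        ns <- sum(stalled)
        x[stalled] <- anchor_x[stalled] + rnorm(ns, 0, p$jitter_sd)
        y[stalled] <- anchor_y[stalled] + rnorm(ns, 0, p$jitter_sd)
      }
      # specular reflection: flip the heading component normal to any wall
      # the cell crossed, so swimmers bounce instead of gliding along walls
      out_x <- x < 0 | x > L
      out_y <- y < 0 | y > L
      heading[out_x] <- pi - heading[out_x]
      heading[out_y] <- -heading[out_y]
      x <- reflect_into(x, L)
      y <- reflect_into(y, L)
      X[f + 1L, ] <- x; Y[f + 1L, ] <- y; S[f + 1L, ] <- stalled
    }

    out <- tibble(
      cell_id = rep(seq_len(n), each = T),
      frame = rep(0:(T - 1L), times = n),
      x_um = as.vector(X),
      y_um = as.vector(Y),
      state = ifelse(as.vector(S), "stalled", "swimming")
    )
    attr(out, "params") <- p
    out
  })
}
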