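#' Per-step velocities from tracks
#'
#' Finite-difference velocities over consecutive-frame pairs only: a step is
#' emitted for frames `f` and `f + 1` of the same track; gap pairs (frame
#' difference greater than 1, as left by the linker's memory) are skipped,
#' never interpolated.
#'
#' @param tracks tibble with `track_id`, `frame`, `x_um`, `y_um`; extra
#'   grouping columns (e.g. `replicate`, `ag_conc`, `exposure_min`) are
#'   carried through.
#' @param dt frame interval (s).
#' @return tibble with `track_id`, `frame` (the earlier frame of the pair),
#'   `t_s`, `vx`, `vy`, `speed` (um/s), plus carried columns.
#' @export
step_velocities <- function(tracks, dt = 0.0396) {
  check_positive(dt, "dt")
  check_columns(tracks, c("track_id", "frame", "x_um", "y_um"), "tracks")
  carried <- setdiff(names(tracks), c("frame", "x_um", "y_um"))
  tracks |>
    arrange(.data$track_id, .data$frame) |>
    group_by(across(all_of(carried))) |>
    mutate(
      dframe = lead(.data$frame) - .data$frame,
      vx = (lead(.data$x_um) - .data$x_um) / dt,
      vy = (lead(.data$y_um) - .data$y_um) / dt
    ) |>
    ungroup() |>
    filter(!is.na(.data$dframe), .data$dframe == 1L) |>
    mutate(t_s = .data$frame * dt, speed = sqrt(.data$vx^2 + .data$vy^2)) |>
    select(all_of(carried), "frame", "t_s", "vx", "vy", "speed")
}

#' Per-step directional changes from tracks
#'
#' The unsigned directional change between two consecutive steps sharing a
#' middle frame is the arccos of the normalized dot product of the two step
#' velocities, with the argument clamped to `[-1, 1]` against floating-point
#' error. The signed variant carries the sign of the 2-D cross product
#' `vx(t) * vy(t + dt) - vy(t) * vx(t + dt)`; an exact reversal (angle pi)
#' takes the positive sign. Pairs in which either step has exactly zero
#' length are dropped (the angle is undefined).
#'
#' @inheritParams step_velocities
#' @return tibble with `track_id`, `frame` (the shared middle frame), `t_s`,
#'   `dtheta` (rad/frame, in `[0, pi]`), `dtheta_signed` (rad/frame, in
#'   `(-pi, pi]`), plus carried columns.
#' @export
directional_changes <- function(tracks, dt = 0.0396) {
  steps <- step_velocities(tracks, dt)
  carried <- setdiff(names(steps), c("frame", "t_s", "vx", "vy", "speed"))
  steps |>
    group_by(across(all_of(carried))) |>
    mutate(
      consec = lead(.data$frame) - .data$frame == 1L,
      dot = .data$vx * lead(.data$vx) + .data$vy * lead(.data$vy),
      cross = .data$vx * lead(.data$vy) - .data$vy * lead(.data$vx),
      nrm = .data$speed * lead(.data$speed)
    ) |>
    ungroup() |>
    filter(!is.na(.data$consec), .data$consec, .data$nrm > 0) |>
    mutate(
      dtheta = acos(pmin(pmax(.data$dot / .data$nrm, -1), 1)),
      dtheta_signed = ifelse(
        .data$dtheta == pi | .data$cross >= 0, .data$dtheta, -.data$dtheta
      ),
      frame = .data$frame + 1L,  # the shared middle frame
      t_s = .data$frame * dt
    ) |>
    select(all_of(carried), "frame", "t_s", "dtheta", "dtheta_signed")
}

#' Condition-level motility summary
#'
#' Averages follow a declared hierarchy: all steps within one replicate
#' video are pooled into a replicate mean; the condition mean is the mean of
#' replicate means; the reported dispersion is the SD across replicate
#' means (the scale of the error bars on condition plots). Replicates with
#' zero steps are excluded with a warning.
#'
#' @param steps step tibble from [step_velocities()] containing a
#'   `replicate` column and the grouping columns in `by`.
#' @param angles optional angle tibble from [directional_changes()] with
#'   the same grouping columns; if supplied, mean directional change is
#'   summarized alongside speed.
#' @param by character vector of condition columns (default
#'   `c("ag_conc", "exposure_min")`).
#' @param expected_reps if given, the number of replicate videos acquired
#'   per condition; conditions contributing fewer replicates (because a
#'   replicate produced zero steps) trigger a warning.
#' @return tibble with one row per condition: `mean_speed`,
#'   `sd_speed_across_reps`, optionally `mean_dtheta`,
#'   `sd_dtheta_across_reps`, and counts `n_reps`, `n_tracks`, `n_steps`.
#' @export
summarize_condition <- function(steps, angles = NULL,
                                by = c("ag_conc", "exposure_min"),
                                expected_reps = NULL) {
  check_columns(steps, c(by, "replicate", "track_id", "speed"), "steps")
  rep_speed <- steps |>
    group_by(across(all_of(c(by, "replicate")))) |>
    summarise(rep_mean_speed = mean(.data$speed),
              n_tracks = dplyr::n_distinct(.data$track_id),
              n_steps = n(), .groups = "drop")
  if (!is.null(expected_reps)) {
    short <- rep_speed |>
      group_by(across(all_of(by))) |>
      summarise(n = n(), .groups = "drop") |>
      filter(.data$n < expected_reps)
    if (nrow(short) > 0L) {
      warn(sprintf(
        "%d condition(s) have replicates with zero steps; those replicates are excluded",
        nrow(short)
      ))
    }
  }
  out <- rep_speed |>
    group_by(across(all_of(by))) |>
    summarise(mean_speed = mean(.data$rep_mean_speed),
              sd_speed_across_reps = sd(.data$rep_mean_speed),
              n_reps = n(),
              n_tracks = sum(.data$n_tracks),
              n_steps = sum(.data$n_steps), .groups = "drop")
  if (!is.null(angles)) {
    check_columns(angles, c(by, "replicate", "dtheta"), "angles")
    rep_ang <- angles |>
      group_by(across(all_of(c(by, "replicate")))) |>
      summarise(rep_mean_dtheta = mean(.data$dtheta), .groups = "drop") |>
      group_by(across(all_of(by))) |>
      summarise(mean_dtheta = mean(.data$rep_mean_dtheta),
                sd_dtheta_across_reps = sd(.data$rep_mean_dtheta),
                .groups = "drop")
    out <- left_join(out, rep_ang, by = by)
  }
  out
}

#' Percent change between two values
#'
#' `100 * (after - before) / before`, sign preserved: a reduction is
#' negative (report its magnitude when quoting "reduced by X percent").
#'
#' @param before,after numeric vectors; `before` must be nonzero.
#' @return percent change (numeric).
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) abort("`before` must be nonzero")
  100 * (after - before) / before
}

#' Fixed-bin histogram of a motility statistic
#'
#' Counts and normalized frequencies on fixed left-closed bins
#' `[left, right)`; values outside `range` are dropped, except that values
#' equal to the upper range limit fall in the last bin.
#'
#' @param x numeric vector (e.g. speeds or angles).
#' @param bin_width bin width (> 0).
#' @param range length-2 numeric range covered by the bins.
#' @return tibble of class `motility_histogram` with `bin_left`,
#'   `bin_right`, `bin_mid`, `count`, `freq`; empty input gives an empty
#'   table.
#' @export
motility_histogram <- function(x, bin_width, range) {
  check_positive(bin_width, "bin_width")
  stopifnot(length(range) == 2L, range[2] > range[1])
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    out <- tibble(bin_left = numeric(0), bin_right = numeric(0),
                  bin_mid = numeric(0), count = integer(0), freq = numeric(0))
    return(structure(out, class = c("motility_histogram", class(out))))
  }
  x <- x[x >= range[1] & x <= range[2]]
  idx <- pmin(findInterval(x, breaks), length(breaks) - 1L)
  cnt <- tabulate(idx, nbins = length(breaks) - 1L)
  out <- tibble(
    bin_left = breaks[-length(breaks)],
    bin_right = breaks[-1],
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = cnt,
    freq = if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, length(cnt))
  )
  structure(out, class = c("motility_histogram", class(out)))
}

#' Speed histogram with the standard bins
#'
#' 5 um/s bins on `[0, 150]` um/s, the binning used for instantaneous-speed
#' distributions.
#'
#' @param steps step tibble from [step_velocities()], or a numeric vector of
#'   speeds.
#' @param bin_width,range see [motility_histogram()].
#' @return a `motility_histogram` tibble.
#' @export
speed_histogram <- function(steps, bin_width = 5, range = c(0, 150)) {
  x <- if (is.data.frame(steps)) steps$speed else steps
  h <- motility_histogram(x, bin_width, range)
  attr(h, "variable") <- "speed"
  h
}

#' Directional-change histogram with the standard bins
#'
#' pi/20 rad bins on `[0, pi]`, the binning used for turning-angle
#' distributions.
#'
#' @param angles angle tibble from [directional_changes()], or a numeric
#'   vector of unsigned angles.
#' @param bin_width,range see [motility_histogram()].
#' @return a `motility_histogram` tibble.
#' @export
angle_histogram <- function(angles, bin_width = pi / 20, range = c(0, pi)) {
  x <- if (is.data.frame(angles)) angles$dtheta else angles
  h <- motility_histogram(x, bin_width, range)
  attr(h, "variable") <- "dtheta"
  h
}

#' Smooth tracks with penalized cubic splines
#'
#' Fits independent smoothing splines to `x(t)` and `y(t)` of each track
#' with roughness weight `reg` and replaces the positions by the fitted
#' values; frames are unchanged. `reg = 0` returns the raw positions.
#' Tracks shorter than 4 frames cannot be smoothed and are returned
#' unchanged. Smoothing is an opt-in robustness check: all statistics are
#' computed on raw tracks by default.
#'
#' @param tracks tibble with `track_id`, `frame`, `x_um`, `y_um`.
#' @param reg non-negative roughness penalty weight (the spline `lambda`).
#' @return tibble of the same shape with smoothed `x_um`, `y_um`.
#' @export
smooth_track <- function(tracks, reg) {
  check_nonneg(reg, "reg")
  check_columns(tracks, c("track_id", "frame", "x_um", "y_um"), "tracks")
  if (reg == 0) return(tracks)
  tracks |>
    group_by(.data$track_id) |>
    mutate(
      x_um = smooth_one(.data$frame, .data$x_um, reg),
      y_um = smooth_one(.data$frame, .data$y_um, reg)
    ) |>
    ungroup()
}

smooth_one <- function(t, v, reg) {
  if (length(t) < 4L) return(v)
  # smooth.spline rescales the abscissa to [0, 1], which inflates the
  # curvature penalty by range^3; rescale so `reg` acts in raw frame units
  lam <- reg / diff(range(t))^3
  fit <- smooth.spline(t, v, lambda = lam, all.knots = TRUE, keep.data = FALSE)
  predict(fit, t)$y
}

#' Heading-uniformity (drift) diagnostic
#'
#' Circular statistics on the step headings `atan2(vy, vx)`: the mean
#' resultant length R (0 for uniform headings, 1 for a single direction)
#' and the Rayleigh-test p-value for the null of uniform headings. A small
#' p-value indicates a preferred direction, i.e. flow or drift in the field
#' of view, and flags the video for exclusion or re-acquisition.
#'
#' @param steps step tibble from [step_velocities()] (needs `vx`, `vy`),
#'   with at least 10 steps.
#' @return one-row tibble: `R`, `p_value`, `n`.
#' @export
heading_uniformity <- function(steps) {
  check_columns(steps, c("vx", "vy"), "steps")
  keep <- steps$vx != 0 | steps$vy != 0
  theta <- atan2(steps$vy[keep], steps$vx[keep])
  n <- length(theta)
  if (n < 10L) abort("need at least 10 nonzero steps for the drift diagnostic")
  R <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  Z <- n * R^2
  # standard Rayleigh-test approximation
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  tibble(R = R, p_value = min(max(p, 0), 1), n = n)
}
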