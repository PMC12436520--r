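#' Build a full-pipeline configuration
#'
#' One nested configuration drives the end-to-end analysis on synthetic
#' data: the motility arm (simulate swimmers per Ag+ concentration,
#' exposure time and replicate video, optionally render and re-detect,
#' link, compute step statistics) and the growth arm (simulate replicated
#' OD750 curves per condition, fit the Gompertz model, compare conditions
#' for hormesis), plus a pigment round-trip. Every stochastic stage has an
#' explicit seed.
#'
#' @param ag_conc Ag+ concentrations for the motility arm (uM).
#' @param exposures exposure times (min).
#' @param n_videos replicate videos per condition.
#' @param imaging list: `px_size` (um), `dt` (s), `field_px`.
#' @param swimmers named list of [swimmer_params()] overrides shared by all
#'   conditions (e.g. `n_cells`, `duration_frames`, `stall_gain`).
#' @param detection named list of [detection_params()] overrides.
#' @param linking named list of [linking_params()] overrides.
#' @param growth list with `baseline`, `no_growth_threshold`, `control`
#'   (condition label), and `conditions`: a named list (labels = uM) of
#'   [growth_sim_params()] overrides per condition.
#' @param pigments list with `chl_a`, `chl_b` vectors and `noise_sd`.
#' @param seeds named list of integer seeds: `swimmers`, `render`,
#'   `growth`, `pigments`.
#' @param mode `"truth"` analyses ground-truth tracks directly (fast);
#'   `"render"` runs the full image pipeline (render, detect, link).
#' @param output_dir directory for the result bundle.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(ag_conc = c(0, 1.77, 2.35),
                            exposures = c(0, 15, 30, 45, 60),
                            n_videos = 5L,
                            imaging = list(px_size = 0.4, dt = 0.0396,
                                           field_px = 512L),
                            swimmers = list(),
                            detection = list(),
                            linking = list(),
                            growth = list(
                              baseline = 0.01, no_growth_threshold = 0.05,
                              control = "0",
                              conditions = default_growth_conditions()
                            ),
                            pigments = list(chl_a = c(2.8, 6.5),
                                            chl_b = c(1.4, 3.3),
                                            noise_sd = 0.002),
                            seeds = list(swimmers = 101L, render = 202L,
                                         growth = 303L, pigments = 404L),
                            mode = c("truth", "render"),
                            output_dir = tempfile("algastress_run_")) {
  cfg <- list(ag_conc = ag_conc, exposures = exposures,
              n_videos = as.integer(n_videos), imaging = imaging,
              swimmers = swimmers, detection = detection, linking = linking,
              growth = growth, pigments = pigments, seeds = seeds,
              mode = match.arg(mode), output_dir = output_dir)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Growth-simulation settings per condition
#'
#' The per-condition Gompertz parameters used by the default pipeline
#' configuration: the fitted control triple (A = 0.54 OD750,
#' mu_m = 0.0084 /hr, lag = 45.6 hr), a low-dose hormetic condition
#' (A = 0.87, mu_m = 0.0096, lag = 82.6 hr), two inhibited conditions with
#' progressively longer lags (101.3 hr and 142.7 hr, the latter with
#' heterogeneous replicate failure), and a lethal condition in which no
#' replicate grows.
#'
#' @return named list of [growth_sim_params()] argument lists, labels in uM.
#' @export
default_growth_conditions <- function() {
  list(
    "0"    = list(A = 0.54, mu_m = 0.0084, lag = 45.6),
    "0.29" = list(A = 0.87, mu_m = 0.0096, lag = 82.6),
    "0.59" = list(A = 1.00, mu_m = 0.0096, lag = 101.3),
    "0.88" = list(A = 0.40, mu_m = 0.0050, lag = 142.7, p_no_growth = 0.5),
    "1.18" = list(A = 0.20, mu_m = 0.0050, lag = 100, p_no_growth = 1)
  )
}

#' Validate a pipeline configuration
#'
#' Checks that the required keys (including a seed for every stochastic
#' stage) are present; the error message lists every missing key.
#'
#' @param cfg a configuration list.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  required <- c("ag_conc", "exposures", "n_videos", "imaging", "growth",
                "seeds", "mode", "output_dir")
  missing <- setdiff(required, names(cfg))
  seed_keys <- c("swimmers", "render", "growth", "pigments")
  if (!"seeds" %in% missing) {
    missing <- c(missing, paste0("seeds$", setdiff(seed_keys, names(cfg$seeds)),
                                 recycle0 = TRUE))
  }
  if (!"growth" %in% missing) {
    missing <- c(missing,
                 paste0("growth$",
                        setdiff(c("baseline", "control", "conditions"),
                                names(cfg$growth)),
                        recycle0 = TRUE))
  }
  if (length(missing) > 0L) {
    abort(paste0("invalid pipeline config; missing key(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(cfg)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the motility arm (simulate, optionally render/detect, link,
#' step and angle statistics, replicate and condition summaries), the
#' growth arm (simulate, fit, hormesis comparison) and a pigment
#' round-trip, writes all result tables and a manifest echoing the
#' configuration and seeds into `output_dir`, and returns the result
#' bundle. Identical configuration and seeds give a bit-identical bundle.
#'
#' @param cfg a [pipeline_config()] object.
#' @return (invisibly) a list with `rep_summary`, `condition_summary`,
#'   `growth_fits`, `hormesis`, `pigments`, `manifest`. The written bundle
#'   additionally includes per-condition speed and angle histogram tables
#'   and per-condition growth CSVs.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  im <- cfg$imaging
  dp <- do.call(detection_params,
                utils::modifyList(list(px_size = im$px_size),
                                  cfg$detection %||% list()))
  lp <- do.call(linking_params, cfg$linking %||% list())

  # ---- motility arm ----
  grid <- expand.grid(replicate = seq_len(cfg$n_videos),
                      exposure_min = cfg$exposures,
                      ag_conc = cfg$ag_conc)
  steps_all <- vector("list", nrow(grid))
  angles_all <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    sp <- do.call(swimmer_params, utils::modifyList(
      list(ag_conc = g$ag_conc, exposure_min = g$exposure_min,
           dt = im$dt, field_um = im$field_px * im$px_size),
      cfg$swimmers %||% list()
    ))
    truth <- simulate_swimmers(sp, seed = cfg$seeds$swimmers + k)
    if (cfg$mode == "render") {
      rp <- render_params(field_px = im$field_px, px_size = im$px_size)
      vid <- render_video(truth, rp, seed = cfg$seeds$render + k)
      dets <- detect_stack(vid$frames, dp)
      tracks <- filter_tracks(link(dets, lp), lp$min_length)
    } else {
      tracks <- truth |>
        select(track_id = "cell_id", "frame", "x_um", "y_um")
    }
    tracks <- mutate(tracks, ag_conc = g$ag_conc,
                     exposure_min = g$exposure_min, replicate = g$replicate)
    steps_all[[k]] <- step_velocities(tracks, dt = im$dt)
    angles_all[[k]] <- directional_changes(tracks, dt = im$dt)
  }
  steps <- bind_rows(steps_all)
  angles <- bind_rows(angles_all)
  rep_summary <- steps |>
    group_by(.data$ag_conc, .data$exposure_min, .data$replicate) |>
    summarise(mean_speed = mean(.data$speed), n_steps = n(),
              .groups = "drop") |>
    left_join(
      angles |>
        group_by(.data$ag_conc, .data$exposure_min, .data$replicate) |>
        summarise(mean_dtheta = mean(.data$dtheta), .groups = "drop"),
      by = c("ag_conc", "exposure_min", "replicate")
    )
  condition_summary <- summarize_condition(steps, angles)
  readr::write_csv(rep_summary, file.path(cfg$output_dir, "motility_replicates.csv"))
  readr::write_csv(condition_summary, file.path(cfg$output_dir, "motility_summary.csv"))
  speed_hists <- steps |>
    group_by(.data$ag_conc, .data$exposure_min) |>
    dplyr::group_modify(function(d, key) speed_histogram(d)) |>
    ungroup()
  angle_hists <- angles |>
    group_by(.data$ag_conc, .data$exposure_min) |>
    dplyr::group_modify(function(d, key) angle_histogram(d)) |>
    ungroup()
  readr::write_csv(speed_hists, file.path(cfg$output_dir, "speed_histograms.csv"))
  readr::write_csv(angle_hists, file.path(cfg$output_dir, "angle_histograms.csv"))

  # ---- growth arm ----
  gconds <- cfg$growth$conditions
  curves <- purrr::imap_dfr(gconds, function(args, label) {
    p <- do.call(growth_sim_params, args)
    simulate_growth_curves(p, seed = cfg$seeds$growth + match(label, names(gconds))) |>
      mutate(condition = label)
  })
  fits <- fit_growth_conditions(
    curves, baseline = cfg$growth$baseline,
    no_growth_threshold = cfg$growth$no_growth_threshold %||% 0.05
  )
  hormesis <- compare_conditions(fits, control = cfg$growth$control)
  per_rep_fits <- purrr::imap_dfr(fits, function(f, cond) {
    mutate(f$fits, condition = cond, .before = 1L)
  })
  readr::write_csv(per_rep_fits, file.path(cfg$output_dir, "growth_fits.csv"))
  readr::write_csv(hormesis, file.path(cfg$output_dir, "hormesis_report.csv"))
  for (label in names(gconds)) {
    write_growth_csv(filter(curves, .data$condition == label),
                     file.path(cfg$output_dir,
                               paste0("growth_", gsub("[^0-9.]", "", label), "uM.csv")))
  }

  # ---- pigment round-trip ----
  pg <- cfg$pigments %||% list(chl_a = c(2.8, 6.5), chl_b = c(1.4, 3.3),
                               noise_sd = 0.002)
  abs_tbl <- simulate_pigment_absorbances(pg$chl_a, pg$chl_b,
                                          noise_sd = pg$noise_sd %||% 0,
                                          seed = cfg$seeds$pigments)
  pig <- chlorophyll_concentrations(abs_tbl)
  write_pigments_csv(abs_tbl, file.path(cfg$output_dir, "absorbances.csv"))
  readr::write_csv(pig, file.path(cfg$output_dir, "chlorophyll.csv"))

  manifest <- list(
    config = unclass_config(cfg),
    counts = list(n_videos = nrow(grid), n_steps = nrow(steps),
                  n_angles = nrow(angles),
                  n_growth_conditions = length(gconds),
                  n_pigment_samples = nrow(abs_tbl))
  )
  write_config_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  invisible(list(rep_summary = rep_summary,
                 condition_summary = condition_summary,
                 growth_fits = per_rep_fits, hormesis = hormesis,
                 pigments = pig, manifest = manifest))
}

# strip classes/attributes so the manifest serializes cleanly to YAML
unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$ag_conc <- as.numeric(cfg$ag_conc)
  cfg$exposures <- as.numeric(cfg$exposures)
  cfg
}
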