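# File I/O with schema-checked headers. Coordinates in files are always in
# micrometers; growth tables are wide (time_hr, rep1..repN) on disk and long
# in memory.

read_csv_quiet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a multi-page TIFF stack
#'
#' Frames are stored on the unit intensity scale at the requested bit depth.
#'
#' @param frames list of numeric matrices with values in `[0, 1]`.
#' @param path output file.
#' @param bit_depth bits per sample (8 or 16).
#' @return `path`, invisibly (writer); list of matrices (reader).
#' @export
write_tiff_stack <- function(frames, path, bit_depth = 16L) {
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16")
  tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  out <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(out)) out <- list(out)
  out
}

#' Write / read detections, tracks, steps, growth and pigment tables
#'
#' Thin CSV wrappers with schema-checked headers: readers fail with an
#' error naming the first missing column. Writers return the path
#' invisibly.
#'
#' @param x tibble to write.
#' @param path CSV file path.
#' @return reader: a tibble; writer: `path`, invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_detections_csv <- function(x, path) {
  check_columns(x, c("frame", "x_um", "y_um"), "detections")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_detections_csv <- function(path) {
  check_columns(read_csv_quiet(path), c("frame", "x_um", "y_um"),
                sprintf("detections file '%s'", path))
}

#' @rdname table_io
#' @export
write_tracks_csv <- function(x, path) {
  check_columns(x, c("track_id", "frame", "x_um", "y_um"), "tracks")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_tracks_csv <- function(path) {
  check_columns(read_csv_quiet(path), c("track_id", "frame", "x_um", "y_um"),
                sprintf("tracks file '%s'", path))
}

#' @rdname table_io
#' @export
write_growth_csv <- function(x, path) {
  check_columns(x, c("time_hr", "replicate", "od"), "growth curves")
  wide <- x |>
    mutate(replicate = paste0("rep", .data$replicate)) |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "od")
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_growth_csv <- function(path) {
  wide <- read_csv_quiet(path)
  check_columns(wide, "time_hr", sprintf("growth file '%s'", path))
  rep_cols <- grep("^rep", names(wide), value = TRUE)
  if (length(rep_cols) == 0L) {
    abort(sprintf("growth file '%s' is missing required column `rep1`", path))
  }
  wide |>
    tidyr::pivot_longer(all_of(rep_cols), names_to = "replicate",
                        values_to = "od") |>
    mutate(replicate = as.integer(sub("^rep", "", .data$replicate))) |>
    arrange(.data$replicate, .data$time_hr)
}

#' @rdname table_io
#' @export
write_pigments_csv <- function(x, path) {
  check_columns(x, c("sample_id", "A663", "A645", "A750", "volume_ml"),
                "pigment samples")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_pigments_csv <- function(path) {
  check_columns(read_csv_quiet(path),
                c("sample_id", "A663", "A645", "A750", "volume_ml"),
                sprintf("pigments file '%s'", path))
}

#' Write / read a YAML configuration or manifest
#'
#' @param x a named list.
#' @param path YAML file path.
#' @return reader: a named list; writer: `path`, invisibly.
#' @export
write_config_yaml <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}
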