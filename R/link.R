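#' Trajectory-linking parameters
#'
#' @param max_disp per-frame search radius (um): a detection can extend a
#'   track only if it lies within this distance of the track's last position.
#' @param memory number of frames a track without a matched detection stays
#'   linkable before it is closed; a value of 3 allows gaps of up to 3
#'   missing frames.
#' @param min_length minimum number of retained frames for a track to
#'   survive [filter_tracks()].
#' @return a list of class `linking_params`.
#' @export
linking_params <- function(max_disp = 6, memory = 3L, min_length = 10L) {
  check_positive(max_disp, "max_disp")
  check_nonneg(memory, "memory")
  check_scalar(min_length, "min_length", function(v) v >= 2, "must be >= 2")
  structure(list(max_disp = max_disp, memory = as.integer(memory),
                 min_length = as.integer(min_length)),
            class = "linking_params")
}

#' Link detections into trajectories
#'
#' Frame-by-frame linking with optimal per-frame assignment: at each frame
#' the candidate pairs (active track, new detection) with distance at most
#' `max_disp` are assigned so that the number of links is maximized and,
#' among such assignments, the total squared displacement is minimal
#' (solved exactly on the per-frame cost matrix). Unmatched detections open
#' new tracks; unmatched tracks stay linkable for `memory` frames and then
#' close. Gap frames are not interpolated. Track ids are assigned in order
#' of track creation, and active tracks are processed in increasing id
#' order, so equal-cost ties resolve to the lowest track id.
#'
#' @param dets detections tibble with `frame`, `x_um`, `y_um`.
#' @param params a [linking_params()] object. `min_length` is applied via
#'   [filter_tracks()] after linking.
#' @return tibble with `track_id`, `frame`, `x_um`, `y_um`, ordered by
#'   track then frame.
#' @export
link <- function(dets, params = linking_params()) {
  stopifnot(inherits(params, "linking_params"))
  check_columns(dets, c("frame", "x_um", "y_um"), "dets")
  if (any(!is.finite(dets$x_um)) || any(!is.finite(dets$y_um))) {
    abort("detections contain NaN or non-finite coordinates")
  }
  if (nrow(dets) == 0L) {
    return(tibble(track_id = integer(0), frame = integer(0),
                  x_um = numeric(0), y_um = numeric(0)))
  }
  dets <- arrange(dets, .data$frame)
  frames_all <- seq(min(dets$frame), max(dets$frame))
  by_frame <- split(seq_len(nrow(dets)), factor(dets$frame, levels = frames_all))

  max_d2 <- params$max_disp^2

  # active track state
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_last <- integer(0)
  next_id <- 1L
  rows_id <- integer(nrow(dets))

  for (f in frames_all) {
    ridx <- by_frame[[as.character(f)]]
    # close tracks that exceeded memory
    alive <- (f - act_last) <= (params$memory + 1L)
    act_id <- act_id[alive]; act_x <- act_x[alive]; act_y <- act_y[alive]
    act_last <- act_last[alive]

    nd <- length(ridx)
    nt <- length(act_id)
    if (nd > 0L && nt > 0L) {
      dx <- outer(act_x, dets$x_um[ridx], "-")
      dy <- outer(act_y, dets$y_um[ridx], "-")
      d2 <- dx^2 + dy^2
      # cost of leaving a node unmatched must dominate any achievable real
      # cost (so links are maximized first), and forbidden pairs must
      # dominate skipping both nodes; keeping the scales moderate preserves
      # floating-point resolution of the real cost differences
      BIG <- 16 * max_d2 * (nt + nd) + 1e4
      FORBID <- 1e4 * BIG
      cost <- ifelse(d2 <= max_d2, d2, FORBID)
      # square matrix with dummy rows/cols: dummies cost BIG (skip), 0 among
      # themselves, so matches are maximized first, then cost minimized
      m <- nt + nd
      C <- matrix(0, m, m)
      C[seq_len(nt), seq_len(nd)] <- cost
      C[seq_len(nt), nd + seq_len(nt)] <- BIG
      C[nt + seq_len(nd), seq_len(nd)] <- BIG
      a <- solve_assignment(C)
      matched_det <- integer(nd)  # det slot -> active slot (0 = new track)
      for (ti in seq_len(nt)) {
        j <- a[ti]
        if (j <= nd && d2[ti, j] <= max_d2) matched_det[j] <- ti
      }
    } else {
      matched_det <- integer(nd)
    }

    if (nd > 0L) {
      for (j in seq_len(nd)) {
        r <- ridx[j]
        ti <- matched_det[j]
        if (ti > 0L) {
          rows_id[r] <- act_id[ti]
          act_x[ti] <- dets$x_um[r]; act_y[ti] <- dets$y_um[r]
          act_last[ti] <- f
        } else {
          rows_id[r] <- next_id
          act_id <- c(act_id, next_id)
          act_x <- c(act_x, dets$x_um[r]); act_y <- c(act_y, dets$y_um[r])
          act_last <- c(act_last, f)
          next_id <- next_id + 1L
        }
      }
    }
  }

  out <- tibble(track_id = rows_id, frame = as.integer(dets$frame),
                x_um = dets$x_um, y_um = dets$y_um)
  arrange(out, .data$track_id, .data$frame)
}

#' Drop short tracks
#'
#' Keeps tracks with at least `min_length` retained frames; the relative
#' order of the surviving rows is unchanged.
#'
#' @param tracks tibble with `track_id` (and one row per retained frame).
#' @param min_length minimum number of rows per track.
#' @return filtered tibble.
#' @export
filter_tracks <- function(tracks, min_length = 10L) {
  check_columns(tracks, "track_id", "tracks")
  keep <- tracks |>
    dplyr::count(.data$track_id) |>
    filter(.data$n >= min_length)
  filter(tracks, .data$track_id %in% keep$track_id)
}
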