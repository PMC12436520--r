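# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

DT <- 0.0396  # frame interval (s)

# ground-truth tracks reshaped for the motility functions
truth_tracks <- function(params, seed) {
  tr <- simulate_swimmers(params, seed)
  dplyr::select(tr, track_id = "cell_id", "frame", "x_um", "y_um")
}

control_params <- function(n_cells = 20L, duration_frames = 300L, ...) {
  swimmer_params(n_cells = n_cells, duration_frames = duration_frames, ...)
}

stressed_params <- function(n_cells = 20L, duration_frames = 300L, ...) {
  swimmer_params(n_cells = n_cells, duration_frames = duration_frames,
                 ag_conc = 2.35, exposure_min = 60, ...)
}

# hand-built track from a position matrix
make_track <- function(xy, frames = seq_len(nrow(xy)) - 1L, id = 1L) {
  tibble::tibble(track_id = id, frame = as.integer(frames),
                 x_um = xy[, 1L], y_um = xy[, 2L])
}

# brute-force minimum-cost maximum-cardinality matching between two frames,
# enumerating subsets and permutations (oracle for the linker)
perm_matrix <- function(n) {
  if (n == 0L) return(matrix(0L, 1L, 0L))
  if (n == 1L) return(matrix(1L))
  p <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

oracle_frame_match <- function(a, b, max_disp) {
  maxd2 <- max_disp^2
  na <- nrow(a); nb <- nrow(b)
  for (k in min(na, nb):0) {
    best <- Inf
    sas <- if (k == 0L) list(integer(0)) else utils::combn(na, k, simplify = FALSE)
    sbs <- if (k == 0L) list(integer(0)) else utils::combn(nb, k, simplify = FALSE)
    for (sa in sas) for (sb in sbs) {
      pm <- perm_matrix(k)
      for (r in seq_len(nrow(pm))) {
        if (k > 0L) {
          dd <- (a$x_um[sa] - b$x_um[sb[pm[r, ]]])^2 +
            (a$y_um[sa] - b$y_um[sb[pm[r, ]]])^2
          if (any(dd > maxd2)) next
          best <- min(best, sum(dd))
        } else {
          best <- min(best, 0)
        }
      }
    }
    if (is.finite(best)) return(c(matches = k, cost = best))
  }
  c(matches = 0L, cost = 0)
}

# total squared per-step displacement and step count of a set of tracks
track_cost <- function(tracks) {
  s <- tracks |>
    dplyr::arrange(track_id, frame) |>
    dplyr::group_by(track_id) |>
    dplyr::mutate(dx = x_um - dplyr::lag(x_um),
                  dy = y_um - dplyr::lag(y_um)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(dx))
  c(matches = nrow(s), cost = sum(s$dx^2 + s$dy^2))
}
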