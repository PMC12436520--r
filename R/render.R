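#' Rendering parameters for synthetic videos
#'
#' @param field_px field side length in pixels.
#' @param px_size pixel size (um/pixel).
#' @param cell_sigma Gaussian spot SD of a rendered cell (um). Must be at
#'   least half a pixel, otherwise spots are undetectable point sources.
#' @param snr peak spot amplitude divided by the additive noise SD.
#' @param background background intensity on the unit intensity scale.
#' @param bit_depth bits per sample used for quantization (8 or 16).
#' @param amplitude peak spot amplitude on the unit intensity scale.
#' @return a list of class `render_params`.
#' @export
render_params <- function(field_px = 512L, px_size = 0.4, cell_sigma = 1.0,
                          snr = 10, background = 0.1, bit_depth = 16L,
                          amplitude = 0.6) {
  check_positive(field_px, "field_px")
  check_positive(px_size, "px_size")
  check_positive(cell_sigma, "cell_sigma")
  if (cell_sigma < px_size / 2) {
    abort("`cell_sigma` must be at least half a pixel; smaller spots are undetectable")
  }
  check_positive(snr, "snr")
  check_nonneg(background, "background")
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16")
  check_positive(amplitude, "amplitude")
  structure(list(field_px = as.integer(field_px), px_size = px_size,
                 cell_sigma = cell_sigma, snr = snr, background = background,
                 bit_depth = as.integer(bit_depth), amplitude = amplitude),
            class = "render_params")
}

# Add one Gaussian spot to an intensity matrix (rows = y, cols = x, 0-based
# pixel centers at multiples of px_size).
add_spot <- function(img, x_um, y_um, sigma_um, px_size, amplitude) {
  n <- nrow(img)
  cx <- x_um / px_size
  cy <- y_um / px_size
  w <- ceiling(4 * sigma_um / px_size)
  c0 <- max(0L, floor(cx) - w); c1 <- min(n - 1L, ceiling(cx) + w)
  r0 <- max(0L, floor(cy) - w); r1 <- min(n - 1L, ceiling(cy) + w)
  if (c0 > c1 || r0 > r1) return(img)
  cols <- c0:c1
  rows <- r0:r1
  gx <- exp(-((cols - cx) * px_size)^2 / (2 * sigma_um^2))
  gy <- exp(-((rows - cy) * px_size)^2 / (2 * sigma_um^2))
  img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
    amplitude * outer(gy, gx)
  img
}

#' Render a synthetic video from ground-truth tracks
#'
#' Each cell is rendered as a Gaussian spot of SD `cell_sigma` on a constant
#' background; independent Gaussian noise with SD `amplitude / snr` is added
#' per pixel, and the frame is clipped to the unit intensity range and
#' quantized to `bit_depth` bits. The per-frame true positions are returned
#' alongside the frames for downstream scoring.
#'
#' @param truth ground-truth tibble from [simulate_swimmers()] (columns
#'   `cell_id`, `frame`, `x_um`, `y_um`).
#' @param rp a [render_params()] object.
#' @param seed integer seed for the noise.
#' @param frames optional integer vector of frame indices (0-based) to
#'   render; defaults to all frames present in `truth`. Rendering a subset
#'   lets callers stream long videos in chunks.
#' @return a list with `frames` (named list of `field_px` x `field_px`
#'   matrices on the unit intensity scale), `truth` (tibble of the rendered
#'   true positions), and `params`.
#' @export
render_video <- function(truth, rp = render_params(), seed, frames = NULL) {
  stopifnot(inherits(rp, "render_params"))
  check_columns(truth, c("frame", "x_um", "y_um"), "truth")
  L <- rp$field_px * rp$px_size
  if (nrow(truth) > 0 &&
      (max(truth$x_um) > L || max(truth$y_um) > L ||
       min(truth$x_um) < 0 || min(truth$y_um) < 0)) {
    abort("truth positions fall outside the rendered field")
  }
  idx <- if (is.null(frames)) sort(unique(truth$frame)) else as.integer(frames)
  if (length(idx) == 0L) idx <- 0L
  noise_sd <- rp$amplitude / rp$snr
  levels <- 2^rp$bit_depth - 1

  withr::with_seed(as.integer(seed), {
    out <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      f <- idx[k]
      img <- matrix(rp$background, rp$field_px, rp$field_px)
      cells <- truth[truth$frame == f, , drop = FALSE]
      for (i in seq_len(nrow(cells))) {
        img <- add_spot(img, cells$x_um[i], cells$y_um[i], rp$cell_sigma,
                        rp$px_size, rp$amplitude)
      }
      img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
      img <- pmin(pmax(img, 0), 1)
      out[[k]] <- round(img * levels) / levels
    }
    names(out) <- as.character(idx)
    list(frames = out,
         truth = as_tibble(truth[truth$frame %in% idx, , drop = FALSE]),
         params = rp)
  })
}
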