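#' Blob-detection parameters
#'
#' Settings for the multi-scale Laplacian-of-Gaussian (LoG) detector.
#' Frames are normalized to zero mean and unit variance before filtering,
#' so `threshold` is expressed in scale-normalized response units and
#' transfers across bit depths and illumination levels.
#'
#' @param sigma_min,sigma_max blob scale range (um), `0 < sigma_min <=
#'   sigma_max`.
#' @param n_scales number of geometrically spaced scales in the range.
#' @param threshold response cutoff for local maxima (scale-normalized LoG
#'   units on the variance-normalized image).
#' @param min_separation non-maximum-suppression radius (um).
#' @param px_size pixel size (um/pixel) used to convert to physical units.
#' @param declump split detections whose window is explained significantly
#'   better by two Gaussian spots than by one (least-squares model
#'   comparison); resolves touching cell pairs below the plain blob-
#'   detection resolution limit.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(sigma_min = 0.8, sigma_max = 1.2, n_scales = 2L,
                             threshold = 1.5, min_separation = 1.2,
                             px_size = 0.4, declump = TRUE) {
  check_positive(sigma_min, "sigma_min")
  check_positive(sigma_max, "sigma_max")
  if (sigma_min > sigma_max) abort("`sigma_min` must not exceed `sigma_max`")
  check_positive(n_scales, "n_scales")
  check_positive(threshold, "threshold")
  check_positive(min_separation, "min_separation")
  check_positive(px_size, "px_size")
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 n_scales = as.integer(n_scales), threshold = threshold,
                 min_separation = min_separation, px_size = px_size,
                 declump = isTRUE(declump)),
            class = "detection_params")
}

# Scale-normalized LoG kernel (negated, so bright blobs give positive peaks),
# sampled on an odd grid covering +-4 sigma. sigma in pixels.
log_kernel <- function(sigma_px) {
  w <- max(2L, ceiling(4 * sigma_px))
  g <- (-w):w
  r2 <- outer(g^2, g^2, "+")
  k <- (2 - r2 / sigma_px^2) * exp(-r2 / (2 * sigma_px^2))
  k / (2 * pi * sigma_px^2)
}

# FFT machinery reused across the frames of a stack: kernels are padded to a
# common composite size and transformed once.
make_log_bank <- function(field_px, params) {
  sig_um <- if (params$n_scales == 1L) {
    sqrt(params$sigma_min * params$sigma_max)
  } else {
    exp(seq(log(params$sigma_min), log(params$sigma_max),
            length.out = params$n_scales))
  }
  sig_px <- sig_um / params$px_size
  pad <- ceiling(4 * max(sig_px)) + 1L
  nfft <- nextn(field_px + 2L * pad, c(2L, 3L, 5L))
  kf <- lapply(sig_px, function(s) {
    k <- log_kernel(s)
    half <- (nrow(k) - 1L) %/% 2L
    km <- matrix(0, nfft, nfft)
    # place kernel centered at origin with wrap-around
    idx <- function(v) ((v + nfft) %% nfft) + 1L
    km[idx((-half):half), idx((-half):half)] <- k
    fft(km)
  })
  list(sig_um = sig_um, sig_px = sig_px, pad = pad, nfft = nfft, kf = kf)
}

# Per-scale LoG responses (list of matrices, one per scale). Close blob
# pairs that merge at coarse scales stay resolved at fine scales, so peak
# picking is done per scale rather than on the max-over-scales image.
log_response <- function(img, bank) {
  n <- nrow(img)
  padded <- matrix(0, bank$nfft, bank$nfft)
  # replicate-pad so the border does not ring
  ext <- n + 2L * bank$pad
  src_r <- pmin(pmax(seq_len(ext) - bank$pad, 1L), n)
  padded[seq_len(ext), seq_len(ext)] <- img[src_r, src_r]
  Fimg <- fft(padded)
  take <- bank$pad + seq_len(n)
  lapply(bank$kf, function(K) {
    resp <- Re(fft(Fimg * K, inverse = TRUE)) / length(Fimg)
    resp[take, take]
  })
}

# Strict-ish 3x3 local maxima above threshold; returns 0-based (row, col).
local_maxima <- function(resp, threshold) {
  n <- nrow(resp)
  if (n < 3L) return(cbind(row = integer(0), col = integer(0)))
  pad <- matrix(-Inf, n + 2L, n + 2L)
  pad[2:(n + 1L), 2:(n + 1L)] <- resp
  ok <- resp >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[2:(n + 1L) + dr, 2:(n + 1L) + dc]
    ok <- ok & (resp > nb | (resp == nb & (dr > 0L | (dr == 0L & dc > 0L))))
  }
  w <- which(ok, arr.ind = TRUE)
  cbind(row = w[, 1L] - 1L, col = w[, 2L] - 1L)
}

# Decide whether the window around a detection is explained significantly
# better by two Gaussian spots than by one (least-squares model comparison
# with linear amplitude + background solves). Returns NULL to keep the
# single detection, or a 2 x 2 matrix of (row, col) split positions in px.
try_split_pair <- function(z, cy, cx, others, sig_px, nv, z_med) {
  n <- nrow(z)
  w <- max(6L, ceiling(3.2 * sig_px))
  r0 <- max(0L, round(cy) - w); r1 <- min(n - 1L, round(cy) + w)
  c0 <- max(0L, round(cx) - w); c1 <- min(n - 1L, round(cx) + w)
  rows <- r0:r1; cols <- c0:c1
  win <- z[rows + 1L, cols + 1L, drop = FALSE] - z_med
  RR <- matrix(rows, length(rows), length(cols))
  CC <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  y <- as.vector(win)
  rr <- as.vector(RR); cc <- as.vector(CC)
  # exclude pixels that belong to other detections in range
  if (nrow(others) > 0L) {
    keep <- rep(TRUE, length(y))
    for (k in seq_len(nrow(others))) {
      d2 <- (rr - others[k, 1L])^2 + (cc - others[k, 2L])^2
      keep <- keep & d2 > (2 * sig_px)^2
    }
    y <- y[keep]; rr <- rr[keep]; cc <- cc[keep]
  }
  npx <- length(y)
  if (npx < 40L) return(NULL)

  ls_rss <- function(X) {
    fit <- tryCatch(stats::.lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf, coef = NULL))
    list(rss = sum(fit$residuals^2), coef = fit$coefficients)
  }
  gauss <- function(py, px, s) exp(-((rr - py)^2 + (cc - px)^2) / (2 * s^2))

  # single-spot fit, small grid over the spot width; first-order shift and
  # width derivative columns absorb sub-pixel centering error so that only
  # genuine two-spot structure can beat this model
  best1 <- list(rss = Inf)
  for (s in sig_px * c(0.8, 1.05, 1.35)) {
    g <- gauss(cy, cx, s)
    dr <- g * (rr - cy) / s
    dc <- g * (cc - cx) / s
    dsig <- g * (((rr - cy)^2 + (cc - cx)^2) / s^2 - 2)
    f <- ls_rss(cbind(g, dr, dc, dsig, 1))
    if (f$rss < best1$rss) { best1 <- f; best1$s <- s }
  }
  excess <- best1$rss - npx * nv
  if (!is.finite(excess) || excess <= 0) return(NULL)

  # principal axis of the clipped window moments
  wgt <- pmax(y - 2.5 * sqrt(nv), 0)
  tot <- sum(wgt)
  if (tot <= 0) return(NULL)
  my <- sum(wgt * rr) / tot; mx <- sum(wgt * cc) / tot
  vy <- sum(wgt * (rr - my)^2) / tot
  vx <- sum(wgt * (cc - mx)^2) / tot
  vxy <- sum(wgt * (rr - my) * (cc - mx)) / tot
  e <- eigen(matrix(c(vy, vxy, vxy, vx), 2L), symmetric = TRUE)
  v <- e$vectors[, 1L]  # (d_row, d_col)

  # two-spot fits along candidate axes, with the per-spot width free to be
  # narrower than the merged single-spot width. Near the field border the
  # window is clipped and the moment axis is unreliable, so the full
  # semicircle of axes is searched there.
  best2 <- list(rss = Inf)
  clipped <- r0 == 0L || c0 == 0L || r1 == n - 1L || c1 == n - 1L
  angles <- if (clipped) seq(0, pi - pi / 9, by = pi / 9) else c(-0.35, 0, 0.35)
  ts <- seq(0.75, max(1.5, min(w - 1.5, 4.5)), by = 0.375)
  for (s2 in sig_px * c(0.85, 1.05)) {
    for (a in angles) {
      va <- c(cos(a) * v[1L] - sin(a) * v[2L],
              sin(a) * v[1L] + cos(a) * v[2L])
      for (t in ts) {
        X <- cbind(gauss(my + t * va[1L], mx + t * va[2L], s2),
                   gauss(my - t * va[1L], mx - t * va[2L], s2), 1)
        f <- ls_rss(X)
        if (f$rss < best2$rss) { best2 <- f; best2$t <- t; best2$v <- va }
      }
    }
  }
  if (!is.finite(best2$rss)) return(NULL)
  a1 <- best2$coef[1L]; a2 <- best2$coef[2L]
  if (best1$rss - best2$rss < 15 * nv) return(NULL)
  if (is.na(a1) || is.na(a2) || min(a1, a2) < 0.25 * abs(best1$coef[1L])) {
    return(NULL)
  }
  rbind(c(my + best2$t * best2$v[1L], mx + best2$t * best2$v[2L]),
        c(my - best2$t * best2$v[1L], mx - best2$t * best2$v[2L]))
}

detect_frame <- function(img, params, bank) {
  if (sd(img) == 0) {
    return(tibble(x_um = numeric(0), y_um = numeric(0),
                  area_um2 = numeric(0), score = numeric(0)))
  }
  z <- (img - mean(img)) / sd(img)
  z_med <- stats::median(z)
  resp <- log_response(z, bank)
  pk_list <- lapply(seq_along(resp), function(s) {
    m <- local_maxima(resp[[s]], params$threshold)
    cbind(m, scale = rep(s, nrow(m)), val = resp[[s]][m[, 1:2, drop = FALSE] + 1L])
  })
  pk <- do.call(rbind, pk_list)
  if (is.null(pk) || nrow(pk) == 0L) {
    return(tibble(x_um = numeric(0), y_um = numeric(0),
                  area_um2 = numeric(0), score = numeric(0)))
  }
  ord <- order(pk[, "val"], decreasing = TRUE)
  pk <- pk[ord, , drop = FALSE]
  vals <- pk[, "val"]

  # greedy non-maximum suppression at min_separation
  sep_px2 <- (params$min_separation / params$px_size)^2
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    kept <- pk[keep, , drop = FALSE]
    d2 <- (kept[, 1L] - pk[i, 1L])^2 + (kept[, 2L] - pk[i, 2L])^2
    keep[i] <- all(d2 > sep_px2)
  }
  pk <- pk[keep, , drop = FALSE]
  vals <- vals[keep]
  scales <- pk[, "scale"]

  # sub-pixel refinement: intensity-weighted centroid of the positive part
  # of the normalized image in a window of ~2 sigma around the peak
  n <- nrow(img)
  xs <- numeric(nrow(pk)); ys <- numeric(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    w <- max(2L, ceiling(2 * bank$sig_px[scales[i]]))
    r0 <- max(0L, pk[i, 1L] - w); r1 <- min(n - 1L, pk[i, 1L] + w)
    c0 <- max(0L, pk[i, 2L] - w); c1 <- min(n - 1L, pk[i, 2L] + w)
    win <- z[(r0:r1) + 1L, (c0:c1) + 1L, drop = FALSE]
    win <- pmax(win - z_med, 0)
    tot <- sum(win)
    if (tot <= 0) { ys[i] <- pk[i, 1L]; xs[i] <- pk[i, 2L]; next }
    ys[i] <- sum(rowSums(win) * (r0:r1)) / tot
    xs[i] <- sum(colSums(win) * (c0:c1)) / tot
  }

  if (params$declump && length(xs) > 0L) {
    nv <- stats::mad(z)^2
    out_y <- list(); out_x <- list(); out_s <- list(); out_v <- list()
    for (i in seq_along(xs)) {
      sig <- bank$sig_px[scales[i]]
      others <- cbind(ys[-i], xs[-i])
      sp <- try_split_pair(z, ys[i], xs[i], others, sig, nv, z_med)
      if (is.null(sp)) {
        out_y[[i]] <- ys[i]; out_x[[i]] <- xs[i]
        out_s[[i]] <- scales[i]; out_v[[i]] <- vals[i]
      } else {
        out_y[[i]] <- sp[, 1L]; out_x[[i]] <- sp[, 2L]
        out_s[[i]] <- rep(scales[i], 2L); out_v[[i]] <- rep(vals[i], 2L)
      }
    }
    ys <- unlist(out_y); xs <- unlist(out_x)
    scales <- unlist(out_s); vals <- unlist(out_v)
  }

  tibble(
    x_um = xs * params$px_size,
    y_um = ys * params$px_size,
    area_um2 = pi * (sqrt(2) * bank$sig_um[scales])^2,
    score = 1 - exp(-vals / 5)
  )
}

#' Detect cell-like blobs in a single frame
#'
#' Runs a multi-scale Laplacian-of-Gaussian filter on the variance-normalized
#' frame, keeps local maxima above `threshold`, applies non-maximum
#' suppression at `min_separation`, and refines positions to sub-pixel
#' accuracy with an intensity-weighted centroid. A constant (degenerate)
#' frame yields zero detections rather than an error.
#'
#' @param frame a numeric matrix of finite grayscale intensities.
#' @param params a [detection_params()] object.
#' @return tibble with columns `x_um`, `y_um`, `area_um2`, `score`.
#' @export
detect_cells <- function(frame, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if (!is.matrix(frame) || !is.numeric(frame)) abort("`frame` must be a numeric matrix")
  if (any(!is.finite(frame))) abort("`frame` must be finite-valued")
  bank <- make_log_bank(nrow(frame), params)
  detect_frame(frame, params, bank)
}

#' Detect cells across a stack of frames
#'
#' @param frames a list of numeric matrices (equal size), or the `frames`
#'   element of a [render_video()] result. Names, if present and numeric,
#'   are used as 0-based frame indices.
#' @param params a [detection_params()] object.
#' @return tibble with columns `frame`, `x_um`, `y_um`, `area_um2`, `score`.
#' @export
detect_stack <- function(frames, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if (length(frames) == 0L) {
    return(tibble(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                  area_um2 = numeric(0), score = numeric(0)))
  }
  idx <- suppressWarnings(as.integer(names(frames)))
  if (is.null(names(frames)) || any(is.na(idx))) idx <- seq_along(frames) - 1L
  bank <- make_log_bank(nrow(frames[[1L]]), params)
  res <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    d <- detect_frame(frames[[k]], params, bank)
    if (nrow(d) > 0) d <- mutate(d, frame = idx[k], .before = 1L)
    else d <- tibble(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                     area_um2 = numeric(0), score = numeric(0))
    res[[k]] <- d
  }
  bind_rows(res)
}
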