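# Bead detection and tracking: discoidal averaging filter, threshold +
# local-maximum peak detection, subpixel 2-D Gaussian localization,
# nearest-neighbour radius-search linking, drift correction against stuck
# beads, and the closed-form localization-precision limit.
#
# Image convention: matrices indexed [row, col]; x runs along columns (the
# flow axis), y along rows. Subpixel positions are 0-based, pixel-center,
# so the center of the top-left pixel is (x, y) = (0, 0).

#' Discoidal averaging filter
#'
#' At each pixel, the mean over the inner disk (Euclidean radius <=
#' `r_inner`, center included) minus the mean over the surrounding annulus
#' (`r_inner` < radius <= `r_outer`). Amplifies bead-sized spots over
#' slowly-varying background: constant images map to zero and the operator
#' is linear. Near the borders, kernels are truncated to in-bounds pixels
#' (no padding), avoiding spurious boundary maxima.
#'
#' @param img Numeric matrix.
#' @param r_inner Inner disk radius in pixels (default 2).
#' @param r_outer Outer annulus radius in pixels (default 5).
#' @return Filtered matrix of the same size.
#' @export
discoidal_filter <- function(img, r_inner = 2, r_outer = 5) {
  stopifnot(is.matrix(img))
  if (!(r_inner > 0 && r_outer > r_inner)) {
    stop("discoidal_filter: need 0 < r_inner < r_outer")
  }
  nr <- nrow(img); nc <- ncol(img)
  rmax <- floor(r_outer)
  offs <- expand.grid(di = -rmax:rmax, dj = -rmax:rmax)
  d2 <- offs$di^2 + offs$dj^2
  disk <- offs[d2 <= r_inner^2, ]
  ann <- offs[d2 > r_inner^2 & d2 <= r_outer^2, ]
  shift_sum <- function(offsets) {
    acc <- matrix(0, nr, nc)
    cnt <- matrix(0, nr, nc)
    for (k in seq_len(nrow(offsets))) {
      di <- offsets$di[k]; dj <- offsets$dj[k]
      r_dst <- max(1, 1 - di):min(nr, nr - di)
      c_dst <- max(1, 1 - dj):min(nc, nc - dj)
      acc[r_dst, c_dst] <- acc[r_dst, c_dst] + img[r_dst + di, c_dst + dj]
      cnt[r_dst, c_dst] <- cnt[r_dst, c_dst] + 1
    }
    acc / cnt
  }
  shift_sum(disk) - shift_sum(ann)
}

#' Detect peaks by intensity threshold plus local-maximum selection
#'
#' Candidate pixels exceed `threshold`; candidates are accepted greedily in
#' order of decreasing intensity (ties: smaller row, then smaller column),
#' rejecting any candidate within Euclidean distance `min_separation` of an
#' already-accepted peak. Every returned pixel is therefore the maximum
#' within `min_separation` and no two returns are closer than that.
#'
#' @param filtered Numeric matrix (typically the discoidal-filtered image).
#' @param threshold Intensity threshold (> 0).
#' @param min_separation Minimum peak separation in pixels.
#' @return Data frame with integer 0-based `x` (col), `y` (row), `value`.
#' @export
detect_peaks <- function(filtered, threshold, min_separation = 3) {
  stopifnot(is.matrix(filtered), threshold > 0, min_separation > 0)
  idx <- which(filtered > threshold)
  if (length(idx) == 0) {
    return(data.frame(x = integer(), y = integer(), value = numeric()))
  }
  nr <- nrow(filtered)
  row <- (idx - 1) %% nr + 1
  col <- (idx - 1) %/% nr + 1
  val <- filtered[idx]
  ord <- order(-val, row, col)
  row <- row[ord]; col <- col[ord]; val <- val[ord]
  keep_r <- numeric(0); keep_c <- numeric(0); keep_v <- numeric(0)
  min2 <- min_separation^2
  for (i in seq_along(row)) {
    if (length(keep_r) == 0 ||
        all((keep_r - row[i])^2 + (keep_c - col[i])^2 >= min2)) {
      keep_r <- c(keep_r, row[i]); keep_c <- c(keep_c, col[i])
      keep_v <- c(keep_v, val[i])
    }
  }
  data.frame(x = keep_c - 1L, y = keep_r - 1L, value = keep_v)
}

#' Subpixel localization by isotropic 2-D Gaussian least squares
#'
#' Default model: `I(x, y) = B + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 s^2))`
#' sampled at pixel centers, fitted by Levenberg-Marquardt least squares.
#' The photon count is estimated as `N = 2*pi*A*s^2` (unit camera gain
#' assumed; scale `A` beforehand for other gains). For photon-limited
#' precision work, `model = "integrated"` fits the pixel-integrated
#' Gaussian instead (with `A` then the total photon count), and supplying
#' `background_sd` enables variance weighting `1/(b^2 + mu)` (two IRLS
#' passes), which approaches the efficiency of a maximum-likelihood fit
#' for mixed Poisson/Gaussian noise.
#'
#' @param patch Numeric matrix, at least 5x5.
#' @param init Optional list with starting values `x`, `y`, `A`, `s`, `B`
#'   (0-based patch coordinates). Defaults: brightest pixel, `s = 1.5`.
#' @param model `"sampled"` (default) or `"integrated"`.
#' @param background_sd Optional background noise sd enabling variance
#'   weighting.
#' @return List of class `peak_fit` with `ok`, `x`, `y`, `A`, `s`, `B`,
#'   `N`, `rss`. `ok = FALSE` flags a failed fit (non-convergence,
#'   non-positive amplitude, or center outside the patch); such peaks
#'   should be dropped.
#' @export
fit_gaussian_2d <- function(patch, init = NULL,
                            model = c("sampled", "integrated"),
                            background_sd = NULL) {
  stopifnot(is.matrix(patch))
  model <- match.arg(model)
  nr <- nrow(patch); nc <- ncol(patch)
  if (nr < 5 || nc < 5) stop("fit_gaussian_2d: patch must be at least 5x5")
  xs <- rep(0:(nc - 1), each = nr)   # column-major flattening
  ys <- rep(0:(nr - 1), times = nc)
  z <- as.numeric(patch)
  if (is.null(init)) {
    B0 <- min(z)
    imax <- which.max(z)
    init <- list(x = xs[imax], y = ys[imax], A = max(z) - B0, s = 1.5, B = B0)
  }
  fail <- structure(list(ok = FALSE, x = NA_real_, y = NA_real_,
                         A = NA_real_, s = NA_real_, B = NA_real_,
                         N = NA_real_, rss = NA_real_), class = "peak_fit")
  if (!is.finite(init$A) || init$A <= 0) return(fail)
  spot <- if (model == "sampled") {
    function(p) p[1] * exp(-((xs - p[2])^2 + (ys - p[3])^2) / (2 * p[4]^2))
  } else {
    function(p) {
      fx <- stats::pnorm(xs + 0.5, p[2], abs(p[4])) -
        stats::pnorm(xs - 0.5, p[2], abs(p[4]))
      fy <- stats::pnorm(ys + 0.5, p[3], abs(p[4])) -
        stats::pnorm(ys - 0.5, p[3], abs(p[4]))
      p[1] * fx * fy
    }
  }
  par <- c(init$A, init$x, init$y, init$s, init$B)
  if (model == "integrated") par[1] <- par[1] * 2 * pi * par[4]^2
  w <- rep(1, length(z))
  n_pass <- if (is.null(background_sd)) 1 else 2
  fit <- NULL
  for (pass in seq_len(n_pass)) {
    sw <- sqrt(w)
    resid_fn <- function(p) sw * (z - (p[5] + spot(p)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) return(fail)
    par <- fit$par
    if (pass < n_pass) w <- 1 / (background_sd^2 + pmax(spot(par), 0))
  }
  p <- fit$par
  A <- p[1]; x0 <- p[2]; y0 <- p[3]; s <- abs(p[4]); B <- p[5]
  if (!all(is.finite(p)) || A <= 0 || s <= 0 ||
      x0 < -0.5 || x0 > nc - 0.5 || y0 < -0.5 || y0 > nr - 0.5) {
    return(fail)
  }
  N <- if (model == "integrated") A else 2 * pi * A * s^2
  structure(list(ok = TRUE, x = x0, y = y0, A = A, s = s, B = B,
                 N = N, rss = sum(fit$fvec^2)),
            class = "peak_fit")
}

#' Link per-frame detections into trajectories by local radius search
#'
#' Frame to frame, detections are matched to open tracks by mutual-nearest
#' greedy assignment in order of ascending distance (ties: ascending
#' detection index); only links shorter than `radius` are made. Unmatched
#' detections open new tracks; tracks survive unmatched for up to
#' `max_gap` frames.
#'
#' @param detections List indexed by frame; each element a data frame with
#'   columns `x`, `y` (in um) and optionally others, or NULL/empty.
#' @param radius Maximum link distance (um).
#' @param max_gap Frames a track may go undetected (default 0).
#' @return List of tracks; each a data frame with columns `frame` (1-based
#'   index into `detections`), `x`, `y`.
#' @export
link_trajectories <- function(detections, radius, max_gap = 0) {
  stopifnot(radius > 0, max_gap >= 0)
  tracks <- list()
  open_track <- integer(0)   # track index
  open_x <- numeric(0); open_y <- numeric(0); open_frame <- integer(0)
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    nd <- if (is.null(det)) 0L else nrow(det)
    # expire tracks whose last detection is too old
    live <- open_frame >= f - 1 - max_gap
    open_track <- open_track[live]; open_x <- open_x[live]
    open_y <- open_y[live]; open_frame <- open_frame[live]
    assigned_det <- integer(0)
    if (nd > 0 && length(open_track) > 0) {
      dx <- outer(open_x, det$x, "-")
      dy <- outer(open_y, det$y, "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= radius, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(dist[cand], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        used_tr <- rep(FALSE, length(open_track))
        used_de <- rep(FALSE, nd)
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_tr[i] && !used_de[j]) {
            used_tr[i] <- TRUE; used_de[j] <- TRUE
            ti <- open_track[i]
            tracks[[ti]] <- rbind(tracks[[ti]],
                                  data.frame(frame = f, x = det$x[j], y = det$y[j]))
            open_x[i] <- det$x[j]; open_y[i] <- det$y[j]; open_frame[i] <- f
          }
        }
        assigned_det <- which(used_de)
      }
    }
    if (nd > 0) {
      for (j in setdiff(seq_len(nd), assigned_det)) {
        tracks[[length(tracks) + 1]] <-
          data.frame(frame = f, x = det$x[j], y = det$y[j])
        open_track <- c(open_track, length(tracks))
        open_x <- c(open_x, det$x[j]); open_y <- c(open_y, det$y[j])
        open_frame <- c(open_frame, f)
      }
    }
  }
  tracks
}

# Running local-linear (Savitzky-Golay order 1) smoother: at each index,
# fit a line to the window [i-h, i+h] (truncated at the edges) and evaluate
# it at t[i]. Exact for linear input even in truncated edge windows.
running_linear_smooth <- function(t, v, half_window) {
  n <- length(t)
  c1 <- c(0, cumsum(rep(1, n)))
  ctv <- c(0, cumsum(t * v))
  ct <- c(0, cumsum(t))
  cv <- c(0, cumsum(v))
  ctt <- c(0, cumsum(t^2))
  i0 <- pmax(1, seq_len(n) - half_window)
  i1 <- pmin(n, seq_len(n) + half_window)
  m <- i1 - i0 + 1
  st <- ct[i1 + 1] - ct[i0]
  sv <- cv[i1 + 1] - cv[i0]
  stt <- ctt[i1 + 1] - ctt[i0]
  stv <- ctv[i1 + 1] - ctv[i0]
  sxx <- stt - st^2 / m
  sxy <- stv - st * sv / m
  slope <- ifelse(sxx > 0, sxy / sxx, 0)
  sv / m + slope * (t - st / m)
}

#' Correct stage drift against stuck reference beads
#'
#' Drift is estimated as the mean displacement of the stuck tracks from
#' their initial positions, smoothed with a running local-linear fit over
#' `window` seconds, and subtracted from all tracks. Pairwise distances
#' between beads are unaffected (the same offset is removed everywhere).
#'
#' @param tracks List of data frames with columns `frame`, `x`, `y`; all
#'   tracks must share the frame grid of the stuck tracks.
#' @param stuck_idx Indices into `tracks` of the stuck reference beads,
#'   which must span the experiment.
#' @param window Smoothing window in seconds (default 300, i.e. 5 min).
#' @param frame_rate Frames per second used to convert `window` to frames.
#' @return List of drift-corrected tracks, with the estimated drift
#'   attached as attribute `drift` (data frame `frame`, `dx`, `dy`).
#' @export
correct_drift <- function(tracks, stuck_idx, window = 300, frame_rate = 1) {
  if (length(stuck_idx) == 0) {
    stop("correct_drift: no stuck reference tracks; skip drift correction")
  }
  frames <- sort(unique(unlist(lapply(tracks[stuck_idx], function(tr) tr$frame))))
  acc_x <- numeric(length(frames)); acc_y <- numeric(length(frames))
  cnt <- numeric(length(frames))
  for (si in stuck_idx) {
    tr <- tracks[[si]]
    pos <- match(tr$frame, frames)
    acc_x[pos] <- acc_x[pos] + (tr$x - tr$x[1])
    acc_y[pos] <- acc_y[pos] + (tr$y - tr$y[1])
    cnt[pos] <- cnt[pos] + 1
  }
  ok <- cnt > 0
  frames <- frames[ok]
  dx <- acc_x[ok] / cnt[ok]
  dy <- acc_y[ok] / cnt[ok]
  h <- max(1L, round(window * frame_rate / 2))
  tt <- frames / frame_rate
  dxs <- running_linear_smooth(tt, dx, h)
  dys <- running_linear_smooth(tt, dy, h)
  out <- lapply(tracks, function(tr) {
    pos <- match(tr$frame, frames)
    if (anyNA(pos)) {
      # interpolate drift for frames missing from the reference grid
      tr$x <- tr$x - stats::approx(frames, dxs, xout = tr$frame, rule = 2)$y
      tr$y <- tr$y - stats::approx(frames, dys, xout = tr$frame, rule = 2)$y
    } else {
      tr$x <- tr$x - dxs[pos]
      tr$y <- tr$y - dys[pos]
    }
    tr
  })
  attr(out, "drift") <- data.frame(frame = frames, dx = dxs, dy = dys)
  out
}

#' Theoretical localization precision of a Gaussian spot
#'
#' `sigma = sqrt(s^2/N + a^2/(12 N) + 8 pi s^4 b^2 / (a^2 N^2))` with `N`
#' photons, pixel size `a`, background standard deviation `b` and spot
#' standard deviation `s` (`a` and `s` in the same length units, which are
#' also the units of the result).
#'
#' @param N Photon count (> 0).
#' @param a Pixel size (> 0).
#' @param b Background standard deviation (>= 0, intensity units).
#' @param s Spot standard deviation (> 0).
#' @return Localization precision, same units as `s` and `a`.
#' @export
localization_precision <- function(N, a, b, s) {
  if (any(N <= 0) || any(a <= 0) || any(b < 0) || any(s <= 0)) {
    stop("localization_precision: N, a, s must be > 0 and b >= 0")
  }
  sqrt(s^2 / N + a^2 / (12 * N) + 8 * pi * s^4 * b^2 / (a^2 * N^2))
}

#' Field of view from sensor geometry and magnification
#'
#' @param n_px_x,n_px_y Sensor size in pixels.
#' @param pixel_pitch Physical pixel pitch in um.
#' @param magnification Optical magnification.
#' @return Numeric vector `c(width_um, height_um)` (unrounded; round only
#'   for presentation).
#' @export
estimate_fov <- function(n_px_x, n_px_y, pixel_pitch, magnification) {
  stopifnot(n_px_x > 0, n_px_y > 0, pixel_pitch > 0, magnification > 0)
  c(width_um = n_px_x * pixel_pitch / magnification,
    height_um = n_px_y * pixel_pitch / magnification)
}

#' Track beads through an image stack
#'
#' Runs the full detection chain on every frame -- discoidal filter,
#' threshold + local maxima, subpixel Gaussian refinement -- then links the
#' localizations into trajectories. Positions are converted to um using
#' `pixel_size`.
#'
#' @param frames 3-D array `[frame, row, col]` or list of matrices.
#' @param pixel_size um per pixel.
#' @param frame_rate Frames per second (sets trajectory timestamps).
#' @param threshold Detection threshold on the filtered image.
#' @param min_separation Minimum peak separation (pixels).
#' @param patch_half Half-size of the fit patch (default 3, i.e. 7x7).
#' @param radius Link radius in um.
#' @param max_gap Allowed linking gap in frames.
#' @param r_inner,r_outer Discoidal filter radii.
#' @return A `mol_archive` with one record per track (frames are 0-based in
#'   the records).
#' @export
track_beads <- function(frames, pixel_size, frame_rate, threshold,
                        min_separation = 5, patch_half = 3, radius = 2,
                        max_gap = 0, r_inner = 2, r_outer = 5) {
  get_frame <- if (is.list(frames)) {
    function(i) frames[[i]]
  } else {
    function(i) frames[i, , ]
  }
  n_frames <- if (is.list(frames)) length(frames) else dim(frames)[1]
  detections <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- get_frame(f)
    filt <- discoidal_filter(img, r_inner, r_outer)
    peaks <- detect_peaks(filt, threshold, min_separation)
    if (nrow(peaks) == 0) next
    xs <- numeric(0); ys <- numeric(0)
    for (k in seq_len(nrow(peaks))) {
      r0 <- max(1, peaks$y[k] + 1 - patch_half)
      r1 <- min(nrow(img), peaks$y[k] + 1 + patch_half)
      c0 <- max(1, peaks$x[k] + 1 - patch_half)
      c1 <- min(ncol(img), peaks$x[k] + 1 + patch_half)
      if (r1 - r0 < 4 || c1 - c0 < 4) next
      fit <- fit_gaussian_2d(img[r0:r1, c0:c1])
      if (!fit$ok) next
      xs <- c(xs, (c0 - 1 + fit$x) * pixel_size)
      ys <- c(ys, (r0 - 1 + fit$y) * pixel_size)
    }
    if (length(xs) > 0) detections[[f]] <- data.frame(x = xs, y = ys)
  }
  tracks <- link_trajectories(detections, radius = radius, max_gap = max_gap)
  arch <- new_archive(metadata = list(
    pixel_size_um = pixel_size, frame_rate_hz = frame_rate,
    tracking = list(threshold = threshold, min_separation = min_separation,
                    radius_um = radius, max_gap = max_gap,
                    r_inner = r_inner, r_outer = r_outer)))
  uids <- fmt_uuid(length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    arch <- add_record(arch, mol_record(
      uid = uids[i],
      trajectory = data.frame(t_s = (tr$frame - 1) / frame_rate,
                              frame = tr$frame - 1L,
                              x_um = tr$x, y_um = tr$y),
      log = "tracked with discoidal filter + Gaussian fit + radius linking"))
  }
  arch
}
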