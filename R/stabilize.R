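#' Rigid motion correction by Lucas-Kanade feature tracking
#'
#' Aircraft vibrations during parabolic flight shift the sample by about
#' a micron between frames. The correction pipeline follows the classic
#' sparse optical-flow recipe: detect trackable points on a reference
#' frame (Shi-Tomasi criterion), track them between consecutive frames
#' with the iterative Lucas-Kanade solver (which assumes small
#' frame-to-frame motion), reduce the per-point displacements to one
#' robust global translation per frame (component-wise median), and
#' resample every frame to cancel the accumulated shift.
#'
#' @name stabilize
NULL

# Central-difference spatial gradients; border rows/cols replicate.
#' @noRd
image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gy <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  gx <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  list(gy = gy / 2, gx = gx / 2)
}

# Box-sum filter via cumulative sums (window w odd).
#' @noRd
box_sum <- function(img, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2 * h, nc + 2 * h)
  pad[(h + 1):(h + nr), (h + 1):(h + nc)] <- img
  cs <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  Z <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  Z[-1, -1] <- cs
  i1 <- 1:nr; i2 <- i1 + 2 * h
  j1 <- 1:nc; j2 <- j1 + 2 * h
  Z[i2 + 1, j2 + 1] - Z[i1, j2 + 1] - Z[i2 + 1, j1] + Z[i1, j1]
}

#' Detect trackable feature points (Shi-Tomasi criterion)
#'
#' Scores each pixel by the minimum eigenvalue of the local structure
#' tensor (spatial-gradient outer products summed over a window), keeps
#' local maxima whose score exceeds \code{quality_level} times the global
#' maximum, and greedily thins them to a minimum pairwise distance, best
#' first, capped at \code{max_n} points.
#'
#' @param frame Numeric matrix (one movie frame).
#' @param max_n Maximum number of features (>= 1).
#' @param quality_level Fraction of the best score below which candidates
#'   are dropped (default 0.05).
#' @param min_distance Minimum pairwise distance between kept features,
#'   px (default 8).
#' @param window Structure-tensor summation window, odd px (default 7).
#' @return data.frame with columns \code{row}, \code{col},
#'   \code{quality}; zero rows if the frame has no texture.
#' @export
detect_features <- function(frame, max_n = 100, quality_level = 0.05,
                            min_distance = 8, window = 7) {
  stopifnot(max_n >= 1, all(is.finite(frame)))
  g <- image_gradients(frame)
  a <- box_sum(g$gy * g$gy, window)
  b <- box_sum(g$gy * g$gx, window)
  c_ <- box_sum(g$gx * g$gx, window)
  min_eig <- ((a + c_) - sqrt((a - c_)^2 + 4 * b^2)) / 2
  m <- max(min_eig)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      quality = numeric(0))
  if (m <= 0) return(empty)

  # exclude a border so tracking windows fit
  bw <- max(window, 5L)
  nr <- nrow(frame); nc <- ncol(frame)
  min_eig[c(1:bw, (nr - bw + 1):nr), ] <- 0
  min_eig[, c(1:bw, (nc - bw + 1):nc)] <- 0

  # strict local maxima over the 8-neighbourhood
  sh <- function(dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- min_eig[rs, cs]
    out
  }
  is_max <- min_eig >= quality_level * m
  for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1)))
    is_max <- is_max & (min_eig >= sh(d[1], d[2]))
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  qual <- min_eig[idx]
  ord <- order(qual, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; qual <- qual[ord]

  keep_r <- numeric(0); keep_c <- numeric(0); keep_q <- numeric(0)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; cc <- idx[i, 2]
    if (length(keep_r) == 0 ||
        all((keep_r - r)^2 + (keep_c - cc)^2 >= min_distance^2)) {
      keep_r <- c(keep_r, r); keep_c <- c(keep_c, cc)
      keep_q <- c(keep_q, qual[i])
      if (length(keep_r) >= max_n) break
    }
  }
  data.frame(row = keep_r, col = keep_c, quality = keep_q)
}

#' Iterative Lucas-Kanade point tracking between two frames
#'
#' For each point, solves the 2x2 normal equations of the window's
#' spatial gradients (from \code{frame_a}) against the temporal residual
#' \code{frame_a - frame_b(shifted)}, updates the displacement, and
#' repeats until the update norm falls below \code{tol} or
#' \code{max_iter} iterations. Valid only while the structure tensor is
#' well conditioned and the tracked point stays inside the frame.
#'
#' @param frame_a,frame_b Numeric matrices of identical size.
#' @param points data.frame with \code{row}, \code{col} (subpixel ok).
#' @param window Odd tracking window size in px, >= 5 (default 15).
#' @param max_iter Maximum iterations (default 30).
#' @param tol Convergence threshold on the update norm, px (default 1e-3).
#' @param min_eig_threshold Minimum normalized structure-tensor
#'   eigenvalue for a point to be trackable (default 1e-4 of the window
#'   intensity scale).
#' @param init Optional length-2 (dy, dx) warm-start displacement
#'   applied to all points.
#' @param normalize Z-normalize each window (zero mean, unit variance)
#'   before matching (default TRUE). Makes the match invariant to
#'   per-window gain and offset changes, which matters when tracking
#'   features on neurons whose brightness swings with calcium
#'   transients.
#' @return List: \code{displacement} (n x 2 matrix, (dy, dx)),
#'   \code{valid} (logical n).
#' @export
lk_track <- function(frame_a, frame_b, points, window = 15, max_iter = 30,
                     tol = 1e-3, min_eig_threshold = 1e-4, init = NULL,
                     normalize = TRUE) {
  stopifnot(all(dim(frame_a) == dim(frame_b)), window >= 5,
            window %% 2 == 1)
  n <- nrow(points)
  disp <- matrix(0, n, 2)
  valid <- rep(TRUE, n)
  if (n == 0) return(list(displacement = disp, valid = valid))
  if (!is.null(init)) {
    disp <- if (is.matrix(init)) init
            else matrix(rep(as.numeric(init), each = n), n, 2)
  }
  h <- (window - 1) / 2
  off <- expand.grid(dr = -h:h, dc = -h:h)
  m <- nrow(off)
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  g <- image_gradients(frame_a)
  scale2 <- mean(g$gy^2 + g$gx^2) + .Machine$double.eps

  # window sample positions, one row per point (n x m)
  WR <- outer(points$row, off$dr, "+")
  WC <- outer(points$col, off$dc, "+")
  inb <- points$row - h >= 1 & points$row + h <= nr &
    points$col - h >= 1 & points$col + h <= nc
  valid <- inb
  Iy <- matrix(bilinear_sample(g$gy, as.vector(WR), as.vector(WC)), n, m)
  Ix <- matrix(bilinear_sample(g$gx, as.vector(WR), as.vector(WC)), n, m)
  Ia <- matrix(bilinear_sample(frame_a, as.vector(WR), as.vector(WC)), n, m)
  Gyy <- rowSums(Iy * Iy); Gyx <- rowSums(Iy * Ix); Gxx <- rowSums(Ix * Ix)
  det <- Gyy * Gxx - Gyx^2
  tr_ <- Gyy + Gxx
  min_eig <- (tr_ - sqrt(pmax(tr_^2 - 4 * det, 0))) / 2
  valid <- valid & min_eig >= min_eig_threshold * scale2 * window^2 & det > 0

  if (normalize) {
    mu_a <- rowMeans(Ia)
    sd_a <- sqrt(pmax(rowMeans(Ia^2) - mu_a^2, .Machine$double.eps))
    Ia <- (Ia - mu_a) / sd_a
    Iy <- Iy / sd_a
    Ix <- Ix / sd_a
    Gyy <- rowSums(Iy * Iy); Gyx <- rowSums(Iy * Ix); Gxx <- rowSums(Ix * Ix)
    det <- Gyy * Gxx - Gyx^2
    valid <- valid & det > 0
  }

  active <- which(valid)
  for (it in seq_len(max_iter)) {
    if (length(active) == 0) break
    R2 <- WR[active, , drop = FALSE] + disp[active, 1]
    C2 <- WC[active, , drop = FALSE] + disp[active, 2]
    out <- rowSums(R2 < 1 | R2 > nr | C2 < 1 | C2 > nc) > 0
    if (any(out)) {
      valid[active[out]] <- FALSE
      active <- active[!out]
      if (length(active) == 0) break
      R2 <- WR[active, , drop = FALSE] + disp[active, 1]
      C2 <- WC[active, , drop = FALSE] + disp[active, 2]
    }
    Ib <- matrix(bilinear_sample(frame_b, as.vector(R2), as.vector(C2)),
                 length(active), m)
    if (normalize) {
      mu_b <- rowMeans(Ib)
      sd_b <- sqrt(pmax(rowMeans(Ib^2) - mu_b^2, .Machine$double.eps))
      Ib <- (Ib - mu_b) / sd_b
    }
    res <- Ia[active, , drop = FALSE] - Ib
    by <- rowSums(Iy[active, , drop = FALSE] * res)
    bx <- rowSums(Ix[active, , drop = FALSE] * res)
    dte <- det[active]
    dy <- (Gxx[active] * by - Gyx[active] * bx) / dte
    dx <- (Gyy[active] * bx - Gyx[active] * by) / dte
    disp[active, 1] <- disp[active, 1] + dy
    disp[active, 2] <- disp[active, 2] + dx
    conv <- sqrt(dy^2 + dx^2) < tol
    active <- active[!conv]
  }
  disp[!valid, ] <- 0
  list(displacement = disp, valid = valid)
}

# 2x2 block-average downsampling (odd trailing row/col cropped).
#' @noRd
downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(nr), seq_len(nc)]
  (img[seq(1, nr, 2), seq(1, nc, 2)] + img[seq(2, nr, 2), seq(1, nc, 2)] +
     img[seq(1, nr, 2), seq(2, nc, 2)] + img[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

#' Coarse-to-fine (pyramidal) Lucas-Kanade tracking
#'
#' Runs [lk_track()] on a block-averaged image pyramid, propagating each
#' point's displacement from coarse to fine levels. Extends the tracker
#' beyond its small-motion assumption (roughly
#' \code{2^(levels-1)} times the single-level range). Not needed for the
#' ~1 px displacements of the default regime, hence optional.
#'
#' @inheritParams lk_track
#' @param levels Pyramid levels (default 3; 1 falls back to plain LK).
#' @return As [lk_track()].
#' @export
lk_track_pyramid <- function(frame_a, frame_b, points, levels = 3,
                             window = 15, max_iter = 30, tol = 1e-3,
                             min_eig_threshold = 1e-4, normalize = TRUE) {
  stopifnot(levels >= 1)
  pyr_a <- list(frame_a); pyr_b <- list(frame_b)
  if (levels > 1) for (l in 2:levels) {
    pyr_a[[l]] <- downsample2(pyr_a[[l - 1]])
    pyr_b[[l]] <- downsample2(pyr_b[[l - 1]])
  }
  n <- nrow(points)
  disp <- matrix(0, n, 2)
  valid <- rep(TRUE, n)
  for (l in seq(levels, 1)) {
    sc <- 2^(l - 1)
    pts_l <- data.frame(row = (points$row - 1) / sc + 1,
                        col = (points$col - 1) / sc + 1)
    tr <- lk_track(pyr_a[[l]], pyr_b[[l]], pts_l, window = window,
                   max_iter = max_iter, tol = max(tol / sc, 1e-4),
                   min_eig_threshold = min_eig_threshold,
                   init = disp / sc, normalize = normalize)
    disp <- tr$displacement * sc
    valid <- valid & tr$valid
  }
  disp[!valid, ] <- 0
  list(displacement = disp, valid = valid)
}

#' Robust global shift from per-point displacements
#'
#' Component-wise median over valid points; robust against the minority
#' of features that sit on blinking neurons or drift independently.
#'
#' @param displacement n x 2 matrix of (dy, dx) per point.
#' @param valid Logical vector (default all TRUE).
#' @return Length-2 numeric (dy, dx).
#' @export
estimate_global_shift <- function(displacement,
                                  valid = rep(TRUE, nrow(displacement))) {
  d <- displacement[valid, , drop = FALSE]
  if (nrow(d) == 0) stop("no valid displacements")
  c(stats::median(d[, 1]), stats::median(d[, 2]))
}

#' Stabilize a movie stack
#'
#' Tracks Shi-Tomasi features from a reference frame to every later
#' frame with Lucas-Kanade (warm-started at the previous frame's shift,
#' so the per-iteration motion stays small), reduces them to one global
#' shift per frame relative to frame 1, and resamples every frame by
#' subpixel translation (bilinear, constant-edge padding) to cancel it.
#' The reference frame and its features are refreshed every
#' \code{refresh_every} frames (or when fewer than \code{min_features}
#' remain trackable) to bound drift; anchoring on a reference rather
#' than chaining consecutive pairs keeps per-pair errors from
#' accumulating as a random walk. A frame on which tracking fails
#' inherits the previous shift and is flagged.
#'
#' @param stack A [movie_stack()].
#' @param max_features Features to detect (default 60).
#' @param window LK window, odd px (default 15).
#' @param quality_level Shi-Tomasi quality fraction (default 0.05).
#' @param min_distance Feature thinning distance, px (default 10).
#' @param refresh_every Re-detect features every this many frames
#'   (default 50).
#' @param min_features Re-detect when fewer valid features remain
#'   (default 4).
#' @param max_iter,tol LK iteration controls.
#' @param presmooth_sigma Gaussian sigma (px) applied to the frames used
#'   for detection and tracking only (default 2). Shot noise at
#'   realistic counts carries gradient energy comparable to a dim
#'   soma's, so unsmoothed Shi-Tomasi scores peak on noise; smoothing
#'   suppresses the (spatially uncorrelated) noise gradients far more
#'   than the blob gradients. The correction itself always resamples
#'   the raw frames.
#' @return List: \code{stack} (corrected [movie_stack()]),
#'   \code{trajectory} data.frame (\code{frame}, \code{dy_px},
#'   \code{dx_px}, \code{dy_um}, \code{dx_um}, \code{n_valid},
#'   \code{flagged}).
#' @export
stabilize_stack <- function(stack, max_features = 60, window = 21,
                            quality_level = 0.05, min_distance = 10,
                            refresh_every = 50, min_features = 4,
                            max_iter = 10, tol = 5e-3,
                            presmooth_sigma = 2) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$data)
  n_frames <- d[1]
  if (n_frames < 2) stop("need >= 2 frames")

  smooth <- if (presmooth_sigma > 0)
    function(m) as.matrix(EBImage::gblur(m, presmooth_sigma))
  else identity

  cum <- matrix(0, n_frames, 2)
  nval <- integer(n_frames); nval[1] <- NA_integer_
  flagged <- rep(FALSE, n_frames)

  ref <- smooth(stack$data[1, , ])
  ref_offset <- c(0, 0)      # global shift of the reference frame itself
  pts <- detect_features(ref, max_n = max_features,
                         quality_level = quality_level,
                         min_distance = min_distance)
  since_detect <- 0L
  for (f in 2:n_frames) {
    fb <- smooth(stack$data[f, , ])
    if (nrow(pts) < min_features || since_detect >= refresh_every) {
      ref <- smooth(stack$data[f - 1, , ])
      ref_offset <- cum[f - 1, ]
      pts <- detect_features(ref, max_n = max_features,
                             quality_level = quality_level,
                             min_distance = min_distance)
      since_detect <- 0L
    }
    if (nrow(pts) == 0) {
      cum[f, ] <- cum[f - 1, ]
      flagged[f] <- TRUE
      next
    }
    tr <- lk_track(ref, fb, pts, window = window, max_iter = max_iter,
                   tol = tol, init = cum[f - 1, ] - ref_offset)
    nv <- sum(tr$valid)
    nval[f] <- nv
    if (nv == 0) {
      cum[f, ] <- cum[f - 1, ]
      flagged[f] <- TRUE
    } else {
      shift <- estimate_global_shift(tr$displacement, tr$valid)
      cum[f, ] <- ref_offset + shift
    }
    since_detect <- since_detect + 1L
  }

  corrected <- stack$data
  for (f in 2:n_frames) {
    if (any(abs(cum[f, ]) > 1e-9))
      corrected[f, , ] <- shift_image(stack$data[f, , ], cum[f, 1], cum[f, 2])
  }
  traj <- data.frame(frame = seq_len(n_frames),
                     dy_px = cum[, 1], dx_px = cum[, 2],
                     dy_um = cum[, 1] * stack$pixel_size,
                     dx_um = cum[, 2] * stack$pixel_size,
                     n_valid = nval, flagged = flagged)
  list(stack = movie_stack(pmax(corrected, 0),
                           pixel_size = stack$pixel_size,
                           frame_interval = stack$frame_interval),
       trajectory = traj)
}

#' Integer global shift by exhaustive cross-correlation
#'
#' Brute-force oracle: the integer (dy, dx) in
#' \code{[-max_shift, max_shift]^2} maximizing the correlation of the
#' overlapping parts of the two mean-subtracted frames. Independent of
#' the Lucas-Kanade path; used to cross-check it.
#'
#' @param frame_a,frame_b Numeric matrices of identical size.
#' @param max_shift Search radius in px (default 5).
#' @return Length-2 integer (dy, dx) such that frame_b approx
#'   frame_a shifted content-wise by (dy, dx).
#' @export
crosscor_shift <- function(frame_a, frame_b, max_shift = 5) {
  stopifnot(all(dim(frame_a) == dim(frame_b)))
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  best <- c(0, 0); best_v <- -Inf
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ra <- max(1, 1 + dy):min(nr, nr + dy)
    ca <- max(1, 1 + dx):min(nc, nc + dx)
    a <- frame_a[ra - dy, ca - dx]
    b <- frame_b[ra, ca]
    a <- a - mean(a); b <- b - mean(b)
    den <- sqrt(sum(a^2) * sum(b^2))
    v <- if (den > 0) sum(a * b) / den else -Inf
    if (v > best_v) { best_v <- v; best <- c(dy, dx) }
  }
  best
}
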