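# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Rejection sampler for a normal truncated below at `lower`.
#' @noRd
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Mean of a normal(mu, sd) truncated below at `lower`.
#' @noRd
truncnorm_mean <- function(mu, sd, lower) {
  a <- (lower - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Truncated-normal sampler parameterized by its REALIZED mean: the
# location is solved so that E[X | X >= lower] equals `mean`. Presets
# quote measured means, so the generative mean must reproduce them
# rather than the pre-truncation location.
#' @noRd
rtruncnorm_target <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  if (mean <= lower)
    stop("target mean must exceed the truncation bound")
  mu <- stats::uniroot(function(m) truncnorm_mean(m, sd, lower) - mean,
                       lower = mean - 4 * sd, upper = mean,
                       extendInt = "upX", tol = 1e-8)$root
  rtruncnorm_lower(n, mu, sd, lower)
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions.
# Out-of-range positions are clamped to the border (constant-edge padding).
#' @noRd
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin.int(pmax.int(row, 1), nr)
  col <- pmin.int(pmax.int(col, 1), nc)
  r0 <- pmin.int(floor(row), nr - 1L); c0 <- pmin.int(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  lin <- (c0 - 1) * nr + r0   # linear index of (r0, c0)
  i00 <- img[lin]
  i10 <- img[lin + 1]
  i01 <- img[lin + nr]
  i11 <- img[lin + nr + 1]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

# Shift an image by a constant subpixel vector (dy, dx): output(r, c) =
# input(r + dy, c + dx), bilinear, constant padding with `fill` outside.
#' @noRd
shift_image <- function(img, dy, dx, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  if (abs(dy) < 1e-12 && abs(dx) < 1e-12) return(img)
  # integer-shift an image with constant-edge padding
  ishift <- function(m, iy, ix) {
    src_r <- pmin.int(pmax.int(seq_len(nr) + iy, 1L), nr)
    src_c <- pmin.int(pmax.int(seq_len(nc) + ix, 1L), nc)
    m[src_r, src_c]
  }
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  out <- (1 - fy) * (1 - fx) * ishift(img, y0, x0)
  if (fy > 0) out <- out + fy * (1 - fx) * ishift(img, y0 + 1, x0)
  if (fx > 0) out <- out + (1 - fy) * fx * ishift(img, y0, x0 + 1)
  if (fy > 0 && fx > 0) out <- out + fy * fx * ishift(img, y0 + 1, x0 + 1)
  if (!is.na(fill)) {
    rows <- seq_len(nr) + dy
    cols <- seq_len(nc) + dx
    out[rows < 1 | rows > nr, ] <- fill
    out[, cols < 1 | cols > nc] <- fill
  }
  out
}

# Centered moving average with edge replication; k is the window width in
# samples (k <= 1 returns x unchanged).
#' @noRd
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  h <- k %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[n], k - h - 1L))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 1))[(k - 1L + 1L):(k - 1L + n)]
}

# Otsu threshold on a numeric vector (maximizes between-class variance over
# a histogram of `nbins` bins). Used for data-driven intensity cutoffs.
#' @noRd
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) return(stats::median(x))
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# Euclidean disk structuring element of radius r (r = 1 is the 4-connected
# von Neumann neighbourhood).
#' @noRd
disk_kernel <- function(r) {
  r <- as.integer(r)
  d <- 2L * r + 1L
  off <- seq(-r, r)
  k <- outer(off^2, off^2, "+") <= r^2
  matrix(as.integer(k), d, d)
}

# Deterministic per-field substream seed derived from a global seed; affine
# so earlier fields are unaffected when more fields are added.
#' @noRd
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}
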