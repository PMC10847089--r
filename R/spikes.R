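#' Calcium transient peak detection and period estimation
#'
#' Calcium transients appear as sharp-rise, slow-decay peaks in the DF/F
#' trace. Peaks are local maxima of the lightly smoothed trace whose
#' topographic prominence exceeds a threshold; the per-neuron
#' "oscillation period" is the mean inter-spike interval (ISI) between
#' consecutive detected peaks within an observation window. With only a
#' few cycles per gravity phase, the mean ISI is a far more stable
#' period measure than any spectral estimate.
#'
#' @name spikes
NULL

# Topographic prominence of each local maximum of x.
#' @noRd
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    v <- x[p]
    # walk left to the nearest strictly higher sample
    lmin <- v
    i <- p - 1L
    while (i >= 1L && x[i] <= v) { lmin <- min(lmin, x[i]); i <- i - 1L }
    left_base <- if (i >= 1L) lmin else min(x[1:p])
    rmin <- v
    i <- p + 1L
    n <- length(x)
    while (i <= n && x[i] <= v) { rmin <- min(rmin, x[i]); i <- i + 1L }
    right_base <- if (i <= n) rmin else min(x[p:n])
    v - max(left_base, right_base)
  }, numeric(1))
}

#' Detect calcium transient peaks in a DF/F trace
#'
#' The trace is smoothed with a centered moving average of width
#' \code{smooth_s}; local maxima with prominence at least
#' \code{min_prominence} are kept, peaks closer than
#' \code{min_separation_s} are thinned (highest first), and peaks that
#' fall on masked (transition-blurred) frames are rejected.
#'
#' @param trace A \code{calcium_trace} from [extract_dff()], or any list
#'   with \code{dff}, \code{time_s}, \code{masked}, and optionally
#'   \code{roi_id}.
#' @param smooth_s Moving-average width, seconds (default 0.8, i.e. two
#'   frames at 2.5 Hz).
#' @param min_prominence Minimum topographic prominence in DF/F units
#'   (default 0.3).
#' @param min_separation_s Minimum peak separation, seconds
#'   (default 1.2).
#' @return Object of class \code{spike_train}: list with \code{roi_id},
#'   \code{peak_times} (strictly increasing, seconds),
#'   \code{peak_amplitudes} (DF/F at the peak frame), \code{peak_frames}.
#'   An empty train is a valid result.
#' @export
detect_peaks <- function(trace, smooth_s = 0.8, min_prominence = 0.3,
                         min_separation_s = 1.2) {
  dff <- trace$dff
  times <- trace$time_s
  masked <- trace$masked %||% rep(FALSE, length(dff))
  if (sum(!masked) < 3) stop("need >= 3 unmasked frames")
  dt <- trace$frame_interval %||% stats::median(diff(times))
  k <- max(1L, round(smooth_s / dt))
  z <- moving_average(dff, k)
  n <- length(z)
  cand <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  empty <- structure(list(roi_id = trace$roi_id %||% NA_integer_,
                          peak_times = numeric(0),
                          peak_amplitudes = numeric(0),
                          peak_frames = integer(0)),
                     class = "spike_train")
  if (length(cand) == 0) return(empty)
  prom <- peak_prominence(z, cand)
  cand <- cand[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  if (length(cand) == 0) return(empty)
  keep_mask <- !masked[cand]
  cand <- cand[keep_mask]; prom <- prom[keep_mask]
  if (length(cand) == 0) return(empty)
  # thin to min separation, strongest (by smoothed height) first
  ord <- order(z[cand], decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        all(abs(times[cand[i]] - times[kept]) >= min_separation_s))
      kept <- c(kept, cand[i])
  }
  kept <- sort(kept)
  structure(list(roi_id = trace$roi_id %||% NA_integer_,
                 peak_times = times[kept],
                 peak_amplitudes = dff[kept],
                 peak_frames = kept),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("spike_train roi", x$roi_id, ":", length(x$peak_times), "peaks\n")
  invisible(x)
}

#' Oscillation period (mean ISI) within a window
#'
#' Restricts peaks to the half-open window \code{[start, end)} and, if at
#' least two remain, returns the mean of consecutive inter-spike
#' intervals. ISIs that span a masked transition gap are discarded
#' rather than interpolated (pass \code{timeline} to enable this). Fewer
#' than two peaks (or no surviving ISI) means the neuron is inactive in
#' the window: the estimate is undefined and \code{NULL} is returned.
#'
#' @param train A [detect_peaks()] \code{spike_train}.
#' @param window Numeric length-2 \code{c(start, end)}, seconds.
#' @param timeline Optional [build_timeline()]; when given, ISIs
#'   containing a masked frame strictly between the two peaks are
#'   dropped.
#' @return \code{NULL}, or a \code{period_estimate}: list with
#'   \code{mean_isi}, \code{n_isi}, \code{isi_values}.
#' @export
estimate_period <- function(train, window, timeline = NULL) {
  pt <- train$peak_times
  pt <- pt[pt >= window[1] & pt < window[2]]
  if (length(pt) < 2) return(NULL)
  isi <- diff(pt)
  lo <- pt[-length(pt)]; hi <- pt[-1]
  if (!is.null(timeline)) {
    mt <- timeline$frame_times[timeline$frame_masked]
    spans <- vapply(seq_along(isi), function(i)
      any(mt > lo[i] & mt < hi[i]), logical(1))
    isi <- isi[!spans]
  }
  if (length(isi) == 0) return(NULL)
  structure(list(mean_isi = mean(isi), n_isi = length(isi),
                 isi_values = isi),
            class = "period_estimate")
}

#' Summary of a set of per-neuron period estimates
#'
#' Order statistics over per-neuron mean ISIs, quartiles by linear
#' interpolation (as drawn on a violin plot: median dot, Q1-Q3 bars).
#'
#' @param estimates List of \code{period_estimate} (NULLs, i.e. inactive
#'   neurons, are dropped).
#' @return List: \code{median}, \code{q1}, \code{q3}, \code{mean},
#'   \code{sd}, \code{n}, \code{values}.
#' @export
period_distribution <- function(estimates) {
  vals <- vapply(Filter(Negate(is.null), estimates),
                 function(e) e$mean_isi, numeric(1))
  if (length(vals) == 0) stop("no defined period estimates")
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n = length(vals), values = vals)
}

#' Per-phase period estimates for one spike train
#'
#' Applies [estimate_period()] to each phase segment of the timeline
#' (skipping segments flagged unstable, such as the second hypergravity
#' phase).
#'
#' @param train A \code{spike_train}.
#' @param timeline A [build_timeline()] object.
#' @param stable_only Skip unstable segments (default TRUE).
#' @return Named list of \code{period_estimate} or NULL, one entry per
#'   phase label.
#' @export
phase_periods <- function(train, timeline, stable_only = TRUE) {
  seg <- timeline$segments
  if (stable_only) seg <- seg[seg$stable, , drop = FALSE]
  out <- lapply(seq_len(nrow(seg)), function(i)
    estimate_period(train, c(seg$start[i], seg$end[i]), timeline))
  names(out) <- seg$label
  out
}

#' Write spike and period tables as CSV
#'
#' \code{spikes.csv}: field_id, roi_id, peak_time_s, amplitude_dff,
#' phase. \code{periods.csv}: field_id, roi_id, phase, mean_isi_s, n_isi.
#'
#' @param trains List of \code{spike_train}.
#' @param timeline A [build_timeline()] object.
#' @param dir Output directory.
#' @param field_id Field identifier.
#' @return \code{dir}, invisibly.
#' @export
write_spikes_csv <- function(trains, timeline, dir, field_id = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- do.call(rbind, lapply(trains, function(tr) {
    if (length(tr$peak_times) == 0) return(NULL)
    data.frame(field_id = field_id, roi_id = tr$roi_id,
               peak_time_s = tr$peak_times,
               amplitude_dff = tr$peak_amplitudes,
               phase = phase_of(tr$peak_times, timeline))
  }))
  if (is.null(sp))
    sp <- data.frame(field_id = integer(0), roi_id = integer(0),
                     peak_time_s = numeric(0), amplitude_dff = numeric(0),
                     phase = character(0))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  pd <- do.call(rbind, lapply(trains, function(tr) {
    pp <- phase_periods(tr, timeline)
    rows <- lapply(names(pp), function(ph) {
      if (is.null(pp[[ph]])) return(NULL)
      data.frame(field_id = field_id, roi_id = tr$roi_id, phase = ph,
                 mean_isi_s = pp[[ph]]$mean_isi, n_isi = pp[[ph]]$n_isi)
    })
    do.call(rbind, rows)
  }))
  if (is.null(pd))
    pd <- data.frame(field_id = integer(0), roi_id = integer(0),
                     phase = character(0), mean_isi_s = numeric(0),
                     n_isi = integer(0))
  utils::write.csv(pd, file.path(dir, "periods.csv"), row.names = FALSE)
  invisible(dir)
}
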