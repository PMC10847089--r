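#' Synthetic calcium-imaging movies with ground truth
#'
#' Generates time-lapse fluorescence movies that emulate the statistical
#' structure of spontaneous calcium activity in immature 2D hippocampal
#' networks imaged during parabolic flights: a handful of active neurons
#' per field of view, quasi-periodic calcium transients whose period is
#' modulated by the gravity phase, hypergravity-triggered activation of
#' silent neurons, micron-scale rigid jitter, and shot/read noise. Every
#' movie comes with exact ground truth (neuron positions, per-phase
#' periods, spike times, the jitter trajectory), so each downstream stage
#' of the pipeline can be checked by parameter recovery.
#'
#' @name simulate
NULL

NEURON_CLASSES <- c("SILENT", "CONSTITUTIVE", "TRIGGERED")
FIELD_CLASSES <- c("CONSTITUTIVE", "TRIGGERED", "INACTIVE")

#' Quasi-periodic spike times from a Gamma renewal process
#'
#' Inter-spike intervals are Gamma distributed with mean \code{period} and
#' coefficient of variation \code{isi_cv} (shape \code{1/isi_cv^2}); at
#' \code{isi_cv = 0} the process is exactly periodic. The first spike is
#' offset from the window start by a Uniform(0, period) draw (random
#' oscillator phase) unless \code{first_offset} is given.
#'
#' @param period Mean inter-spike interval, seconds (> 0).
#' @param isi_cv Coefficient of variation of the intervals, in [0, 1).
#' @param window Numeric length-2, half-open observation window
#'   \code{[start, end)} in seconds.
#' @param seed Optional integer seed for reproducibility of this call.
#' @param first_offset Optional fixed offset (seconds) of the first spike
#'   from the window start.
#' @return Numeric vector of strictly increasing spike times (possibly
#'   empty).
#' @export
draw_spike_times <- function(period, isi_cv, window, seed = NULL,
                             first_offset = NULL) {
  stopifnot(period > 0, isi_cv >= 0, isi_cv < 1, length(window) == 2)
  if (!is.null(seed)) set.seed(seed)
  start <- window[1]; end <- window[2]
  if (end <= start) return(numeric(0))
  draw_isi <- function(n) {
    if (isi_cv == 0) rep(period, n)
    else stats::rgamma(n, shape = 1 / isi_cv^2, scale = period * isi_cv^2)
  }
  t <- start + (first_offset %||% stats::runif(1, 0, period))
  out <- numeric(0)
  # draw in blocks to avoid one rgamma call per spike
  while (t < end) {
    n <- max(8L, ceiling((end - t) / period * 1.5))
    isis <- draw_isi(n)
    times <- t + cumsum(c(0, isis))
    out <- c(out, times[times < end])
    t <- times[length(times)]
  }
  out[out >= start & out < end]
}

#' Calcium transient kernel (difference of exponentials)
#'
#' Fluorescent calcium transients show a sharp rise and a slow decay; the
#' kernel \eqn{(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}} is normalized to unit
#' peak. It is 0 at onset (t = 0) and decays to 0 as t grows.
#'
#' @param t Time since transient onset, seconds (values < 0 give 0).
#' @param rise_tau Rise time constant, seconds.
#' @param decay_tau Decay time constant, seconds; must exceed
#'   \code{rise_tau}.
#' @return Dimensionless amplitude in [0, 1], same length as \code{t}.
#' @export
transient_kernel <- function(t, rise_tau = 0.2, decay_tau = 1.0) {
  if (rise_tau <= 0 || rise_tau >= decay_tau)
    stop("require 0 < rise_tau < decay_tau")
  t_pk <- rise_tau * log((rise_tau + decay_tau) / rise_tau)
  peak <- (1 - exp(-t_pk / rise_tau)) * exp(-t_pk / decay_tau)
  v <- ifelse(t > 0, (1 - exp(-t / rise_tau)) * exp(-t / decay_tau), 0)
  v / peak
}

#' Movie stack container
#'
#' @param data Numeric array, dimensions T x H x W, intensities >= 0.
#' @param pixel_size Micrometers per pixel (default 1).
#' @param frame_interval Seconds between frames (default 0.4).
#' @return Object of class \code{movie_stack}.
#' @export
movie_stack <- function(data, pixel_size = 1.0, frame_interval = 0.4) {
  stopifnot(length(dim(data)) == 3, all(data >= 0))
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("movie_stack:", d[1], "frames of", d[2], "x", d[3], "px,",
      x$frame_interval, "s/frame,", x$pixel_size, "um/px\n")
  invisible(x)
}

# frames x pixels matrix view of a stack (columns are pixels, column-major
# over (row, col) of the frame)
#' @noRd
stack_matrix <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, d[1], d[2] * d[3])
}

# Smooth anchored random walk used as the rigid jitter trajectory.
# Returns an n x 2 matrix (dy, dx), first row (0, 0), overall RMS
# magnitude scaled to `amp` pixels.
#' @noRd
make_jitter <- function(n, amp, smooth_frames = 7) {
  if (amp <= 0) return(matrix(0, n, 2))
  walk <- apply(matrix(stats::rnorm(2 * n), n, 2), 2, cumsum)
  k <- stats::dnorm(seq(-3, 3, length.out = smooth_frames))
  k <- k / sum(k)
  sm <- apply(walk, 2, function(v) {
    vp <- c(rep(v[1], smooth_frames), v, rep(v[n], smooth_frames))
    stats::filter(vp, k, sides = 2)[(smooth_frames + 1):(smooth_frames + n)]
  })
  sm <- sweep(sm, 2, sm[1, ])   # anchor frame 1 at (0, 0)
  rms <- sqrt(mean(sm^2) * 2)
  if (rms > 0) sm <- sm * (amp / rms)
  sm
}

#' Render a synthetic movie from neuron specs and ground-truth spikes
#'
#' Each frame is a constant background plus, for every neuron, an
#' isotropic Gaussian soma profile scaled by its instantaneous brightness
#' (a resting baseline plus the sum of transient kernels over past
#' spikes). The whole scene is rigidly shifted by the frame's jitter, then
#' Poisson shot noise and Gaussian read noise are applied and intensities
#' are rounded to non-negative integer counts.
#'
#' @param neurons data.frame with columns \code{neuron_id}, \code{row},
#'   \code{col}, \code{radius}, \code{amplitude}, \code{baseline_frac},
#'   \code{rise_tau}, \code{decay_tau}.
#' @param spikes data.frame with columns \code{neuron_id}, \code{time_s}.
#' @param timeline A [build_timeline()] object.
#' @param dims Frame size c(H, W) in pixels.
#' @param noise List: \code{background} (counts), \code{read_sigma}
#'   (counts), \code{shot} (logical).
#' @param jitter_amp RMS amplitude of the rigid jitter random walk, px.
#' @param pixel_size Micrometers per pixel.
#' @param seed Optional integer seed.
#' @param jitter Optional pre-computed n_frames x 2 jitter matrix
#'   (overrides \code{jitter_amp}).
#' @param bleach_tau Optional photobleaching time constant in seconds:
#'   the whole fluorescent scene decays as \code{exp(-t/bleach_tau)}.
#'   Off (NULL) by default — the imaging protocol samples a fresh region
#'   per recording precisely to avoid bleaching — but useful for
#'   robustness tests.
#' @return List with \code{stack} (a [movie_stack()]) and \code{jitter}
#'   (the n_frames x 2 trajectory actually applied, in px).
#' @export
render_movie <- function(neurons, spikes, timeline, dims = c(256, 256),
                         noise = list(background = 100, read_sigma = 2,
                                      shot = TRUE),
                         jitter_amp = 1.0, pixel_size = 1.0, seed = NULL,
                         jitter = NULL, bleach_tau = NULL) {
  stopifnot(inherits(timeline, "gravity_timeline"))
  if (!is.null(seed)) set.seed(seed)
  H <- dims[1]; W <- dims[2]
  n_frames <- timeline$n_frames
  times <- timeline$frame_times
  if (is.null(jitter)) jitter <- make_jitter(n_frames, jitter_amp)
  max_j <- if (nrow(jitter) > 0) max(abs(jitter)) else 0
  margin <- neurons$radius + max_j
  if (any(neurons$row - margin < 1 | neurons$row + margin > H |
          neurons$col - margin < 1 | neurons$col + margin > W))
    stop("neuron outside frame (margin = radius + max jitter)")

  # per-neuron brightness time series: amplitude * (baseline + sum of kernels)
  signal <- matrix(0, n_frames, nrow(neurons))
  for (i in seq_len(nrow(neurons))) {
    nid <- neurons$neuron_id[i]
    s <- neurons$amplitude[i] * neurons$baseline_frac[i]
    st <- spikes$time_s[spikes$neuron_id == nid]
    sig <- rep(s, n_frames)
    for (tk in st) {
      sig <- sig + neurons$amplitude[i] *
        transient_kernel(times - tk, neurons$rise_tau[i], neurons$decay_tau[i])
    }
    signal[, i] <- sig
  }

  bg <- noise$background %||% 100
  read_sigma <- noise$read_sigma %||% 0
  shot <- isTRUE(noise$shot)
  sigma <- neurons$radius / 2
  ext <- ceiling(4 * sigma)

  data <- array(0L, dim = c(n_frames, H, W))
  for (f in seq_len(n_frames)) {
    img <- matrix(bg, H, W)
    for (i in seq_len(nrow(neurons))) {
      cy <- neurons$row[i] + jitter[f, 1]
      cx <- neurons$col[i] + jitter[f, 2]
      rr <- max(1L, floor(cy - ext[i])):min(H, ceiling(cy + ext[i]))
      cc <- max(1L, floor(cx - ext[i])):min(W, ceiling(cx + ext[i]))
      prof <- outer(exp(-(rr - cy)^2 / (2 * sigma[i]^2)),
                    exp(-(cc - cx)^2 / (2 * sigma[i]^2)))
      img[rr, cc] <- img[rr, cc] + signal[f, i] * prof
    }
    if (!is.null(bleach_tau)) img <- img * exp(-times[f] / bleach_tau)
    if (shot) img <- matrix(stats::rpois(length(img), img), H, W)
    if (read_sigma > 0) img <- img + stats::rnorm(length(img), 0, read_sigma)
    data[f, , ] <- as.integer(round(pmax(img, 0)))
  }
  list(stack = movie_stack(data, pixel_size = pixel_size,
                           frame_interval = timeline$frame_interval),
       jitter = jitter)
}

#' Flight campaign simulation preset
#'
#' Generative parameters for a parabolic-flight campaign: 29 fields of
#' view split into 5 constitutive, 14 hypergravity-triggered and 10
#' inactive networks; 2 to 13 active neurons per field (mean 6);
#' per-phase oscillation periods with 1 g mean 2.9 s (sd 1.54), 1.8 g
#' mean 4.8 s (sd 2.09), all truncated below at 0.8 s (two frame
#' intervals). In microgravity, constitutive networks slow down further
#' (mean 6.5 s, sd 1.5) while triggered networks speed up relative to
#' their own 1.8 g period (ratio mean 0.9, sd 0.08), so the pooled 0 g
#' period across the class mix is ~5 s and the field-level period ratios
#' are directional: alpha_{1->1.8g} > 1, alpha_{1->0g} > 1,
#' alpha_{1.8->0g} < 1. Rigid jitter RMS 1 px (~1 um).
#'
#' @return Named list of generator parameters.
#' @export
flight_preset <- function() {
  list(name = "flight",
       phases = flight_phases(), frame_interval = 0.4, blur_halfwidth = 2,
       n_fields = 29,
       class_counts = c(CONSTITUTIVE = 5, TRIGGERED = 14, INACTIVE = 10),
       neurons_per_field = c(min = 2, max = 13, mean = 6),
       period = list(PRE_1G = c(mean = 2.9, sd = 1.54),
                     HYPER_1 = c(mean = 4.8, sd = 2.09),
                     MICRO_0G_CONST = c(mean = 6.5, sd = 1.5),
                     TRIG_RATIO_18_0 = c(mean = 0.9, sd = 0.08)),
       period_floor = 0.8, isi_cv = 0.2,
       dims = c(256, 256), pixel_size = 1.0,
       jitter_amp = 1.0,
       noise = list(background = 100, read_sigma = 2, shot = TRUE),
       rise_tau = 0.2, decay_tau = 1.0)
}

#' Laboratory (ground control) simulation preset
#'
#' A single 82 s 1 g recording per field; all fields constitutive with 12
#' to 27 active neurons (matching ground-control fields of view) and
#' oscillation periods drawn from mean 5 s, sd 1.5 s (range ~2-8 s),
#' truncated below at 0.8 s. Jitter is small (0.2 px RMS): the bench
#' setup does not vibrate like the aircraft.
#'
#' @return Named list of generator parameters.
#' @export
lab_preset <- function() {
  list(name = "lab",
       phases = lab_phases(82), frame_interval = 0.4, blur_halfwidth = 0,
       n_fields = 5,
       class_counts = c(CONSTITUTIVE = 5, TRIGGERED = 0, INACTIVE = 0),
       neurons_per_field = c(min = 12, max = 27, mean = 19),
       period = list(PRE_1G = c(mean = 5, sd = 1.5)),
       period_floor = 0.8, isi_cv = 0.2,
       dims = c(256, 256), pixel_size = 1.0,
       jitter_amp = 0.2,
       noise = list(background = 100, read_sigma = 2, shot = TRUE),
       rise_tau = 0.2, decay_tau = 1.0)
}

#' Get a preset by name
#' @param name "flight" or "lab".
#' @return Parameter list.
#' @export
get_preset <- function(name) {
  switch(match.arg(name, c("flight", "lab")),
         flight = flight_preset(), lab = lab_preset())
}

# Draw the number of active neurons in a field: Poisson(mean) conditioned
# on the observed range [min, max].
#' @noRd
draw_neuron_count <- function(spec) {
  k <- spec[["min"]]:spec[["max"]]
  if (length(k) == 1L) return(k)
  p <- stats::dpois(k, spec[["mean"]])
  k[sample.int(length(k), 1, prob = p / sum(p))]
}

# Random non-overlapping neuron positions with a frame margin; falls back
# to jittered grid placement if rejection sampling stalls.
#' @noRd
place_neurons <- function(n, dims, margin, min_sep) {
  H <- dims[1]; W <- dims[2]
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L; tries <- 0L
  while (placed < n && tries < 4000L) {
    cand <- c(stats::runif(1, 1 + margin, H - margin),
              stats::runif(1, 1 + margin, W - margin))
    ok <- placed == 0L ||
      all(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2,
                             cand)^2)) >= min_sep)
    if (ok) { placed <- placed + 1L; pos[placed, ] <- cand }
    tries <- tries + 1L
  }
  if (placed < n) {
    g <- ceiling(sqrt(n))
    ys <- seq(1 + margin, H - margin, length.out = g)
    xs <- seq(1 + margin, W - margin, length.out = g)
    grid <- expand.grid(row = ys, col = xs)
    idx <- sample.int(nrow(grid), n)
    pos <- as.matrix(grid[idx, ]) + matrix(stats::runif(2 * n, -2, 2), n, 2)
  }
  pos
}

# Draw per-phase ground-truth periods for one neuron given its class.
#' @noRd
draw_neuron_periods <- function(class, preset, phase_labels) {
  p <- preset$period; fl <- preset$period_floor
  out <- stats::setNames(rep(NA_real_, length(phase_labels)), phase_labels)
  if (class == "SILENT") return(out)
  if (is.null(p$HYPER_1)) {
    # single-phase (laboratory) configuration
    if ("PRE_1G" %in% phase_labels)
      out[["PRE_1G"]] <- rtruncnorm_target(1, p$PRE_1G[["mean"]],
                                           p$PRE_1G[["sd"]], fl)
    return(out)
  }
  t18 <- rtruncnorm_target(1, p$HYPER_1[["mean"]], p$HYPER_1[["sd"]], fl)
  if (class == "CONSTITUTIVE") {
    if ("PRE_1G" %in% phase_labels)
      out[["PRE_1G"]] <- rtruncnorm_target(1, p$PRE_1G[["mean"]],
                                          p$PRE_1G[["sd"]], fl)
    if ("MICRO_0G" %in% phase_labels)
      out[["MICRO_0G"]] <- rtruncnorm_target(1, p$MICRO_0G_CONST[["mean"]],
                                            p$MICRO_0G_CONST[["sd"]], fl)
  } else { # TRIGGERED: 0 g period tied to own 1.8 g period, ratio < 1
    if ("MICRO_0G" %in% phase_labels) {
      ratio <- rtruncnorm_lower(1, p$TRIG_RATIO_18_0[["mean"]],
                                p$TRIG_RATIO_18_0[["sd"]], 0.5)
      out[["MICRO_0G"]] <- max(fl, t18 * ratio)
    }
  }
  if ("HYPER_1" %in% phase_labels) out[["HYPER_1"]] <- t18
  if ("HYPER_2" %in% phase_labels) out[["HYPER_2"]] <- t18
  out
}

#' Simulate one field of view
#'
#' Builds the neuron table, draws ground-truth per-phase periods and spike
#' times for the requested field class, and (optionally) renders the
#' movie.
#'
#' @param field_id Integer id.
#' @param field_class One of "CONSTITUTIVE", "TRIGGERED", "INACTIVE".
#' @param preset Parameter list from [flight_preset()] / [lab_preset()].
#' @param timeline A [build_timeline()] object consistent with the preset.
#' @param seed Integer seed for this field.
#' @param render If FALSE, skip movie rendering (ground truth only).
#' @param n_neurons Number of active neurons; drawn from the preset's
#'   range when NULL.
#' @return List with \code{field_id}, \code{stack} (or NULL),
#'   \code{truth} (list: \code{neurons}, \code{spikes}, \code{jitter},
#'   \code{field_class}), \code{timeline}.
#' @export
simulate_field <- function(field_id, field_class, preset, timeline,
                           seed, render = TRUE, n_neurons = NULL) {
  field_class <- match.arg(field_class, FIELD_CLASSES)
  set.seed(seed)
  phase_labels <- timeline$segments$label
  n <- n_neurons %||% draw_neuron_count(preset$neurons_per_field)
  radius <- 7
  margin <- 2 * radius + 4 * preset$jitter_amp + 2
  pos <- place_neurons(n, preset$dims, margin, min_sep = 4 * radius)
  nclass <- switch(field_class, CONSTITUTIVE = "CONSTITUTIVE",
                   TRIGGERED = "TRIGGERED", INACTIVE = "SILENT")
  neurons <- data.frame(
    field_id = field_id, neuron_id = seq_len(n),
    row = pos[, 1], col = pos[, 2], radius = radius,
    amplitude = stats::runif(n, 420, 560), baseline_frac = 0.25,
    class = nclass, isi_cv = preset$isi_cv,
    rise_tau = preset$rise_tau, decay_tau = preset$decay_tau,
    stringsAsFactors = FALSE)

  pm <- vapply(seq_len(n), function(i)
    draw_neuron_periods(nclass, preset, phase_labels),
    numeric(length(phase_labels)))
  periods <- if (length(phase_labels) == 1L) matrix(pm, ncol = 1L) else t(pm)
  colnames(periods) <- paste0("period_", phase_labels)
  neurons <- cbind(neurons, as.data.frame(periods))

  spikes <- list()
  for (i in seq_len(n)) {
    for (s in seq_len(nrow(timeline$segments))) {
      lab <- timeline$segments$label[s]
      per <- periods[i, paste0("period_", lab)]
      if (is.na(per)) next
      st <- draw_spike_times(per, preset$isi_cv,
                             c(timeline$segments$start[s],
                               timeline$segments$end[s]))
      if (length(st))
        spikes[[length(spikes) + 1L]] <-
          data.frame(field_id = field_id, neuron_id = i, time_s = st)
    }
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes)
            else data.frame(field_id = integer(0), neuron_id = integer(0),
                            time_s = numeric(0))
  spikes <- spikes[order(spikes$neuron_id, spikes$time_s), , drop = FALSE]

  stack <- NULL
  jit <- matrix(0, timeline$n_frames, 2)
  if (render) {
    rm_ <- render_movie(neurons, spikes, timeline, dims = preset$dims,
                        noise = preset$noise, jitter_amp = preset$jitter_amp,
                        pixel_size = preset$pixel_size)
    stack <- rm_$stack
    jit <- rm_$jitter
  }
  list(field_id = field_id, stack = stack,
       truth = list(neurons = neurons, spikes = spikes, jitter = jit,
                    field_class = field_class),
       timeline = timeline)
}

#' Simulate a campaign of fields of view
#'
#' Field classes are planted exactly per \code{class_counts} (randomly
#' ordered); each field gets its own deterministic RNG substream derived
#' from \code{seed}, so results are bit-reproducible and earlier fields
#' do not change when more fields are added.
#'
#' @param n_fields Number of fields (must equal \code{sum(class_counts)}).
#' @param preset Parameter list ([flight_preset()] or [lab_preset()]).
#' @param class_counts Named counts for CONSTITUTIVE / TRIGGERED /
#'   INACTIVE; defaults to the preset's.
#' @param seed Global integer seed.
#' @param render If FALSE, ground truth only (fast; for tests).
#' @return List of fields as returned by [simulate_field()].
#' @export
simulate_campaign <- function(n_fields = NULL, preset = flight_preset(),
                              class_counts = NULL, seed = 1,
                              render = TRUE) {
  n_fields <- n_fields %||% preset$n_fields
  class_counts <- class_counts %||% preset$class_counts
  if (sum(class_counts) != n_fields)
    stop("sum(class_counts) must equal n_fields")
  timeline <- build_timeline(preset$phases, preset$frame_interval,
                             preset$blur_halfwidth)
  set.seed(seed)
  classes <- sample(rep(names(class_counts), class_counts))
  lapply(seq_len(n_fields), function(f)
    simulate_field(f, classes[f], preset, timeline,
                   seed = substream_seed(seed, f), render = render))
}

#' Write campaign ground truth as CSV files
#'
#' Writes \code{neurons.csv} (positions, classes, per-phase periods),
#' \code{spikes.csv} (per-neuron spike times) and \code{jitter.csv}
#' (per-frame rigid displacement) into \code{dir}.
#'
#' @param fields List from [simulate_campaign()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_truth_csvs <- function(fields, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  neurons <- do.call(rbind, lapply(fields, function(f) f$truth$neurons))
  spikes <- do.call(rbind, lapply(fields, function(f) f$truth$spikes))
  jit <- do.call(rbind, lapply(fields, function(f)
    data.frame(field_id = f$field_id,
               frame = seq_len(nrow(f$truth$jitter)),
               dy = f$truth$jitter[, 1], dx = f$truth$jitter[, 2])))
  utils::write.csv(neurons, file.path(dir, "neurons.csv"), row.names = FALSE)
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(jit, file.path(dir, "jitter.csv"), row.names = FALSE)
  invisible(dir)
}
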