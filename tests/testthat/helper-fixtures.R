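# Shared fixtures built in code: textured frames, analytic blob scenes,
# and tiny rendered fields.

# Smooth random texture with strong trackable structure.
textured_frame <- function(n = 180, seed = 3, sigma = 3, gain = 60,
                           offset = 120) {
  set.seed(seed)
  img <- matrix(rnorm(n * n), n, n)
  as.matrix(EBImage::gblur(img, sigma)) * gain + offset
}

# Integer-shift with constant-edge padding: content moves by +(dy, dx).
int_shift <- function(a, dy, dx) {
  nr <- nrow(a); nc <- ncol(a)
  a[pmin(pmax(seq_len(nr) - dy, 1), nr),
    pmin(pmax(seq_len(nc) - dx, 1), nc)]
}

# Analytic scene of Gaussian blobs at given (possibly subpixel) offset;
# exact rendering, no interpolation.
blob_scene <- function(centers, n = 160, amp = 200, sigma = 3.5,
                       offset = c(0, 0), background = 100) {
  img <- matrix(background, n, n)
  rows <- seq_len(n); cols <- seq_len(n)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1] + offset[1]
    cx <- centers[i, 2] + offset[2]
    img <- img + amp * outer(exp(-(rows - cy)^2 / (2 * sigma^2)),
                             exp(-(cols - cx)^2 / (2 * sigma^2)))
  }
  img
}

# Small rendered flight-like field with known jitter; cached per session.
small_field_cache <- new.env(parent = emptyenv())
small_jittered_field <- function() {
  if (!is.null(small_field_cache$field)) return(small_field_cache$field)
  tl <- build_timeline()
  set.seed(11)
  neurons <- data.frame(field_id = 1, neuron_id = 1:6,
                        row = c(60, 60, 120, 150, 180, 100),
                        col = c(60, 150, 100, 60, 160, 200),
                        radius = 7, amplitude = runif(6, 350, 480),
                        baseline_frac = 0.25, class = "CONSTITUTIVE",
                        isi_cv = 0.2, rise_tau = 0.2, decay_tau = 1)
  spikes <- do.call(rbind, lapply(1:6, function(i)
    data.frame(neuron_id = i,
               time_s = draw_spike_times(4, 0.2, c(0, 82)))))
  rm_ <- render_movie(neurons, spikes, tl,
                      noise = list(background = 100, read_sigma = 2,
                                   shot = TRUE),
                      jitter_amp = 1.0, seed = 21)
  small_field_cache$field <- list(stack = rm_$stack, jitter = rm_$jitter,
                                  neurons = neurons, spikes = spikes,
                                  timeline = tl)
  small_field_cache$field
}

# Build a calcium_trace-like object directly from a dff vector.
toy_trace <- function(dff, dt = 0.4, masked = rep(FALSE, length(dff)),
                      roi_id = 1L) {
  structure(list(roi_id = roi_id, time_s = (seq_along(dff) - 1) * dt,
                 F = dff + 1, F_m = rep(1, length(dff)), dff = dff,
                 masked = masked, frame_interval = dt),
            class = "calcium_trace")
}

# Build a spike_train directly from peak times.
toy_train <- function(times, roi_id = 1L) {
  structure(list(roi_id = roi_id, peak_times = sort(times),
                 peak_amplitudes = rep(1, length(times)),
                 peak_frames = seq_along(times)),
            class = "spike_train")
}
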