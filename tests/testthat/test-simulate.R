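test_that("spike times are exactly periodic at zero ISI dispersion", {
  s <- draw_spike_times(5, 0, c(0, 20), seed = 1)
  expect_true(all(abs(diff(s) - 5) < 1e-12))
  expect_true(all(s >= 0 & s < 20))
  expect_length(draw_spike_times(5, 0.3, c(3, 3)), 0)
  expect_length(draw_spike_times(5, 0, c(0, 4), first_offset = 5), 0)
})

test_that("Gamma ISI parameterization recovers mean and CV", {
  set.seed(2)
  isis <- diff(draw_spike_times(5, 0.3, c(0, 60000)))
  expect_gt(length(isis), 10000)
  expect_equal(mean(isis), 5, tolerance = 0.1 / 5)
  expect_equal(sd(isis) / mean(isis), 0.3, tolerance = 0.05)
})

test_that("spike times are strictly increasing across random draws", {
  for (s in 1:20) {
    st <- draw_spike_times(runif(1, 1, 8), runif(1, 0, 0.5), c(0, 82),
                           seed = s)
    if (length(st) > 1) expect_true(all(diff(st) > 0))
  }
})

test_that("transient kernel is 0 at onset, unit peak, and decays", {
  expect_equal(transient_kernel(0), 0)
  tt <- seq(0, 20, by = 1e-3)
  expect_equal(max(transient_kernel(tt)), 1, tolerance = 1e-6)
  expect_lt(transient_kernel(10 * 1.0), 1e-3)
  expect_error(transient_kernel(1, rise_tau = 1, decay_tau = 0.5),
               "rise_tau")
})

test_that("a silent noiseless jitter-free movie is static", {
  tl <- build_timeline(lab_phases(8), 0.4, 0)
  neurons <- data.frame(field_id = 1, neuron_id = 1, row = 40, col = 40,
                        radius = 7, amplitude = 300, baseline_frac = 0.25,
                        class = "SILENT", isi_cv = 0, rise_tau = 0.2,
                        decay_tau = 1)
  spikes <- data.frame(neuron_id = integer(0), time_s = numeric(0))
  rm_ <- render_movie(neurons, spikes, tl, dims = c(80, 80),
                      noise = list(background = 50, read_sigma = 0,
                                   shot = FALSE),
                      jitter_amp = 0)
  for (f in 2:tl$n_frames)
    expect_identical(rm_$stack$data[f, , ], rm_$stack$data[1, , ])
  # background-subtracted scene is non-negative and zero off-soma
  img <- rm_$stack$data[1, , ] - 50
  expect_true(all(img >= 0))
  expect_equal(img[5, 5], 0)
})

test_that("rendered jitter has the requested RMS amplitude", {
  for (s in 1:5) {
    set.seed(s)
    j <- gravitrace:::make_jitter(205, 1.0)
    expect_equal(sqrt(mean(j^2) * 2), 1.0, tolerance = 0.3)
    expect_equal(j[1, ], c(0, 0))
  }
})

test_that("a constitutive neuron at 5 s period spikes >= 14 times in 82 s", {
  tl <- build_timeline()
  st <- unlist(lapply(seq_len(nrow(tl$segments)), function(i)
    draw_spike_times(5, 0, c(tl$segments$start[i], tl$segments$end[i]),
                     seed = i, first_offset = 2.5)))
  expect_gte(length(st), 14)
})

test_that("photobleaching decays the scene but leaves DF/F unchanged", {
  tl <- build_timeline(lab_phases(8), 0.4, 0)
  neurons <- data.frame(field_id = 1, neuron_id = 1, row = 40, col = 40,
                        radius = 7, amplitude = 400, baseline_frac = 0.25,
                        class = "CONSTITUTIVE", isi_cv = 0, rise_tau = 0.2,
                        decay_tau = 1)
  spikes <- data.frame(neuron_id = 1, time_s = c(1, 4))
  base <- render_movie(neurons, spikes, tl, dims = c(80, 80),
                       noise = list(background = 100, read_sigma = 0,
                                    shot = FALSE), jitter_amp = 0)
  bl <- render_movie(neurons, spikes, tl, dims = c(80, 80),
                     noise = list(background = 100, read_sigma = 0,
                                  shot = FALSE), jitter_amp = 0,
                     bleach_tau = 20)
  expect_lt(mean(bl$stack$data[20, , ]), mean(base$stack$data[20, , ]))
  label <- matrix(0L, 80, 80); label[35:45, 35:45] <- 1L
  rois <- structure(list(label = label,
                         table = data.frame(roi_id = 1L, centroid_row = 40,
                                            centroid_col = 40,
                                            area = 121L)),
                    class = "roi_set")
  d1 <- extract_dff(base$stack, rois)[[1]]$dff
  d2 <- extract_dff(bl$stack, rois)[[1]]$dff
  # bleaching scales F and F_m by the same factor (up to quantization)
  expect_equal(d1, d2, tolerance = 0.02)
})

test_that("neuron outside the frame is a generation error", {
  tl <- build_timeline(lab_phases(4), 0.4, 0)
  neurons <- data.frame(field_id = 1, neuron_id = 1, row = 3, col = 40,
                        radius = 7, amplitude = 300, baseline_frac = 0.25,
                        class = "SILENT", isi_cv = 0, rise_tau = 0.2,
                        decay_tau = 1)
  expect_error(render_movie(neurons,
                            data.frame(neuron_id = integer(0),
                                       time_s = numeric(0)),
                            tl, dims = c(80, 80), jitter_amp = 0),
               "outside")
})

test_that("campaign plants field classes exactly and bounds neuron counts", {
  fields <- simulate_campaign(seed = 5, render = FALSE)
  classes <- sapply(fields, function(f) f$truth$field_class)
  expect_equal(sum(classes == "CONSTITUTIVE"), 5L)
  expect_equal(sum(classes == "TRIGGERED"), 14L)
  expect_equal(sum(classes == "INACTIVE"), 10L)
  n_pre_active <- sum(sapply(fields, function(f)
    any(f$truth$spikes$time_s < 10)))
  expect_equal(n_pre_active, 5L)   # only constitutive fields spike at 1 g
  for (f in fields) {
    n <- nrow(f$truth$neurons)
    expect_gte(n, 2); expect_lte(n, 13)
    expect_true(all(diff(order(f$truth$spikes$neuron_id,
                               f$truth$spikes$time_s)) > 0) ||
                  nrow(f$truth$spikes) <= 1 ||
                  !is.unsorted(f$truth$spikes$time_s[
                    f$truth$spikes$neuron_id ==
                      f$truth$spikes$neuron_id[1]]))
  }
})

test_that("triggered fields have no spikes before hypergravity onset", {
  fields <- simulate_campaign(seed = 8, render = FALSE)
  for (f in fields) {
    if (f$truth$field_class == "TRIGGERED")
      expect_true(all(f$truth$spikes$time_s >= 10))
    if (f$truth$field_class == "INACTIVE")
      expect_equal(nrow(f$truth$spikes), 0L)
  }
})

test_that("simulation is bit-reproducible for a fixed seed", {
  a <- simulate_campaign(n_fields = 2,
                         class_counts = c(CONSTITUTIVE = 1, TRIGGERED = 1,
                                          INACTIVE = 0),
                         seed = 4, render = FALSE)
  b <- simulate_campaign(n_fields = 2,
                         class_counts = c(CONSTITUTIVE = 1, TRIGGERED = 1,
                                          INACTIVE = 0),
                         seed = 4, render = FALSE)
  expect_identical(lapply(a, function(f) f$truth),
                   lapply(b, function(f) f$truth))
})

test_that("ground-truth mean ISI converges to the preset period", {
  # law of large numbers at >= 10,000 intervals, 2% tolerance
  set.seed(9)
  isis <- diff(draw_spike_times(3, 0.2, c(0, 40000)))
  expect_gt(length(isis), 10000)
  expect_equal(mean(isis), 3, tolerance = 0.02)
})

test_that("flight preset period draws realize the printed means", {
  set.seed(13)
  p <- flight_preset()$period
  x <- gravitrace:::rtruncnorm_target(40000, p$PRE_1G[["mean"]],
                                      p$PRE_1G[["sd"]], 0.8)
  expect_true(all(x >= 0.8))
  expect_equal(mean(x), 2.9, tolerance = 0.02)
  y <- gravitrace:::rtruncnorm_target(40000, p$HYPER_1[["mean"]],
                                      p$HYPER_1[["sd"]], 0.8)
  expect_equal(mean(y), 4.8, tolerance = 0.02)
})
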