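pe <- function(v) structure(list(mean_isi = v, n_isi = 2,
                                 isi_values = c(v, v)),
                            class = "period_estimate")

test_that("field-level phase period averages defined neurons only", {
  periods <- list(list(MICRO_0G = pe(4), PRE_1G = NULL),
                  list(MICRO_0G = pe(6), PRE_1G = NULL))
  expect_equal(field_phase_period(periods, "MICRO_0G"), 5)
  expect_true(is.na(field_phase_period(periods, "PRE_1G")))
  expect_equal(field_phase_period(periods[1], "MICRO_0G"), 4)
})

test_that("field classification from first peak timing", {
  tl <- build_timeline()
  expect_equal(classify_field(list(toy_train(c(3, 20, 45))), tl),
               "CONSTITUTIVE")
  expect_equal(classify_field(list(toy_train(c(15, 25, 50))), tl),
               "TRIGGERED")
  expect_equal(classify_field(list(toy_train(numeric(0))), tl), "INACTIVE")
  # deterministic pure function: same input, same answer
  expect_equal(classify_field(list(toy_train(c(15, 25))), tl),
               classify_field(list(toy_train(c(15, 25))), tl))
})

test_that("alpha ratios follow their definitions and never blow up", {
  st <- data.frame(T_1g = 2.9, T_18g = 4.8, T_0g = 5.0)
  a <- compute_alphas(st)
  expect_equal(a$alpha_1_18, 4.8 / 2.9, tolerance = 1e-12)
  expect_equal(round(a$alpha_1_18, 3), 1.655)
  eq <- compute_alphas(data.frame(T_1g = 3, T_18g = 3, T_0g = 3))
  expect_equal(c(eq$alpha_1_18, eq$alpha_1_0, eq$alpha_18_0), c(1, 1, 1))
  trig <- compute_alphas(data.frame(T_1g = NA_real_, T_18g = 6, T_0g = 5))
  expect_true(is.na(trig$alpha_1_18) && is.na(trig$alpha_1_0))
  expect_equal(trig$alpha_18_0, 5 / 6, tolerance = 1e-12)
  z <- compute_alphas(data.frame(T_1g = 0, T_18g = 6, T_0g = 5))
  expect_true(is.na(z$alpha_1_18))
})

test_that("alpha ratios are scale-free", {
  for (c_ in c(0.5, 2, 17)) {
    a1 <- compute_alphas(data.frame(T_1g = 2.2, T_18g = 4.1, T_0g = 5.3))
    a2 <- compute_alphas(data.frame(T_1g = 2.2 * c_, T_18g = 4.1 * c_,
                                    T_0g = 5.3 * c_))
    expect_equal(a1$alpha_1_18, a2$alpha_1_18, tolerance = 1e-12)
    expect_equal(a1$alpha_1_0, a2$alpha_1_0, tolerance = 1e-12)
    expect_equal(a1$alpha_18_0, a2$alpha_18_0, tolerance = 1e-12)
  }
})

test_that("Sarle's bimodality coefficient separates known distributions", {
  set.seed(7)
  u <- runif(1000)
  expect_equal(bimodality_coefficient(u), 5 / 9, tolerance = 0.05 / (5 / 9))
  g <- rnorm(1000)
  expect_lt(bimodality_coefficient(g), 5 / 9)
  two_point <- rep(c(3, 8), 500)
  expect_gt(bimodality_coefficient(two_point), 5 / 9)
  expect_true(is.na(bimodality_coefficient(c(1, 2, 3))))
  expect_true(is.na(bimodality_coefficient(rep(2, 10))))
})

test_that("campaign summary recovers planted structure from spike trains", {
  tl <- build_timeline()
  # constitutive field: active in all phases, periods 3 / 5 / 6
  mk_field <- function(id, trains) {
    list(field_id = id, stats = field_stats(id, trains, tl),
         trains = trains, timeline = tl)
  }
  const_train <- toy_train(c(seq(1, 7.9, by = 3),       # 1 g, ISI 3
                             seq(13, 37.9, by = 5),     # 1.8 g, ISI 5
                             seq(43, 59.9, by = 6)))    # 0 g, ISI 6
  trig_train <- toy_train(c(seq(13, 37.9, by = 5),
                            seq(43, 59.9, by = 4)))
  silent <- toy_train(numeric(0))
  analyzed <- list(mk_field(1, list(const_train, const_train)),
                   mk_field(2, list(trig_train)),
                   mk_field(3, list(silent)))
  s <- summarize_campaign(analyzed)
  expect_equal(unname(s$class_counts),
               c(1L, 1L, 1L))
  expect_equal(s$phase$T_1g$mean, 3)
  expect_equal(s$phase$T_18g$mean, 5)
  expect_equal(s$phase$T_0g$mean, (6 + 6 + 4) / 3)
  expect_equal(unname(s$median_alpha["alpha_1_18"]), 5 / 3)
  expect_equal(s$n_neurons, 4L)
  expect_equal(s$frac_active, 3 / 4)
  expect_equal(s$frac_reacted, 1)  # all active neurons change > 20%
})

test_that("identical periods across phases give unit alphas, none reacted", {
  tl <- build_timeline()
  tr <- toy_train(c(seq(1, 9.9, by = 4), seq(13, 37.9, by = 4),
                    seq(43, 59.9, by = 4)))
  analyzed <- list(list(field_id = 1,
                        stats = field_stats(1, list(tr), tl),
                        trains = list(tr), timeline = tl))
  s <- summarize_campaign(analyzed)
  expect_equal(unname(s$median_alpha), c(1, 1, 1))
  expect_equal(s$frac_reacted, 0)
})

test_that("per-neuron alpha mode medians over neuron-level ratios", {
  tl <- build_timeline()
  tr1 <- toy_train(c(seq(1, 7.9, by = 3), seq(13, 37.9, by = 6),
                     seq(43, 59.9, by = 6)))   # alpha_1_18 = 2
  tr2 <- toy_train(c(seq(1, 7.9, by = 2), seq(13, 37.9, by = 8),
                     seq(43, 59.9, by = 8)))   # alpha_1_18 = 4
  analyzed <- list(list(field_id = 1,
                        stats = field_stats(1, list(tr1, tr2), tl),
                        trains = list(tr1, tr2), timeline = tl))
  s_field <- summarize_campaign(analyzed, alpha_mode = "field")
  s_neuron <- summarize_campaign(analyzed, alpha_mode = "neuron")
  # field level: T ratios of averaged periods; neuron level: median(2, 4)
  expect_equal(unname(s_neuron$median_alpha["alpha_1_18"]), 3)
  expect_equal(unname(s_field$median_alpha["alpha_1_18"]), 7 / 2.5)
})

test_that("summary export writes the documented schemas", {
  tl <- build_timeline()
  tr <- toy_train(c(2, 5, 15, 20, 45, 50))
  analyzed <- list(list(field_id = 1,
                        stats = field_stats(1, list(tr), tl),
                        trains = list(tr), timeline = tl))
  s <- summarize_campaign(analyzed)
  dir <- tempfile(); dir.create(dir)
  write_summary(analyzed, s, dir)
  fs <- read.csv(file.path(dir, "fieldstats.csv"))
  expect_true(all(c("field_id", "class", "T_1g", "T_18g", "T_0g",
                    "alpha_1_18", "alpha_1_0", "alpha_18_0",
                    "n_active") %in% names(fs)))
  pv <- read.csv(file.path(dir, "period_values.csv"))
  expect_named(pv, c("field_id", "roi_id", "phase", "period_s"))
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_true(all(c("phase", "median_alpha", "class_counts") %in% names(js)))
})
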