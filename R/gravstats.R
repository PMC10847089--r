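#' Per-phase network statistics and period ratios
#'
#' Field-level statistics across gravity phases: the mean oscillation
#' period of a field's active neurons per phase, the period ratios
#' (alpha) between phases, the constitutive/triggered/inactive network
#' classification, and campaign-wide summaries (pooled period
#' distributions, median alphas, class counts, fraction of neurons that
#' reacted to gravity changes, bimodality of the period distribution).
#'
#' Conventions: \eqn{\alpha_{1\to1.8g} = T_{1.8g}/T_{1g}},
#' \eqn{\alpha_{1\to0g} = T_{0g}/T_{1g}},
#' \eqn{\alpha_{1.8\to0g} = T_{0g}/T_{1.8g}}, each defined only when both
#' operand phase periods are defined (triggered networks have no 1 g
#' period, so their \eqn{\alpha_{1\to\cdot}} are undefined). The second
#' hypergravity phase is excluded from all statistics: its acceleration
#' is not stable.
#'
#' @name gravstats
NULL

#' Field-level mean period for one phase
#'
#' Mean over the neurons whose period estimate is defined for that
#' phase; \code{NA} when no neuron is active there.
#'
#' @param periods List (one element per neuron) of named lists of
#'   \code{period_estimate}/NULL as returned by [phase_periods()].
#' @param phase Phase label.
#' @return Mean period in seconds, or \code{NA_real_}.
#' @export
field_phase_period <- function(periods, phase) {
  vals <- unlist(lapply(periods, function(pp) {
    e <- pp[[phase]]
    if (is.null(e)) NULL else e$mean_isi
  }))
  if (is.null(vals) || length(vals) == 0) NA_real_ else mean(vals)
}

#' Classify a field as constitutive, triggered, or inactive
#'
#' CONSTITUTIVE if any neuron has an unmasked peak during the initial
#' 1 g phase; otherwise TRIGGERED if any neuron has a peak from the
#' first hypergravity phase onward; otherwise INACTIVE.
#'
#' @param trains List of \code{spike_train}.
#' @param timeline A [build_timeline()] object.
#' @return One of "CONSTITUTIVE", "TRIGGERED", "INACTIVE".
#' @export
classify_field <- function(trains, timeline) {
  seg <- timeline$segments
  pre_end <- if ("PRE_1G" %in% seg$label)
    seg$end[seg$label == "PRE_1G"][1] else 0
  all_peaks <- unlist(lapply(trains, function(tr) tr$peak_times))
  if (length(all_peaks) == 0) return("INACTIVE")
  if (any(all_peaks < pre_end)) "CONSTITUTIVE" else "TRIGGERED"
}

#' Compute alpha period ratios for a field
#'
#' @param stats A one-row data.frame (or list) with \code{T_1g},
#'   \code{T_18g}, \code{T_0g} (NA when undefined).
#' @return The input with \code{alpha_1_18}, \code{alpha_1_0},
#'   \code{alpha_18_0} added; a ratio is \code{NA} (never infinite) when
#'   either operand is undefined or the denominator is zero.
#' @export
compute_alphas <- function(stats) {
  rat <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  stats$alpha_1_18 <- rat(stats$T_18g, stats$T_1g)
  stats$alpha_1_0 <- rat(stats$T_0g, stats$T_1g)
  stats$alpha_18_0 <- rat(stats$T_0g, stats$T_18g)
  stats
}

#' Build the field-statistics row for one analyzed field
#'
#' @param field_id Field identifier.
#' @param trains List of \code{spike_train} for the field's ROIs.
#' @param timeline A [build_timeline()] object.
#' @return One-row data.frame: \code{field_id}, \code{class},
#'   \code{T_1g}, \code{T_18g}, \code{T_0g}, \code{alpha_1_18},
#'   \code{alpha_1_0}, \code{alpha_18_0}, \code{n_active} (ROIs with at
#'   least one peak), and per-phase active-neuron counts.
#' @export
field_stats <- function(field_id, trains, timeline) {
  pp <- lapply(trains, phase_periods, timeline = timeline)
  phases_present <- if (length(pp)) names(pp[[1]]) else character(0)
  getT <- function(ph) if (ph %in% phases_present)
    field_phase_period(pp, ph) else NA_real_
  n_active_phase <- function(ph) {
    if (!(ph %in% phases_present)) return(0L)
    sum(vapply(pp, function(x) !is.null(x[[ph]]), logical(1)))
  }
  st <- data.frame(
    field_id = field_id,
    class = classify_field(trains, timeline),
    T_1g = getT("PRE_1G"), T_18g = getT("HYPER_1"), T_0g = getT("MICRO_0G"),
    n_active = sum(vapply(trains, function(tr) length(tr$peak_times) > 0,
                          logical(1))),
    n_active_1g = n_active_phase("PRE_1G"),
    n_active_18g = n_active_phase("HYPER_1"),
    n_active_0g = n_active_phase("MICRO_0G"),
    stringsAsFactors = FALSE)
  compute_alphas(st)
}

#' Sarle's bimodality coefficient
#'
#' \deqn{BC = (g_1^2 + 1) / (g_2 + 3(n-1)^2 / ((n-2)(n-3))),} with
#' \eqn{g_1} the sample skewness and \eqn{g_2} the sample excess
#' kurtosis. The uniform distribution gives ~0.555; larger values flag a
#' bimodal candidate (this is a descriptive flag, not a hypothesis
#' test).
#'
#' @param values Numeric vector, length >= 4.
#' @return Coefficient in (0, 1], or \code{NA_real_} when n < 4 or the
#'   values are degenerate.
#' @export
bimodality_coefficient <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) return(NA_real_)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((values - m)^3) / m2^1.5
  g2 <- mean((values - m)^4) / m2^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

BIMODALITY_CUTOFF <- 5 / 9  # uniform-law benchmark

#' Summarize an analyzed campaign
#'
#' Pools per-neuron period values per phase, takes median alphas over
#' fields where defined, counts field classes, and reports the fraction
#' of imaged neurons (detected ROIs) that were spontaneously active and
#' the fraction of active neurons that "reacted" to gravity, i.e. whose
#' maximum pairwise relative period change across phases exceeds
#' \code{react_tolerance}.
#'
#' @param analyzed List of per-field results from [analyze_field()]
#'   (each with \code{stats}, \code{trains}, \code{timeline}).
#' @param react_tolerance Relative period-change threshold (default
#'   0.2).
#' @param alpha_mode \code{"field"} (default): median alphas are taken
#'   over field-level period ratios (linked per-field points).
#'   \code{"neuron"}: over per-neuron ratios instead.
#' @return List: \code{phase} (per-phase list with \code{mean},
#'   \code{sd}, \code{n}, \code{values}, \code{bimodality}),
#'   \code{median_alpha} (named), \code{class_counts} (named),
#'   \code{n_neurons}, \code{frac_active}, \code{frac_reacted}.
#' @export
summarize_campaign <- function(analyzed, react_tolerance = 0.2,
                               alpha_mode = c("field", "neuron")) {
  stopifnot(length(analyzed) >= 1)
  alpha_mode <- match.arg(alpha_mode)
  stats <- do.call(rbind, lapply(analyzed, function(a) a$stats))
  phases <- c(T_1g = "PRE_1G", T_18g = "HYPER_1", T_0g = "MICRO_0G")

  per_neuron <- lapply(analyzed, function(a) {
    lapply(a$trains, phase_periods, timeline = a$timeline)
  })
  pooled <- lapply(phases, function(ph) {
    vals <- unlist(lapply(per_neuron, function(field)
      unlist(lapply(field, function(pp) {
        e <- pp[[ph]]
        if (is.null(e)) NULL else e$mean_isi
      }))))
    vals <- as.numeric(vals %||% numeric(0))
    list(mean = if (length(vals)) mean(vals) else NA_real_,
         sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
         n = length(vals), values = vals,
         bimodality = bimodality_coefficient(vals))
  })
  names(pooled) <- names(phases)

  if (alpha_mode == "field") {
    med_alpha <- c(
      alpha_1_18 = stats::median(stats$alpha_1_18, na.rm = TRUE),
      alpha_1_0 = stats::median(stats$alpha_1_0, na.rm = TRUE),
      alpha_18_0 = stats::median(stats$alpha_18_0, na.rm = TRUE))
  } else {
    nr <- do.call(rbind, lapply(per_neuron, function(field)
      do.call(rbind, lapply(field, function(pp) {
        g <- function(ph) if (is.null(pp[[ph]])) NA_real_ else pp[[ph]]$mean_isi
        compute_alphas(data.frame(T_1g = g("PRE_1G"), T_18g = g("HYPER_1"),
                                  T_0g = g("MICRO_0G")))
      }))))
    med_alpha <- c(
      alpha_1_18 = stats::median(nr$alpha_1_18, na.rm = TRUE),
      alpha_1_0 = stats::median(nr$alpha_1_0, na.rm = TRUE),
      alpha_18_0 = stats::median(nr$alpha_18_0, na.rm = TRUE))
  }

  cls <- table(factor(stats$class, levels = FIELD_CLASSES))
  class_counts <- stats::setNames(as.integer(cls), names(cls))

  n_neurons <- 0L; n_active <- 0L; n_reacted <- 0L
  for (fi in seq_along(analyzed)) {
    trains <- analyzed[[fi]]$trains
    n_neurons <- n_neurons + length(trains)
    for (ni in seq_along(trains)) {
      if (length(trains[[ni]]$peak_times) == 0) next
      n_active <- n_active + 1L
      pv <- unlist(lapply(per_neuron[[fi]][[ni]], function(e)
        if (is.null(e)) NULL else e$mean_isi))
      if (length(pv) >= 2) {
        rel <- max(abs(outer(pv, pv, "-"))) / min(pv)
        if (rel > react_tolerance) n_reacted <- n_reacted + 1L
      }
    }
  }

  list(phase = pooled, median_alpha = med_alpha,
       class_counts = class_counts,
       n_neurons = n_neurons,
       frac_active = if (n_neurons) n_active / n_neurons else NA_real_,
       frac_reacted = if (n_active) n_reacted / n_active else NA_real_)
}

#' Write field statistics and campaign summary
#'
#' \code{fieldstats.csv} per field, \code{summary.json} for the
#' campaign, and \code{period_values.csv} (tidy phase/period table, one
#' row per neuron per phase) for violin/strip plots.
#'
#' @param analyzed List from [analyze_campaign()]'s \code{fields}.
#' @param summary List from [summarize_campaign()].
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_summary <- function(analyzed, summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stats <- do.call(rbind, lapply(analyzed, function(a) a$stats))
  utils::write.csv(stats, file.path(dir, "fieldstats.csv"),
                   row.names = FALSE)
  tidy <- do.call(rbind, lapply(analyzed, function(a) {
    rows <- lapply(seq_along(a$trains), function(ni) {
      pp <- phase_periods(a$trains[[ni]], a$timeline)
      do.call(rbind, lapply(names(pp), function(ph) {
        if (is.null(pp[[ph]])) return(NULL)
        data.frame(field_id = a$stats$field_id,
                   roi_id = a$trains[[ni]]$roi_id, phase = ph,
                   period_s = pp[[ph]]$mean_isi)
      }))
    })
    do.call(rbind, rows)
  }))
  if (is.null(tidy))
    tidy <- data.frame(field_id = integer(0), roi_id = integer(0),
                       phase = character(0), period_s = numeric(0))
  utils::write.csv(tidy, file.path(dir, "period_values.csv"),
                   row.names = FALSE)
  js <- summary
  js$phase <- lapply(js$phase, function(p) p[c("mean", "sd", "n",
                                               "bimodality")])
  jsonlite::write_json(js, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
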