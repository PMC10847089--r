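#' End-to-end analysis pipeline
#'
#' Glue running the full chain on one field or a whole campaign:
#' stabilization -> activity map -> ROI detection -> DF/F extraction ->
#' peak detection -> per-phase periods -> field statistics.
#'
#' @name pipeline
NULL

#' Default analysis parameters
#'
#' @return Named list of tunables for [analyze_field()]: stabilization
#'   (\code{max_features}, \code{lk_window}), segmentation
#'   (\code{threshold_quantile}, \code{min_area}, \code{max_area},
#'   \code{smooth_sigma}), peak detection (\code{smooth_s},
#'   \code{min_prominence}, \code{min_separation_s}).
#' @export
default_params <- function() {
  list(stabilize = TRUE, max_features = 60, lk_window = 15,
       threshold_quantile = 0.95, min_area = 20, max_area = 400,
       smooth_sigma = 2,
       smooth_s = 0.8, min_prominence = 0.3, min_separation_s = 1.2)
}

#' Analyze one field of view
#'
#' @param stack A [movie_stack()] (raw; stabilized internally unless
#'   \code{params$stabilize} is FALSE).
#' @param timeline A [build_timeline()] object.
#' @param field_id Field identifier.
#' @param params Parameter list, see [default_params()].
#' @return List: \code{field_id}, \code{stats} (one-row data.frame from
#'   [field_stats()]), \code{trains}, \code{traces}, \code{rois},
#'   \code{trajectory}, \code{timeline}.
#' @export
analyze_field <- function(stack, timeline, field_id = 1L,
                          params = default_params()) {
  p <- utils::modifyList(default_params(), params)
  traj <- NULL
  if (isTRUE(p$stabilize)) {
    st <- stabilize_stack(stack, max_features = p$max_features,
                          window = p$lk_window)
    stack <- st$stack
    traj <- st$trajectory
  }
  amap <- activity_map(stack, timeline, smooth_sigma = p$smooth_sigma)
  rois <- detect_rois(amap, threshold_quantile = p$threshold_quantile,
                      min_area = p$min_area, max_area = p$max_area)
  traces <- extract_dff(stack, rois, timeline)
  trains <- lapply(traces, detect_peaks, smooth_s = p$smooth_s,
                   min_prominence = p$min_prominence,
                   min_separation_s = p$min_separation_s)
  list(field_id = field_id,
       stats = field_stats(field_id, trains, timeline),
       trains = trains, traces = traces, rois = rois,
       trajectory = traj, timeline = timeline)
}

#' Analyze a simulated or loaded campaign
#'
#' @param fields List of fields, each with \code{stack}, \code{timeline},
#'   \code{field_id} (the format produced by [simulate_campaign()]).
#' @param params Parameter list, see [default_params()].
#' @param react_tolerance Passed to [summarize_campaign()].
#' @param verbose Print one line per field.
#' @return List: \code{fields} (per-field [analyze_field()] results),
#'   \code{stats} (row-bound field statistics), \code{summary}
#'   ([summarize_campaign()] result).
#' @export
analyze_campaign <- function(fields, params = default_params(),
                             react_tolerance = 0.2, verbose = FALSE) {
  analyzed <- lapply(fields, function(f) {
    if (verbose) message("analyzing field ", f$field_id)
    analyze_field(f$stack, f$timeline, f$field_id, params)
  })
  list(fields = analyzed,
       stats = do.call(rbind, lapply(analyzed, function(a) a$stats)),
       summary = summarize_campaign(analyzed,
                                    react_tolerance = react_tolerance))
}

#' Simulate and analyze a campaign one field at a time
#'
#' Streaming equivalent of [simulate_campaign()] followed by
#' [analyze_campaign()]: each field's movie is rendered, analyzed, and
#' discarded before the next is generated, so memory stays bounded by
#' one field regardless of campaign size. Identical seeding to
#' [simulate_campaign()], so results match the two-step route.
#'
#' @param preset Generator preset ([flight_preset()] / [lab_preset()]).
#' @param n_fields,class_counts,seed As in [simulate_campaign()].
#' @param params Analysis parameters, see [default_params()].
#' @param react_tolerance Passed to [summarize_campaign()].
#' @param verbose Print one line per field.
#' @return As [analyze_campaign()], with each per-field element carrying
#'   \code{truth} (the simulator's ground truth, movie excluded) and no
#'   pixel data.
#' @export
simulate_and_analyze <- function(preset = flight_preset(), n_fields = NULL,
                                 class_counts = NULL, seed = 1,
                                 params = default_params(),
                                 react_tolerance = 0.2, verbose = FALSE) {
  n_fields <- n_fields %||% preset$n_fields
  class_counts <- class_counts %||% preset$class_counts
  if (sum(class_counts) != n_fields)
    stop("sum(class_counts) must equal n_fields")
  timeline <- build_timeline(preset$phases, preset$frame_interval,
                             preset$blur_halfwidth)
  set.seed(seed)
  classes <- sample(rep(names(class_counts), class_counts))
  analyzed <- lapply(seq_len(n_fields), function(f) {
    if (verbose) message("field ", f, "/", n_fields)
    fld <- simulate_field(f, classes[f], preset, timeline,
                          seed = substream_seed(seed, f))
    a <- analyze_field(fld$stack, timeline, f, params)
    a$traces <- NULL
    a$rois <- NULL
    a$truth <- fld$truth
    rm(fld)
    a
  })
  list(fields = analyzed,
       stats = do.call(rbind, lapply(analyzed, function(a) a$stats)),
       summary = summarize_campaign(analyzed,
                                    react_tolerance = react_tolerance))
}
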