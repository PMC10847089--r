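#' Gravity-phase timelines for parabolic-flight recordings
#'
#' A parabolic-flight recording spans a fixed sequence of gravity phases:
#' level flight at 1 g, a first hypergravity pull-up at 1.8 g, the
#' microgravity (0 g) phase, and a second hypergravity pull-out. Frames
#' acquired while the aircraft transitions between phases are blurred and
#' must be excluded from analysis. A \code{gravity_timeline} maps every
#' movie frame to its phase and carries the transition mask.
#'
#' @name timeline
NULL

PHASE_LEVELS <- c("PRE_1G", "HYPER_1", "MICRO_0G", "HYPER_2", "POST")
PHASE_G <- c(PRE_1G = 1.0, HYPER_1 = 1.8, MICRO_0G = 0.0, HYPER_2 = 1.8, POST = 1.0)

#' Default parabola phase configuration
#'
#' Phase durations for one parabola: 10 s of 1 g before parabola onset,
#' 30 s of 1.8 g hypergravity, 22 s of microgravity, then 20 s of the
#' second hypergravity phase, for an 82 s recording. The second
#' hypergravity phase is flagged unstable (aircraft trajectory
#' adjustments) and is excluded from phase statistics downstream.
#'
#' @return A data.frame with columns \code{label}, \code{g},
#'   \code{duration_s}, \code{stable}.
#' @export
flight_phases <- function() {
  data.frame(
    label = c("PRE_1G", "HYPER_1", "MICRO_0G", "HYPER_2"),
    g = c(1.0, 1.8, 0.0, 1.8),
    duration_s = c(10, 30, 22, 20),
    stable = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Laboratory (ground) phase configuration
#'
#' A single 1 g segment, for on-ground control recordings.
#'
#' @param duration_s Recording length in seconds (default 82 s, matching
#'   the flight recordings).
#' @return A data.frame in the same format as [flight_phases()].
#' @export
lab_phases <- function(duration_s = 82) {
  data.frame(label = "PRE_1G", g = 1.0, duration_s = duration_s,
             stable = TRUE, stringsAsFactors = FALSE)
}

#' Build a gravity timeline aligned to movie frames
#'
#' Lays the configured phase segments end to end on a time axis, assigns
#' every frame (acquired at a constant interval) to the segment containing
#' its timestamp, and masks frames within \code{blur_halfwidth} seconds of
#' any boundary between segments (transition blur).
#'
#' @param phases data.frame with columns \code{label}, \code{g},
#'   \code{duration_s} and optionally \code{stable}; default
#'   [flight_phases()].
#' @param frame_interval Acquisition cadence in seconds (default 0.4 s,
#'   i.e. 2.5 Hz).
#' @param blur_halfwidth Half-width in seconds of the transition mask
#'   around each inter-segment boundary (default 2 s; 0 disables masking).
#' @return An object of class \code{gravity_timeline}: a list with
#'   \code{segments} (data.frame with \code{label}, \code{g},
#'   \code{start}, \code{end}, \code{stable}), \code{frame_interval},
#'   \code{n_frames}, \code{frame_times}, \code{frame_phase},
#'   \code{frame_masked}, \code{total_duration}.
#' @examples
#' tl <- build_timeline()
#' tl$total_duration   # 82
#' tl$n_frames         # 205
#' @export
build_timeline <- function(phases = flight_phases(), frame_interval = 0.4,
                           blur_halfwidth = 2) {
  if (!all(c("label", "g", "duration_s") %in% names(phases)))
    stop("phases must have columns label, g, duration_s")
  if (any(phases$duration_s <= 0)) stop("all phase durations must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (blur_halfwidth < 0) stop("blur_halfwidth must be >= 0")
  if (!all(phases$label %in% PHASE_LEVELS))
    stop("unknown phase label; allowed: ", paste(PHASE_LEVELS, collapse = ", "))
  if (any(abs(phases$g - PHASE_G[phases$label]) > 1e-9))
    stop("g level does not match phase label")
  stable <- if ("stable" %in% names(phases)) phases$stable else rep(TRUE, nrow(phases))

  ends <- cumsum(phases$duration_s)
  starts <- c(0, ends[-length(ends)])
  segments <- data.frame(label = phases$label, g = phases$g,
                         start = starts, end = ends, stable = stable,
                         stringsAsFactors = FALSE)
  total <- ends[length(ends)]
  n_frames <- as.integer(floor(total / frame_interval + 1e-9))
  frame_times <- (seq_len(n_frames) - 1L) * frame_interval
  # half-open [start, end): findInterval on starts gives the containing segment
  seg_idx <- findInterval(frame_times, segments$start)
  frame_phase <- segments$label[seg_idx]

  frame_masked <- rep(FALSE, n_frames)
  if (blur_halfwidth > 0) {
    interior <- segments$end[-nrow(segments)]
    for (b in interior) {
      frame_masked <- frame_masked | (abs(frame_times - b) <= blur_halfwidth)
    }
  }

  structure(list(segments = segments, frame_interval = frame_interval,
                 n_frames = n_frames, frame_times = frame_times,
                 frame_phase = frame_phase, frame_masked = frame_masked,
                 total_duration = total, blur_halfwidth = blur_halfwidth),
            class = "gravity_timeline")
}

#' Phase label at a given time
#'
#' Segments are half-open \code{[start, end)}, so a boundary time belongs
#' to the segment that starts there.
#'
#' @param t Time in seconds, \code{0 <= t < total_duration}.
#' @param timeline A [build_timeline()] object.
#' @return Phase label (character).
#' @export
phase_of <- function(t, timeline) {
  stopifnot(inherits(timeline, "gravity_timeline"))
  if (any(t < 0 | t >= timeline$total_duration))
    stop("t out of range [0, ", timeline$total_duration, ")")
  timeline$segments$label[findInterval(t, timeline$segments$start)]
}

#' Per-frame timeline table
#'
#' @param timeline A [build_timeline()] object.
#' @return data.frame with columns \code{frame} (1-based index),
#'   \code{time_s}, \code{phase}, \code{g}, \code{masked}.
#' @export
timeline_frames <- function(timeline) {
  stopifnot(inherits(timeline, "gravity_timeline"))
  g <- timeline$segments$g[match(timeline$frame_phase, timeline$segments$label)]
  data.frame(frame = seq_len(timeline$n_frames),
             time_s = timeline$frame_times,
             phase = timeline$frame_phase,
             g = g,
             masked = timeline$frame_masked,
             stringsAsFactors = FALSE)
}

#' Phases usable for statistics
#'
#' Phases present in the timeline whose segments are flagged stable (the
#' second hypergravity phase is excluded by default: its acceleration is
#' not stable enough for period statistics).
#'
#' @param timeline A [build_timeline()] object.
#' @return Character vector of phase labels.
#' @export
stable_phases <- function(timeline) {
  stopifnot(inherits(timeline, "gravity_timeline"))
  timeline$segments$label[timeline$segments$stable]
}

#' Read a timeline configuration from JSON or YAML
#'
#' Expected keys: \code{phases} (list of \code{label}, \code{g},
#' \code{duration_s}, optional \code{stable}), \code{frame_interval_s},
#' \code{blur_halfwidth_s}.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{gravity_timeline}.
#' @export
read_timeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else stop("unsupported config format: ", ext)
  ph <- cfg$phases
  if (is.null(ph)) stop("config missing 'phases'")
  if (!is.data.frame(ph)) {
    ph <- do.call(rbind, lapply(ph, function(p)
      data.frame(label = p$label, g = p$g, duration_s = p$duration_s,
                 stable = p$stable %||% TRUE, stringsAsFactors = FALSE)))
  }
  build_timeline(ph,
                 frame_interval = cfg$frame_interval_s %||% 0.4,
                 blur_halfwidth = cfg$blur_halfwidth_s %||% 2)
}

#' Write the per-frame timeline table as CSV
#'
#' @param timeline A [build_timeline()] object.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(timeline_frames(timeline), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.gravity_timeline <- function(x, ...) {
  cat("gravity_timeline:", x$total_duration, "s,", x$n_frames, "frames @",
      x$frame_interval, "s\n")
  print(x$segments)
  cat(sum(x$frame_masked), "frames masked (transition blur halfwidth",
      x$blur_halfwidth, "s)\n")
  invisible(x)
}
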