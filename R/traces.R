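#' Activity-based ROI detection and DF/F trace extraction
#'
#' Active neurons are located from the temporal variability of each
#' pixel: calcium transients make a soma's pixels flicker, so the
#' per-pixel standard deviation over (unmasked) frames lights up active
#' somata. ROIs are connected components of the thresholded activity
#' map; the fluorescence of each ROI is normalized per the recording
#' convention \deqn{DF/F = (F - F_m) / F_m,} where \eqn{F} is the mean
#' ROI intensity and \eqn{F_m} the mean intensity of the whole field of
#' view at that frame.
#'
#' @name traces
NULL

#' Temporal-activity map of a stabilized stack
#'
#' Per-pixel standard deviation of intensity over frames (optionally
#' excluding masked transition frames), lightly Gaussian-smoothed.
#'
#' @param stack A stabilized [movie_stack()].
#' @param timeline Optional [build_timeline()]; needed when
#'   \code{exclude_masked = TRUE}.
#' @param exclude_masked Drop transition-blurred frames before computing
#'   the variance (default TRUE when a timeline is given).
#' @param smooth_sigma Gaussian smoothing sigma in px (default 2,
#'   about half a soma radius); 0 disables smoothing.
#' @param border_margin Pixels zeroed at each frame edge (default 8):
#'   stabilization resamples with constant-edge padding, so the border
#'   band carries spurious temporal variance.
#' @return Numeric H x W matrix (same orientation as the frames).
#' @export
activity_map <- function(stack, timeline = NULL,
                         exclude_masked = !is.null(timeline),
                         smooth_sigma = 2, border_margin = 8) {
  stopifnot(inherits(stack, "movie_stack"))
  m <- stack_matrix(stack)
  keep <- rep(TRUE, nrow(m))
  if (exclude_masked) {
    if (is.null(timeline)) stop("timeline required to exclude masked frames")
    keep <- !timeline$frame_masked
  }
  if (!any(keep)) stop("all frames masked")
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  mu <- colMeans(m)
  if (n < 2) return(matrix(0, dim(stack$data)[2], dim(stack$data)[3]))
  # two-pass variance: the one-pass moment formula cancels catastrophically
  # for pixels whose variance is tiny relative to their mean squared
  v <- colMeans(sweep(m, 2, mu)^2) * n / (n - 1)
  sd_map <- matrix(sqrt(pmax(v, 0)), dim(stack$data)[2], dim(stack$data)[3])
  if (smooth_sigma > 0)
    sd_map <- as.matrix(EBImage::gblur(sd_map, sigma = smooth_sigma))
  if (border_margin > 0) {
    b <- min(border_margin, floor(min(dim(sd_map)) / 2))
    sd_map[c(seq_len(b), nrow(sd_map) - seq_len(b) + 1L), ] <- 0
    sd_map[, c(seq_len(b), ncol(sd_map) - seq_len(b) + 1L)] <- 0
  }
  sd_map
}

#' Segment active-neuron ROIs from an activity map
#'
#' Thresholds the map at a quantile of its nonzero values (bounded below
#' by a robust noise floor, so a field with no active neuron yields no
#' ROIs), labels 8-connected components, discards components outside the
#' allowed area range, and splits components larger than \code{max_area}
#' (touching neurons) by a watershed on the activity map. A component
#' that exceeds \code{max_area} but contains a single watershed object
#' is one bright activity source, not merged neurons, and is kept.
#'
#' @param map Non-negative activity map from [activity_map()].
#' @param threshold_quantile Quantile of nonzero map values used as
#'   threshold (default 0.95).
#' @param min_area,max_area Component area limits in px (defaults 20 and
#'   400 at 1 um/px).
#' @param noise_floor_k The threshold is never below
#'   \code{median + noise_floor_k * mad} of the nonzero map values
#'   (default 6): in an inactive field the quantile threshold would sit
#'   inside the noise distribution and segment noise clusters.
#' @return An object of class \code{roi_set}: list with \code{label}
#'   (integer H x W label image, 0 = background) and \code{table}
#'   (data.frame \code{roi_id}, \code{centroid_row}, \code{centroid_col},
#'   \code{area}). Zero ROIs means the field is inactive (not an error).
#' @export
detect_rois <- function(map, threshold_quantile = 0.95, min_area = 20,
                        max_area = 400, noise_floor_k = 6) {
  stopifnot(all(map >= 0))
  empty <- structure(list(label = matrix(0L, nrow(map), ncol(map)),
                          table = data.frame(roi_id = integer(0),
                                             centroid_row = numeric(0),
                                             centroid_col = numeric(0),
                                             area = integer(0))),
                     class = "roi_set")
  nz <- map[map > 0]
  if (length(nz) == 0) return(empty)
  thr <- max(stats::quantile(nz, threshold_quantile, names = FALSE),
             stats::median(nz) + noise_floor_k * stats::mad(nz))
  mask <- map > thr
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(map), ncol(map))

  # split oversized components (merged neurons) by watershed on the map
  areas <- tabulate(lab[lab > 0])
  big <- which(areas > max_area)
  single_src <- integer(0)   # oversized but with a single watershed object
  if (length(big)) {
    nxt <- max(lab)
    for (bid in big) {
      sel <- lab == bid
      sub <- map; sub[!sel] <- 0
      ws <- EBImage::watershed(EBImage::Image(sub), tolerance = 0.1 * max(sub),
                               ext = 2)
      ws <- matrix(as.integer(EBImage::imageData(ws)), nrow(map), ncol(map))
      if (max(ws) <= 1) { single_src <- c(single_src, bid); next }
      lab[sel] <- ifelse(ws[sel] > 0, nxt + ws[sel], 0L)
      nxt <- max(lab)
    }
  }

  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(empty)
  areas <- vapply(ids, function(i) sum(lab == i), integer(1))
  keep <- ids[(areas >= min_area & areas <= max_area) |
                ids %in% single_src]
  out_lab <- matrix(0L, nrow(map), ncol(map))
  tab <- data.frame(roi_id = integer(0), centroid_row = numeric(0),
                    centroid_col = numeric(0), area = integer(0))
  rid <- 0L
  for (i in keep) {
    rid <- rid + 1L
    idx <- which(lab == i, arr.ind = TRUE)
    out_lab[idx] <- rid
    tab <- rbind(tab, data.frame(roi_id = rid,
                                 centroid_row = mean(idx[, 1]),
                                 centroid_col = mean(idx[, 2]),
                                 area = nrow(idx)))
  }
  structure(list(label = out_lab, table = tab), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set:", nrow(x$table), "ROIs\n")
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Extract DF/F calcium traces for each ROI
#'
#' For every frame t: \eqn{F(t)} is the mean intensity over the ROI's
#' pixels, \eqn{F_m(t)} the mean intensity of the entire field of view,
#' and \eqn{DF/F = (F - F_m)/F_m}. Transition-mask flags are copied from
#' the timeline.
#'
#' @param stack A [movie_stack()] (stabilized).
#' @param rois A [detect_rois()] \code{roi_set}.
#' @param timeline A [build_timeline()] object (for times and masks);
#'   optional, defaults to unmasked frames at the stack's interval.
#' @param fm_mode \code{"per_frame"} (default): \eqn{F_m(t)} is the
#'   field mean of frame t. \code{"scalar"}: one time-averaged field
#'   mean for the whole recording, provided for sensitivity checks.
#' @return List of \code{calcium_trace} objects, each a list with
#'   \code{roi_id}, \code{time_s}, \code{F}, \code{F_m}, \code{dff},
#'   \code{masked}, \code{frame_interval}.
#' @export
extract_dff <- function(stack, rois, timeline = NULL,
                        fm_mode = c("per_frame", "scalar")) {
  stopifnot(inherits(stack, "movie_stack"), inherits(rois, "roi_set"))
  fm_mode <- match.arg(fm_mode)
  d <- dim(stack$data)
  m <- stack_matrix(stack)
  F_m <- rowMeans(m)
  if (fm_mode == "scalar") F_m <- rep(mean(F_m), length(F_m))
  if (any(F_m == 0)) stop("degenerate input: field mean intensity is 0")
  times <- if (!is.null(timeline)) timeline$frame_times
           else (seq_len(d[1]) - 1) * stack$frame_interval
  masked <- if (!is.null(timeline)) timeline$frame_masked
            else rep(FALSE, d[1])
  lapply(rois$table$roi_id, function(id) {
    px <- which(as.vector(rois$label == id))
    F_ <- rowMeans(m[, px, drop = FALSE])
    structure(list(roi_id = id, time_s = times, F = F_, F_m = F_m,
                   dff = (F_ - F_m) / F_m, masked = masked,
                   frame_interval = stack$frame_interval),
              class = "calcium_trace")
  })
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat("calcium_trace roi", x$roi_id, ":", length(x$dff), "frames, dff range [",
      round(min(x$dff), 3), ",", round(max(x$dff), 3), "]\n")
  invisible(x)
}

#' Write an ROI label image as 16-bit TIFF
#'
#' Background is 0; each ROI keeps its integer label.
#'
#' @param rois A \code{roi_set}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_roi_tiff <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  tiff::writeTIFF(rois$label / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read an ROI label image written by [write_roi_tiff()]
#'
#' @param path TIFF path.
#' @return A \code{roi_set}.
#' @export
read_roi_tiff <- function(path) {
  lab <- round(tiff::readTIFF(path) * 65535)
  mode(lab) <- "integer"
  ids <- sort(unique(lab[lab > 0]))
  tab <- do.call(rbind, lapply(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    data.frame(roi_id = i, centroid_row = mean(idx[, 1]),
               centroid_col = mean(idx[, 2]), area = nrow(idx))
  }))
  if (is.null(tab))
    tab <- data.frame(roi_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area = integer(0))
  structure(list(label = lab, table = tab), class = "roi_set")
}

#' Write trace and ROI tables as CSV
#'
#' \code{traces.csv}: field_id, roi_id, frame, time_s, F, F_m, dff,
#' masked. \code{rois.csv}: field_id, roi_id, centroid_row, centroid_col,
#' area_px.
#'
#' @param traces List of \code{calcium_trace} from [extract_dff()].
#' @param rois A \code{roi_set}.
#' @param dir Output directory.
#' @param field_id Field identifier recorded in the tables.
#' @return \code{dir}, invisibly.
#' @export
write_traces_csv <- function(traces, rois, dir, field_id = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- do.call(rbind, lapply(traces, function(x)
    data.frame(field_id = field_id, roi_id = x$roi_id,
               frame = seq_along(x$dff), time_s = x$time_s,
               F = x$F, F_m = x$F_m, dff = x$dff, masked = x$masked)))
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  rt <- rois$table
  rt <- data.frame(field_id = field_id, roi_id = rt$roi_id,
                   centroid_row = rt$centroid_row,
                   centroid_col = rt$centroid_col, area_px = rt$area)
  utils::write.csv(rt, file.path(dir, "rois.csv"), row.names = FALSE)
  invisible(dir)
}
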