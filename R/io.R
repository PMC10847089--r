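#' Movie stack I/O: multi-page TIFF with a JSON metadata sidecar
#'
#' Movies are stored as multi-page grayscale TIFF (16-bit unsigned, one
#' page per frame). The acquisition metadata (frame interval, pixel
#' size) travels in a small JSON sidecar next to the TIFF
#' (\code{<name>.json}); when absent, documented defaults are applied
#' with a warning.
#'
#' @name io
NULL

#' Write a movie stack as multi-page 16-bit TIFF (+ JSON sidecar)
#'
#' Pixel values must be integers in [0, 65535]; they round-trip exactly
#' through [read_stack()].
#'
#' @param stack A [movie_stack()].
#' @param path Output TIFF path.
#' @param sidecar Write the metadata sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$data)
  if (any(stack$data < 0 | stack$data > 65535))
    stop("pixel values must lie in [0, 65535] for 16-bit TIFF")
  pages <- lapply(seq_len(d[1]), function(f)
    round(stack$data[f, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  if (sidecar) {
    jsonlite::write_json(
      list(frame_interval_s = stack$frame_interval,
           pixel_size_um = stack$pixel_size, n_frames = d[1]),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @noRd
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a multi-page grayscale TIFF as a movie stack
#'
#' @param path TIFF path; a \code{<name>.json} sidecar supplies
#'   \code{frame_interval_s} and \code{pixel_size_um} (defaults 0.4 s
#'   and 1 um/px with a warning when missing).
#' @return A [movie_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("format error reading ", path,
                                             ": ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, integer(1)) != 2))
    stop("format error: expected grayscale pages, got multi-channel")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("format error: irregular page sizes")
  H <- dims[[1]][1]; W <- dims[[1]][2]
  data <- array(0, dim = c(length(pages), H, W))
  for (f in seq_along(pages)) data[f, , ] <- round(pages[[f]] * 65535)
  sc <- sidecar_path(path)
  fi <- 0.4; ps <- 1.0
  if (file.exists(sc)) {
    meta <- jsonlite::fromJSON(sc)
    fi <- meta$frame_interval_s %||% fi
    ps <- meta$pixel_size_um %||% ps
  } else {
    warning("no metadata sidecar for ", path,
            "; using defaults frame_interval = 0.4 s, pixel_size = 1 um")
  }
  movie_stack(data, pixel_size = ps, frame_interval = fi)
}

#' Write a campaign of simulated fields to a directory
#'
#' One \code{field_###.tif} (+ sidecar) per field, ground-truth CSVs via
#' [write_truth_csvs()], and the timeline as \code{timeline.csv}.
#'
#' @param fields List from [simulate_campaign()] (rendered).
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_campaign <- function(fields, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in fields) {
    if (is.null(f$stack)) stop("field ", f$field_id, " has no rendered stack")
    write_stack(f$stack,
                file.path(dir, sprintf("field_%03d.tif", f$field_id)))
  }
  write_truth_csvs(fields, dir)
  write_timeline_csv(fields[[1]]$timeline, file.path(dir, "timeline.csv"))
  invisible(dir)
}

#' Read a campaign directory written by [write_campaign()]
#'
#' @param dir Directory containing \code{field_*.tif}.
#' @param timeline A [build_timeline()] object to attach to each field.
#' @return List of fields (\code{field_id}, \code{stack},
#'   \code{timeline}) suitable for [analyze_campaign()].
#' @export
read_campaign <- function(dir, timeline) {
  tifs <- sort(list.files(dir, pattern = "^field_[0-9]+\\.tif$",
                          full.names = TRUE))
  if (length(tifs) == 0) stop("no field TIFFs found in ", dir)
  lapply(seq_along(tifs), function(i)
    list(field_id = i, stack = read_stack(tifs[i]), timeline = timeline))
}
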