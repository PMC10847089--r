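#' Nuclei viability and cell-type sorting
#'
#' Automated counting of live/dead cells and neuron/astrocyte sorting
#' from a nuclei label mask plus DAPI / MAP2 / GFAP channels. A nucleus
#' is dead when it is mononucleolated AND condensed (small) AND bright
#' in DAPI; polynucleolated nuclei are alive. Because MAP2 and GFAP
#' labeling is somatic (not nuclear), each nucleus mask is dilated and
#' the original subtracted to obtain a ring-shaped somatic ROI on which
#' the marker intensities are measured. Segmentation itself is out of
#' scope: the module consumes label masks (the synthetic generator
#' provides them with ground truth).
#'
#' @name viability
NULL

#' Alive/dead call for one nucleus
#'
#' Dead iff mononucleolated (<= 1 nucleolus) AND condensed (area below
#' \code{area_threshold}) AND bright (mean DAPI above
#' \code{intensity_threshold}); alive otherwise. Increasing the
#' nucleoli count can only move a call toward alive.
#'
#' @param nucleoli_count Number of detected nucleoli.
#' @param area Nucleus area, px.
#' @param mean_dapi Mean DAPI intensity over the nucleus.
#' @param intensity_threshold DAPI intensity cutoff.
#' @param area_threshold Area cutoff, px.
#' @return Logical: TRUE if alive.
#' @export
classify_nucleus <- function(nucleoli_count, area, mean_dapi,
                             intensity_threshold = 0.65,
                             area_threshold = 40) {
  !(nucleoli_count <= 1 & area < area_threshold &
      mean_dapi > intensity_threshold)
}

#' Ring-shaped somatic ROI from a nucleus mask
#'
#' Morphological dilation by a Euclidean disk of radius
#' \code{dilation_px}, minus the original mask; the ring never overlaps
#' the nucleus.
#'
#' @param nucleus_mask Logical (or 0/1) matrix, nonempty.
#' @param dilation_px Disk radius, px >= 1 (default 4, ~4 um somatic
#'   shell at 1 um/px).
#' @return Logical matrix of the ring.
#' @export
ring_roi <- function(nucleus_mask, dilation_px = 4) {
  mask <- nucleus_mask > 0
  if (!any(mask)) stop("empty nucleus mask")
  stopifnot(dilation_px >= 1)
  dil <- EBImage::dilate(EBImage::Image(mask * 1),
                         disk_kernel(dilation_px))
  dil <- matrix(as.numeric(EBImage::imageData(dil)) > 0,
                nrow(mask), ncol(mask))
  dil & !mask
}

#' Cell-type call from somatic ring intensities
#'
#' NEURON if the ring's mean MAP2 passes its threshold and dominates the
#' (scaled) GFAP signal; ASTROCYTE for the symmetric case; OTHER when
#' neither marker is above threshold.
#'
#' @param ring_map2,ring_gfap Mean marker intensities over the ring.
#' @param map2_thr,gfap_thr Marker thresholds (data-driven Otsu defaults
#'   are computed upstream in [viability_pipeline()]).
#' @param balance Scale applied to the competing marker (default 1).
#' @return "NEURON", "ASTROCYTE" or "OTHER".
#' @export
assign_cell_type <- function(ring_map2, ring_gfap, map2_thr, gfap_thr,
                             balance = 1) {
  if (ring_map2 >= map2_thr && ring_map2 > balance * ring_gfap) "NEURON"
  else if (ring_gfap >= gfap_thr && ring_gfap > balance * ring_map2)
    "ASTROCYTE"
  else "OTHER"
}

#' Per-nucleus records from a label mask and DAPI image
#'
#' Computes area, mean DAPI intensity, centroid, and the nucleoli count
#' per labeled nucleus. Nucleoli are strict local maxima (8-neighbour)
#' of the DAPI image inside the nucleus that rise at least
#' \code{prominence} above the nucleus' median intensity.
#'
#' @param label_mask Integer matrix (0 = background).
#' @param dapi Numeric matrix, same size.
#' @param prominence Required height above the nucleus median (default
#'   0.15, for intensities scaled to [0, 1]).
#' @return data.frame: \code{label}, \code{area}, \code{mean_dapi},
#'   \code{nucleoli}, \code{centroid_row}, \code{centroid_col}.
#' @export
nucleus_records <- function(label_mask, dapi, prominence = 0.15) {
  stopifnot(all(dim(label_mask) == dim(dapi)))
  nr <- nrow(dapi); nc <- ncol(dapi)
  # strict local maxima of dapi
  is_max <- matrix(TRUE, nr, nc)
  for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))) {
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + d[1]):min(nr, nr + d[1])
    cs <- max(1, 1 + d[2]):min(nc, nc + d[2])
    shifted[rs - d[1], cs - d[2]] <- dapi[rs, cs]
    is_max <- is_max & (dapi > shifted)
  }
  ids <- sort(unique(label_mask[label_mask > 0]))
  rows <- lapply(ids, function(i) {
    idx <- which(label_mask == i, arr.ind = TRUE)
    vals <- dapi[idx]
    med <- stats::median(vals)
    loc_max <- is_max[idx] & (vals >= med + prominence)
    data.frame(label = i, area = nrow(idx), mean_dapi = mean(vals),
               nucleoli = sum(loc_max),
               centroid_row = mean(idx[, 1]),
               centroid_col = mean(idx[, 2]))
  })
  do.call(rbind, rows)
}

#' Simulate a stained nuclei field with ground truth
#'
#' Places elliptical nuclei on a jittered grid (no overlap). Alive cells
#' get a moderate DAPI level with 2-4 bright nucleolar spots and a
#' somatic MAP2 (neuron) or GFAP (astrocyte) halo per the type ratio;
#' dead cells are shrunken, uniformly bright, with at most one spot.
#'
#' @param n_cells Number of nuclei.
#' @param alive_fraction Probability a cell is alive (default 0.65).
#' @param neuron_to_astro_ratio Neuron:astrocyte ratio among alive cells
#'   (default 2).
#' @param seed Integer seed.
#' @return List: \code{label} (integer mask), \code{dapi}, \code{map2},
#'   \code{gfap} (numeric images in [0, 1]), \code{truth} (data.frame:
#'   \code{label}, \code{alive}, \code{type}).
#' @export
simulate_nuclei_field <- function(n_cells = 400, alive_fraction = 0.65,
                                  neuron_to_astro_ratio = 2, seed = 1) {
  stopifnot(alive_fraction > 0, alive_fraction <= 1,
            neuron_to_astro_ratio > 0)
  set.seed(seed)
  spacing <- 18
  g <- ceiling(sqrt(n_cells))
  side <- g * spacing + 24
  lab <- matrix(0L, side, side)
  dapi <- matrix(0.05, side, side)
  map2 <- matrix(0.05, side, side)
  gfap <- matrix(0.05, side, side)

  centers <- expand.grid(row = seq_len(g), col = seq_len(g))
  centers <- centers[sample.int(nrow(centers), n_cells), ]
  cy <- 12 + (centers$row - 0.5) * spacing + stats::runif(n_cells, -1.5, 1.5)
  cx <- 12 + (centers$col - 0.5) * spacing + stats::runif(n_cells, -1.5, 1.5)

  alive <- stats::runif(n_cells) < alive_fraction
  p_neuron <- neuron_to_astro_ratio / (neuron_to_astro_ratio + 1)
  type <- ifelse(alive,
                 ifelse(stats::runif(n_cells) < p_neuron, "NEURON",
                        "ASTROCYTE"),
                 NA_character_)

  for (i in seq_len(n_cells)) {
    a <- if (alive[i]) stats::runif(1, 4, 5.5) else stats::runif(1, 2.2, 3)
    b <- a * stats::runif(1, 0.7, 1)
    th <- stats::runif(1, 0, pi)
    ext <- ceiling(max(a, b)) + 1L
    rr <- max(1L, round(cy[i]) - ext):min(side, round(cy[i]) + ext)
    cc <- max(1L, round(cx[i]) - ext):min(side, round(cx[i]) + ext)
    dy <- outer(rr - cy[i], rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - cx[i])
    u <- (dy * cos(th) + dx * sin(th)) / a
    v <- (-dy * sin(th) + dx * cos(th)) / b
    inside <- (u^2 + v^2) <= 1
    lab[rr, cc][inside] <- i
    base <- if (alive[i]) stats::runif(1, 0.4, 0.5) else
      stats::runif(1, 0.8, 0.9)
    dapi[rr, cc][inside] <- base
    if (alive[i]) {
      n_nucleoli <- sample(2:4, 1)
      # first two on opposite sides so they always resolve as separate
      # maxima; extras fill in where space permits
      ang0 <- stats::runif(1, 0, 2 * pi)
      placed <- rbind(
        c(cy[i] + 0.55 * a * cos(ang0), cx[i] + 0.55 * a * sin(ang0)),
        c(cy[i] - 0.55 * a * cos(ang0), cx[i] - 0.55 * a * sin(ang0)))
      tries <- 0L
      while (nrow(placed) < n_nucleoli && tries < 60L) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.6)
        py <- cy[i] + rad * a * cos(ang)
        px <- cx[i] + rad * a * sin(ang)
        if (all((placed[, 1] - py)^2 + (placed[, 2] - px)^2 >= 9))
          placed <- rbind(placed, c(py, px))
        tries <- tries + 1L
      }
      for (k in seq_len(nrow(placed))) {
        bump <- exp(-((outer(rr - placed[k, 1], rep(1, length(cc)))^2 +
                         outer(rep(1, length(rr)), cc - placed[k, 2])^2)) /
                      (2 * 1.0^2))
        dapi[rr, cc] <- dapi[rr, cc] + 0.35 * bump * inside
      }
      # somatic halo on the marker channel for the cell's type
      halo_ext <- ext + 5L
      hr <- max(1L, round(cy[i]) - halo_ext):min(side, round(cy[i]) + halo_ext)
      hc <- max(1L, round(cx[i]) - halo_ext):min(side, round(cx[i]) + halo_ext)
      hdy <- outer(hr - cy[i], rep(1, length(hc)))
      hdx <- outer(rep(1, length(hr)), hc - cx[i])
      hu <- (hdy * cos(th) + hdx * sin(th)) / (a + 4)
      hv <- (-hdy * sin(th) + hdx * cos(th)) / (b + 4)
      halo <- ((hu^2 + hv^2) <= 1)
      if (type[i] == "NEURON") map2[hr, hc][halo] <- stats::runif(1, 0.5, 0.7)
      else gfap[hr, hc][halo] <- stats::runif(1, 0.5, 0.7)
    } else if (stats::runif(1) < 0.4) {
      bump <- exp(-((dy^2 + dx^2)) / (2 * 1.0^2))
      dapi[rr, cc] <- dapi[rr, cc] + 0.1 * bump * inside
    }
  }
  noise <- function(m) pmin(pmax(m + matrix(stats::rnorm(length(m), 0, 0.02),
                                            nrow(m)), 0), 1)
  list(label = lab, dapi = noise(dapi), map2 = noise(map2),
       gfap = noise(gfap),
       truth = data.frame(label = seq_len(n_cells), alive = alive,
                          type = type, stringsAsFactors = FALSE))
}

#' Write a stained nuclei field as TIFF files
#'
#' The label mask as 16-bit TIFF (\code{label.tif}), the DAPI/MAP2/GFAP
#' channels as 16-bit TIFFs scaled from [0, 1].
#'
#' @param field List from [simulate_nuclei_field()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_nuclei_field <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(field$label / 65535, file.path(dir, "label.tif"),
                  bits.per.sample = 16, compression = "none")
  for (ch in c("dapi", "map2", "gfap"))
    tiff::writeTIFF(pmin(pmax(field[[ch]], 0), 1),
                    file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16, compression = "none")
  invisible(dir)
}

#' Read a stained nuclei field from TIFF files
#'
#' @param dir Directory holding \code{label.tif}, \code{dapi.tif},
#'   \code{map2.tif}, \code{gfap.tif} (as written by
#'   [write_nuclei_field()], or an equivalent export from another
#'   segmentation tool).
#' @return List with \code{label} (integer mask) and the three channel
#'   images, suitable for [viability_pipeline()].
#' @export
read_nuclei_field <- function(dir) {
  need <- file.path(dir, c("label.tif", "dapi.tif", "map2.tif", "gfap.tif"))
  if (!all(file.exists(need)))
    stop("missing TIFFs in ", dir, ": expected label/dapi/map2/gfap")
  lab <- round(tiff::readTIFF(need[1]) * 65535)
  mode(lab) <- "integer"
  list(label = lab,
       dapi = tiff::readTIFF(need[2]),
       map2 = tiff::readTIFF(need[3]),
       gfap = tiff::readTIFF(need[4]))
}

#' Viability report over a set of cell calls
#'
#' @param calls data.frame with logical \code{alive} and character
#'   \code{type} columns (one row per cell).
#' @return List: \code{percent_alive}, \code{neuron_astro_ratio}
#'   (\code{NA}, never infinite, when no astrocytes), \code{counts}
#'   (named: total, alive, dead, neurons, astrocytes, other).
#' @export
viability_report <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  alive <- calls$alive
  typed <- calls$type[alive]
  n_neu <- sum(typed == "NEURON", na.rm = TRUE)
  n_ast <- sum(typed == "ASTROCYTE", na.rm = TRUE)
  list(percent_alive = 100 * mean(alive),
       neuron_astro_ratio = if (n_ast > 0) n_neu / n_ast else NA_real_,
       counts = c(total = nrow(calls), alive = sum(alive),
                  dead = sum(!alive), neurons = n_neu,
                  astrocytes = n_ast,
                  other = sum(alive) - n_neu - n_ast))
}

#' Full viability pipeline on one stained field
#'
#' Builds nucleus records, calls alive/dead (with data-driven Otsu
#' thresholds on mean DAPI and area when not supplied), constructs the
#' ring ROI per nucleus, measures ring MAP2/GFAP means, Otsu-thresholds
#' them across cells, assigns a type to each alive cell and returns the
#' per-cell table plus the summary report.
#'
#' @param field List with \code{label}, \code{dapi}, \code{map2},
#'   \code{gfap} (as produced by [simulate_nuclei_field()], or loaded
#'   from TIFFs).
#' @param dilation_px Ring dilation radius (default 4).
#' @param intensity_threshold,area_threshold Alive/dead cutoffs; Otsu
#'   over the per-nucleus values when NULL.
#' @return List: \code{cells} (data.frame: label, area, dapi_mean,
#'   nucleoli, alive, type, ring_map2, ring_gfap), \code{report}
#'   ([viability_report()] output), \code{thresholds}.
#' @export
viability_pipeline <- function(field, dilation_px = 4,
                               intensity_threshold = NULL,
                               area_threshold = NULL) {
  rec <- nucleus_records(field$label, field$dapi)
  int_thr <- intensity_threshold %||% otsu_threshold(rec$mean_dapi)
  area_thr <- area_threshold %||% otsu_threshold(rec$area)
  alive <- classify_nucleus(rec$nucleoli, rec$area, rec$mean_dapi,
                            intensity_threshold = int_thr,
                            area_threshold = area_thr)

  ring_m2 <- numeric(nrow(rec)); ring_gf <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    # ring built on a local crop for speed
    ext <- ceiling(sqrt(rec$area[i])) + dilation_px + 3L
    rr <- max(1L, round(rec$centroid_row[i]) - ext):
      min(nrow(field$label), round(rec$centroid_row[i]) + ext)
    cc <- max(1L, round(rec$centroid_col[i]) - ext):
      min(ncol(field$label), round(rec$centroid_col[i]) + ext)
    sub <- field$label[rr, cc] == rec$label[i]
    ring <- ring_roi(sub, dilation_px)
    ring <- ring & (field$label[rr, cc] == 0)  # exclude neighbours' nuclei
    ring_m2[i] <- mean(field$map2[rr, cc][ring])
    ring_gf[i] <- mean(field$gfap[rr, cc][ring])
  }
  m2_thr <- otsu_threshold(ring_m2)
  gf_thr <- otsu_threshold(ring_gf)
  type <- rep(NA_character_, nrow(rec))
  for (i in which(alive))
    type[i] <- assign_cell_type(ring_m2[i], ring_gf[i], m2_thr, gf_thr)

  cells <- data.frame(label = rec$label, area = rec$area,
                      dapi_mean = rec$mean_dapi, nucleoli = rec$nucleoli,
                      alive = alive, type = type,
                      ring_map2 = ring_m2, ring_gfap = ring_gf,
                      stringsAsFactors = FALSE)
  list(cells = cells, report = viability_report(cells),
       thresholds = c(intensity = int_thr, area = area_thr,
                      map2 = m2_thr, gfap = gf_thr))
}
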