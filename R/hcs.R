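#' A three-channel high-content field image
#'
#' One imaging field of a well: DNA channel (nuclear stain), mitotic-marker
#' channel (spindle-associated marker or phospho-histone H3), and readout
#' channel (total kinase or its activating phosphorylation).
#'
#' @param dna,marker,readout Numeric intensity matrices of identical shape,
#'   values >= 0.
#' @param pixel_size Pixel size (micrometers per pixel, > 0).
#' @param well Well id (e.g. `"B2"`).
#' @param field Field index within the well.
#' @return A `field_image`.
#' @export
field_image <- function(dna, marker, readout, pixel_size, well, field) {
  dims <- list(dim(dna), dim(marker), dim(readout))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all channels must have the same shape", call. = FALSE)
  }
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(dna = dna, marker = marker, readout = readout,
                 pixel_size = pixel_size, well = well,
                 field = as.integer(field)),
            class = "field_image")
}

#' Scoring configuration for the high-content pipeline
#'
#' All tunable parameters of the mislocalization / dephosphorylation scoring
#' algorithm, with their defaults.
#'
#' @param pixel_size Micrometers per pixel (default 0.65, emulating a 20x
#'   objective with 2x2 binning).
#' @param segment_factor Nuclei are pixels brighter than this multiple of
#'   the DNA-channel background.
#' @param marker_factor A nucleus is mitotic when its mean marker intensity
#'   exceeds this multiple of the marker-channel background.
#' @param tophat_factor The spindle mask keeps top-hat output above this
#'   multiple of the reference background.
#' @param tophat_background Reference background for the spindle-mask
#'   threshold: `"channel"` (background of the unfiltered marker channel,
#'   default — its scale is far from both the top-hat noise floor and the
#'   spindle signal, so the mask is stable) or `"tophat"` (background
#'   statistic of the top-hat output itself).
#' @param kernel_diameter_um Top-hat structuring-element (disc) diameter in
#'   micrometers.
#' @param window_um Side of the square analysis window centred on each
#'   mitotic nucleus for the top-hat, in micrometers. Must comfortably
#'   contain one mitotic cell plus the structuring element.
#' @param min_area_um2,max_area_um2 Nucleus area filter (square micrometers).
#' @param decile Darkest fraction of control cells that sets the per-plate
#'   threshold.
#' @param min_control_cells Minimum pooled control mitotic cells required to
#'   set a plate threshold.
#' @param min_well_cells Wells with fewer scored mitotic cells are flagged
#'   low-count and excluded from curve fits.
#' @param mask_kind `"spindle"` for the mislocalization assay or
#'   `"whole-nucleus"` for the dephosphorylation variant.
#' @param background_floor Absolute threshold floor used when a channel
#'   background estimate is 0.
#' @return A list of class `hcs_config`.
#' @export
hcs_config <- function(pixel_size = 0.65,
                       segment_factor = 100,
                       marker_factor = 100,
                       tophat_factor = 100,
                       tophat_background = c("channel", "tophat"),
                       kernel_diameter_um = 25,
                       window_um = 60,
                       min_area_um2 = 30,
                       max_area_um2 = 600,
                       decile = 0.10,
                       min_control_cells = 10,
                       min_well_cells = 20,
                       mask_kind = c("spindle", "whole-nucleus"),
                       background_floor = 0) {
  structure(list(pixel_size = pixel_size,
                 segment_factor = segment_factor,
                 marker_factor = marker_factor,
                 tophat_factor = tophat_factor,
                 tophat_background = match.arg(tophat_background),
                 kernel_diameter_um = kernel_diameter_um,
                 window_um = window_um,
                 min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2,
                 decile = decile,
                 min_control_cells = min_control_cells,
                 min_well_cells = min_well_cells,
                 mask_kind = match.arg(mask_kind),
                 background_floor = background_floor),
            class = "hcs_config")
}

#' Estimate the background level of a channel image
#'
#' Robust background statistic: the median of the lowest-intensity quartile
#' of pixels. Insensitive to sparse bright objects covering a minority of
#' the field. The estimate is clamped at 0.
#'
#' @param img Numeric intensity matrix.
#' @param quartile Fraction of lowest-intensity pixels used (default 0.25).
#' @return Scalar background level (>= 0). A constant-zero image returns 0
#'   with a warning.
#' @export
estimate_background <- function(img, quartile = 0.25) {
  v <- as.numeric(img)
  if (!length(v)) stop("empty image", call. = FALSE)
  if (all(v == 0)) {
    warning("constant-zero image: background is 0")
    return(0)
  }
  q <- quantile(v, quartile, names = FALSE)
  max(0, median(v[v <= q]))
}

# dense relabel of an integer label matrix after dropping some labels
relabel_dense <- function(labels, keep) {
  lut <- integer(max(labels, 1L))
  lut[keep] <- seq_along(keep)
  out <- labels
  nz <- labels > 0L
  out[nz] <- lut[labels[nz]]
  out
}

#' Segment nuclei in a DNA-channel image
#'
#' Connected components of pixels brighter than `factor` times the channel
#' background, filtered to a plausible nucleus area range. Labels are dense
#' from 1. When the background estimate is 0 the threshold falls back to the
#' configured absolute floor.
#'
#' @param dna DNA-channel intensity matrix.
#' @param background Channel background; computed with
#'   [estimate_background()] when `NULL`.
#' @param factor Threshold multiple of the background (default 100).
#' @param pixel_size Micrometers per pixel.
#' @param min_area_um2,max_area_um2 Area filter in square micrometers.
#' @param background_floor Absolute threshold used when `background` is 0.
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(dna, background = NULL, factor = 100,
                           pixel_size = 0.65, min_area_um2 = 30,
                           max_area_um2 = 600, background_floor = 0) {
  stopifnot_scalar(factor, "factor", positive = TRUE)
  if (is.null(background)) background <- estimate_background(dna)
  thr <- factor * background
  if (thr <= 0) thr <- background_floor
  mask <- dna > thr
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(labels) <- "integer"
  if (max(labels) == 0L) return(labels)
  px_area <- pixel_size^2
  areas <- tabulate(labels[labels > 0L], nbins = max(labels)) * px_area
  keep <- which(areas >= min_area_um2 & areas <= max_area_um2)
  drop_mask <- !(labels %in% c(0L, keep))
  labels[drop_mask] <- 0L
  relabel_dense(labels, keep)
}

# per-label mean of a channel over a label matrix; returns numeric named 1..K
label_means <- function(labels, channel) {
  k <- max(labels)
  if (k == 0L) return(numeric(0))
  nz <- labels > 0L
  sums <- rowsum(as.numeric(channel[nz]), labels[nz])
  counts <- tabulate(labels[nz], nbins = k)
  means <- as.numeric(sums[, 1]) / counts[sort(unique(labels[nz]))]
  setNames(means, sort(unique(labels[nz])))
}

#' Flag mitotic nuclei by marker positivity
#'
#' A nucleus is mitotic when its mean marker-channel intensity exceeds
#' `factor` times the marker-channel background (spindle-marker positivity
#' in the mislocalization assay, phospho-histone H3 positivity in the
#' dephosphorylation variant).
#'
#' @param labels Nucleus label matrix from [segment_nuclei()].
#' @param marker Marker-channel intensity matrix, same shape.
#' @param background Marker-channel background; estimated when `NULL`.
#' @param factor Positivity multiple of the background (default 100).
#' @return Logical vector, one entry per nucleus label (empty when there are
#'   no nuclei).
#' @export
classify_mitotic <- function(labels, marker, background = NULL, factor = 100) {
  if (!identical(dim(labels), dim(marker))) {
    stop("shape mismatch between labels and marker", call. = FALSE)
  }
  k <- max(labels)
  if (k == 0L) return(logical(0))
  if (is.null(background)) background <- estimate_background(marker)
  means <- numeric(k)
  mm <- label_means(labels, marker)
  means[as.integer(names(mm))] <- mm
  means > factor * background
}

#' Extract a fine spindle mask around a mitotic nucleus
#'
#' Applies a white top-hat transform (image minus its morphological opening)
#' with a disc structuring element of `kernel_diameter_um` to the marker
#' channel and keeps, within a square window centred on the nucleus, the
#' pixels above `factor` times the reference background. The top-hat passes
#' structures finer than the disc — the mitotic spindle — while removing the
#' diffuse cell body and any flat background. The transform is computed over
#' the whole field (so cell bodies sliced by the window boundary cannot leak
#' into the mask as artifacts) and the mask is then restricted to the
#' window; the thresholding statistics are taken from the windowed portion.
#'
#' @param marker Marker-channel intensity matrix.
#' @param nucleus_pixels Integer matrix indices (into `marker`) of the
#'   nucleus pixels.
#' @param pixel_size Micrometers per pixel.
#' @param kernel_diameter_um Disc diameter of the structuring element
#'   (default 25).
#' @param window_um Analysis window side (default 60).
#' @param factor Threshold multiple of the reference background.
#' @param background Marker-channel background (used when
#'   `tophat_background = "channel"`); estimated from `marker` when `NULL`.
#' @param tophat_background `"channel"` (default) to threshold against the
#'   unfiltered marker-channel background, `"tophat"` to use the background
#'   statistic of the top-hat output itself.
#' @param tophat Optional precomputed full-field top-hat of `marker` with
#'   the same kernel (avoids recomputing the transform for every cell of a
#'   field).
#' @return Integer vector of matrix indices of the mask (possibly empty; an
#'   empty mask means the cell is excluded from scoring and tallied in QC).
#' @export
spindle_mask <- function(marker, nucleus_pixels, pixel_size = 0.65,
                         kernel_diameter_um = 25, window_um = 60,
                         factor = 100, background = NULL,
                         tophat_background = c("channel", "tophat"),
                         tophat = NULL) {
  tophat_background <- match.arg(tophat_background)
  if (!length(nucleus_pixels)) stop("empty nucleus", call. = FALSE)
  nr <- nrow(marker); nc <- ncol(marker)
  half <- max(1L, round(window_um / pixel_size / 2))
  if (is.null(tophat)) {
    tophat <- field_tophat(marker, pixel_size, kernel_diameter_um)
  }

  rows <- ((nucleus_pixels - 1L) %% nr) + 1L
  cols <- ((nucleus_pixels - 1L) %/% nr) + 1L
  cr <- round(mean(range(rows))); cc <- round(mean(range(cols)))
  r0 <- max(1L, cr - half); r1 <- min(nr, cr + half)
  c0 <- max(1L, cc - half); c1 <- min(nc, cc + half)
  th <- tophat[r0:r1, c0:c1, drop = FALSE]
  ref <- if (tophat_background == "tophat") {
    estimate_background(th)
  } else {
    background %||% estimate_background(marker)
  }
  sel <- which(th > factor * ref)
  if (!length(sel)) return(integer(0))
  lr <- ((sel - 1L) %% nrow(th)) + r0
  lc <- ((sel - 1L) %/% nrow(th)) + c0
  as.integer((lc - 1L) * nr + lr)
}

# Full-field white top-hat of a channel with a disc element of the given
# diameter (micrometers). The channel is normalized to [0, 1] before the
# morphology and rescaled afterwards: the grayscale rank filters expect
# unit-range input, and the normalization makes the transform exactly
# equivariant under intensity scaling.
field_tophat <- function(channel, pixel_size, kernel_diameter_um = 25) {
  kpx <- max(1L, round(kernel_diameter_um / pixel_size))
  if (kpx %% 2L == 0L) kpx <- kpx + 1L
  s <- max(channel)
  if (s <= 0) return(array(0, dim(channel)))
  s * EBImage::imageData(
    EBImage::whiteTopHat(channel / s, EBImage::makeBrush(kpx, shape = "disc")))
}

#' Mean readout intensity over per-cell masks
#'
#' Samples the readout channel over each cell's mask (spindle mask for the
#' mislocalization assay, whole-nucleus mask for the dephosphorylation
#' variant) and records the mean.
#'
#' @param readout Readout-channel intensity matrix.
#' @param masks List of integer index vectors, one per cell; empty masks are
#'   not allowed (exclude those cells upstream).
#' @param mask_kind `"spindle"` or `"whole-nucleus"`, recorded alongside.
#' @return Data frame with `mean_intensity` and `mask_kind` per cell.
#' @export
score_cells <- function(readout, masks, mask_kind = c("spindle", "whole-nucleus")) {
  mask_kind <- match.arg(mask_kind)
  n <- max(as.numeric(unlist(masks, use.names = FALSE)), 0)
  if (n > length(readout)) stop("shape mismatch: mask outside image", call. = FALSE)
  if (any(!lengths(masks))) stop("empty mask", call. = FALSE)
  means <- vapply(masks, function(ix) mean(readout[ix]), numeric(1))
  data.frame(mean_intensity = means, mask_kind = mask_kind,
             stringsAsFactors = FALSE)
}

#' Per-plate assay threshold from untreated control cells
#'
#' Pools the mask mean intensities of mitotic cells from untreated control
#' wells, takes the darkest `decile` fraction (count rounded up), and sets
#' the threshold at the highest intensity among them. Cells strictly below
#' the threshold are later classified as mislocalized (or dephosphorylated).
#'
#' @param control_intensities Mask mean intensities of control mitotic cells.
#' @param decile Darkest fraction used (default 0.10).
#' @param min_cells Minimum control cells; fewer is an error instructing
#'   plate rejection.
#' @return List of class `plate_threshold` with `threshold`, `n_control`,
#'   `decile`.
#' @export
plate_threshold <- function(control_intensities, decile = 0.10,
                            min_cells = 10) {
  x <- control_intensities[is.finite(control_intensities)]
  n <- length(x)
  if (n < min_cells) {
    stop(sprintf(
      "only %d control mitotic cells (< %d): reject the plate", n, min_cells),
      call. = FALSE)
  }
  k <- ceiling(decile * n)
  thr <- sort(x)[k]
  structure(list(threshold = thr, n_control = n, decile = decile),
            class = "plate_threshold")
}

#' Score a well's mislocalization percentage
#'
#' Percentage of the well's mitotic cells whose mask mean intensity falls
#' strictly below the plate threshold.
#'
#' @param intensities Mask mean intensities of the well's mitotic cells.
#' @param threshold A [plate_threshold()] or a scalar threshold.
#' @param well Well id carried through to the result.
#' @param min_cells Wells with fewer cells are flagged `low_count`.
#' @return List of class `well_score`: `well`, `n_mitotic`, `n_below`,
#'   `percent`, `flags`.
#' @export
well_mislocalization <- function(intensities, threshold, well = NA_character_,
                                 min_cells = 20) {
  thr <- if (inherits(threshold, "plate_threshold")) threshold$threshold else threshold
  x <- intensities[is.finite(intensities)]
  n <- length(x)
  flags <- character()
  if (n == 0) {
    return(structure(list(well = well, n_mitotic = 0L, n_below = 0L,
                          percent = NA_real_, flags = "no_mitotic_cells"),
                     class = "well_score"))
  }
  if (n < min_cells) flags <- "low_count"
  below <- sum(x < thr)
  structure(list(well = well, n_mitotic = n, n_below = below,
                 percent = 100 * below / n, flags = flags),
            class = "well_score")
}

#' Fit the assay EC50 from per-well scores
#'
#' Four-parameter logistic fit of percent-positive scores against compound
#' dose; the midpoint is the assay EC50. Flagged (low-count or empty) wells
#' must be excluded before calling.
#'
#' @param dose Dose per well (molar; 0 for vehicle wells).
#' @param percent Percent-positive score per well.
#' @return A `dose_response_fit` (see [fit_4pl()]).
#' @export
assay_ec50 <- function(dose, percent) {
  fit_4pl(dose, percent)
}

# Score one field: segment, classify, mask, and measure. Returns a per-cell
# data frame plus a QC tally.
score_field <- function(field, config = hcs_config()) {
  stopifnot(inherits(field, "field_image"))
  px <- field$pixel_size %||% config$pixel_size
  bg_dna <- estimate_background(field$dna)
  bg_marker <- estimate_background(field$marker)
  labels <- segment_nuclei(field$dna, bg_dna, config$segment_factor, px,
                           config$min_area_um2, config$max_area_um2,
                           config$background_floor)
  k <- max(labels)
  qc <- c(nuclei = k, mitotic = 0L, empty_mask = 0L)
  empty <- data.frame(well = character(), field = integer(), label = integer(),
                      mean_intensity = numeric(), mask_px = integer(),
                      mask_kind = character(), stringsAsFactors = FALSE)
  if (k == 0L) return(list(cells = empty, qc = qc))
  mitotic <- classify_mitotic(labels, field$marker, bg_marker,
                              config$marker_factor)
  qc["mitotic"] <- sum(mitotic)
  if (!any(mitotic)) return(list(cells = empty, qc = qc))

  ids <- which(mitotic)
  masks <- vector("list", length(ids))
  th <- if (config$mask_kind == "spindle") {
    field_tophat(field$marker, px, config$kernel_diameter_um)
  }
  for (i in seq_along(ids)) {
    npx <- which(labels == ids[i])
    masks[[i]] <- if (config$mask_kind == "spindle") {
      spindle_mask(field$marker, npx, px, config$kernel_diameter_um,
                   config$window_um, config$tophat_factor, bg_marker,
                   config$tophat_background, tophat = th)
    } else {
      npx
    }
  }
  ok <- lengths(masks) > 0L
  qc["empty_mask"] <- sum(!ok)
  if (!any(ok)) return(list(cells = empty, qc = qc))
  scored <- score_cells(field$readout, masks[ok], config$mask_kind)
  cells <- data.frame(well = field$well, field = field$field,
                      label = ids[ok],
                      mean_intensity = scored$mean_intensity,
                      mask_px = lengths(masks[ok]),
                      mask_kind = scored$mask_kind,
                      stringsAsFactors = FALSE)
  list(cells = cells, qc = qc)
}

# Gather per-cell records for a list of field_image objects.
score_fields <- function(fields, config = hcs_config()) {
  parts <- lapply(fields, score_field, config = config)
  cells <- do.call(rbind, lapply(parts, `[[`, "cells"))
  qc <- Reduce(`+`, lapply(parts, `[[`, "qc"))
  list(cells = cells, qc = qc)
}

#' Score a plate of field images
#'
#' Runs the full scoring algorithm over a plate: per field, nuclei are
#' segmented from the DNA channel, mitotic cells identified by marker
#' positivity, a top-hat spindle mask (or whole-nucleus mask) extracted, and
#' the readout channel measured over the mask. Control (vehicle) cells set
#' the per-plate darkest-decile threshold; every well is then scored as the
#' percentage of its mitotic cells strictly below the threshold.
#'
#' The pipeline is deterministic: no random numbers are used in scoring.
#'
#' @param plate Either a synthetic plate object from [generate_plate()], a
#'   directory of single-channel TIFFs named
#'   `{plate}_{well}_{field}_{channel}.tif` (channels `dna`, `marker`,
#'   `readout`), or a list of [field_image()] objects.
#' @param plate_map Plate map data frame (see [load_plate_map()]) with
#'   columns `well`, `compound`, `dose_molar`, `role`.
#' @param config An [hcs_config()].
#' @return List with `cells` (per-cell table), `well_scores` (per-well data
#'   frame with `well`, `dose_molar`, `role`, `n_mitotic`, `n_below`,
#'   `percent`, `flag`), `threshold` (the [plate_threshold()]), and `qc`.
#' @export
score_plate <- function(plate, plate_map, config = hcs_config()) {
  well_ids <- plate_map$well
  cells_by_well <- vector("list", length(well_ids))
  qc <- NULL
  for (i in seq_along(well_ids)) {
    fields <- plate_fields(plate, well_ids[i], config)
    if (is.null(fields)) next
    sc <- score_fields(fields, config)
    cells_by_well[[i]] <- sc$cells
    qc <- if (is.null(qc)) sc$qc else qc + sc$qc
  }
  cells <- do.call(rbind, cells_by_well)
  finalize_plate_scores(cells, plate_map, config, qc)
}

# Resolve the 12 (or however many) fields of one well from the supported
# plate representations.
plate_fields <- function(plate, well, config) {
  if (inherits(plate, "synthetic_plate")) {
    return(plate$wells[[well]])
  }
  if (is.character(plate) && length(plate) == 1L && dir.exists(plate)) {
    return(read_well_fields(plate, well, config$pixel_size))
  }
  if (is.list(plate)) { # flat list of field_image objects
    fields <- Filter(function(f) identical(f$well, well), plate)
    return(if (length(fields)) fields else NULL)
  }
  stop("unsupported plate representation", call. = FALSE)
}

finalize_plate_scores <- function(cells, plate_map, config, qc) {
  if (is.null(cells) || !nrow(cells)) {
    stop("no mitotic cells scored on the plate", call. = FALSE)
  }
  vehicle_wells <- plate_map$well[plate_map$role == "vehicle"]
  control <- cells$mean_intensity[cells$well %in% vehicle_wells]
  thr <- plate_threshold(control, config$decile, config$min_control_cells)

  rows <- lapply(seq_len(nrow(plate_map)), function(i) {
    w <- plate_map$well[i]
    if (plate_map$role[i] == "blank") return(NULL)
    ints <- cells$mean_intensity[cells$well == w]
    ws <- well_mislocalization(ints, thr, w, config$min_well_cells)
    data.frame(well = w, dose_molar = plate_map$dose_molar[i],
               role = plate_map$role[i], n_mitotic = ws$n_mitotic,
               n_below = ws$n_below, percent = ws$percent,
               flag = paste(ws$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  well_scores <- do.call(rbind, rows)
  list(cells = cells, well_scores = well_scores, threshold = thr, qc = qc)
}

# Read the fields of one well from a directory of TIFFs.
read_well_fields <- function(dir, well, pixel_size) {
  pat <- sprintf("^[^_]+_%s_(\\d+)_dna\\.tif$", well)
  files <- list.files(dir, pattern = pat)
  if (!length(files)) return(NULL)
  idx <- sort(as.integer(sub(pat, "\\1", files)))
  plate_name <- sub(sprintf("_%s_.*$", well), "", files[1])
  lapply(idx, function(fi) {
    ch <- lapply(c("dna", "marker", "readout"), function(channel) {
      path <- file.path(dir, sprintf("%s_%s_%d_%s.tif",
                                     plate_name, well, fi, channel))
      if (!file.exists(path)) stop("missing channel image: ", path, call. = FALSE)
      tiff::readTIFF(path)
    })
    field_image(ch[[1]], ch[[2]], ch[[3]], pixel_size, well, fi)
  })
}
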