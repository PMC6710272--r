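#' Split a multi-well field of view into single-well images
#'
#' Microscope fields span several nanowells (2x2 by default); this cuts a
#' field into equal quadrant images and assigns chip well coordinates from
#' the field's position in the scan order.
#'
#' @param field_image Numeric matrix or named list of channel matrices.
#' @param layout List with `wells_per_field` (default `c(2, 2)`),
#'   `chip_wells` (total chip well grid, default `c(72, 72)`), and `order`
#'   (`"raster"` or `"serpentine"`).
#' @param field_index 0-based index of the field in the chip scan.
#' @return List of well images; each has `pixels` (matrix or channel list)
#'   and `well_id = c(row, col)` (0-based).
#' @export
split_field_into_wells <- function(field_image,
                                   layout = list(wells_per_field = c(2L, 2L),
                                                 chip_wells = c(72L, 72L),
                                                 order = "raster"),
                                   field_index = 0L) {
  wpf <- as.integer(layout$wells_per_field %||% c(2L, 2L))
  chip <- as.integer(layout$chip_wells %||% c(72L, 72L))
  ord <- layout$order %||% "raster"
  chans <- if (is.matrix(field_image)) list(field_image) else field_image
  dims <- dim(chans[[1]])
  if (dims[1] %% wpf[1] != 0L)
    stop(sprintf("field rows (%d) not divisible by wells per field (%d)",
                 dims[1], wpf[1]), call. = FALSE)
  if (dims[2] %% wpf[2] != 0L)
    stop(sprintf("field cols (%d) not divisible by wells per field (%d)",
                 dims[2], wpf[2]), call. = FALSE)
  fields_per_row <- chip[2] %/% wpf[2]
  frow <- field_index %/% fields_per_row
  fcol <- field_index %% fields_per_row
  if (ord == "serpentine" && frow %% 2L == 1L)
    fcol <- fields_per_row - 1L - fcol
  h <- dims[1] %/% wpf[1]; w <- dims[2] %/% wpf[2]
  wells <- list()
  for (qr in seq_len(wpf[1]) - 1L) {
    for (qc in seq_len(wpf[2]) - 1L) {
      rows <- (qr * h + 1L):((qr + 1L) * h)
      cols <- (qc * w + 1L):((qc + 1L) * w)
      px <- lapply(chans, function(m) m[rows, cols, drop = FALSE])
      if (is.matrix(field_image)) px <- px[[1]]
      wells[[length(wells) + 1L]] <- list(
        pixels = px,
        well_id = c(frow * wpf[1] + qr, fcol * wpf[2] + qc))
    }
  }
  wells
}

#' Z-projection of an image stack
#'
#' @param stack 3D array ordered (z, row, col) with at least one plane.
#' @param mode `"mean"` (average-intensity projection, used for
#'   immunofluorescence) or `"max"` (maximum-intensity projection, used for
#'   RNA FISH).
#' @return 2D numeric matrix.
#' @export
project_z <- function(stack, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(stack)) == 3L, dim(stack)[1] >= 1L)
  apply(stack, c(2, 3), if (mode == "mean") mean else max)
}

#' Segment spheroids in a 2D fluorescence image
#'
#' Gaussian smoothing, global Otsu threshold, 8-connected component
#' labelling, then removal of objects outside the size window (defaults:
#' sigma 2, keep 300 to 800,000 px).  Labels are renumbered consecutively.
#'
#' @param image Single-channel numeric matrix with finite intensities.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param min_area,max_area Object size window in pixels.
#' @return Integer label matrix (0 = background).  A constant image yields
#'   an empty mask with a warning.
#' @export
segment_spheroids <- function(image, sigma = 2, min_area = 300L,
                              max_area = 800000L) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  sm <- gaussian_blur(image, sigma)
  thr <- withCallingHandlers(
    otsu_threshold(sm),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.na(thr)) {
    warning("constant image: returning empty mask")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  lab <- label_components(sm > thr, connectivity = 8L)
  filter_mask_by_area(lab, min_area, max_area)
}

# drop objects outside [min_area, max_area] and renumber consecutively
filter_mask_by_area <- function(lab, min_area, max_area) {
  if (!any(lab > 0L)) return(lab)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area & areas <= max_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Nuclear mask for RNA-FISH quantification
#'
#' DAPI-channel preset: Gaussian smoothing (sigma 5), grayscale maximum
#' filter (radius 12 px), Otsu threshold, connected components; when more
#' than one object is present only the biggest is retained.
#'
#' @param dapi_image Single-channel numeric matrix.
#' @param sigma Gaussian sigma (default 5).
#' @param maxfilter_radius Maximum-filter radius in pixels (default 12).
#' @return Integer label matrix with at most one object (label 1).
#' @export
fish_nuclear_mask <- function(dapi_image, sigma = 5, maxfilter_radius = 12L) {
  stopifnot(is.matrix(dapi_image), all(is.finite(dapi_image)))
  sm <- max_filter(gaussian_blur(dapi_image, sigma), maxfilter_radius)
  thr <- withCallingHandlers(
    otsu_threshold(sm),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.na(thr)) {
    warning("constant image: returning empty mask")
    return(matrix(0L, nrow(dapi_image), ncol(dapi_image)))
  }
  lab <- label_components(sm > thr, connectivity = 8L)
  if (!any(lab > 0L)) return(lab)
  areas <- tabulate(lab[lab > 0L])
  biggest <- which.max(areas)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab == biggest] <- 1L
  out
}

#' Morphology and intensity features per labelled object
#'
#' For each object: pixel area, outer-contour perimeter, circularity
#' \eqn{4\pi \cdot area / perimeter^2} (capped at 1 to absorb discretization
#' overshoot), centroid, and the mean intensity in each supplied channel.
#'
#' @param mask Integer label matrix (0 = background).
#' @param channels Named list of intensity matrices sharing the mask's
#'   dimensions (may be empty).
#' @param well_id Optional `c(row, col)` well coordinate to attach.
#' @return data.frame with one row per object: `well_row`, `well_col`,
#'   `object_id`, `area_px`, `perimeter_px`, `circularity`, `centroid_row`,
#'   `centroid_col`, then one `mean_<channel>` column per channel.
#' @export
compute_features <- function(mask, channels = list(), well_id = c(NA, NA)) {
  stopifnot(is.matrix(mask))
  for (ch in channels) stopifnot(identical(dim(ch), dim(mask)))
  ids <- sort(unique(mask[mask > 0L]))
  rows <- lapply(ids, function(id) {
    sel <- mask == id
    area <- sum(sel)
    per <- object_perimeter(sel)
    circ <- min(4 * pi * area / per^2, 1.0)
    w <- which(sel, arr.ind = TRUE)
    rec <- data.frame(well_row = well_id[1], well_col = well_id[2],
                      object_id = id, area_px = area, perimeter_px = per,
                      circularity = circ,
                      centroid_row = mean(w[, 1]), centroid_col = mean(w[, 2]))
    for (ch in names(channels))
      rec[[paste0("mean_", ch)]] <- mean(channels[[ch]][sel])
    rec
  })
  if (!length(rows)) {
    out <- data.frame(well_row = numeric(0), well_col = numeric(0),
                      object_id = integer(0), area_px = integer(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
    for (ch in names(channels)) out[[paste0("mean_", ch)]] <- numeric(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Intermodes histogram threshold
#'
#' Iteratively smooths a 256-bin intensity histogram with a 3-bin mean
#' filter until exactly two local maxima remain, at bin centers j < k, and
#' returns the threshold (j + k) / 2.  Used to separate FISH probe signal
#' from background within a spheroid.
#'
#' @param pixels Numeric intensity sample with at least 2 distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @param max_iterations Smoothing iteration cap; an effectively unimodal
#'   histogram raises a bimodality error.
#' @return List of class `intermodes_result`: `j`, `k`, `threshold`,
#'   `smoothing_iterations`.
#' @export
intermodes_threshold <- function(pixels, n_bins = 256L,
                                 max_iterations = 10000L) {
  v <- as.numeric(pixels)
  stopifnot(all(is.finite(v)))
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("intermodes threshold needs at least 2 distinct intensity values",
         call. = FALSE)
  width <- (hi - lo) / (n_bins - 1L)
  centers <- lo + (seq_len(n_bins) - 1L) * width
  h <- tabulate(round((v - lo) / width) + 1L, n_bins)
  n_modes <- function(h) {
    interior <- seq(2L, length(h) - 1L)
    sum(h[interior] > h[interior - 1L] & h[interior] >= h[interior + 1L]) +
      (h[1] > h[2]) + (h[n_bins] > h[n_bins - 1L])
  }
  mode_bins <- function(h) {
    interior <- seq(2L, length(h) - 1L)
    c(if (h[1] > h[2]) 1L,
      interior[h[interior] > h[interior - 1L] & h[interior] >= h[interior + 1L]],
      if (h[n_bins] > h[n_bins - 1L]) n_bins)
  }
  it <- 0L
  h <- as.numeric(h)
  while (n_modes(h) > 2L && it < max_iterations) {
    h <- (c(h[1], h[-n_bins]) + h + c(h[-1], h[n_bins])) / 3
    it <- it + 1L
  }
  if (n_modes(h) != 2L)
    stop("histogram is not bimodal: intermodes threshold undefined",
         call. = FALSE)
  jk <- centers[mode_bins(h)]
  structure(list(j = jk[1], k = jk[2], threshold = mean(jk),
                 smoothing_iterations = it),
            class = "intermodes_result")
}

#' Fraction of object pixels above a threshold
#'
#' FISH quantification: per labelled object, the fraction of its pixels in
#' the probe channel whose intensity exceeds the threshold.
#'
#' @param probe_image Numeric matrix (probe channel).
#' @param mask Integer label matrix of matching dimensions.
#' @param threshold Intensity cutoff (strictly exceeded counts).
#' @return Named numeric vector, one fraction in `[0, 1]` per object label.
#' @export
fraction_above_threshold <- function(probe_image, mask, threshold) {
  stopifnot(identical(dim(probe_image), dim(mask)))
  ids <- sort(unique(mask[mask > 0L]))
  out <- vapply(ids, function(id) {
    px <- probe_image[mask == id]
    mean(px > threshold)
  }, 0)
  stats::setNames(out, as.character(ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
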