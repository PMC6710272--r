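#' Specification of a synthetic spheroid image
#'
#' Describes a 2D multi-channel fluorescence image populated with
#' non-overlapping objects of three classes: `round` (filled disks),
#' `aberrant` (star-convex disks with radius
#' \eqn{r(\theta) = r_0 (1 + \sum_k a_k \sin(k\theta + \phi_k))}), and
#' `debris` (specks constrained to an area below 300 px, the segmentation
#' size filter).  Objects may carry FISH-like "spots": a fraction of their
#' pixels set to a high intensity in a probe channel, giving a bimodal
#' within-object intensity histogram.
#'
#' @param image_shape Integer `(rows, cols)`.
#' @param objects List of object descriptors; each is a list with `center`
#'   `(row, col)`, `radius`, `intensity`, `class` (one of `"round"`,
#'   `"aberrant"`, `"debris"`), and optionally `amplitudes`/`phases`
#'   (aberrant only), `spot_fraction` and `spot_intensity`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param channels Character vector of channel names (default `"mask"`;
#'   add `"probe"` to render spots).
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(image_shape, objects = list(), noise_sd = 0,
                                 channels = "mask") {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L), noise_sd >= 0,
            length(channels) >= 1L)
  for (ob in objects) {
    if (!ob$class %in% c("round", "aberrant", "debris"))
      stop("unknown object class: ", ob$class, call. = FALSE)
    rmax <- ob$radius * (1 + if (is.null(ob$amplitudes)) 0 else sum(abs(ob$amplitudes)))
    if (ob$center[1] - rmax < 1 || ob$center[1] + rmax > image_shape[1] ||
        ob$center[2] - rmax < 1 || ob$center[2] + rmax > image_shape[2])
      stop("object does not lie within image bounds", call. = FALSE)
    if (ob$class == "debris" && pi * ob$radius^2 >= 300)
      stop("debris objects must have area < 300 px", call. = FALSE)
  }
  structure(list(image_shape = image_shape, objects = objects,
                 noise_sd = noise_sd, channels = channels),
            class = "synthetic_image_spec")
}

# rasterize one object: TRUE/FALSE matrix over the whole image
rasterize_object <- function(ob, shape) {
  amp <- if (is.null(ob$amplitudes)) numeric(0) else ob$amplitudes
  phs <- if (is.null(ob$phases)) rep(0, length(amp)) else ob$phases
  rmax <- ob$radius * (1 + sum(abs(amp)))
  r0 <- max(1L, floor(ob$center[1] - rmax)); r1 <- min(shape[1], ceiling(ob$center[1] + rmax))
  c0 <- max(1L, floor(ob$center[2] - rmax)); c1 <- min(shape[2], ceiling(ob$center[2] + rmax))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - ob$center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - ob$center[2])
  rad <- sqrt(dr^2 + dc^2)
  rtheta <- ob$radius
  if (length(amp)) {
    theta <- atan2(dc, dr)
    pert <- 0
    for (k in seq_along(amp)) pert <- pert + amp[k] * sin(k * theta + phs[k])
    rtheta <- ob$radius * (1 + pert)
  }
  inside <- rad <= rtheta
  m <- matrix(FALSE, shape[1], shape[2])
  m[rows, cols] <- inside
  m
}

#' Render a synthetic spheroid image with ground truth
#'
#' Rasterizes the objects of a [synthetic_image_spec()] into a multi-channel
#' image, adds Gaussian noise clipped to the 16-bit range, and returns the
#' exact per-object ground truth (label mask, pixel area, class).
#' Overlapping objects are rejected because their ground truth would be
#' ambiguous.
#'
#' @param spec A [synthetic_image_spec()].
#' @param seed Integer seed (noise and spot placement).
#' @return List with `image` (named list of numeric matrices, one per
#'   channel), `mask` (integer label matrix, 0 = background), and `truth`
#'   (data.frame: `object_id`, `class`, `center_row`, `center_col`,
#'   `radius`, `area_px`, `intensity`, `spot_fraction`).
#' @export
render_spheroid_image <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  seed <- check_seed(seed)
  set.seed(seed)
  shape <- spec$image_shape
  mask <- matrix(0L, shape[1], shape[2])
  chans <- stats::setNames(
    lapply(spec$channels, function(ch) matrix(0, shape[1], shape[2])),
    spec$channels)
  truth <- vector("list", length(spec$objects))
  for (k in seq_along(spec$objects)) {
    ob <- spec$objects[[k]]
    m <- rasterize_object(ob, shape)
    if (any(mask[m] != 0L))
      stop("objects overlap; ground truth would be ambiguous", call. = FALSE)
    mask[m] <- k
    for (ch in spec$channels) chans[[ch]][m] <- ob$intensity
    sf <- if (is.null(ob$spot_fraction)) 0 else ob$spot_fraction
    if (sf > 0 && "probe" %in% spec$channels) {
      px <- which(m)
      spots <- sample(px, round(sf * length(px)))
      chans[["probe"]][m] <- 0        # probe channel carries spots only
      chans[["probe"]][spots] <- ob$spot_intensity
    }
    truth[[k]] <- data.frame(
      object_id = k, class = ob$class,
      center_row = ob$center[1], center_col = ob$center[2],
      radius = ob$radius, area_px = sum(m), intensity = ob$intensity,
      spot_fraction = sf)
  }
  if (spec$noise_sd > 0) {
    for (ch in spec$channels) {
      noisy <- chans[[ch]] +
        stats::rnorm(length(chans[[ch]]), 0, spec$noise_sd)
      chans[[ch]] <- pmin(pmax(noisy, 0), 65535)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(object_id = integer(0), class = character(0),
               center_row = numeric(0), center_col = numeric(0),
               radius = numeric(0), area_px = integer(0),
               intensity = numeric(0), spot_fraction = numeric(0))
  list(image = chans, mask = mask, truth = truth)
}
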