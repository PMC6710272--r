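#' Gaussian smoothing of a 2D image
#'
#' Separable Gaussian convolution with replicate (edge-clamp) padding,
#' kernel truncated at 3 sigma.
#'
#' @param image Numeric matrix.
#' @param sigma Standard deviation in pixels; `0` returns the input.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_blur <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma >= 0)
  if (sigma == 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {                      # convolve along rows (dim 1)
    nr <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(nr, r), , drop = FALSE])
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[j:(j + nr - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(image))))
}

#' Otsu threshold of an image or intensity sample
#'
#' Classic maximum between-class-variance threshold on a 256-bin histogram.
#'
#' @param x Numeric matrix or vector of finite intensities.
#' @param n_bins Number of histogram bins.
#' @return Threshold value, or `NA` (with a warning) for a constant input.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  stopifnot(all(is.finite(v)))
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    warning("constant image: Otsu threshold undefined")
    return(NA_real_)
  }
  width <- (hi - lo) / n_bins
  idx <- pmin(floor((v - lo) / width) + 1L, n_bins)
  h <- tabulate(idx, n_bins)
  w <- cumsum(h)
  m <- cumsum(h * seq_len(n_bins))
  total_w <- w[n_bins]; total_m <- m[n_bins]
  w1 <- w[-n_bins]; m1 <- m[-n_bins]
  w2 <- total_w - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (m1[valid] / w1[valid] - (total_m - m1[valid]) / w2[valid])^2 *
    w1[valid] * w2[valid]
  t_bin <- which.max(between)
  lo + t_bin * width                           # upper edge of best bin
}

#' Label connected components of a binary image
#'
#' Iterative minimum-label propagation with 4- or 8-connectivity; labels are
#' renumbered to consecutive positive integers in scan order.
#'
#' @param binary Logical (or 0/1) matrix; `TRUE` = foreground.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(binary, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  b <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  nr <- nrow(b); nc <- ncol(b)
  lab <- matrix(0, nr, nc)
  lab[b] <- seq_len(sum(b))
  lab[!b] <- Inf
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- lab
    for (s in shifts) new <- pmin(new, shift_mat(lab, s[1], s[2]))
    new[!b] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!b] <- 0
  ids <- unique(lab[lab > 0])
  out <- matrix(0L, nr, nc)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

#' Grayscale maximum filter with a disk structuring element
#'
#' @param image Numeric matrix.
#' @param radius Disk radius in pixels.
#' @return Filtered matrix (each pixel replaced by the maximum over the
#'   disk neighbourhood; edges use the available pixels only).
#' @export
max_filter <- function(image, radius) {
  stopifnot(is.matrix(image), radius >= 0)
  if (radius == 0) return(image)
  r <- as.integer(ceiling(radius))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    sh <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- image[rs - dr, cs - dc]
    out <- pmax(out, sh)
  }
  out
}

# perimeter of the outer contour of one object's binary mask:
# marching-squares contour at level 0.5 on a zero-padded image, lightly
# smoothed with a 3-vertex circular moving average to remove the staircase
# bias (a digitized disk then scores within ~2% of its true perimeter while
# an axis-aligned square keeps circularity ~ pi/4)
object_perimeter <- function(b) {
  bp <- matrix(0, nrow(b) + 2L, ncol(b) + 2L)
  bp[2:(nrow(b) + 1L), 2:(ncol(b) + 1L)] <- b
  cl <- grDevices::contourLines(x = seq_len(nrow(bp)), y = seq_len(ncol(bp)),
                                z = bp, levels = 0.5)
  if (!length(cl)) return(NA_real_)
  plen <- function(xy) {
    x <- xy$x; y <- xy$y
    n <- length(x)
    if (n >= 7) {                              # circular 3-point smoothing
      sm <- function(v) (c(v[n], v[-n]) + v + c(v[-1], v[1])) / 3
      x <- sm(x); y <- sm(y)
    }
    sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  }
  max(vapply(cl, plen, 0))                     # outer contour is the longest
}
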