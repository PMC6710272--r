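#' Library quality-control thresholds
#'
#' Default values are the colon-spheroid criteria: more than 200,000 reads,
#' more than 3,000 detected genes, and less than 15% mitochondrial reads.
#' Mitochondrial genes are identified by an explicit gene list or, by
#' default, by the `"MT-"` identifier prefix.
#'
#' @param min_reads Minimum total counts (exclusive bound).
#' @param min_genes_detected Minimum number of genes with count > 0
#'   (exclusive bound).
#' @param max_mito_fraction Maximum mitochondrial count fraction
#'   (exclusive bound).
#' @param mito_genes Character vector of mitochondrial gene identifiers, or
#'   `NULL` to use `mito_prefix`.
#' @param mito_prefix Identifier prefix marking mitochondrial genes.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_reads = 200000L, min_genes_detected = 3000L,
                          max_mito_fraction = 0.15, mito_genes = NULL,
                          mito_prefix = "MT-") {
  stopifnot(min_reads >= 0, min_genes_detected >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_reads = min_reads,
                 min_genes_detected = min_genes_detected,
                 max_mito_fraction = max_mito_fraction,
                 mito_genes = mito_genes, mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter RNA-seq libraries by quality control criteria
#'
#' A spheroid library is kept iff its total counts exceed `min_reads`, its
#' detected genes (count > 0) exceed `min_genes_detected`, and its
#' mitochondrial read fraction is below `max_mito_fraction`.  The report
#' lists each removed library with the first failing criterion
#' (`"reads"`, `"genes"`, or `"mito"`).
#'
#' @param counts Integer matrix, genes x spheroids, with dimnames.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `counts` (filtered matrix) and `removed` (data.frame
#'   `spheroid_id`, `reason`).
#' @export
qc_filter_libraries <- function(counts, thresholds = qc_thresholds()) {
  check_count_matrix(counts)
  mito <- if (!is.null(thresholds$mito_genes)) {
    rownames(counts) %in% thresholds$mito_genes
  } else {
    startsWith(rownames(counts), thresholds$mito_prefix)
  }
  totals <- colSums(counts)
  detected <- colSums(counts > 0)
  mito_frac <- ifelse(totals > 0, colSums(counts[mito, , drop = FALSE]) / totals, 0)
  reason <- rep(NA_character_, ncol(counts))
  reason[mito_frac >= thresholds$max_mito_fraction] <- "mito"
  reason[detected <= thresholds$min_genes_detected] <- "genes"
  reason[totals <= thresholds$min_reads] <- "reads"
  keep <- is.na(reason)
  if (!any(keep))
    stop("QC thresholds removed every library", call. = FALSE)
  list(counts = counts[, keep, drop = FALSE],
       removed = data.frame(spheroid_id = colnames(counts)[!keep],
                            reason = reason[!keep]))
}

#' Fit a spheroid-size to cell-number calibration model
#'
#' Relates imaged spheroid size to nuclei counts.  The power form fits
#' `log(count) = log(a) + b * log(area)` by least squares; the linear form
#' fits `count = a * area + b`.
#'
#' @param pairs data.frame with columns `area_px` and `nuclei_count`
#'   (at least 3 rows, all positive).
#' @param model_form `"power"` (default) or `"linear"`.
#' @return List of class `calibration_model`: `model_form`, `a`, `b`,
#'   `fit_residual_sd` (log scale for power, response scale for linear).
#' @export
fit_size_to_cells <- function(pairs, model_form = c("power", "linear")) {
  model_form <- match.arg(model_form)
  stopifnot(nrow(pairs) >= 3L, all(pairs$area_px > 0),
            all(pairs$nuclei_count > 0))
  if (stats::sd(pairs$area_px) == 0)
    stop("degenerate calibration design: all areas equal", call. = FALSE)
  if (model_form == "power") {
    fit <- stats::lm(log(nuclei_count) ~ log(area_px), data = pairs)
    a <- exp(unname(stats::coef(fit)[1]))
    b <- unname(stats::coef(fit)[2])
  } else {
    fit <- stats::lm(nuclei_count ~ area_px, data = pairs)
    a <- unname(stats::coef(fit)[2])
    b <- unname(stats::coef(fit)[1])
  }
  structure(list(model_form = model_form, a = a, b = b,
                 fit_residual_sd = stats::sigma(fit)),
            class = "calibration_model")
}

#' Predict cell numbers from a calibration model
#'
#' @param object A `calibration_model`.
#' @param newdata data.frame with an `area_px` column (or numeric vector of
#'   areas).
#' @param ... Unused.
#' @return Numeric predictions (not yet rounded or floored).
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  area <- if (is.data.frame(newdata)) newdata$area_px else as.numeric(newdata)
  if (object$model_form == "power") object$a * area^object$b
  else object$a * area + object$b
}

#' Estimate per-spheroid cell numbers from image features
#'
#' Applies the calibration model to each spheroid's segmented area and
#' rounds to an integer cell number, floored at 1.
#'
#' @param features data.frame with columns `spheroid_id` and `area_px`.
#' @param model A [fit_size_to_cells()] calibration model.
#' @return Named integer vector: spheroid_id -> n_i (all `>= 1`).
#' @export
estimate_cell_numbers <- function(features, model) {
  if (any(is.na(features$area_px)))
    stop("missing area for spheroid(s): ",
         paste(features$spheroid_id[is.na(features$area_px)], collapse = ", "),
         call. = FALSE)
  n <- pmax(1L, as.integer(round(predict(model, features))))
  stats::setNames(n, features$spheroid_id)
}

#' Minimal average mRNA count per cell
#'
#' The minimum over spheroids of (column total / estimated cell number);
#' the downsampling target must not exceed this value.
#'
#' @param counts Count matrix, genes x spheroids.
#' @param cells Named integer vector of cell numbers covering all columns.
#' @return Single numeric value.
#' @export
min_per_cell_count <- function(counts, cells) {
  n <- match_cells(counts, cells)
  min(colSums(counts) / n)
}

#' Suggest a per-cell downsampling target
#'
#' Convenience helper: the minimal per-cell count floored to the nearest
#' 100.  Returned as a suggestion only; the target is always an explicit
#' user choice.
#'
#' @param minimal_per_cell Value from [min_per_cell_count()].
#' @return Integer target.
#' @export
suggest_target_per_cell <- function(minimal_per_cell) {
  as.integer(floor(minimal_per_cell / 100) * 100)
}

#' Downsample a count matrix to a constant per-cell depth
#'
#' Each column is replaced by a without-replacement (multivariate
#' hypergeometric) subsample of its counts with new total exactly
#' `target_per_cell * n_i`, so that after downsampling the correlation
#' between column totals and cell numbers is exactly 1.  Each column uses
#' an independent seed substream derived from `(seed, spheroid_id)`, and
#' genes are processed in sorted identifier order internally, so the result
#' is invariant to gene and column order.
#'
#' @param counts Integer count matrix, genes x spheroids.
#' @param cells Named integer vector of cell numbers.
#' @param target_per_cell Target counts per cell; every column total must
#'   be at least `target_per_cell * n_i`.
#' @param seed Integer seed.
#' @return Integer count matrix of the same dimensions.
#' @export
downsample_per_cell <- function(counts, cells, target_per_cell, seed) {
  check_count_matrix(counts)
  n <- match_cells(counts, cells)
  target_per_cell <- as.integer(target_per_cell)
  stopifnot(target_per_cell >= 1L)
  seed <- check_seed(seed)
  totals <- colSums(counts)
  targets <- target_per_cell * n
  short <- totals < targets
  if (any(short))
    stop("column total below downsampling target for spheroid(s): ",
         paste(colnames(counts)[short], collapse = ", "), call. = FALSE)
  out <- counts
  for (i in seq_len(ncol(counts)))
    out[, i] <- downsample_column(counts[, i], targets[i],
                                  derive_seed(seed, colnames(counts)[i]))
  out
}

#' Downsample one library to a fixed total
#'
#' Without-replacement subsample of a single count vector with new total
#' exactly `target_total` (used, e.g., to downsample libraries to 100,000
#' reads for method comparison).
#'
#' @param column Non-negative integer count vector.
#' @param target_total New total, at most `sum(column)`.
#' @param seed Integer seed.
#' @return Integer vector with `sum == target_total`, elementwise at most
#'   the input.
#' @export
downsample_library <- function(column, target_total, seed) {
  stopifnot(all(column >= 0), target_total >= 0)
  if (sum(column) < target_total)
    stop("column total below downsampling target", call. = FALSE)
  downsample_column(column, as.integer(target_total), check_seed(seed))
}

# core hypergeometric subsampler; operates in sorted-name order when names
# exist so the draw is invariant to input gene order
downsample_column <- function(x, target, seed) {
  ord <- if (!is.null(names(x))) order(names(x)) else seq_along(x)
  xs <- x[ord]
  total <- sum(xs)
  if (target == total) return(x)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  items <- sample.int(total, target)          # distinct item indices
  breaks <- cumsum(as.numeric(xs))
  gene_of <- findInterval(items, c(0, breaks), left.open = TRUE)
  new_sorted <- tabulate(gene_of, nbins = length(xs))
  out <- integer(length(x))
  out[ord] <- new_sorted
  names(out) <- names(x)
  out
}

#' Gene filters ahead of deconvolution
#'
#' Keeps a gene iff (i) its mean count over the *original* (pre-downsampling)
#' matrix is at least `min_mean` and (ii) at least `min_wells` wells of the
#' *working* matrix hold at least `min_count` counts.  Whether rule (ii)
#' reads the working (downsampled) or original matrix is configurable via
#' `count_rule_on`; the downsampled matrix is the default.
#'
#' @param original Count matrix before downsampling.
#' @param working Count matrix after downsampling (same gene universe).
#' @param min_mean Mean-count threshold on the original matrix (default 1).
#' @param min_count Per-well count threshold (default 5).
#' @param min_wells Number of wells required to reach `min_count` (default 2).
#' @param count_rule_on `"working"` (default) or `"original"`.
#' @return The working matrix restricted to the retained genes.
#' @export
filter_genes_for_deconvolution <- function(original, working, min_mean = 1,
                                           min_count = 5L, min_wells = 2L,
                                           count_rule_on = c("working", "original")) {
  count_rule_on <- match.arg(count_rule_on)
  if (!identical(sort(rownames(original)), sort(rownames(working))))
    stop("original and working matrices must share the same gene universe",
         call. = FALSE)
  original <- original[rownames(working), , drop = FALSE]
  rule_mat <- if (count_rule_on == "working") working else original
  keep <- rowMeans(original) >= min_mean &
    rowSums(rule_mat >= min_count) >= min_wells
  working[keep, , drop = FALSE]
}

#' Replace zeros ahead of lognormal modelling
#'
#' Lognormal densities are undefined at zero, so zero entries are replaced
#' by a small positive pseudo-expression (default 0.1).
#'
#' @param matrix Numeric matrix.
#' @param value Replacement value, `> 0`.
#' @return Matrix with zeros replaced; all other entries unchanged.
#' @export
replace_zeros <- function(matrix, value = 0.1) {
  stopifnot(value > 0)
  matrix[matrix == 0] <- value
  matrix
}

# internal validators -------------------------------------------------------

check_count_matrix <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have gene and spheroid identifiers", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or spheroid identifiers", call. = FALSE)
  invisible(counts)
}

match_cells <- function(counts, cells) {
  miss <- setdiff(colnames(counts), names(cells))
  if (length(miss))
    stop("missing cell numbers for spheroid(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- as.integer(cells[colnames(counts)])
  if (any(n < 1L)) stop("cell numbers must be >= 1", call. = FALSE)
  n
}
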