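#' Simulate spheroid expression under the mixed-n LN-LN model
#'
#' Generates a continuous genes-by-spheroids expression matrix in which
#' entry (g, i) is the sum of `cell_numbers[i]` independent per-cell draws:
#' each cell expresses gene g at `LogNormal(mu2, sigma)` with probability
#' `f`, otherwise at `LogNormal(mu1, sigma)`.  Population assignments are
#' drawn independently per cell and per gene, which matches the gene-by-gene
#' fitting of the deconvolution model.
#'
#' @param params_per_gene List of [lnln_params()] objects, one per gene
#'   (named to set gene identifiers).
#' @param cell_numbers Integer vector of cells per spheroid (all `>= 1`);
#'   names, if present, become spheroid identifiers.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list with elements `matrix` (genes x spheroids, numeric) and
#'   `truth` (class `simulation_truth`: the parameters, cell numbers, seed,
#'   and per-spheroid counts of high-population cells per gene).
#' @examples
#' p <- list(g1 = lnln_params(0, 2, 0.2, 0.5))
#' sim <- simulate_lnln_matrix(p, cell_numbers = c(s1 = 10, s2 = 20), seed = 1)
#' dim(sim$matrix)
#' @export
simulate_lnln_matrix <- function(params_per_gene, cell_numbers, seed) {
  params_per_gene <- lapply(params_per_gene, as_lnln)
  n <- as.integer(cell_numbers)
  if (length(n) < 1L || any(n < 1L))
    stop("cell_numbers must contain at least one spheroid, all >= 1",
         call. = FALSE)
  seed <- check_seed(seed)
  genes <- names(params_per_gene)
  if (is.null(genes)) genes <- sprintf("gene_%d", seq_along(params_per_gene))
  sph <- names(cell_numbers)
  if (is.null(sph)) sph <- sprintf("spheroid_%d", seq_along(n))

  g_n <- length(params_per_gene)
  mat <- matrix(0, g_n, length(n), dimnames = list(genes, sph))
  high <- matrix(0L, g_n, length(n), dimnames = list(genes, sph))
  set.seed(seed)
  idx <- rep(seq_along(n), n)          # spheroid of each simulated cell
  for (g in seq_len(g_n)) {
    p <- params_per_gene[[g]]
    hi <- stats::rbinom(length(idx), 1L, p$f) == 1L
    x <- stats::rlnorm(length(idx),
                       meanlog = ifelse(hi, p$mu2, p$mu1),
                       sdlog = p$sigma)
    mat[g, ] <- as.numeric(rowsum(x, idx))
    high[g, ] <- as.integer(rowsum(as.integer(hi), idx))
  }
  truth <- structure(
    list(params = params_per_gene, cell_numbers = stats::setNames(n, sph),
         seed = seed, high_cells = high),
    class = "simulation_truth")
  list(matrix = mat, truth = truth)
}

#' Simulate a depth-scaled count matrix
#'
#' Fixture generator for normalization: column i is a single multinomial
#' draw of size `per_cell_depth * cell_numbers[i]` over genes with fixed
#' relative rates, so column totals scale exactly with cell number.
#'
#' @param relative_gene_rates Non-negative probability vector summing to 1
#'   (names become gene identifiers).
#' @param cell_numbers Integer vector of cells per spheroid (`>= 1`).
#' @param per_cell_depth Target counts per cell (`>= 1`).
#' @param seed Integer seed.
#' @return Integer count matrix, genes x spheroids.
#' @export
simulate_depth_matrix <- function(relative_gene_rates, cell_numbers,
                                  per_cell_depth, seed) {
  r <- as.numeric(relative_gene_rates)
  if (any(r < 0)) stop("gene rates must be non-negative", call. = FALSE)
  if (abs(sum(r) - 1) > 1e-8) stop("gene rates must sum to 1", call. = FALSE)
  n <- as.integer(cell_numbers)
  stopifnot(length(n) >= 1L, all(n >= 1L))
  per_cell_depth <- as.integer(per_cell_depth)
  if (per_cell_depth < 1L) stop("per_cell_depth must be >= 1", call. = FALSE)
  seed <- check_seed(seed)
  genes <- names(relative_gene_rates)
  if (is.null(genes)) genes <- sprintf("gene_%d", seq_along(r))
  sph <- names(cell_numbers)
  if (is.null(sph)) sph <- sprintf("spheroid_%d", seq_along(n))

  set.seed(seed)
  cols <- vapply(seq_along(n),
                 function(i) stats::rmultinom(1L, per_cell_depth * n[i], r)[, 1L],
                 integer(length(r)))
  dimnames(cols) <- list(genes, sph)
  storage.mode(cols) <- "integer"
  cols
}

#' Simulate spheroid size vs nuclei-count calibration pairs
#'
#' Emulates a size-to-cell-number calibration experiment with a power-law
#' relation `count = a * area^b` and multiplicative lognormal noise:
#' `count = round(a * area^b * exp(eps))`, `eps ~ Normal(0, noise_sd)`,
#' floored at 1 nucleus.
#'
#' @param a Scale coefficient, `> 0`.
#' @param b Exponent.
#' @param noise_sd Standard deviation of the log-scale noise (`>= 0`).
#' @param areas Positive pixel areas.
#' @param seed Integer seed.
#' @return A data.frame with columns `area_px` and `nuclei_count`.
#' @examples
#' simulate_calibration_pairs(1, 1.5, 0, areas = 100, seed = 1)
#' @export
simulate_calibration_pairs <- function(a, b, noise_sd, areas, seed) {
  stopifnot(a > 0, noise_sd >= 0, all(areas > 0))
  seed <- check_seed(seed)
  set.seed(seed)
  eps <- stats::rnorm(length(areas), 0, noise_sd)
  counts <- pmax(1, round(a * areas^b * exp(eps)))
  data.frame(area_px = as.numeric(areas), nuclei_count = as.numeric(counts))
}
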