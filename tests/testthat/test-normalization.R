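test_that("qc_filter_libraries applies the three criteria in order", {
  # 3 libraries: totals (250k, 150k, 300k), detected genes (4000, 5000, 2000),
  # mito 5% everywhere -> only the first is kept
  build_lib <- function(total, detected, mito_frac, n_genes = 6000) {
    x <- integer(n_genes)
    mito_total <- round(total * mito_frac)
    body <- total - mito_total
    x[seq_len(detected - 1)] <- 1L
    x[1] <- x[1] + body - (detected - 1L)
    x[n_genes] <- mito_total                  # the single MT- gene
    x
  }
  genes <- c(sprintf("g%04d", 1:5999), "MT-ND1")
  m <- cbind(s1 = build_lib(250000, 4000, 0.05),
             s2 = build_lib(150000, 5000, 0.05),
             s3 = build_lib(300000, 2000, 0.05))
  rownames(m) <- genes
  res <- qc_filter_libraries(m, qc_thresholds())
  expect_identical(colnames(res$counts), "s1")
  expect_identical(res$removed$reason, c("reads", "genes"))

  # a library failing the reads rule reports "reads" first
  low <- cbind(s1 = build_lib(150000, 4000, 0.5))
  rownames(low) <- genes
  expect_error(qc_filter_libraries(low), "every library")

  # identity thresholds keep everything; filtering is idempotent
  all_kept <- qc_filter_libraries(m, qc_thresholds(0, 0, 1.0))
  expect_identical(all_kept$counts, m)
  twice <- qc_filter_libraries(res$counts, qc_thresholds())
  expect_identical(twice$counts, res$counts)
})

test_that("qc mito rule catches high-mitochondrial libraries", {
  m <- matrix(10L, 10, 2, dimnames = list(c(sprintf("g%d", 1:8),
                                            "MT-CO1", "MT-ND2"),
                                          c("ok", "bad")))
  m[c("MT-CO1", "MT-ND2"), "ok"] <- 2L         # 4/84 ~ 5% mito
  m["MT-CO1", "bad"] <- 500L                   # 510/590 ~ 86% mito
  res <- qc_filter_libraries(m, qc_thresholds(0, 0, 0.15))
  expect_identical(res$removed$spheroid_id, "bad")
  expect_identical(res$removed$reason, "mito")
})

test_that("fit_size_to_cells recovers noiseless and noisy relations", {
  areas <- c(50, 120, 300, 800, 2000)
  exact <- data.frame(area_px = areas, nuclei_count = 1 * areas^1.5)
  fit <- fit_size_to_cells(exact, "power")
  expect_equal(fit$a, 1, tolerance = 1e-10)
  expect_equal(fit$b, 1.5, tolerance = 1e-10)

  lin <- data.frame(area_px = areas, nuclei_count = 2 * areas)
  lfit <- fit_size_to_cells(lin, "linear")
  expect_equal(lfit$a, 2, tolerance = 1e-10)
  expect_equal(lfit$b, 0, tolerance = 1e-8)

  # noisy recovery within 10% (generator round trip)
  set.seed(2)
  noisy <- simulate_calibration_pairs(0.5, 1.5, 0.1,
                                      areas = runif(50, 100, 5000), seed = 11)
  nfit <- fit_size_to_cells(noisy, "power")
  expect_equal(nfit$a, 0.5, tolerance = 0.1)
  expect_equal(nfit$b, 1.5, tolerance = 0.1)

  expect_error(fit_size_to_cells(
    data.frame(area_px = c(10, 10, 10), nuclei_count = c(1, 2, 3))),
    "degenerate")
})

test_that("estimate_cell_numbers rounds, floors, and tracks ground truth", {
  model <- structure(list(model_form = "power", a = 1, b = 1.5,
                          fit_residual_sd = 0), class = "calibration_model")
  feats <- data.frame(spheroid_id = c("a", "b"), area_px = c(100, 0.5))
  n <- estimate_cell_numbers(feats, model)
  expect_identical(unname(n), c(1000L, 1L))    # prediction 0.35 floored to 1

  expect_error(estimate_cell_numbers(
    data.frame(spheroid_id = "x", area_px = NA), model), "missing area")

  # areas from 20 generated disks, noiseless calibration: n within 5%
  radii <- seq(21, 59, 2)
  areas <- vapply(radii, function(r) sum(make_disk(r)), 0)
  pairs <- simulate_calibration_pairs(0.05, 1.2, 0, areas = areas, seed = 1)
  m <- fit_size_to_cells(pairs, "power")
  est <- estimate_cell_numbers(
    data.frame(spheroid_id = sprintf("d%d", seq_along(areas)),
               area_px = areas), m)
  expect_true(all(abs(est - pairs$nuclei_count) / pairs$nuclei_count <= 0.05))
})

test_that("min_per_cell_count is the column-wise minimum of totals/n", {
  m <- matrix(c(4600L, 0L, 9000L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(min_per_cell_count(m, c(s1 = 2L, s2 = 3L)), 2300)
  single <- matrix(10L, 1, 1, dimnames = list("g", "s"))
  expect_equal(min_per_cell_count(single, c(s = 1L)), 10)

  # brute-force oracle on random matrices
  for (seed in 1:5) {
    cm <- make_counts(30, 8, seed = seed)
    cells <- setNames(sample(1:9, 8, replace = TRUE), colnames(cm))
    brute <- min(vapply(colnames(cm),
                        function(s) sum(cm[, s]) / cells[s], 0))
    expect_equal(min_per_cell_count(cm, cells), brute)
  }
  expect_equal(suggest_target_per_cell(2374.644), 2300L)
})

test_that("downsample_per_cell hits exact totals and preserves shares", {
  cm <- make_counts(40, 6, lambda = 800, seed = 3)
  cells <- setNames(c(2L, 3L, 1L, 4L, 2L, 3L), colnames(cm))
  ds <- downsample_per_cell(cm, cells, 2300L, seed = 1)
  expect_identical(unname(colSums(ds)), as.numeric(2300 * cells))
  expect_true(all(ds <= cm))
  # the paper's "perfect correlation" of totals and cell numbers
  expect_equal(cor(colSums(ds), cells[colnames(ds)]), 1)

  # target equal to total/n leaves the column unchanged
  tot <- colSums(cm)[1]
  ds_id <- downsample_per_cell(cm[, 1, drop = FALSE],
                               setNames(1L, colnames(cm)[1]),
                               as.integer(tot), seed = 1)
  expect_identical(ds_id[, 1], cm[, 1])

  # insufficient counts produce an error naming the spheroid
  expect_error(downsample_per_cell(cm, cells, 100000L, seed = 1),
               colnames(cm)[1])

  # gene holding ~50% of a column keeps its share in expectation
  x <- setNames(c(5000L, rep(100L, 50)), c("big", sprintf("g%02d", 1:50)))
  share <- vapply(1:100, function(s)
    downsample_library(x, 2000L, seed = s)[["big"]] / 2000, 0)
  expect_lt(abs(mean(share) - 0.5), 0.01)
})

test_that("downsampling is seed-reproducible and order-independent", {
  cm <- make_counts(25, 4, lambda = 500, seed = 8)
  cells <- setNames(c(2L, 2L, 3L, 1L), colnames(cm))
  a <- downsample_per_cell(cm, cells, 1000L, seed = 42)
  b <- downsample_per_cell(cm, cells, 1000L, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, downsample_per_cell(cm, cells, 1000L, seed = 43)))

  # permuting gene order commutes with downsampling
  perm <- sample(nrow(cm))
  c1 <- downsample_per_cell(cm[perm, ], cells, 1000L, seed = 42)
  expect_identical(c1, a[perm, ])
  # permuting spheroid order too
  c2 <- downsample_per_cell(cm[, c(3, 1, 4, 2)], cells, 1000L, seed = 42)
  expect_identical(c2, a[, c(3, 1, 4, 2)])
})

test_that("downsample_library handles forced and identity cases", {
  expect_identical(downsample_library(c(a = 100L, b = 0L), 50L, seed = 1),
                   c(a = 50L, b = 0L))
  x <- c(g1 = 7L, g2 = 3L)
  expect_identical(downsample_library(x, 10L, seed = 1), x)
  expect_error(downsample_library(x, 11L, seed = 1), "below")
})

test_that("filter_genes_for_deconvolution applies both stated rules", {
  working <- rbind(kept = c(5L, 5L, 0L), low = c(1L, 1L, 1L),
                   zero = c(0L, 0L, 0L))
  colnames(working) <- c("s1", "s2", "s3")
  original <- rbind(kept = c(4L, 4L, 2L), low = c(1L, 1L, 1L),
                    zero = c(0L, 0L, 0L))
  colnames(original) <- colnames(working)
  out <- filter_genes_for_deconvolution(original, working)
  expect_identical(rownames(out), "kept")     # mean 3.33 >= 1 and two wells >= 5
  expect_error(filter_genes_for_deconvolution(original[1:2, ], working),
               "universe")
})

test_that("replace_zeros substitutes exactly the zero entries", {
  m <- matrix(c(0, 2, 3, 0), 2, 2)
  r <- replace_zeros(m)
  expect_equal(r, matrix(c(0.1, 2, 3, 0.1), 2, 2))
  clean <- matrix(1:4, 2, 2)
  expect_equal(replace_zeros(clean), clean)
  expect_identical(sum(replace_zeros(m) == 0.1), sum(m == 0))
})
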