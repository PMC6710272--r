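test_that("lognormal_sum_params matches identities and degenerate sums", {
  expect_equal(unname(lognormal_sum_params(1, 0, 1)), c(0, 1))
  # sigma -> 0: sum of constants 1 + 3 = 4
  p <- lognormal_sum_params(c(1, 1), c(0, log(3)), 1e-9)
  expect_equal(unname(p[1]), log(4), tolerance = 1e-8)
  expect_lt(p[2], 1e-8)
  expect_error(lognormal_sum_params(0, 0, 1), "empty sum")
})

test_that("Fenton-Wilkinson approximates the 2-term sum within 3%", {
  g <- exp(seq(log(0.2), log(15), length.out = 50))
  fw <- lognormal_sum_params(2, 0, 0.5)
  mc <- mc_sum_density_oracle(g, 2, lnln_params(0, 0, 0, 0.5),
                              n_draws = 1e6, seed = 4)
  expect_lt(max(abs(dlnorm(g, fw[1], fw[2]) - mc)) / max(mc), 0.03)
})

test_that("mixture_density has exact lognormal limits and finite values", {
  # n=1, F=0: standard lognormal at its median
  p <- lnln_params(0, 5, 0, 1)
  expect_equal(mixture_density(1, 1, p), 1 / sqrt(2 * pi), tolerance = 1e-12)

  # n=1, mu1=mu2: independent of F
  y <- c(0.3, 1, 4)
  d1 <- mixture_density(y, 1, lnln_params(1, 1, 0.2, 0.5))
  d2 <- mixture_density(y, 1, lnln_params(1, 1, 0.9, 0.5))
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_equal(d1, dlnorm(y, 1, 0.5), tolerance = 1e-12)

  expect_error(mixture_density(1, 1, list(mu1 = 0, mu2 = 2, f = 2, sigma = 1)))
})

test_that("mixture_density integrates to 1 and matches the MC oracle", {
  p <- lnln_params(0, 2, 0.2, 0.5)
  for (n in c(2L, 5L, 10L)) {
    total <- integrate(function(y) mixture_density(y, n, p), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-3)
  }
  # 5% sup-norm against 2e5-draw MC at n=5 (full 1e6 draws in acceptance)
  g <- exp(seq(log(0.5), log(80), length.out = 60))
  mc <- mc_sum_density_oracle(g, 5, p, n_draws = 2e5, seed = 7)
  expect_lt(max(abs(mixture_density(g, 5, p) - mc)) / max(mc), 0.05)
})

test_that("mixture density is symmetric under label swap (oracle check)", {
  # brute-force mixture with swapped labels (mu2 plays the low role)
  brute_swapped <- function(y, n, mu1, mu2, f, sigma) {
    out <- 0
    for (h in 0:n) {                # h = number of cells in the *mu1* state
      pars <- lognormal_sum_params(c(h, n - h), c(mu1, mu2), sigma)
      out <- out + dbinom(h, n, 1 - f) * dlnorm(y, pars[1], pars[2])
    }
    out
  }
  y <- c(2, 8, 20); p <- lnln_params(0, 2, 0.3, 0.4)
  expect_equal(mixture_density(y, 3, p),
               brute_swapped(y, 3, p$mu1, p$mu2, p$f, p$sigma),
               tolerance = 1e-12)
})

test_that("loglik is additive and maximal near the truth", {
  p <- lnln_params(0, 2, 0.3, 0.4)
  y <- c(3, 10, 25); n <- c(2L, 5L, 8L)
  expect_equal(as.numeric(loglik(y[1], n[1], p)),
               mixture_density(y[1], n[1], p, log = TRUE))
  expect_equal(as.numeric(loglik(c(y, y), c(n, n), p)),
               2 * as.numeric(loglik(y, n, p)))

  # F -> 0: two-pop loglik converges to the one-pop loglik at mu1
  # (tail observations feel residual mixture mass, hence the tiny F)
  almost0 <- loglik(y, n, lnln_params(0, 2, 1e-18, 0.4))
  onepop <- loglik(y, n, onepop_params(0, 0.4))
  expect_equal(as.numeric(almost0), as.numeric(onepop), tolerance = 1e-5)
  almost1 <- loglik(y, n, lnln_params(0, 2, 1 - 1e-18, 0.4))
  onepop2 <- loglik(y, n, onepop_params(2, 0.4))
  expect_equal(as.numeric(almost1), as.numeric(onepop2), tolerance = 1e-5)

  # consistency: truth beats perturbed parameters on simulated data
  set.seed(31); nn <- sample(5:50, 1000, replace = TRUE)
  sim <- simulate_lnln_matrix(list(g = p), nn, seed = 31)
  yy <- sim$matrix[1, ]
  ll_true <- as.numeric(loglik(yy, nn, p))
  expect_gt(ll_true, as.numeric(loglik(yy, nn, lnln_params(0, 3, 0.3, 0.4))))
  expect_gt(ll_true, as.numeric(loglik(yy, nn, lnln_params(0, 1, 0.3, 0.4))))
})

test_that("fit_gene recovers parameters on single-cell data", {
  p <- lnln_params(0, 2, 0.3, 0.3)
  sim <- simulate_lnln_matrix(list(g = p), rep(1L, 2000), seed = 17)
  fit <- fit_gene(sim$matrix[1, ], rep(1L, 2000), "two_pop",
                  n_starts = 8, seed = 5)
  expect_lt(abs(fit$params$mu1 - 0), 0.1)
  expect_lt(abs(fit$params$mu2 - 2), 0.1)
  expect_lt(abs(fit$params$f - 0.3), 0.05)
  expect_lt(abs(fit$params$sigma - 0.3), 0.05)
  expect_gte(fit$n_starts_converged, 1L)
  expect_lte(fit$params$mu1, fit$params$mu2)   # relabeling contract
})

test_that("fit_gene recovers the one-population model under mixed n", {
  set.seed(6); n <- sample(5:50, 300, replace = TRUE)
  sim <- simulate_lnln_matrix(list(g = lnln_params(1, 1, 0, 0.5)), n,
                              seed = 19)
  fit <- fit_gene(sim$matrix[1, ], n, "one_pop", seed = 2)
  expect_lt(abs(fit$params$mu - 1), 0.1)
  expect_lt(abs(fit$params$sigma - 0.5), 0.1)
})

test_that("fit_gene rejects degenerate inputs", {
  expect_error(fit_gene(rep(3, 50), rep(1L, 50), "two_pop", seed = 1),
               "degenerate")
  expect_error(fit_gene(c(1, 2, 3), c(1L, 1L, 1L), "two_pop", seed = 1),
               "at least 5")
})

test_that("select_model follows the BIC arithmetic", {
  mk <- function(ll, model) structure(
    list(params = if (model == "one_pop") onepop_params(0, 1)
         else lnln_params(0, 1, 0.5, 1),
         loglik = ll, n_starts_converged = 10L, model = model),
    class = "gene_fit_model")
  # equal likelihoods: the lighter penalty wins
  eq <- select_model(mk(-500, "one_pop"), mk(-500, "two_pop"), 100)
  expect_identical(eq$selected, "one_pop")
  expect_equal(eq$delta_bic, -2 * log(100))
  # dominant two-population likelihood
  dom <- select_model(mk(-600, "one_pop"), mk(-500, "two_pop"), 100)
  expect_identical(dom$selected, "two_pop")
  expect_equal(dom$bic_one, 2 * 600 + 2 * log(100))
  expect_equal(dom$bic_two, 2 * 500 + 4 * log(100))
})

test_that("deconvolve_matrix separates planted one- and two-pop genes", {
  set.seed(13); n <- setNames(sample(1:10, 150, replace = TRUE),
                              sprintf("s%03d", 1:150))
  params <- c(
    lapply(1:5, function(i) lnln_params(1, 1, 0, 0.5)),
    lapply(1:5, function(i) lnln_params(0, 2, 0.2, 0.5)))
  names(params) <- c(sprintf("one%02d", 1:5), sprintf("two%02d", 1:5))
  sim <- simulate_lnln_matrix(params, n, seed = 29)
  res <- deconvolve_matrix(sim$matrix, n, n_starts = 6, seed = 3)
  planted <- names(params)[6:10]
  correct <- sum(res$fits$selected[match(planted, res$fits$gene_id)] == "two_pop") +
    sum(res$fits$selected[match(names(params)[1:5], res$fits$gene_id)] == "one_pop")
  expect_gte(correct, 9L)
  expect_s3_class(res$fits, "data.frame")
  expect_identical(nrow(res$fits), 10L)

  # determinism: identical reruns, regardless of gene order
  res2 <- deconvolve_matrix(sim$matrix[sample(10), ], n, n_starts = 6,
                            seed = 3)
  reord <- res2$fits[match(res$fits$gene_id, res2$fits$gene_id), ]
  rownames(reord) <- NULL; rownames(res$fits) <- NULL
  expect_equal(res$fits, reord, tolerance = 1e-12)

  # empty input warns and returns empty tables
  empty <- matrix(numeric(0), 0, 150,
                  dimnames = list(character(0), names(n)))
  expect_warning(e <- deconvolve_matrix(empty, n), "empty")
  expect_identical(nrow(e$fits), 0L)
})

test_that("mc_sum_density_oracle is itself a density", {
  p <- lnln_params(0, 2, 0.2, 0.5)
  g <- exp(seq(log(0.05), log(150), length.out = 400))
  d <- mc_sum_density_oracle(g, 1, p, n_draws = 2e5, seed = 12)
  # integrates to ~1 over a wide grid (trapezoid)
  area <- sum(diff(g) * (head(d, -1) + tail(d, -1)) / 2)
  expect_equal(area, 1, tolerance = 0.02)
  # n=1 converges to the exact mixture pdf
  exact <- 0.8 * dlnorm(g, 0, 0.5) + 0.2 * dlnorm(g, 2, 0.5)
  expect_lt(max(abs(d - exact)) / max(exact), 0.05)
})
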