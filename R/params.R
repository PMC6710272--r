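#' Two-population lognormal (LN-LN) parameter set
#'
#' Container for the four parameters of the two-population single-cell
#' expression model: each cell expresses at a low level
#' \eqn{LogNormal(\mu_1, \sigma)} or, with probability \eqn{F}, at a high
#' level \eqn{LogNormal(\mu_2, \sigma)}.  The two populations share a common
#' log-standard deviation \eqn{\sigma}; for lognormals this is equivalent to
#' sharing a common coefficient of variation.
#'
#' @param mu1 Log-mean of the low population (log expression units).
#' @param mu2 Log-mean of the high population; must satisfy `mu1 <= mu2`.
#' @param f Proportion of cells in the high population, in `[0, 1]`.
#' @param sigma Common log-standard deviation, `> 0`.
#' @return An object of class `lnln_params`.
#' @examples
#' lnln_params(mu1 = 0, mu2 = 2, f = 0.2, sigma = 0.5)
#' @export
lnln_params <- function(mu1, mu2, f, sigma) {
  stopifnot(is.numeric(mu1), length(mu1) == 1L, is.finite(mu1),
            is.numeric(mu2), length(mu2) == 1L, is.finite(mu2),
            is.numeric(f), length(f) == 1L, is.finite(f),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (mu1 > mu2)
    stop("invalid LN-LN parameters: mu1 must not exceed mu2", call. = FALSE)
  if (f < 0 || f > 1)
    stop("invalid LN-LN parameters: f must lie in [0, 1]", call. = FALSE)
  if (sigma <= 0)
    stop("invalid LN-LN parameters: sigma must be > 0", call. = FALSE)
  structure(list(mu1 = mu1, mu2 = mu2, f = f, sigma = sigma),
            class = "lnln_params")
}

#' One-population lognormal parameter set
#'
#' Null model against which the two-population LN-LN fit is compared:
#' every cell expresses at \eqn{LogNormal(\mu, \sigma)}.
#'
#' @param mu Log-mean.
#' @param sigma Log-standard deviation, `> 0`.
#' @return An object of class `onepop_params`.
#' @export
onepop_params <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0)
    stop("invalid one-population parameters: sigma must be > 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma), class = "onepop_params")
}

#' @export
print.lnln_params <- function(x, ...) {
  cat(sprintf("LN-LN parameters: mu1 = %.4g, mu2 = %.4g, F = %.4g, sigma = %.4g\n",
              x$mu1, x$mu2, x$f, x$sigma))
  invisible(x)
}

#' @export
print.onepop_params <- function(x, ...) {
  cat(sprintf("One-population parameters: mu = %.4g, sigma = %.4g\n",
              x$mu, x$sigma))
  invisible(x)
}

# internal: accept lnln_params or a list-alike with the right names
as_lnln <- function(params) {
  if (inherits(params, "lnln_params")) return(params)
  lnln_params(params$mu1, params$mu2,
              if (!is.null(params$f)) params$f else params$F,
              params$sigma)
}

check_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer(seed)
}

# deterministic sub-seed from an integer seed and a string id; stays < 2^31
derive_seed <- function(seed, id) {
  h <- 0
  for (v in utf8ToInt(as.character(id))) h <- (h * 31 + v) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 + h) %% 2147483563) + 1L
}
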