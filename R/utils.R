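#' Beta-binomial log density
#'
#' Log probability mass of the beta-binomial distribution, the allele-count
#' emission model used throughout the package. A draw of size \code{d} with
#' success probability integrated over Beta(\code{alpha}, \code{beta}).
#' Observations with \code{d == 0} carry no information and have log mass 0.
#'
#' @param y numeric vector of successes, \code{0 <= y <= d}.
#' @param d numeric vector of trials.
#' @param alpha,beta positive shape parameters.
#' @param log if \code{FALSE}, return the probability instead of its log.
#' @return numeric vector of log probabilities (recycled to common length).
#' @export
dbetabinom <- function(y, d, alpha, beta, log = TRUE) {
  n <- max(length(y), length(d), length(alpha), length(beta))
  y <- rep_len(y, n); d <- rep_len(d, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  ll <- lchoose(d, y) + lbeta(y + alpha, d - y + beta) - lbeta(alpha, beta)
  ll[d == 0] <- 0
  bad <- y < 0 | y > d
  ll[bad] <- -Inf
  if (log) ll else exp(ll)
}

#' Beta-binomial random deviates
#'
#' @param n number of draws.
#' @param d trials (recycled).
#' @param alpha,beta shape parameters (recycled).
#' @return integer vector of length \code{n}.
#' @export
rbetabinom <- function(n, d, alpha, beta) {
  p <- stats::rbeta(n, rep_len(alpha, n), rep_len(beta, n))
  stats::rbinom(n, rep_len(d, n), p)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

# negative binomial log density in (mu, dispersion phi) parametrization:
# Var = mu + phi * mu^2. phi -> 0 recovers Poisson.
dnbinom_mu_phi <- function(x, mu, phi) {
  if (phi <= 1e-8) return(stats::dpois(x, lambda = mu, log = TRUE))
  stats::dnbinom(x, size = 1 / phi, mu = mu, log = TRUE)
}

rnbinom_mu_phi <- function(n, mu, phi) {
  if (phi <= 1e-8) return(stats::rpois(n, lambda = mu))
  stats::rnbinom(n, size = 1 / phi, mu = rep_len(mu, n))
}

# deterministic k-nearest-neighbour indices from a coordinate matrix.
# Ties broken by index order. Returns an n x k matrix of neighbour indices.
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  if (k < 1L) return(matrix(integer(0), nrow = n, ncol = 0L))
  dm <- as.matrix(stats::dist(coords))
  diag(dm) <- Inf
  t(apply(dm, 1L, function(row) order(row)[seq_len(k)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
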