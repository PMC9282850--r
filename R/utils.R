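#' @keywords internal
"_PACKAGE"

# Internal numeric helpers shared across modules.

#' Draw from a truncated normal distribution by inverse-CDF
#'
#' Exact sampling via quantile transformation; used for all bounded
#' generator draws (distances, angles, merge times).
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Mean of a truncated normal with the given parent parameters.
truncnorm_mean <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter such that the [lower, upper]-truncated normal with scale
# `sd` has mean `target`. Solved once at config-construction time.
truncnorm_location_for_mean <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  stopifnot(target > lower, target < upper)
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  stats::uniroot(f, lower = target - 6 * sd, upper = target + 6 * sd,
                 tol = 1e-10)$root
}

# Uniform random 3x3 rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Row-wise euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Child seed derivation: documented stream order for reproducible,
# per-oocyte-independent simulation. Kept below 2^31 - 1.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
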