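#' The skew-normal distribution
#'
#' Density, distribution function and random generation for the skew-normal
#' distribution with location `xi`, scale `omega` and shape `alpha`. The
#' skew-normal generalises the normal distribution with one extra shape
#' parameter controlling skewness; its population skewness is bounded by
#' approximately +/- 0.9953, and `alpha = 0` recovers the normal
#' distribution exactly.
#'
#' The distribution function is evaluated as
#' `pnorm(z) - 2 * T(z, alpha)` with `z = (x - xi) / omega`, where `T` is
#' Owen's T function, computed here by adaptive quadrature of its defining
#' integral (with the standard reduction to arguments `|a| <= 1` for
#' accuracy at extreme shapes).
#'
#' @param x vector of quantiles.
#' @param n number of draws.
#' @param xi location parameter (outcome units).
#' @param omega scale parameter, `> 0` (outcome units).
#' @param alpha shape parameter (dimensionless).
#' @return `dsn` and `psn` return numeric vectors; `rsn` returns `n` draws.
#' @examples
#' psn(0, xi = 0, omega = 1, alpha = 0) # 0.5, the normal limit
#' @export
dsn <- function(x, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

#' @rdname dsn
#' @export
psn <- function(x, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  stats::pnorm(z) - 2 * owen_t(z, alpha)
}

#' @rdname dsn
#' @export
rsn <- function(n, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

#' Owen's T function
#'
#' Computes `T(h, a) = (2 * pi)^-1 * integral_0^a exp(-h^2 (1 + t^2) / 2) /
#' (1 + t^2) dt`, the bivariate-normal rectangle probability kernel needed
#' for the skew-normal distribution function. Arguments with `|a| > 1` are
#' reduced through the identity
#' `T(h, a) = (Phi(h) + Phi(ah)) / 2 - Phi(h) Phi(ah) - T(ah, 1/a)` so the
#' quadrature range never exceeds one.
#'
#' @param h numeric vector.
#' @param a numeric scalar.
#' @return numeric vector of the same length as `h`.
#' @export
owen_t <- function(h, a) {
  stopifnot(length(a) == 1L, is.finite(a))
  vapply(h, owen_t1, numeric(1), a = a)
}

owen_t1 <- function(h, a) {
  if (a == 0 || is.na(h)) {
    return(if (is.na(h)) NA_real_ else 0)
  }
  if (a < 0) {
    return(-owen_t1(h, -a))
  }
  h <- abs(h) # T(h, a) is even in h
  if (a > 1) {
    ph <- stats::pnorm(h)
    pah <- stats::pnorm(a * h)
    return((ph + pah) / 2 - ph * pah - owen_t1(a * h, 1 / a))
  }
  f <- function(t) exp(-0.5 * h^2 * (1 + t^2)) / (1 + t^2)
  stats::integrate(f, 0, a, rel.tol = 1e-12, abs.tol = 1e-14)$value / (2 * pi)
}

# Maximum |skewness| accepted by the moment fit; the supremum attainable by
# the skew-normal family is (4 - pi)/2 * (2/pi)^(3/2) / (1 - 2/pi)^(3/2),
# about 0.9953, so fits are clamped just inside it.
SN_SKEW_MAX <- 0.99

#' Fit a skew-normal distribution by the method of moments
#'
#' Maps a sample mean, standard deviation and moment skewness coefficient to
#' skew-normal parameters `(xi, omega, alpha)` whose population mean, SD and
#' skewness reproduce them. Because the skew-normal family's skewness is
#' bounded by about +/- 0.9953, input skewness is clamped to +/- 0.99;
#' when clamping occurs the returned object carries `clamped = TRUE`.
#'
#' @param mean sample mean (outcome units).
#' @param sd sample standard deviation, `> 0` (outcome units).
#' @param skewness moment coefficient of skewness `m3 / m2^(3/2)`.
#' @return an object of class `sn_params`: a list with elements `xi`,
#'   `omega`, `alpha`, `skewness` (the value actually fitted, after any
#'   clamping) and `clamped`.
#' @examples
#' sn_from_moments(0, 1, 0.5)
#' @export
sn_from_moments <- function(mean, sd, skewness) {
  if (!is.finite(sd) || sd <= 0) {
    stop("skew-normal fit requires a positive standard deviation", call. = FALSE)
  }
  clamped <- FALSE
  if (abs(skewness) > SN_SKEW_MAX) {
    skewness <- sign(skewness) * SN_SKEW_MAX
    clamped <- TRUE
  }
  if (skewness == 0) {
    out <- list(xi = mean, omega = sd, alpha = 0, skewness = 0, clamped = clamped)
    class(out) <- "sn_params"
    return(out)
  }
  # gamma1 = (4 - pi)/2 * u^3 / (1 - u^2)^(3/2) with u = delta * sqrt(2/pi)
  cc <- sign(skewness) * (2 * abs(skewness) / (4 - pi))^(1 / 3)
  u <- cc / sqrt(1 + cc^2)
  delta <- u * sqrt(pi / 2)
  alpha <- delta / sqrt(1 - delta^2)
  omega <- sd / sqrt(1 - u^2)
  xi <- mean - omega * u
  out <- list(xi = xi, omega = omega, alpha = alpha,
              skewness = skewness, clamped = clamped)
  class(out) <- "sn_params"
  out
}

#' Population moments implied by skew-normal parameters
#'
#' Inverse of [sn_from_moments()]: the mean, SD and skewness of the
#' distribution with the given parameters.
#'
#' @param params an `sn_params` object or a list with `xi`, `omega`, `alpha`.
#' @return named numeric vector `c(mean, sd, skewness)`.
#' @export
sn_moments <- function(params) {
  delta <- params$alpha / sqrt(1 + params$alpha^2)
  u <- delta * sqrt(2 / pi)
  m <- params$xi + params$omega * u
  s <- params$omega * sqrt(1 - u^2)
  g1 <- (4 - pi) / 2 * u^3 / (1 - u^2)^(3 / 2)
  c(mean = m, sd = s, skewness = g1)
}

#' @export
print.sn_params <- function(x, ...) {
  cat(sprintf("skew-normal parameters: xi = %.4g, omega = %.4g, alpha = %.4g\n",
              x$xi, x$omega, x$alpha))
  if (isTRUE(x$clamped)) {
    cat(sprintf("  (input skewness clamped to %.2f)\n", x$skewness))
  }
  invisible(x)
}
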