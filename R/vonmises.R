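## von Mises distribution: ML fit and sampling.
## Written in-package: concentration solved from the Bessel-ratio equation
## A1(kappa) = Rbar, sampling by the Best-Fisher (1979) wrapped-Cauchy
## rejection envelope.

## I1(k)/I0(k), stable for large k via exponentially scaled Bessel functions
.besselRatio <- function(kappa)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)

## wrap any angle into (-pi, pi]
wrapAngle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

#' Maximum-likelihood von Mises fit
#'
#' Mean direction is the argument of the resultant vector; concentration
#' solves `I1(kappa)/I0(kappa) = Rbar`. Near-degenerate samples (all angles
#' essentially equal) hit `kappaCap` and are flagged.
#'
#' @param theta angles in radians.
#' @param kappaCap upper bound on the fitted concentration.
#' @return list with `mu`, `kappa`, `degenerate`.
#' @export
fitVonMises <- function(theta, kappaCap = 500) {
  theta <- theta[is.finite(theta)]
  if (length(theta) < 2L) stop("need at least 2 angles")
  C <- mean(cos(theta)); S <- mean(sin(theta))
  rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  if (rbar < 1e-12) return(list(mu = mu, kappa = 0, degenerate = FALSE))
  if (.besselRatio(kappaCap) <= rbar)
    return(list(mu = mu, kappa = kappaCap, degenerate = TRUE))
  kappa <- stats::uniroot(function(k) .besselRatio(k) - rbar,
                          lower = 1e-10, upper = kappaCap,
                          tol = 1e-10)$root
  list(mu = mu, kappa = kappa, degenerate = FALSE)
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler; uniform on `(-pi, pi]` when `kappa = 0`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa < 1e-10) return(wrapAngle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + k)] <- th
      got <- got + k
    }
  }
  wrapAngle(out + mu)
}

#' @rdname rvonmises
#' @param theta angles at which to evaluate the density.
#' @return `dvonmises` returns the density.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1)
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
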