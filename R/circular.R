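# Circular statistics: resultant vectors, von Mises sampling,
# Watson-Williams test, circular correlation coefficients.
# Angles are radians internally; user-facing spike-phase output is degrees.

#' Mean resultant length and mean angle
#' @param phi angles in radians.
#' @return `circ_resultant`: list with `r` (MRL in `[0,1]`) and `mu` (radians).
#' @export
circ_resultant <- function(phi) {
  z <- mean(exp(1i * phi))
  list(r = Mod(z), mu = Arg(z))
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# wrap to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' von Mises random angles (Best-Fisher rejection sampler)
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration >= 0 (0 = uniform).
#' @return angles in radians, wrapped to (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 1e6) return(rep(wrap_pi(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_pi(sign(u[3] - 0.5) * acos(f) + mu)
      i <- i + 1L
    }
  }
  out
}

# A1 inverse: kappa from mean resultant length (Fisher 1993 approximations)
kappa_from_r <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams two-sample test for equal circular means
#'
#' High-concentration F approximation with the standard correction factor
#' `1 + 3/(8*kappa_hat)`. Warns when the pooled concentration is low
#' (the approximation assumes reasonably concentrated samples).
#'
#' @param a,b angle samples in radians.
#' @return list with `F`, `p`, `df`, and the pooled concentration estimate.
#' @export
watson_williams <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("need at least 2 angles per group")
  r1 <- n1 * circ_resultant(a)$r
  r2 <- n2 * circ_resultant(b)$r
  rr <- n * circ_resultant(c(a, b))$r
  rw <- (r1 + r2) / n
  if (rw > 1 - 1e-12) {
    # both groups fully concentrated
    same <- abs(wrap_pi(circ_resultant(a)$mu - circ_resultant(b)$mu)) < 1e-10
    return(list(F = if (same) 0 else Inf, p = if (same) 1 else 0,
                df = c(1, n - 2), kappa = Inf))
  }
  if (rw < 0.45)
    warning("low concentration (rw < 0.45): Watson-Williams approximation unreliable")
  kap <- kappa_from_r(rw)
  K <- 1 + 3 / (8 * kap)
  Fstat <- K * (n - 2) * (r1 + r2 - rr) / (n - (r1 + r2))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(F = Fstat, p = p, df = c(1, n - 2), kappa = kap)
}

#' Circular-circular correlation (Jammalamadaka-SenGupta)
#' @param a,b paired angle samples, radians.
#' @return list with `rho` and asymptotic `p`.
#' @export
circ_circ_cor <- function(a, b) {
  n <- length(a)
  if (n != length(b) || n < 3) stop("need paired samples, n >= 3")
  sa <- sin(a - circ_resultant(a)$mu)
  sb <- sin(b - circ_resultant(b)$mu)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- sum(sa * sb) / den
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  if (l22 > 0) {
    ts <- sqrt(n * l20 * l02 / l22) * rho
    p <- 2 * stats::pnorm(abs(ts), lower.tail = FALSE)
  } else p <- NA_real_
  list(rho = rho, p = p)
}

#' Circular-linear correlation (Mardia)
#' @param theta angles in radians.
#' @param x linear values.
#' @return list with `rho` (in `[0,1]`) and chi-square `p`.
#' @export
circ_lin_cor <- function(theta, x) {
  n <- length(x)
  if (n != length(theta) || n < 4) stop("need paired samples, n >= 4")
  rxc <- stats::cor(x, cos(theta))
  rxs <- stats::cor(x, sin(theta))
  rcs <- stats::cor(cos(theta), sin(theta))
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  r2 <- min(max(r2, 0), 1)
  p <- stats::pchisq(n * r2, df = 2, lower.tail = FALSE)
  list(rho = sqrt(r2), p = p)
}
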