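# von Mises primitives used by the diel-activity estimators.
# Densities use exponentially scaled Bessel functions so large
# concentrations do not overflow.

#' von Mises density
#'
#' @param theta angles in radians.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0); 0 gives the circular uniform density.
#' @return Density values.
#' @export
dvonmises <- function(theta, mu, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa == 0) return(rep(1 / (2 * pi), length(theta)))
  # exp(k cos d)/(2 pi I0(k)) = exp(k (cos d - 1)) / (2 pi I0(k) e^-k)
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw from a von Mises distribution
#'
#' Best–Fisher (1979) wrapped-Cauchy rejection sampler; reduces to uniform
#' draws on the circle when \code{kappa = 0}.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return Angles in \code{[0, 2*pi)}.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

# Mean resultant length of a circular sample.
resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

# A1(kappa) = I1(kappa)/I0(kappa); scaled ratio is overflow-safe.
A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises concentration
#'
#' Solves \code{A1(kappa) = Rbar}, the ML score equation for the
#' concentration of a von Mises sample, where \code{Rbar} is the mean
#' resultant length; the root is found by bisection after bracketing with
#' Fisher's series approximation.  The result, multiplied by \code{adjust},
#' is the kernel bandwidth used by \code{\link{kde_density}}: larger
#' \code{kappa} means a more concentrated (less smoothed) kernel.
#'
#' @param times angles in radians (n >= 2).
#' @param adjust bandwidth multiplier applied to the ML estimate (default 1).
#' @param kappa_max cap for near-degenerate samples; when all points
#'   coincide the ML estimate diverges and is capped here with a warning.
#' @return The (adjusted) concentration estimate; 0 for samples with zero
#'   resultant length (e.g. two antipodal points).
#' @export
fit_vonmises_kappa <- function(times, adjust = 1, kappa_max = 500) {
  if (length(times) < 2L) stop("need at least two observations")
  rbar <- resultant_length(times)
  if (rbar < 1e-12) return(0)
  if (A1(kappa_max) <= rbar) {
    warning("sample nearly degenerate; kappa capped at ", kappa_max)
    return(kappa_max * adjust)
  }
  # Fisher (1993) starting value
  k0 <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
        else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
        else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  lo <- max(k0 / 10, 1e-10); hi <- min(max(k0 * 10, 1), kappa_max)
  while (A1(lo) > rbar) lo <- lo / 10
  while (A1(hi) < rbar) hi <- min(hi * 2, kappa_max)
  k <- stats::uniroot(function(k) A1(k) - rbar, c(lo, hi),
                      tol = 1e-10)$root
  k * adjust
}

#' Plug-in kernel concentration for circular KDE
#'
#' Taylor's (2008) circular plug-in rule, the standard bandwidth choice in
#' diel-activity kernel estimation: from the ML concentration
#' \eqn{\hat\kappa} of the sample, the kernel concentration is
#' \deqn{\kappa^* = \left[\frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}
#'   {4\sqrt{\pi} I_0(\hat\kappa)^2}\right]^{2/5},}
#' which sharpens with sample size so the estimated density is consistent
#' (a fixed ML concentration is not: it over-smooths multimodal activity
#' at every n).  \code{adjust} multiplies the result.
#'
#' @param times angles in radians (n >= 2).
#' @param adjust bandwidth multiplier (default 1).
#' @param kappa_max cap passed to \code{\link{fit_vonmises_kappa}}.
#' @return Kernel concentration (0 for samples with zero resultant
#'   length).
#' @export
kernel_bandwidth <- function(times, adjust = 1, kappa_max = 500) {
  n <- length(times)
  khat <- fit_vonmises_kappa(times, adjust = 1, kappa_max = kappa_max)
  if (khat == 0) return(0)
  # scaled Bessel ratio: the e^{2k} factors cancel exactly
  ratio <- besselI(2 * khat, 2, expon.scaled = TRUE) /
    besselI(khat, 0, expon.scaled = TRUE)^2
  kstar <- (3 * n * khat^2 * ratio / (4 * sqrt(pi)))^(2 / 5)
  kstar * adjust
}

#' Convert clock times to circular angles
#'
#' Maps time of day to radians on \code{[0, 2*pi)}: midnight is 0, noon is
#' pi.  Accepts decimal hours or \code{POSIXct} timestamps (whose date part
#' is dropped).
#'
#' @param t decimal hours in \code{[0, 24)} or \code{POSIXct}.
#' @return Angles in radians.
#' @export
time_to_angle <- function(t) {
  if (inherits(t, "POSIXct")) {
    lt <- as.POSIXlt(t)
    t <- lt$hour + lt$min / 60 + lt$sec / 3600
  }
  (t %% 24) * 2 * pi / 24
}
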