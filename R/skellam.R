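# Floor applied to Poisson means everywhere: the Skellam pmf requires
# theta > 0, and the floor keeps the near-degenerate Poisson limit usable.
.THETA_FLOOR <- 1e-6

#' Log modified Bessel function of the first kind, integer order
#'
#' Evaluates log I_nu(x) for nu >= 0 and x > 0 without overflow or
#' underflow.  Three regimes are stitched together:
#' exponentially scaled [besselI()] where it is reliable, a log-space
#' ascending series when the scaled value underflows (nu >> x), and the
#' uniform large-order asymptotic expansion for orders beyond the range
#' base R handles.
#'
#' @param x positive real, vectorised.
#' @param nu non-negative order, vectorised (recycled against `x`).
#' @return `log(besselI(x, nu))`, finite for x > 0.
#' @keywords internal
log_besselI <- function(x, nu) {
  n <- max(length(x), length(nu))
  x <- rep_len(x, n)
  nu <- rep_len(nu, n)
  out <- numeric(n)

  big_nu <- nu >= 150
  big_x <- !big_nu & x > 5e4
  std <- !big_nu & !big_x

  if (any(std)) {
    b <- suppressWarnings(besselI(x[std], nu[std], expon.scaled = TRUE))
    ok <- is.finite(b) & b > 0
    idx <- which(std)
    out[idx[ok]] <- log(b[ok]) + x[std][ok]
    if (any(!ok)) { # underflow of the scaled value: nu >> x, series converges fast
      for (i in idx[!ok]) out[i] <- .log_besselI_series(x[i], nu[i])
    }
  }
  if (any(big_x)) {
    ib <- which(big_x)
    out[ib] <- .log_besselI_hankel(x[ib], nu[ib])
  }
  if (any(big_nu)) {
    ibn <- which(big_nu)
    out[ibn] <- .log_besselI_uniform(x[ibn], nu[ibn])
  }
  out
}

# Ascending series sum_k (x/2)^(2k+nu) / (k! Gamma(k+nu+1)), leading term
# taken in log space.  Used only where the scaled besselI underflows,
# i.e. x appreciably smaller than nu, where few terms are needed.
.log_besselI_series <- function(x, nu) {
  lt0 <- nu * log(x / 2) - lgamma(nu + 1)
  q <- x * x / 4
  s <- 1; r <- 1; k <- 0
  repeat {
    k <- k + 1
    r <- r * q / (k * (k + nu))
    s <- s + r
    if (r < s * 1e-17 || k > 20000L) break
  }
  lt0 + log(s)
}

# Hankel large-argument expansion, valid for x >> nu^2; reached only for
# x > 5e4 with nu < 150 where the asymptotic terms decay factorially.
.log_besselI_hankel <- function(x, nu) {
  mu <- 4 * nu * nu
  s <- rep(1, length(x)); term <- rep(1, length(x))
  for (k in 1:10) {
    term <- -term * (mu - (2 * k - 1)^2) / (k * 8 * x)
    s <- s + term
  }
  x - 0.5 * log(2 * pi * x) + log(s)
}

# Uniform large-order expansion (Debye), accurate to well below 1e-10
# relative for nu >= 150 at any x > 0.
.log_besselI_uniform <- function(x, nu) {
  w <- x / nu
  s <- sqrt(1 + w * w)
  eta <- s + log(w) - log1p(s)
  t <- 1 / s
  t2 <- t * t
  u1 <- (3 * t - 5 * t^3) / 24
  u2 <- (81 * t2 - 462 * t2^2 + 385 * t2^3) / 1152
  u3 <- (30375 * t^3 - 369603 * t^5 + 765765 * t^7 - 425425 * t^9) / 414720
  u4 <- (4465125 * t2^2 - 94121676 * t2^3 + 349922430 * t2^4 -
           446185740 * t2^5 + 185910725 * t2^6) / 39813120
  corr <- 1 + u1 / nu + u2 / nu^2 + u3 / nu^3 + u4 / nu^4
  -0.5 * log(2 * pi * nu) - 0.25 * log1p(w * w) + nu * eta + log(corr)
}

.check_theta <- function(theta1, theta2) {
  if (any(!is.finite(theta1)) || any(!is.finite(theta2)) ||
      any(theta1 <= 0) || any(theta2 <= 0)) {
    stop("Poisson means theta1, theta2 must be finite and > 0", call. = FALSE)
  }
}

.check_z <- function(z) {
  if (any(!is.finite(z)) || any(z != round(z))) {
    stop("count differences z must be finite integers", call. = FALSE)
  }
}

#' Skellam probability mass function
#'
#' Density of Z = X - Y where X ~ Poisson(theta1) and Y ~ Poisson(theta2)
#' independently:
#' f(z) = exp(-(theta1 + theta2)) (theta1/theta2)^(z/2) I_|z|(2 sqrt(theta1 theta2)).
#' Evaluated in log space so that it remains finite for |z| and theta up to
#' at least 1e6.
#'
#' @param z integer count difference(s), any sign.
#' @param theta1,theta2 positive Poisson means for the two treatments.
#' @param log if `TRUE`, return the natural-log probability.
#' @return vector of (log-)probabilities.
#' @examples
#' dskellam(0, 1, 1)                 # ~ 0.3085083
#' sum(dskellam(-200:200, 5, 3))     # ~ 1
#' @export
dskellam <- function(z, theta1, theta2, log = FALSE) {
  .check_z(z)
  .check_theta(theta1, theta2)
  theta1 <- pmax(theta1, .THETA_FLOOR)
  theta2 <- pmax(theta2, .THETA_FLOOR)
  lp <- -(theta1 + theta2) + (z / 2) * (base::log(theta1) - base::log(theta2)) +
    log_besselI(2 * sqrt(theta1 * theta2), abs(z))
  if (log) lp else exp(lp)
}

#' Skellam pmf by truncated Poisson convolution (verification oracle)
#'
#' Direct summation f(z) = sum_{x >= max(0,z)} dpois(x; theta1) *
#' dpois(x - z; theta2), truncated at mean + 12 sd + 50 terms, where the
#' Poisson tail is negligible at double precision.  Independent of the
#' Bessel-function route in [dskellam()]; intended for cross-validation at
#' moderate parameter values.
#'
#' @param z integer count difference (scalar or vector).
#' @param theta1,theta2 positive Poisson means, each at most 1e4.
#' @return probability vector.
#' @export
dskellam_conv <- function(z, theta1, theta2) {
  .check_z(z)
  .check_theta(theta1, theta2)
  if (theta1 > 1e4 || theta2 > 1e4) {
    stop("convolution oracle supports theta <= 1e4 only", call. = FALSE)
  }
  vapply(z, function(zz) {
    x_lo <- max(0, zz)
    x_hi <- ceiling(max(theta1, theta1 + zz) + 12 * sqrt(theta1) + 50)
    x <- x_lo:x_hi
    sum(stats::dpois(x, theta1) * stats::dpois(x - zz, theta2))
  }, numeric(1))
}

#' Conditional means of the latent Poisson pair given their difference
#'
#' For X ~ Poisson(theta1), Y ~ Poisson(theta2) independent and Z = X - Y,
#' returns E[X | Z = z] and E[Y | Z = z].  Uses the Bessel-ratio identity
#' E[X | Z = z] = theta1 f(z - 1) / f(z), with E[Y | Z = z] =
#' E[X | Z = z] - z following from the deterministic relation X - Y = z.
#'
#' @param z integer count difference(s).
#' @param theta1,theta2 positive Poisson means.
#' @return list with components `ex` and `ey`, vectors aligned with `z`.
#' @examples
#' m <- skellam_cond_mean(0, 1, 1)   # ex = ey = I_1(2)/I_0(2) ~ 0.69777
#' @export
skellam_cond_mean <- function(z, theta1, theta2) {
  .check_z(z)
  .check_theta(theta1, theta2)
  theta1 <- pmax(theta1, .THETA_FLOOR)
  theta2 <- pmax(theta2, .THETA_FLOOR)
  lf <- dskellam(z, theta1, theta2, log = TRUE)
  lfm <- dskellam(z - 1, theta1, theta2, log = TRUE)
  ex <- theta1 * exp(lfm - lf)
  if (any(!is.finite(ex))) {
    stop("non-finite conditional mean; parameters out of supported range",
         call. = FALSE)
  }
  list(ex = ex, ey = ex - z)
}
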