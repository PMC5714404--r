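#' The inverse-Gaussian distribution in mean / standard-deviation form
#'
#' Density, distribution function and random generation for the inverse
#' Gaussian (Wald) distribution, parameterized by its mean \code{mean} and
#' standard deviation \code{sd}. This is the first-passage-time law of a
#' Brownian motion with positive drift to a fixed barrier, and the dominance
#' time distribution used throughout the package. The classical shape
#' parameter is \code{lambda = mean^3 / sd^2}.
#'
#' @param x,q vector of quantiles (times, in seconds; must be positive where
#'   a density is requested).
#' @param n number of draws.
#' @param mean mean of the distribution (> 0).
#' @param sd standard deviation of the distribution (> 0).
#' @param log,log.p logical; if TRUE, probabilities/densities are returned on
#'   the log scale.
#' @param lower.tail logical; if TRUE (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @return \code{dinvgauss} gives the density, \code{pinvgauss} the
#'   distribution function, \code{rinvgauss} random deviates.
#' @examples
#' x <- rinvgauss(500, mean = 10.5, sd = 8.18)
#' mean(x)
#' @export
dinvgauss <- function(x, mean, sd, log = FALSE) {
  check_ig_params(mean, sd)
  lambda <- mean^3 / sd^2
  logf <- ifelse(x > 0,
    0.5 * (log(lambda) - log(2 * pi) - 3 * log(pmax(x, .Machine$double.xmin))) -
      lambda * (x - mean)^2 / (2 * mean^2 * pmax(x, .Machine$double.xmin)),
    -Inf)
  if (log) logf else exp(logf)
}

#' @rdname dinvgauss
#' @export
pinvgauss <- function(q, mean, sd, lower.tail = TRUE, log.p = FALSE) {
  check_ig_params(mean, sd)
  lambda <- mean^3 / sd^2
  p <- numeric(length(q))
  p[q == Inf] <- 1
  pos <- is.finite(q) & q > 0
  qq <- q[pos]
  a <- sqrt(lambda / qq) * (qq / mean - 1)
  b <- -sqrt(lambda / qq) * (qq / mean + 1)
  # second term via logs: exp(2*lambda/mean) can overflow on its own
  p[pos] <- pnorm(a) + exp(2 * lambda / mean + pnorm(b, log.p = TRUE))
  p[!pos] <- 0
  p[q == Inf] <- 1
  p <- pmin(pmax(p, 0), 1)
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

#' @rdname dinvgauss
#' @export
rinvgauss <- function(n, mean, sd) {
  check_ig_params(mean, sd)
  stopifnot(n >= 1)
  lambda <- mean^3 / sd^2
  # Michael-Schucany-Haas transformation with uniform root selection
  y <- rchisq(n, df = 1)
  x1 <- mean + mean^2 * y / (2 * lambda) -
    mean / (2 * lambda) * sqrt(4 * mean * lambda * y + mean^2 * y^2)
  u <- runif(n)
  ifelse(u <= mean / (mean + x1), x1, mean^2 / x1)
}

check_ig_params <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("inverse-Gaussian mean must be positive and finite")
  if (any(!is.finite(sd)) || any(sd <= 0))
    stop("inverse-Gaussian sd must be positive and finite")
  invisible(TRUE)
}

#' Maximum-likelihood estimation for inverse-Gaussian dominance times
#'
#' Closed-form ML estimators of the mean and standard deviation of an
#' inverse-Gaussian sample: \code{mu} is the sample mean and
#' \code{sigma = sqrt(mu^3 * mean(1/d - 1/mu))}.
#'
#' @param d vector of dominance times (all > 0, length >= 2).
#' @return list with components \code{mu}, \code{sigma}, \code{n} and
#'   \code{loglik} (the maximized inverse-Gaussian log-likelihood).
#' @examples
#' invgauss_mle(c(1, 2, 4))
#' @export
invgauss_mle <- function(d) {
  if (any(d <= 0)) stop("dominance times must be positive")
  n <- length(d)
  if (n < 2) stop("need at least two dominance times")
  mu <- mean(d)
  s2 <- mu^3 * mean(1 / d - 1 / mu)
  if (s2 <= 0)
    stop("degenerate sample: all dominance times equal, sigma-hat is zero")
  sigma <- sqrt(s2)
  list(mu = mu, sigma = sigma, n = n,
       loglik = sum(dinvgauss(d, mu, sigma, log = TRUE)))
}

#' Convert between inverse-Gaussian and barrier/drift parameterizations
#'
#' A Brownian motion with drift \code{nu} started at \code{-b} first hits the
#' barrier \code{+b} after an inverse-Gaussian time with mean
#' \code{mu = 2 b / nu} and standard deviation \code{sigma = sqrt(2 b / nu^3)}.
#' `ig_to_barrier` inverts these relations: \code{b = sqrt(mu^3 / sigma^2) / 2}
#' and \code{nu = sqrt(mu) / sigma}. The coefficient of variation satisfies
#' \code{sigma / mu = 1 / sqrt(2 b nu)}.
#'
#' @param mu,sigma inverse-Gaussian mean and standard deviation (> 0).
#' @param b barrier half-distance (> 0, activity units).
#' @param nu drift rate (> 0, activity units per second).
#' @return `ig_to_barrier`: list with components \code{b} and \code{nu};
#'   `barrier_to_ig`: list with components \code{mu} and \code{sigma}.
#' @examples
#' ig_to_barrier(10.50, 8.18)   # b = 2.08, nu = 0.40
#' barrier_to_ig(2.42, 0.72)
#' @export
ig_to_barrier <- function(mu, sigma) {
  check_ig_params(mu, sigma)
  list(b = 0.5 * sqrt(mu^3 / sigma^2), nu = sqrt(mu) / sigma)
}

#' @rdname ig_to_barrier
#' @export
barrier_to_ig <- function(b, nu) {
  if (any(b <= 0) || any(nu <= 0)) stop("barrier and drift must be positive")
  list(mu = 2 * b / nu, sigma = sqrt(2 * b / nu^3))
}

#' The normal-inverse-Gaussian distribution
#'
#' Density and distribution function of the normal-inverse-Gaussian (NIG)
#' law in the (location, tail-steepness \code{alpha}, asymmetry \code{beta},
#' scale \code{delta}) parameterization. The NIG law arises here as the
#' position of a Brownian motion with drift \code{beta} evaluated at an
#' independent inverse-Gaussian time: if \code{D} is inverse Gaussian with
#' mean \code{delta / sqrt(alpha^2 - beta^2)} and shape \code{delta^2}, and
#' \code{X | D} is normal with mean \code{loc + beta * D} and variance
#' \code{D}, then \code{X} is NIG(\code{loc, alpha, beta, delta}). It governs
#' the marginal state-transition probabilities of the hierarchical Brownian
#' model: the background process observed at the end of a dominance time.
#'
#' @param x,q numeric vector of positions.
#' @param loc location parameter.
#' @param alpha tail steepness (> |beta|).
#' @param beta asymmetry (drift of the subordinated Brownian motion).
#' @param delta scale (> 0; twice the perception-process border).
#' @param log logical; return log-density.
#' @return `dnig` the density, `pnig` the distribution function.
#' @examples
#' pnig(0, loc = 0, alpha = 0.5, beta = 0, delta = 2)  # 0.5 by symmetry
#' @export
dnig <- function(x, loc, alpha, beta, delta, log = FALSE) {
  check_nig_spec(loc, alpha, beta, delta)
  gam <- sqrt(alpha^2 - beta^2)
  z <- x - loc
  q <- sqrt(delta^2 + z^2)
  az <- alpha * q
  # exponentially-scaled Bessel K1 keeps large delta*gamma exponents finite
  logf <- log(alpha * delta / pi) + log(besselK(az, 1, expon.scaled = TRUE)) -
    az - log(q) + delta * gam + beta * z
  if (log) logf else exp(logf)
}

#' @rdname dnig
#' @export
pnig <- function(q, loc, alpha, beta, delta) {
  check_nig_spec(loc, alpha, beta, delta)
  vapply(q, function(x) {
    if (!is.finite(x)) return(if (x > 0) 1 else 0)
    # integrate the density over (-Inf, x], anchored at the distribution centre
    centre <- loc + delta * beta / sqrt(alpha^2 - beta^2)
    f <- function(t) dnig(t, loc, alpha, beta, delta)
    if (x <= centre) {
      val <- integrate(f, -Inf, x, rel.tol = 1e-10, abs.tol = 1e-12,
                       stop.on.error = FALSE)$value
    } else {
      val <- 1 - integrate(f, x, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
                           stop.on.error = FALSE)$value
    }
    min(max(val, 0), 1)
  }, numeric(1))
}

check_nig_spec <- function(loc, alpha, beta, delta) {
  if (!is.finite(loc)) stop("NIG location must be finite")
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= abs(beta))
    stop("NIG requires alpha > |beta|")
  if (!is.finite(delta) || delta <= 0) stop("NIG scale delta must be positive")
  invisible(TRUE)
}

#' Normal distribution function in mean/variance form
#'
#' Thin wrapper around [stats::pnorm()] taking a variance rather than a
#' standard deviation, matching the transition-probability formulas of the
#' hierarchical model where the background-process variance equals the
#' elapsed time.
#'
#' @param x quantile.
#' @param mean mean of the normal distribution.
#' @param var variance (> 0).
#' @export
pnorm_var <- function(x, mean = 0, var = 1) {
  if (any(var <= 0)) stop("variance must be positive")
  pnorm(x, mean = mean, sd = sqrt(var))
}
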