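# Independent brute-force oracles used against the recursive implementations.
# These enumerate all 2^n hidden-state paths and are tractable for n <= 12.

# total likelihood of the two-state HMM by path enumeration
enum_hmm_loglik <- function(d, p) {
  n <- length(d)
  f <- function(x, st) {
    if (st == 1) dinvgauss(x, p$mu_S, p$sigma_S)
    else dinvgauss(x, p$mu_U, p$sigma_U)
  }
  tr <- matrix(c(p$p_SS, 1 - p$p_SS, 1 - p$p_UU, p$p_UU), 2, 2, byrow = TRUE)
  tot <- 0
  for (mask in 0:(2^n - 1)) {
    y <- as.integer(intToBits(mask))[1:n] + 1L   # 1 = S, 2 = U
    pr <- if (y[1] == 1) p$pi_S else 1 - p$pi_S
    pr <- pr * f(d[1], y[1])
    if (n > 1) for (i in 2:n) pr <- pr * tr[y[i - 1], y[i]] * f(d[i], y[i])
    tot <- tot + pr
  }
  log(tot)
}

# total likelihood of the duration-dependent model by path enumeration
enum_hbmi_loglik <- function(d, params) {
  p <- params
  igS <- barrier_to_ig(p$b_S, p$nu_S_star)
  igU <- barrier_to_ig(p$b_U, p$nu_U_star)
  n <- length(d)
  f <- function(x, st) {
    if (st == 1) dinvgauss(x, igS$mu, igS$sigma)
    else dinvgauss(x, igU$mu, igU$sigma)
  }
  tr <- function(from, to, dprev) {
    pSS <- ptrans_stay_stable(dprev, p$nu_B_star, p$btilde_S)
    pUU <- ptrans_stay_unstable(dprev, p$nu_B_star, p$btilde_U)
    m <- matrix(c(pSS, 1 - pSS, 1 - pUU, pUU), 2, 2, byrow = TRUE)
    m[from, to]
  }
  tot <- 0
  for (mask in 0:(2^n - 1)) {
    y <- as.integer(intToBits(mask))[1:n] + 1L
    pr <- if (y[1] == 1) p$pi_S else 1 - p$pi_S
    pr <- pr * f(d[1], y[1])
    if (n > 1)
      for (i in 2:n) pr <- pr * tr(y[i - 1], y[i], d[i - 1]) * f(d[i], y[i])
    tot <- tot + pr
  }
  log(tot)
}

# most probable hidden path by brute force (ties resolved toward S to match
# the documented convention)
enum_viterbi <- function(d, p) {
  n <- length(d)
  lf <- function(x, st) {
    if (st == 1) dinvgauss(x, p$mu_S, p$sigma_S, log = TRUE)
    else dinvgauss(x, p$mu_U, p$sigma_U, log = TRUE)
  }
  ltr <- log(matrix(c(p$p_SS, 1 - p$p_SS, 1 - p$p_UU, p$p_UU), 2, 2,
                    byrow = TRUE))
  best <- -Inf
  best_y <- NULL
  for (mask in 0:(2^n - 1)) {
    y <- as.integer(intToBits(mask))[1:n] + 1L
    lp <- log(if (y[1] == 1) p$pi_S else 1 - p$pi_S) + lf(d[1], y[1])
    if (n > 1) for (i in 2:n) lp <- lp + ltr[y[i - 1], y[i]] + lf(d[i], y[i])
    if (lp > best + 1e-12) { best <- lp; best_y <- y }
  }
  c("S", "U")[best_y]
}

# position of a drifting Brownian motion at an independent IG time,
# computed by quadrature over the mixing density (independent of dnig/pnig)
mixing_cdf_oracle <- function(x, loc, alpha, beta, delta) {
  gam <- sqrt(alpha^2 - beta^2)
  mu_D <- delta / gam                 # mixing time: IG with shape delta^2
  sigma_D <- sqrt(mu_D^3 / delta^2)
  integrate(function(t) dinvgauss(t, mu_D, sigma_D) *
              pnorm((x - loc - beta * t) / sqrt(t)),
            0, Inf, rel.tol = 1e-10)$value
}

# Table-style parameter constellations used across recovery tests
# (starred drifts from the cycle-average with l_p = 0.6, l_b = 0.8)
fixture_hbmi <- function(row = c("C", "D", "F")) {
  row <- match.arg(row)
  tab <- list(
    C = list(nu0 = 0.72, b_S = 41.74, nu_S = 0.24, b_U = 1.84, nu_U = 0.74,
             bt_S = 49.71, bt_U = 2.39, nu_B = 0.54),
    D = list(nu0 = 0.27, b_S = 5.42, nu_S = 0.08, b_U = 1.06, nu_U = 0.93,
             bt_S = 4.56, bt_U = 1.13, nu_B = 0.06),
    F = list(nu0 = 0.57, b_S = 13.5, nu_S = 0.24, b_U = 1.00, nu_U = 0.24,
             bt_S = 110.28, bt_U = 0.77, nu_B = 1.90))
  r <- tab[[row]]
  hbmi_params(r$b_S, starred_drift(r$nu_S, r$nu0),
              r$b_U, starred_drift(r$nu_U, r$nu0),
              r$bt_S, r$bt_U, starred_drift(r$nu_B, 0),
              pi_S = 0.5, nu0 = r$nu0)
}

table2_rowC <- function() {
  hmm_params(186.45, 30.50, 5.01, 3.06, 0.67, 0.96)
}
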