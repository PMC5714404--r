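#' Hierarchical Brownian model parameter set (intermittent viewing)
#'
#' Parameters of the hierarchical Brownian model for intermittent viewing:
#' the perception process fluctuates between borders `+/- b_S` (stable
#' regime) or `+/- b_U` (unstable regime) with mean drift per second
#' `nu_S_star` / `nu_U_star`; a background process with mean drift
#' `nu_B_star` observed at each percept change decides, against the borders
#' `btilde_S` and `btilde_U`, whether the regime switches.
#'
#' @param b_S,b_U perception-process borders, stable/unstable (activity
#'   units, `0 <= b_U <= b_S`).
#' @param nu_S_star,nu_U_star mean perception drifts per second (> 0).
#' @param btilde_S background border for staying stable (fitted models
#'   satisfy `btilde_S >= 0`; the constructor admits any finite value so
#'   that degenerate limits can be explored).
#' @param btilde_U background border for leaving the unstable state (any
#'   real value).
#' @param nu_B_star mean background drift per second (> 0).
#' @param pi_S probability that the run starts in the stable state.
#' @param nu0 optional drift during stimulus presentation, taken from the
#'   same subject's continuous fit; needed only to decompose the starred
#'   (cycle-averaged) drifts into their blank-display components.
#' @param l_p,l_b presentation and blank lengths (s).
#' @return a named list of class `hbmi_params`. One-regime models may carry
#'   `NA` in the fields of the missing state.
#' @export
hbmi_params <- function(b_S, nu_S_star, b_U, nu_U_star, btilde_S, btilde_U,
                        nu_B_star, pi_S = 0.5, nu0 = NULL,
                        l_p = 0.6, l_b = 0.8) {
  hasS <- is.finite(b_S) && is.finite(nu_S_star)
  hasU <- is.finite(b_U) && is.finite(nu_U_star)
  if (!hasS && !hasU) stop("at least one regime must have finite parameters")
  if (hasS && (b_S <= 0 || nu_S_star <= 0))
    stop("stable border and drift must be positive")
  if (hasU && (b_U <= 0 || nu_U_star <= 0))
    stop("unstable border and drift must be positive")
  if (hasS && hasU && b_U > b_S)
    stop("the unstable border must not exceed the stable border")
  if (!is.finite(nu_B_star) || nu_B_star <= 0)
    stop("the background drift nu_B_star must be positive")
  if (pi_S < 0 || pi_S > 1) stop("pi_S must lie in [0, 1]")
  structure(list(b_S = b_S, nu_S_star = nu_S_star, b_U = b_U,
                 nu_U_star = nu_U_star, btilde_S = btilde_S,
                 btilde_U = btilde_U, nu_B_star = nu_B_star, pi_S = pi_S,
                 nu0 = nu0, l_p = l_p, l_b = l_b),
            class = "hbmi_params")
}

#' Cycle-averaged (starred) drifts and their decomposition
#'
#' During intermittent viewing the perception process has drift `nu0` in
#' presentation intervals of length `l_p` and a state drift `nu_raw` in
#' blanks of length `l_b`; its behaviour over whole cycles equals that of a
#' Brownian motion with the time-weighted mean drift
#' `(l_b * nu_raw + l_p * nu0) / (l_b + l_p)`. `decompose_drift` inverts the
#' average back to the blank-display component. The background process has
#' zero drift during presentations, so its average is obtained with
#' `nu0 = 0`.
#'
#' @param nu_raw drift during blank displays (per second).
#' @param nu_star cycle-averaged drift (per second).
#' @param nu0 drift during stimulus presentation (per second).
#' @param l_p,l_b presentation and blank lengths (s, > 0 for intermittent).
#' @return the averaged (`starred_drift`) or blank-display
#'   (`decompose_drift`) drift per second.
#' @examples
#' starred_drift(0.24, 0.72, l_p = 0.6, l_b = 0.8)  # 0.44571
#' @export
starred_drift <- function(nu_raw, nu0, l_p = 0.6, l_b = 0.8) {
  if (l_b == 0) {
    if (any(abs(nu_raw - nu0) > 1e-12))
      stop("continuous viewing (l_b = 0) requires nu_raw == nu0")
    return(nu0)
  }
  (l_b * nu_raw + l_p * nu0) / (l_b + l_p)
}

#' @rdname starred_drift
#' @export
decompose_drift <- function(nu_star, nu0, l_p = 0.6, l_b = 0.8) {
  if (l_b == 0) {
    if (any(abs(nu_star - nu0) > 1e-12))
      stop("continuous viewing (l_b = 0) requires nu_star == nu0")
    return(nu0)
  }
  ((l_b + l_p) * nu_star - l_p * nu0) / l_b
}

#' Duration-dependent state-transition probabilities
#'
#' Probability of staying in the stable (resp. unstable) state after a
#' dominance time of length `d`: the background process at the end of the
#' interval is normal with mean `+nu_B_star * d` (stable) or
#' `-nu_B_star * d` (unstable) and variance `d`, and is compared with the
#' background border. Longer stable dominance times make staying stable more
#' likely; longer unstable dominance times make staying unstable more
#' likely to end.
#'
#' @param d dominance time (s, > 0); vectorized.
#' @param nu_B_star mean background drift per second.
#' @param btilde_S,btilde_U background borders.
#' @return probability (vector).
#' @examples
#' ptrans_stay_stable(100, nu_B_star = 0.1, btilde_S = 5)   # 1 - pnorm(-0.5)
#' @export
ptrans_stay_stable <- function(d, nu_B_star, btilde_S) {
  if (any(d <= 0)) stop("dominance times must be positive")
  1 - pnorm(btilde_S, mean = nu_B_star * d, sd = sqrt(d))
}

#' @rdname ptrans_stay_stable
#' @export
ptrans_stay_unstable <- function(d, nu_B_star, btilde_U) {
  if (any(d <= 0)) stop("dominance times must be positive")
  pnorm(btilde_U, mean = -nu_B_star * d, sd = sqrt(d))
}

#' Marginal state-transition probabilities
#'
#' Expectations of the duration-dependent transition probabilities over the
#' state's inverse-Gaussian dominance-time law. The background-process
#' position at the end of an IG-distributed dominance time follows a
#' normal-inverse-Gaussian law, so
#' `p_SS_star = P(X_S > btilde_S)` with
#' `X_S ~ NIG(0, sqrt(nu_S*^2 + nu_B*^2), nu_B*, 2 b_S)` and
#' `p_UU_star = P(X_U <= btilde_U)` with
#' `X_U ~ NIG(0, sqrt(nu_U*^2 + nu_B*^2), -nu_B*, 2 b_U)`.
#'
#' @param params an `hbmi_params` object.
#' @return list with `p_SS_star` and `p_UU_star` (NA for a missing regime).
#' @export
marginal_transitions <- function(params) {
  stopifnot(inherits(params, "hbmi_params"))
  p <- params
  pSS <- pUU <- NA_real_
  if (is.finite(p$b_S) && is.finite(p$btilde_S)) {
    pSS <- 1 - pnig(p$btilde_S, loc = 0,
                    alpha = sqrt(p$nu_S_star^2 + p$nu_B_star^2),
                    beta = p$nu_B_star, delta = 2 * p$b_S)
  }
  if (is.finite(p$b_U) && is.finite(p$btilde_U)) {
    pUU <- pnig(p$btilde_U, loc = 0,
                alpha = sqrt(p$nu_U_star^2 + p$nu_B_star^2),
                beta = -p$nu_B_star, delta = 2 * p$b_U)
  }
  list(p_SS_star = pSS, p_UU_star = pUU)
}

#' Forward log-likelihood of the hierarchical model
#'
#' Scaled forward recursion with inverse-Gaussian emissions (means
#' `2 b / nu*`, per state) and duration-dependent transition probabilities
#' evaluated at the preceding dominance time. The log-likelihood is the sum
#' of the logarithms of the scaling constants.
#'
#' @param d dominance times (or a `dominance_series`).
#' @param params an `hbmi_params` object (both regimes finite).
#' @return the log-likelihood (scalar).
#' @export
hbmi_loglik <- function(d, params) {
  d <- as_durations(d)
  stopifnot(inherits(params, "hbmi_params"))
  p <- params
  ig_S <- barrier_to_ig(p$b_S, p$nu_S_star)
  ig_U <- barrier_to_ig(p$b_U, p$nu_U_star)
  ll <- hbmi_loglik_cpp(d, ig_S$mu, ig_S$sigma, ig_U$mu, ig_U$sigma,
                        p$btilde_S, p$btilde_U, p$nu_B_star, p$pi_S)
  if (!is.finite(ll))
    stop("likelihood underflow: both state densities vanish for some interval")
  ll
}

# quadrature weight integrals: int f_IG(t) w(t) t^pow dt. The density can
# be sharply peaked (small CV), so the domain is split at the mean and
# truncated where the IG tail is numerically zero.
ig_weighted_integral <- function(mu, sigma, w, pow = 0) {
  f <- function(t) dinvgauss(t, mu, sigma) * w(t) * t^pow
  # tail exponent is lambda x / (2 mu^2) = mu x / (2 sigma^2); cut where it
  # exceeds ~40 so the discarded t-weighted mass is far below 1e-10
  upper <- mu + 40 * sigma + 80 * sigma^2 / mu
  i1 <- integrate(f, lower = 0, upper = mu, rel.tol = 1e-10,
                  abs.tol = 1e-12, subdivisions = 400L,
                  stop.on.error = FALSE)
  i2 <- integrate(f, lower = mu, upper = upper, rel.tol = 1e-10,
                  abs.tol = 1e-12, subdivisions = 400L,
                  stop.on.error = FALSE)
  i1$value + i2$value
}

#' Conditional mean dominance times before a regime transition
#'
#' Expected length of a stable (or unstable) dominance time given whether
#' the following interval stays in the same regime. Computed by adaptive
#' quadrature of the inverse-Gaussian density weighted with the
#' duration-dependent transition probability; the weights satisfy the law of
#' total expectation, e.g.
#' `mu_S_plus * p_SS_star + mu_S_minus * (1 - p_SS_star) = mu_S_star`.
#' Dominance times directly before a regime change are systematically
#' shorter than those followed by the same regime.
#'
#' @param params an `hbmi_params` object.
#' @param state `"S"` or `"U"`.
#' @param next_same logical: condition on staying in the same regime
#'   (`TRUE`, the "plus" mean) or on switching (`FALSE`, the "minus" mean).
#' @return conditional mean dominance time (s).
#' @export
mu_conditional <- function(params, state = c("S", "U"), next_same = TRUE) {
  stopifnot(inherits(params, "hbmi_params"))
  state <- match.arg(state)
  p <- params
  if (state == "S") {
    ig <- barrier_to_ig(p$b_S, p$nu_S_star)
    stay <- function(t) ptrans_stay_stable(t, p$nu_B_star, p$btilde_S)
  } else {
    ig <- barrier_to_ig(p$b_U, p$nu_U_star)
    stay <- function(t) ptrans_stay_unstable(t, p$nu_B_star, p$btilde_U)
  }
  pstay <- ig_weighted_integral(ig$mu, ig$sigma, stay)
  w <- if (next_same) stay else function(t) 1 - stay(t)
  pw <- if (next_same) pstay else 1 - pstay
  if (pw <= 0 || pw >= 1)
    stop("conditional mean undefined: transition probability is degenerate")
  ig_weighted_integral(ig$mu, ig$sigma, w, pow = 1) / pw
}

#' Derived pattern statistics of the hierarchical model
#'
#' Computes, from the borders and drifts, the quantities that are directly
#' comparable to the two-state HMM and to observed response patterns:
#' state-wise inverse-Gaussian means and standard deviations
#' (`mu = 2 b / nu*`, `sigma = sqrt(2 b / nu*^3)`), coefficients of
#' variation `1 / sqrt(2 b nu*)`, marginal transition probabilities,
#' conditional pre-transition means, the expected relative time in the
#' stable state, and the long-run alternation rate
#' `rho = phi_S / mu_S_star + phi_U / mu_U_star`.
#'
#' @param params an `hbmi_params` object.
#' @return a list of class `hbmi_derived` with fields `mu_S_star`,
#'   `sigma_S_star`, `mu_U_star`, `sigma_U_star`, `cv_S_star`, `cv_U_star`,
#'   `p_SS_star`, `p_UU_star`, `mu_S_plus`, `mu_S_minus`, `mu_U_plus`,
#'   `mu_U_minus`, `phi_S_star`, `rho`. Fields of a missing regime are NA.
#' @export
derived_params <- function(params) {
  stopifnot(inherits(params, "hbmi_params"))
  p <- params
  hasS <- is.finite(p$b_S)
  hasU <- is.finite(p$b_U)
  out <- list(mu_S_star = NA_real_, sigma_S_star = NA_real_,
              mu_U_star = NA_real_, sigma_U_star = NA_real_,
              cv_S_star = NA_real_, cv_U_star = NA_real_,
              p_SS_star = NA_real_, p_UU_star = NA_real_,
              mu_S_plus = NA_real_, mu_S_minus = NA_real_,
              mu_U_plus = NA_real_, mu_U_minus = NA_real_,
              phi_S_star = NA_real_, rho = NA_real_)
  if (hasS) {
    ig <- barrier_to_ig(p$b_S, p$nu_S_star)
    out$mu_S_star <- ig$mu
    out$sigma_S_star <- ig$sigma
    out$cv_S_star <- 1 / sqrt(2 * p$b_S * p$nu_S_star)
  }
  if (hasU) {
    ig <- barrier_to_ig(p$b_U, p$nu_U_star)
    out$mu_U_star <- ig$mu
    out$sigma_U_star <- ig$sigma
    out$cv_U_star <- 1 / sqrt(2 * p$b_U * p$nu_U_star)
  }
  mt <- marginal_transitions(params)
  out$p_SS_star <- mt$p_SS_star
  out$p_UU_star <- mt$p_UU_star

  tol <- 1e-7
  if (!hasU || (hasS && is.finite(out$p_SS_star) &&
                out$p_SS_star >= 1 - tol)) {
    # stable-locked limit: every interval is stable
    out$mu_S_plus <- out$mu_S_star
    out$phi_S_star <- 1
    out$rho <- 1 / out$mu_S_star
    return(structure(out, class = "hbmi_derived"))
  }
  if (!hasS || (is.finite(out$p_UU_star) && out$p_UU_star >= 1 - tol)) {
    out$mu_U_plus <- out$mu_U_star
    out$phi_S_star <- 0
    out$rho <- 1 / out$mu_U_star
    return(structure(out, class = "hbmi_derived"))
  }

  # conditional means and phase lengths from one consistent quadrature:
  # the stay probability and the t-weighted stay integral share the weight
  # function, so the law of total expectation holds to quadrature accuracy
  igS <- barrier_to_ig(p$b_S, p$nu_S_star)
  igU <- barrier_to_ig(p$b_U, p$nu_U_star)
  stayS <- function(t) ptrans_stay_stable(t, p$nu_B_star, p$btilde_S)
  stayU <- function(t) ptrans_stay_unstable(t, p$nu_B_star, p$btilde_U)
  pS <- ig_weighted_integral(igS$mu, igS$sigma, stayS)
  pU <- ig_weighted_integral(igU$mu, igU$sigma, stayU)
  pS <- min(max(pS, 0), 1)
  pU <- min(max(pU, 0), 1)
  if (pS >= 1 - tol) {     # quadrature-level locked states
    out$mu_S_plus <- out$mu_S_star
    out$phi_S_star <- 1
    out$rho <- 1 / out$mu_S_star
    return(structure(out, class = "hbmi_derived"))
  }
  if (pU >= 1 - tol) {
    out$mu_U_plus <- out$mu_U_star
    out$phi_S_star <- 0
    out$rho <- 1 / out$mu_U_star
    return(structure(out, class = "hbmi_derived"))
  }
  iS <- ig_weighted_integral(igS$mu, igS$sigma, stayS, pow = 1)
  iU <- ig_weighted_integral(igU$mu, igU$sigma, stayU, pow = 1)
  if (pS > tol) out$mu_S_plus <- iS / pS
  if (pS < 1 - tol) out$mu_S_minus <- (out$mu_S_star - iS) / (1 - pS)
  if (pU > tol) out$mu_U_plus <- iU / pU
  if (pU < 1 - tol) out$mu_U_minus <- (out$mu_U_star - iU) / (1 - pU)
  # expected phase length: (E[N] - 1) "stay" intervals plus the final one
  lenS <- if (pS > tol) pS / (1 - pS) * out$mu_S_plus + out$mu_S_minus
          else out$mu_S_minus
  lenU <- if (pU > tol) pU / (1 - pU) * out$mu_U_plus + out$mu_U_minus
          else out$mu_U_minus
  out$phi_S_star <- lenS / (lenS + lenU)
  out$rho <- out$phi_S_star / out$mu_S_star +
    (1 - out$phi_S_star) / out$mu_U_star
  structure(out, class = "hbmi_derived")
}

#' @export
print.hbmi_derived <- function(x, ...) {
  cat("Derived hierarchical-model statistics\n")
  cat(sprintf("  stable:   mu* = %.2f s, sigma* = %.2f s, CV* = %.2f\n",
              x$mu_S_star, x$sigma_S_star, x$cv_S_star))
  cat(sprintf("  unstable: mu* = %.2f s, sigma* = %.2f s, CV* = %.2f\n",
              x$mu_U_star, x$sigma_U_star, x$cv_U_star))
  cat(sprintf("  p_SS* = %.3f, p_UU* = %.3f, phi_S* = %.3f\n",
              x$p_SS_star, x$p_UU_star, x$phi_S_star))
  cat(sprintf("  alternation rate rho = %.4f / s\n", x$rho))
  invisible(x)
}

#' Long-run alternation rate
#'
#' Expected number of percept changes per second in the long run,
#' `rho = phi_S* / mu_S* + phi_U* / mu_U*`.
#'
#' @param params an `hbmi_params` or `hbmi_derived` object.
#' @return rate (1/s).
#' @export
alternation_rate <- function(params) {
  d <- if (inherits(params, "hbmi_derived")) params else derived_params(params)
  d$rho
}

#' Alternation rate as a function of blank-display length
#'
#' Model-extension hook: given drift functions `nu_S_fun(l_b)` and
#' `nu_U_fun(l_b)` for the blank-display drifts and a raw background drift
#' `nu_B`, recompute the cycle-averaged drifts for each blank length,
#' rebuild the derived statistics and return the alternation-rate curve.
#' The model presumes `l_b <= l_p * nu0 / nu_S(l_b)`; larger blank lengths
#' give a non-positive averaged stable drift and are dropped with a warning.
#'
#' @param params an `hbmi_params` object whose borders are reused along the
#'   curve; its `nu0` field must be set.
#' @param nu_S_fun,nu_U_fun functions of `l_b` returning blank-display
#'   drifts.
#' @param nu_B raw background drift during blanks.
#' @param l_b_grid blank lengths (s) at which to evaluate the curve.
#' @return data.frame with columns `l_b`, `nu_S_star`, `nu_U_star`,
#'   `nu_B_star`, `phi_S_star`, `rho`.
#' @export
rate_vs_blank <- function(params, nu_S_fun, nu_U_fun, nu_B, l_b_grid) {
  stopifnot(inherits(params, "hbmi_params"))
  if (is.null(params$nu0)) stop("params$nu0 is required for the rate curve")
  nu0 <- params$nu0
  l_p <- params$l_p
  ok <- l_b_grid <= l_p * nu0 / nu_S_fun(l_b_grid)
  if (any(!ok)) {
    warning(sprintf("%d blank lengths exceed l_p * nu0 / nu_S and were dropped",
                    sum(!ok)))
    l_b_grid <- l_b_grid[ok]
  }
  rows <- lapply(l_b_grid, function(lb) {
    nuS <- starred_drift(nu_S_fun(lb), nu0, l_p, lb)
    nuU <- starred_drift(nu_U_fun(lb), nu0, l_p, lb)
    nuB <- starred_drift(nu_B, 0, l_p, lb)
    pp <- hbmi_params(params$b_S, nuS, params$b_U, nuU, params$btilde_S,
                      params$btilde_U, nuB, pi_S = params$pi_S, nu0 = nu0,
                      l_p = l_p, l_b = lb)
    dd <- derived_params(pp)
    data.frame(l_b = lb, nu_S_star = nuS, nu_U_star = nuU, nu_B_star = nuB,
               phi_S_star = dd$phi_S_star, rho = dd$rho)
  })
  do.call(rbind, rows)
}

#' Interval-level simulation of the hierarchical model
#'
#' Exact (in distribution, under the cycle-averaged drift description)
#' simulation: per regime an inverse-Gaussian dominance time is drawn, then
#' the background endpoint (normal, mean `+/- nu_B* d`, variance `d`) is
#' compared with the regime's background border to decide a switch. The
#' final interval overrunning `T` is discarded.
#'
#' @param params an `hbmi_params` object.
#' @param T run length (s).
#' @param seed optional integer seed.
#' @return a `dominance_series` with attribute `states`.
#' @export
simulate_hbmi <- function(params, T, seed = NULL) {
  stopifnot(inherits(params, "hbmi_params"), T > 0)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  muS <- sgS <- muU <- sgU <- NA_real_
  if (is.finite(p$b_S)) {
    ig <- barrier_to_ig(p$b_S, p$nu_S_star); muS <- ig$mu; sgS <- ig$sigma
  }
  if (is.finite(p$b_U)) {
    ig <- barrier_to_ig(p$b_U, p$nu_U_star); muU <- ig$mu; sgU <- ig$sigma
  }
  piS <- if (!is.finite(muU)) 1 else if (!is.finite(muS)) 0 else p$pi_S
  sim <- hbmi_sim_cpp(T, muS, sgS, muU, sgU,
                      if (is.finite(p$btilde_S)) p$btilde_S else 0,
                      if (is.finite(p$btilde_U)) p$btilde_U else 0,
                      p$nu_B_star, piS)
  dur <- sim$durations
  states <- c("U", "S")[sim$states + 1L]
  if (length(dur) == 0) {
    # no percept change within the run: one censored interval of length T
    dur <- T
    states <- c("U", "S")[sim$first_state + 1L]
  }
  percepts <- rep(c("L", "R"), length.out = length(dur))
  out <- dominance_series(dur, percepts, condition = "intermittent",
                          l_p = p$l_p, l_b = p$l_b, duration_total = T,
                          truncated = TRUE)
  attr(out, "states") <- states
  out
}

#' Euler-Maruyama simulation of the full Brownian path
#'
#' Simulates the perception and background processes on a time grid of step
#' `dt`, honouring the presentation/blank drift switching, border hits,
#' percept flips, regime decisions and resets. With `l_b = 0` the process is
#' the continuous-viewing drift-diffusion model (single regime, border `b_S`,
#' drift `nu0`). The raw blank-display drifts are recovered from the starred
#' drifts, so `params$nu0` must be set for intermittent paths.
#'
#' @param params an `hbmi_params` object, or for continuous viewing a list
#'   with fields `b` and `nu` (e.g. from [ig_to_barrier()]).
#' @param T run length (s).
#' @param dt time step (s); should be well below `min(l_p, l_b)`.
#' @param seed optional integer seed.
#' @param diffusion scale of the Brownian increments (1 = standard; 0 gives
#'   the deterministic drift skeleton).
#' @param keep_paths logical; keep the sampled `P`, `B`, state paths.
#' @return list of class `hbm_path` with `hits` (first-hitting times),
#'   `durations` (their increments), `hit_state`, and, if kept, `t`, `P`,
#'   `B`, `state`.
#' @export
simulate_hbm_path <- function(params, T, dt = 1e-3, seed = NULL,
                              diffusion = 1, keep_paths = FALSE) {
  stopifnot(T > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "hbmi_params")) {
    p <- params
    if (dt > min(p$l_p, p$l_b) / 10)
      warning("dt is coarse relative to the presentation/blank cycle")
    if (is.null(p$nu0))
      stop("params$nu0 is required to recover the blank-display drifts")
    nuS <- decompose_drift(p$nu_S_star, p$nu0, p$l_p, p$l_b)
    nuU <- decompose_drift(p$nu_U_star, p$nu0, p$l_p, p$l_b)
    nuB <- decompose_drift(p$nu_B_star, 0, p$l_p, p$l_b)
    start_state <- as.integer(runif(1) < p$pi_S)
    sim <- hbm_path_cpp(T, dt, p$b_S, p$b_U, p$btilde_S, p$btilde_U, p$nu0,
                        nuS, nuU, nuB, p$l_p, p$l_b, start_state, diffusion,
                        keep_paths)
  } else {
    if (is.null(params$b) || is.null(params$nu))
      stop("continuous path simulation needs fields b and nu")
    sim <- hbm_path_cpp(T, dt, params$b, params$b, 0, 0, params$nu,
                        params$nu, params$nu, 0, 0.6, 0, 1L, diffusion,
                        keep_paths)
  }
  out <- list(hits = sim$hits, durations = diff(c(0, sim$hits)),
              hit_state = c("U", "S")[sim$hit_state + 1L], dt = dt)
  if (keep_paths) {
    out$t <- seq(dt, by = dt, length.out = length(sim$P))
    out$P <- sim$P
    out$B <- sim$B
    out$state <- c("U", "S")[sim$state + 1L]
  }
  structure(out, class = "hbm_path")
}
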