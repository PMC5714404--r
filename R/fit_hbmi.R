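#' Constrained maximum-likelihood fit of the hierarchical model
#'
#' Maximizes the forward log-likelihood of the duration-dependent two-regime
#' model over the seven parameters (b_S, nu_S*, b_U, nu_U*, btilde_S,
#' btilde_U, nu_B*). Starting values are built from the data: with
#' `U = {mean(d > 15), mean(d > 30)}` and
#' `O = {sd(d > 15), sd(d > 30), 1.15 sd(d > 30)}`, the stable border and
#' drift start at `sqrt(mu^3/sigma^2)/2` and `sqrt(mu)/sigma` for all
#' `(mu, sigma)` in `U x O`; per stable start, `b_U` in
#' `{0.01, 0.05, 0.15} b_S`, `btilde_S` in `{b_S, 10 b_S}`, `nu_U*` in
#' `{1.01, 3, 7} nu_S*`, `nu_B*` in `{0.1, 3}` and `btilde_U` in
#' `{-3, 0, 3}` complete the Cartesian grid. The grid is screened by its
#' log-likelihood and the best starts are polished with a quasi-Newton
#' search on log-transformed positive parameters ([stats::nlm()]); polished
#' fits are kept only when they satisfy the acceptance constraints
#' `nu_U* >= nu_S*`, `b_U <= b_S`, `btilde_S >= 0`, `nu_B* > 0`,
#' `mu_S* >= 0.98 mean(d > 15)` and `sigma_S* < 1.20 sd(d > 15)`.
#'
#' Runs whose dominance times all exceed 30 s reduce to a stable-only
#' drift-diffusion fit with `btilde_S = 0`; runs with all dominance times at
#' or below 30 s reduce to an unstable-only fit with `btilde_U = 1e10`; in
#' both cases `nu_B*` is fixed at 10. The start-state probability is set
#' from the first dominance time: 1 if `d[1] >= 45`, 0 if `d[1] <= 15`,
#' otherwise 0.5.
#'
#' @param d dominance times (or a `dominance_series`).
#' @param nu0 optional presentation drift from the same subject's continuous
#'   fit; stored for drift decomposition (the likelihood itself depends only
#'   on the starred drifts).
#' @param l_p,l_b presentation and blank lengths (s).
#' @param n_polish number of screened starts polished per batch (the top
#'   `2 * n_polish` are always polished; later batches run only while no
#'   start has been accepted).
#' @param max_polish upper bound on the total number of polished starts;
#'   when it is reached without an accepted fit, the one-regime fallback is
#'   returned.
#' @param iterlim optimizer iteration limit per start.
#' @return list with `model` ("hbmi", "stable_only", "unstable_only" or
#'   "one_state_fallback"), `params` (`hbmi_params`), `derived`
#'   (`hbmi_derived`), `loglik`, `n`, `n_accepted`, `n_starts`.
#' @export
fit_hbmi <- function(d, nu0 = NULL, l_p = 0.6, l_b = 0.8, n_polish = 30,
                     max_polish = 240, iterlim = 200) {
  d <- as_durations(d)
  n <- length(d)
  if (n < 2) stop("need at least two dominance times")
  piS <- if (d[1] >= 45) 1 else if (d[1] <= 15) 0 else 0.5

  if (all(d > 30)) {
    est <- invgauss_mle(d)
    bar <- ig_to_barrier(est$mu, est$sigma)
    pars <- hbmi_params(bar$b, bar$nu, NA, NA, btilde_S = 0, btilde_U = NA,
                        nu_B_star = 10, pi_S = 1, nu0 = nu0,
                        l_p = l_p, l_b = l_b)
    return(list(model = "stable_only", params = pars,
                derived = derived_params(pars), loglik = est$loglik, n = n,
                n_accepted = NA_integer_, n_starts = 0L))
  }
  if (all(d <= 30)) {
    est <- invgauss_mle(d)
    bar <- ig_to_barrier(est$mu, est$sigma)
    pars <- hbmi_params(NA, NA, bar$b, bar$nu, btilde_S = NA,
                        btilde_U = 1e10, nu_B_star = 10, pi_S = 0, nu0 = nu0,
                        l_p = l_p, l_b = l_b)
    return(list(model = "unstable_only", params = pars,
                derived = derived_params(pars), loglik = est$loglik, n = n,
                n_accepted = NA_integer_, n_starts = 0L))
  }

  mu15 <- mean(d[d > 15])
  mu30 <- mean(d[d > 30])
  sd15 <- if (sum(d > 15) >= 2) sd(d[d > 15]) else sd(d)
  sd30 <- if (sum(d > 30) >= 2) sd(d[d > 30]) else sd15
  U <- unique(c(mu15, mu30))
  O <- unique(c(sd15, sd30, 1.15 * sd30))
  O <- O[is.finite(O) & O > 0]
  if (length(O) == 0) O <- max(sd(d), 1)

  musig <- expand.grid(mu = U, sig = O)
  bS0 <- sqrt(musig$mu^3 / musig$sig^2) / 2
  nuS0 <- sqrt(musig$mu) / musig$sig
  base <- expand.grid(iS = seq_along(bS0), jS = seq_along(nuS0),
                      fU = c(0.01, 0.05, 0.15), fBt = c(1, 10),
                      fNu = c(1.01, 3, 7), nuB = c(0.1, 3),
                      btU = c(-3, 0, 3))
  theta <- cbind(b_S = bS0[base$iS], nu_S = nuS0[base$jS],
                 b_U = base$fU * bS0[base$iS],
                 nu_U = base$fNu * nuS0[base$jS],
                 bt_S = base$fBt * bS0[base$iS],
                 bt_U = base$btU, nu_B = base$nuB)

  screen <- hbmi_loglik_grid_cpp(d, theta, piS)
  ord <- order(screen, decreasing = TRUE)
  ord <- ord[is.finite(screen[ord])]

  negll <- function(x) {
    ll <- hbmi_loglik_cpp(d, 2 * exp(x[1]) / exp(x[2]),
                          sqrt(2 * exp(x[1]) / exp(x[2])^3),
                          2 * exp(x[3]) / exp(x[4]),
                          sqrt(2 * exp(x[3]) / exp(x[4])^3),
                          exp(x[5]), x[6], exp(x[7]), piS)
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  n_acc <- 0L
  polished <- 0L
  min_polish <- min(length(ord), 2L * n_polish)
  limit <- min(length(ord), max_polish)
  while (polished < limit &&
         (polished < min_polish || is.null(best))) {
    batch <- ord[(polished + 1):min(polished + n_polish, length(ord))]
    polished <- polished + length(batch)
    for (r in batch) {
      x0 <- c(log(theta[r, 1]), log(theta[r, 2]), log(theta[r, 3]),
              log(theta[r, 4]), log(max(theta[r, 5], 1e-8)), theta[r, 6],
              log(theta[r, 7]))
      opt <- tryCatch(nlm(negll, x0, iterlim = iterlim),
                      error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$minimum) || opt$minimum >= 1e10)
        next
      x <- opt$estimate
      bS <- exp(x[1]); nuS <- exp(x[2]); bU <- exp(x[3]); nuU <- exp(x[4])
      btS <- exp(x[5]); btU <- x[6]; nuB <- exp(x[7])
      if (nuU < nuS) next                       # A
      if (bU > bS) next                         # B (C, D hold by transform)
      if (2 * bS / nuS < 0.98 * mu15) next      # E
      if (sqrt(2 * bS / nuS^3) >= 1.20 * sd15) next  # F
      n_acc <- n_acc + 1L
      if (is.null(best) || -opt$minimum > best$loglik)
        best <- list(loglik = -opt$minimum,
                     theta = c(bS, nuS, bU, nuU, btS, btU, nuB))
    }
  }

  if (is.null(best)) {
    # all starts rejected: explicit one-regime fallback
    est <- invgauss_mle(d)
    bar <- ig_to_barrier(est$mu, est$sigma)
    stable <- mean(d) > 30
    pars <- if (stable)
      hbmi_params(bar$b, bar$nu, NA, NA, 0, NA, 10, pi_S = 1, nu0 = nu0,
                  l_p = l_p, l_b = l_b)
    else
      hbmi_params(NA, NA, bar$b, bar$nu, NA, 1e10, 10, pi_S = 0, nu0 = nu0,
                  l_p = l_p, l_b = l_b)
    return(list(model = "one_state_fallback", params = pars,
                derived = derived_params(pars), loglik = est$loglik, n = n,
                n_accepted = 0L, n_starts = nrow(theta)))
  }

  th <- best$theta
  pars <- hbmi_params(th[1], th[2], th[3], th[4], th[5], th[6], th[7],
                      pi_S = piS, nu0 = nu0, l_p = l_p, l_b = l_b)
  list(model = "hbmi", params = pars, derived = derived_params(pars),
       loglik = best$loglik, n = n, n_accepted = n_acc,
       n_starts = nrow(theta))
}
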