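test_that("cycle-averaged drifts match the weighted mean and invert", {
  expect_equal(starred_drift(0.24, 0.72, 0.6, 0.8), 0.44571, tolerance = 1e-5)
  expect_equal(starred_drift(0.5, 0.5, 0.6, 0.8), 0.5)
  set.seed(2)
  for (k in 1:5) {
    nu <- runif(1, 0.01, 1); nu0 <- runif(1, 0.1, 1)
    lp <- runif(1, 0.3, 1); lb <- runif(1, 0.3, 1)
    expect_equal(decompose_drift(starred_drift(nu, nu0, lp, lb), nu0, lp, lb),
                 nu, tolerance = 1e-12)
  }
  expect_error(starred_drift(0.3, 0.5, 0.6, 0), "continuous")
  expect_equal(starred_drift(0.5, 0.5, 0.6, 0), 0.5)
})

test_that("duration-dependent transition probabilities match the normal law", {
  expect_equal(ptrans_stay_stable(100, 0.1, 5), 0.69146, tolerance = 1e-5)
  expect_equal(ptrans_stay_unstable(4, 0.1, 1), 0.75804, tolerance = 1e-5)
  # symmetric degenerate case
  expect_equal(ptrans_stay_stable(3, 1e-12, 0), 0.5, tolerance = 1e-6)
  # staying stable becomes more likely after longer dominance times
  d <- seq(0.5, 300, length.out = 50)
  expect_true(all(diff(ptrans_stay_stable(d, 0.3, 20)) > 0))
  expect_error(ptrans_stay_stable(-1, 0.1, 5), "positive")
})

test_that("marginal transition probabilities equal the averaged local ones", {
  set.seed(14)
  for (k in 1:10) {
    bS <- runif(1, 5, 60); nuS <- runif(1, 0.1, 0.8)
    bU <- runif(1, 0.5, 3); nuU <- nuS * runif(1, 1, 4)
    btS <- runif(1, 0, 2 * bS); btU <- runif(1, -2, 3)
    nuB <- runif(1, 0.05, 1)
    pars <- hbmi_params(bS, nuS, bU, nuU, btS, btU, nuB)
    mt <- marginal_transitions(pars)
    quad2 <- function(ig, w) {
      up <- ig$mu + 40 * ig$sigma + 80 * ig$sigma^2 / ig$mu
      integrate(function(t) dinvgauss(t, ig$mu, ig$sigma) * w(t),
                0, ig$mu, rel.tol = 1e-11, subdivisions = 500L)$value +
        integrate(function(t) dinvgauss(t, ig$mu, ig$sigma) * w(t),
                  ig$mu, up, rel.tol = 1e-11, subdivisions = 500L)$value
    }
    quadS <- quad2(barrier_to_ig(bS, nuS),
                   function(t) ptrans_stay_stable(t, nuB, btS))
    expect_equal(mt$p_SS_star, quadS, tolerance = 1e-6)
    quadU <- quad2(barrier_to_ig(bU, nuU),
                   function(t) ptrans_stay_unstable(t, nuB, btU))
    expect_equal(mt$p_UU_star, quadU, tolerance = 1e-6)
  }
  # symmetric limit
  sym <- marginal_transitions(hbmi_params(10, 0.3, 1, 0.5, 0, 0, 1e-9))
  expect_equal(sym$p_SS_star, 0.5, tolerance = 1e-5)
  # Monte-Carlo check of the stable branch
  set.seed(15)
  pars <- fixture_hbmi("C")
  ig <- barrier_to_ig(pars$b_S, pars$nu_S_star)
  D <- rinvgauss(1e6, ig$mu, ig$sigma)
  X <- rnorm(1e6, pars$nu_B_star * D, sqrt(D))
  phat <- mean(X > pars$btilde_S)
  expect_lt(abs(marginal_transitions(pars)$p_SS_star - phat),
            3 * sqrt(phat * (1 - phat) / 1e6))
})

test_that("hierarchical forward likelihood equals path enumeration", {
  set.seed(23)
  for (k in 1:5) {
    pars <- hbmi_params(runif(1, 10, 50), runif(1, 0.2, 0.6),
                        runif(1, 0.8, 2.5), runif(1, 0.6, 1.2),
                        runif(1, 5, 60), runif(1, -2, 3),
                        runif(1, 0.05, 0.8), pi_S = runif(1))
    n <- sample(4:10, 1)
    d <- exp(runif(n, log(1), log(250)))
    expect_equal(hbmi_loglik(d, pars), enum_hbmi_loglik(d, pars),
                 tolerance = 1e-10)
  }
  pars <- fixture_hbmi("C")
  igS <- barrier_to_ig(pars$b_S, pars$nu_S_star)
  igU <- barrier_to_ig(pars$b_U, pars$nu_U_star)
  expect_equal(hbmi_loglik(7, pars),
               log(0.5 * dinvgauss(7, igS$mu, igS$sigma) +
                   0.5 * dinvgauss(7, igU$mu, igU$sigma)),
               tolerance = 1e-12)
})

test_that("an unreachable stable->unstable border reduces to the one-state likelihood", {
  pars <- fixture_hbmi("C")
  deg <- hbmi_params(pars$b_S, pars$nu_S_star, pars$b_U, pars$nu_U_star,
                     btilde_S = -1e6, btilde_U = pars$btilde_U,
                     nu_B_star = pars$nu_B_star, pi_S = 1)
  ig <- barrier_to_ig(pars$b_S, pars$nu_S_star)
  d <- c(150, 200, 90, 300, 170)
  expect_equal(hbmi_loglik(d, deg),
               sum(dinvgauss(d, ig$mu, ig$sigma, log = TRUE)),
               tolerance = 1e-10)
})

test_that("derived statistics are internally consistent", {
  pars <- fixture_hbmi("C")
  dv <- derived_params(pars)
  expect_equal(dv$mu_S_star, 2 * 41.74 / starred_drift(0.24, 0.72),
               tolerance = 1e-10)
  expect_equal(dv$mu_S_star, 187.3, tolerance = 0.01)
  expect_equal(dv$cv_S_star, dv$sigma_S_star / dv$mu_S_star,
               tolerance = 1e-10)
  expect_true(dv$mu_S_minus < dv$mu_S_plus)
  expect_true(dv$phi_S_star > 0 && dv$phi_S_star < 1)
  # one-regime models report NA for the missing state
  one <- hbmi_params(20, 0.4, NA, NA, 0, NA, 10, pi_S = 1)
  dv1 <- derived_params(one)
  expect_true(is.na(dv1$mu_U_star))
  expect_equal(dv1$phi_S_star, 1)
  expect_equal(dv1$rho, 1 / dv1$mu_S_star, tolerance = 1e-9)
})

test_that("conditional means obey the law of total expectation", {
  set.seed(33)
  for (k in 1:10) {
    bS <- runif(1, 5, 60); nuS <- runif(1, 0.15, 0.6)
    bU <- runif(1, 0.5, 3); nuU <- nuS * runif(1, 1.2, 4)
    pars <- hbmi_params(bS, nuS, bU, nuU, runif(1, 2, 1.5 * bS),
                        runif(1, -1, 2.5), runif(1, 0.05, 0.8))
    dv <- derived_params(pars)
    if (!is.finite(dv$mu_S_plus) || !is.finite(dv$mu_S_minus)) next
    expect_equal(dv$mu_S_plus * dv$p_SS_star +
                   dv$mu_S_minus * (1 - dv$p_SS_star),
                 dv$mu_S_star, tolerance = 1e-6)
    expect_equal(dv$mu_U_plus * dv$p_UU_star +
                   dv$mu_U_minus * (1 - dv$p_UU_star),
                 dv$mu_U_star, tolerance = 1e-6)
    expect_true(dv$mu_S_minus < dv$mu_S_plus)
  }
})

test_that("conditional means match direct simulation of the background endpoint", {
  pars <- fixture_hbmi("C")
  dv <- derived_params(pars)
  set.seed(44)
  ig <- barrier_to_ig(pars$b_S, pars$nu_S_star)
  D <- rinvgauss(1e6, ig$mu, ig$sigma)
  stay <- rnorm(1e6, pars$nu_B_star * D, sqrt(D)) > pars$btilde_S
  for (branch in c(TRUE, FALSE)) {
    sel <- if (branch) stay else !stay
    se <- sd(D[sel]) / sqrt(sum(sel))
    target <- if (branch) dv$mu_S_plus else dv$mu_S_minus
    expect_lt(abs(mean(D[sel]) - target), 3 * se)
  }
})

test_that("the alternation rate matches a long renewal simulation", {
  pars <- fixture_hbmi("C")
  dv <- derived_params(pars)
  sim <- simulate_hbmi(pars, 1e6, seed = 10)
  emp <- length(sim$durations) / 1e6
  expect_lt(abs(emp - dv$rho) / dv$rho, 0.02)
  # time spent stable agrees with phi_S*
  st <- attr(sim, "states")
  frac <- sum(sim$durations[st == "S"]) / sum(sim$durations)
  expect_lt(abs(frac - dv$phi_S_star), 0.02)
})

test_that("interval simulator reproduces the marginal transition probability", {
  pars <- fixture_hbmi("C")
  dv <- derived_params(pars)
  sim <- simulate_hbmi(pars, 6e5, seed = 20)
  st <- attr(sim, "states")
  fromS <- which(st[-length(st)] == "S")
  phat <- mean(st[fromS + 1] == "S")
  se <- sqrt(dv$p_SS_star * (1 - dv$p_SS_star) / length(fromS))
  expect_lt(abs(phat - dv$p_SS_star), 3 * se)
  s1 <- simulate_hbmi(pars, 5000, seed = 31)
  s2 <- simulate_hbmi(pars, 5000, seed = 31)
  expect_identical(s1$durations, s2$durations)
})

test_that("rate curve over blank length shows the inverted-U shape", {
  pars <- fixture_hbmi("C")
  # blank-display drifts decreasing in l_b and crossing nu0, as posited for
  # the stabilization of long blanks
  nu_S_fun <- function(lb) 1.6 * pars$nu0 * exp(-2.2 * lb)
  nu_U_fun <- function(lb) 3.0 * pars$nu0 * exp(-1.2 * lb)
  curve <- rate_vs_blank(pars, nu_S_fun, nu_U_fun, nu_B = 0.54,
                         l_b_grid = seq(0.05, 1.0, by = 0.05))
  k <- which.max(curve$rho)
  expect_gt(k, 1)
  expect_lt(k, nrow(curve))
  # with a constant blank drift the admissible range is l_b <= l_p nu0 / nu_S
  expect_warning(
    rate_vs_blank(pars, function(lb) rep(pars$nu0, length(lb)),
                  function(lb) rep(2 * pars$nu0, length(lb)), 0.54,
                  l_b_grid = c(0.2, 50)),
    "dropped")
})

test_that("path simulation of continuous viewing yields IG first passages", {
  pass <- vapply(1:10, function(seed) {
    ps <- simulate_hbm_path(list(b = 2.08, nu = 0.40), T = 1500, dt = 1e-3,
                            seed = seed)
    ig <- barrier_to_ig(2.08, 0.40)
    suppressWarnings(ks.test(ps$durations,
                             function(q) pinvgauss(q, ig$mu, ig$sigma))
                     )$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9)
})

test_that("path and interval simulators agree in distribution", {
  pars <- fixture_hbmi("C")
  pass <- vapply(1:10, function(seed) {
    ps <- simulate_hbm_path(pars, T = 2500, dt = 1e-3, seed = seed)
    iv <- simulate_hbmi(pars, 2500, seed = seed + 100)
    suppressWarnings(ks.test(ps$durations, iv$durations))$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9)
})

test_that("the noiseless path is a sawtooth with period 2b/nu", {
  ps <- simulate_hbm_path(list(b = 2, nu = 1), T = 50, dt = 1e-3, seed = 1,
                          diffusion = 0)
  expect_true(all(abs(ps$durations - 4) <= 1e-3 + 1e-9))
  expect_equal(length(ps$hits), floor(50 / 4))
})

test_that("the constrained fitter recovers the generating constellation", {
  pars <- fixture_hbmi("C")
  sim <- simulate_hbmi(pars, 3600, seed = 6)
  fit <- fit_hbmi(sim$durations)
  expect_identical(fit$model, "hbmi")
  dv <- fit$derived
  tv <- derived_params(pars)
  rel <- function(a, b) abs(a - b) / b
  errs <- c(rel(dv$mu_S_star, tv$mu_S_star),
            rel(dv$sigma_S_star, tv$sigma_S_star),
            rel(dv$mu_U_star, tv$mu_U_star),
            rel(dv$sigma_U_star, tv$sigma_U_star),
            abs(dv$p_SS_star - tv$p_SS_star),
            abs(dv$p_UU_star - tv$p_UU_star))
  expect_lt(mean(errs), 0.25)
})

test_that("one-regime runs reduce to the drift-diffusion fit", {
  set.seed(61)
  dS <- rinvgauss(25, 300, 40)
  fS <- fit_hbmi(dS)
  expect_identical(fS$model, "stable_only")
  expect_equal(fS$params$btilde_S, 0)
  expect_equal(fS$params$nu_B_star, 10)
  bar <- ig_to_barrier(mean(dS), invgauss_mle(dS)$sigma)
  expect_equal(fS$params$b_S, bar$b, tolerance = 1e-10)
  expect_equal(fS$derived$phi_S_star, 1)
  dU <- pmin(rinvgauss(40, 4, 2), 28)
  fU <- fit_hbmi(dU)
  expect_identical(fU$model, "unstable_only")
  expect_equal(fU$params$btilde_U, 1e10)
  expect_equal(fU$derived$phi_S_star, 0)
})

test_that("refitting data simulated from a fit reproduces its derived statistics", {
  pars <- fixture_hbmi("C")
  sim <- simulate_hbmi(pars, 3600, seed = 71)
  fit1 <- fit_hbmi(sim$durations)
  sim2 <- simulate_hbmi(fit1$params, 3600, seed = 72)
  fit2 <- fit_hbmi(sim2$durations)
  expect_identical(fit2$model, "hbmi")
  expect_lt(abs(fit2$derived$mu_S_star - fit1$derived$mu_S_star) /
              fit1$derived$mu_S_star, 0.5)
  expect_lt(abs(fit2$derived$p_SS_star - fit1$derived$p_SS_star), 0.3)
})

test_that("hbm front end handles both conditions", {
  set.seed(81)
  sc <- dominance_series(rinvgauss(30, 10.5, 8.18), condition = "continuous",
                         duration_total = 400)
  f <- fit_hbm(sc)
  expect_s3_class(f, "bphbm")
  expect_identical(f$model, "hbmc")
  expect_named(coef(f), c("b", "nu0"))
  si <- simulate_hbmi(fixture_hbmi("C"), 1500, seed = 82)
  fi <- fit_hbm(si)
  expect_true(fi$model %in%
    c("hbmi", "stable_only", "unstable_only", "one_state_fallback"))
  expect_s3_class(simulate(fi, seed = 2), "dominance_series")
  expect_output(print(summary(fi)), "alternation rate")
})
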