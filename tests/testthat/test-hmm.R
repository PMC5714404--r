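test_that("forward-backward likelihood equals path enumeration", {
  set.seed(21)
  for (k in 1:5) {
    p <- hmm_params(runif(1, 50, 200), runif(1, 10, 60),
                    runif(1, 2, 8), runif(1, 1, 5),
                    runif(1, 0.1, 0.95), runif(1, 0.1, 0.95))
    n <- sample(4:10, 1)
    d <- exp(runif(n, log(1), log(250)))
    fb <- forward_backward(d, p)
    expect_equal(fb$loglik, enum_hmm_loglik(d, p), tolerance = 1e-10)
    # normalization invariants
    expect_equal(rowSums(fb$alpha_tilde), rep(1, n), tolerance = 1e-12)
    expect_equal(rowSums(fb$gamma), rep(1, n), tolerance = 1e-12)
    if (n > 1) expect_equal(rowSums(fb$xi), rep(1, n - 1), tolerance = 1e-12)
  }
  # single observation: mixture of the two start densities
  p <- table2_rowC()
  fb1 <- forward_backward(5, p)
  expect_equal(fb1$loglik,
               log(p$pi_S * dinvgauss(5, p$mu_S, p$sigma_S) +
                   (1 - p$pi_S) * dinvgauss(5, p$mu_U, p$sigma_U)),
               tolerance = 1e-12)
})

test_that("forward recursion reports underflow with the failing index", {
  p <- hmm_params(5, 0.01, 4, 0.01, 0.5, 0.5)
  expect_error(forward_backward(c(5, 4, 4000), p), "interval 3")
})

test_that("EM iterations never decrease the log-likelihood", {
  set.seed(31)
  for (k in 1:20) {
    gen <- hmm_params(runif(1, 60, 250), runif(1, 15, 60),
                      runif(1, 2, 9), runif(1, 1, 6),
                      runif(1, 0.2, 0.9), runif(1, 0.5, 0.97))
    s <- simulate_hmm(gen, 1500)
    init <- hmm_params(80, 30, 4, 5, 0.5, 0.5)
    # pure EM update: provably monotone
    bw <- baum_welch(s$durations, init, tol = 1e-8, max_iter = 200,
                     pi_update = "em")
    expect_gt(length(bw$trace), 1)
    expect_true(all(diff(bw$trace) > -1e-9))
    # stationary-pi reset: monotone except for transient, bounded dips
    # caused by the start-distribution reset (a non-EM step)
    bws <- baum_welch(s$durations, init, tol = 1e-8, max_iter = 200)
    expect_true(all(diff(bws$trace) > -1e-3))
    expect_gt(bws$trace[length(bws$trace)], bws$trace[1] - 1e-9)
  }
})

test_that("stationary start distribution matches the transition matrix", {
  expect_equal(stationary_pi_S(0.67, 0.96), 0.10811, tolerance = 1e-4)
  # eigen check: pi P = pi
  P <- matrix(c(0.67, 0.33, 0.04, 0.96), 2, 2, byrow = TRUE)
  piv <- c(stationary_pi_S(0.67, 0.96), 1 - stationary_pi_S(0.67, 0.96))
  expect_equal(as.numeric(piv %*% P), piv, tolerance = 1e-12)
  expect_equal(stationary_pi_S(1, 1), 0.5)
})

test_that("Baum-Welch recovers a well-separated two-state pattern", {
  gen <- table2_rowC()
  set.seed(2)
  s <- simulate_hmm(gen, 3600)
  fit <- fit_two_state(s$durations)
  expect_identical(fit$model, "two_state")
  p <- fit$params
  expect_lt(abs(p$mu_S - gen$mu_S) / gen$mu_S, 0.25)
  expect_lt(abs(p$mu_U - gen$mu_U) / gen$mu_U, 0.25)
  expect_lt(abs(p$p_SS - gen$p_SS), 0.25)
  expect_lt(abs(p$p_UU - gen$p_UU), 0.25)
  expect_true(p$mu_S >= p$mu_U)  # label convention
})

test_that("one-regime runs reduce to single-state fits", {
  set.seed(12)
  dS <- rinvgauss(30, 300, 40)           # all far above 30 s
  fS <- fit_two_state(dS)
  expect_identical(fS$model, "stable_only")
  expect_equal(fS$params$p_SS, 1)
  expect_equal(fS$params$mu_S, mean(dS))
  dU <- pmin(rinvgauss(40, 4, 2), 29)    # all at or below 30 s
  fU <- fit_two_state(dU)
  expect_identical(fU$model, "unstable_only")
  expect_equal(fU$params$p_UU, 1)
})

test_that("a constructed cohort triggers the fallback for exactly the one-state subjects", {
  set.seed(77)
  one_state <- c(rep(TRUE, 7), rep(FALSE, 3))
  models <- vapply(seq_along(one_state), function(k) {
    d <- if (one_state[k]) rinvgauss(25, 250, 35)
         else simulate_hmm(table2_rowC(), 1200)$durations
    fit_two_state(d)$model
  }, character(1))
  expect_identical(models %in% c("stable_only", "unstable_only"), one_state)
})

test_that("Viterbi decoding matches brute force and breaks ties toward S", {
  p <- table2_rowC()
  expect_identical(viterbi(200, p), "S")
  # direct one-interval comparison
  expect_gt(p$pi_S * dinvgauss(200, p$mu_S, p$sigma_S),
            (1 - p$pi_S) * dinvgauss(200, p$mu_U, p$sigma_U))
  set.seed(41)
  for (k in 1:5) {
    q <- hmm_params(runif(1, 50, 150), runif(1, 10, 40),
                    runif(1, 2, 8), runif(1, 1, 5),
                    runif(1, 0.2, 0.9), runif(1, 0.2, 0.9))
    n <- sample(3:9, 1)
    d <- exp(runif(n, log(1), log(200)))
    expect_identical(viterbi(d, q), enum_viterbi(d, q))
  }
  # absorbing chains stay in the better initial state
  pa <- hmm_params(100, 20, 3, 2, 1, 1, pi_S = 0.6)
  expect_identical(unique(viterbi(c(90, 110, 95), pa)), "S")
  # exact ties (identical emissions, symmetric chain) resolve to S
  pt <- hmm_params(5, 3, 5, 3, 0.5, 0.5, pi_S = 0.5)
  expect_identical(viterbi(c(4, 6, 5), pt), c("S", "S", "S"))
})

test_that("state separation is recovered on well-separated data", {
  set.seed(8)
  gen <- hmm_params(100, 20, 3, 1.5, 0.8, 0.8)
  s <- simulate_hmm(gen, 4000)
  fit <- fit_two_state(s$durations)
  expect_identical(fit$model, "two_state")
  dec <- viterbi(s$durations, do.call(hmm_params, fit$params[1:6]))
  expect_gt(mean(dec == attr(s, "states")), 0.95)
})

test_that("phi_S matches the closed form and the long-run time fraction", {
  p <- table2_rowC()
  expect_equal(phi_stable(p), 0.81854, tolerance = 1e-5)
  expect_equal(phi_stable(hmm_params(5, 2, 5, 2, 0.7, 0.7)), 0.5)
  expect_equal(phi_stable(list(mu_S = 10, mu_U = 2, p_SS = 1, p_UU = 0.5)), 1)
  expect_equal(phi_stable(list(mu_S = 10, mu_U = 2, p_SS = 0.5, p_UU = 1)), 0)
  expect_error(phi_stable(list(mu_S = 10, mu_U = 2, p_SS = 1, p_UU = 1)),
               "absorbing")
  # long-run simulation: geometric sojourns, IG durations
  set.seed(55)
  n_runs <- 2e4
  nS <- rgeom(n_runs, 1 - p$p_SS) + 1
  nU <- rgeom(n_runs, 1 - p$p_UU) + 1
  tS <- sum(rinvgauss(sum(nS), p$mu_S, p$sigma_S))
  tU <- sum(rinvgauss(sum(nU), p$mu_U, p$sigma_U))
  expect_lt(abs(tS / (tS + tU) - phi_stable(p)) / phi_stable(p), 0.01)
})

test_that("HMM simulation honours the transition matrix and the seed", {
  p <- table2_rowC()
  s1 <- simulate_hmm(p, 2000, seed = 3)
  s2 <- simulate_hmm(p, 2000, seed = 3)
  expect_identical(s1$durations, s2$durations)
  # single-state reduction: all durations from the stable IG law
  pS <- hmm_params(20, 8, 3, 2, 1, 0.5, pi_S = 1)
  pass <- vapply(1:10, function(seed) {
    s <- simulate_hmm(pS, 4000, seed = seed)
    suppressWarnings(ks.test(s$durations,
                             function(q) pinvgauss(q, 20, 8))$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9)
  # empirical self-transition frequency within 3 binomial SE
  set.seed(13)
  pmix <- hmm_params(12, 5, 4, 2, 0.7, 0.6)
  s <- simulate_hmm(pmix, 6e5)
  st <- attr(s, "states")
  fromS <- which(st[-length(st)] == "S")
  phat <- mean(st[fromS + 1] == "S")
  se <- sqrt(0.7 * 0.3 / length(fromS))
  expect_lt(abs(phat - 0.7), 3 * se)
})

test_that("the one-state fitter returns consistent dual parameterizations", {
  est <- fit_one_state(c(1, 2, 4))
  expect_equal(est$mu, 2.3333, tolerance = 1e-4)
  expect_equal(est$sigma, 1.4022, tolerance = 1e-4)
  rt <- barrier_to_ig(est$b, est$nu)
  expect_equal(rt$mu, est$mu, tolerance = 1e-12)
  expect_equal(rt$sigma, est$sigma, tolerance = 1e-12)
})

test_that("model front end dispatches on condition and exposes methods", {
  set.seed(19)
  sc <- dominance_series(rinvgauss(30, 10.5, 8.18), condition = "continuous",
                         duration_total = 400)
  f <- fit_hmm(sc)
  expect_s3_class(f, "bphmm")
  expect_identical(f$model, "one_state")
  expect_named(coef(f), c("mu", "sigma"))
  expect_equal(as.numeric(logLik(f)), f$loglik)
  sim <- simulate(f, seed = 4)
  expect_s3_class(sim, "dominance_series")
  si <- simulate_hmm(table2_rowC(), 1200, seed = 5)
  fi <- fit_hmm(si)
  expect_true(fi$model %in%
    c("two_state", "stable_only", "unstable_only", "one_state_fallback"))
  expect_output(print(summary(fi)), "alternation rate")
})
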