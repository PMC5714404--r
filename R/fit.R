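#' Fit the hidden Markov model to a dominance-time series
#'
#' Front end dispatching on the viewing condition: continuous runs get the
#' one-state inverse-Gaussian fit (with its drift-diffusion
#' reparameterization), intermittent runs the constrained two-state
#' Baum-Welch fit of [fit_two_state()].
#'
#' @param series a `dominance_series` (or a bare vector of dominance times,
#'   taken as the stated `condition`).
#' @param condition used only when `series` is a bare vector.
#' @param ... passed to [fit_two_state()].
#' @return an object of class `bphmm` with components `model`, `params`,
#'   `loglik`, `n`, `condition` and (for one-state fits) the barrier/drift
#'   equivalents `b`, `nu`.
#' @examples
#' d <- rinvgauss(40, 10.5, 8.18)
#' fit_hmm(dominance_series(d, condition = "continuous"))
#' @export
fit_hmm <- function(series, condition = c("continuous", "intermittent"),
                    ...) {
  if (!inherits(series, "dominance_series"))
    series <- dominance_series(series, condition = match.arg(condition))
  d <- series$durations
  if (series$condition == "continuous") {
    est <- fit_one_state(d)
    out <- list(model = "one_state", condition = "continuous",
                params = list(mu = est$mu, sigma = est$sigma),
                b = est$b, nu = est$nu, loglik = est$loglik, n = est$n,
                series = series)
  } else {
    fit <- fit_two_state(d, ...)
    out <- c(fit, list(condition = "intermittent", series = series))
  }
  structure(out, class = "bphmm")
}

#' Fit the hierarchical Brownian model to a dominance-time series
#'
#' Continuous runs give the two-parameter drift-diffusion model (border `b`,
#' drift `nu0`), a pure reparameterization of the one-state
#' inverse-Gaussian fit. Intermittent runs are fitted with the constrained
#' maximum-likelihood procedure of [fit_hbmi()].
#'
#' @param series a `dominance_series` (or bare vector, with `condition`).
#' @param nu0 optional presentation drift from the same subject's continuous
#'   fit; enables decomposition of the starred drifts.
#' @param condition used only when `series` is a bare vector.
#' @param ... passed to [fit_hbmi()].
#' @return an object of class `bphbm`.
#' @export
fit_hbm <- function(series, nu0 = NULL,
                    condition = c("continuous", "intermittent"), ...) {
  if (!inherits(series, "dominance_series"))
    series <- dominance_series(series, condition = match.arg(condition))
  d <- series$durations
  if (series$condition == "continuous") {
    est <- fit_one_state(d)
    out <- list(model = "hbmc", condition = "continuous",
                params = list(b = est$b, nu0 = est$nu),
                ig = list(mu = est$mu, sigma = est$sigma),
                loglik = est$loglik, n = est$n, series = series)
  } else {
    fit <- fit_hbmi(d, nu0 = nu0, l_p = series$l_p, l_b = series$l_b, ...)
    out <- c(fit, list(condition = "intermittent", series = series))
  }
  structure(out, class = "bphbm")
}

#' @export
print.bphmm <- function(x, ...) {
  if (x$model == "one_state") {
    cat("One-state inverse-Gaussian model (continuous viewing)\n")
    cat(sprintf("  mu = %.2f s, sigma = %.2f s  (b = %.2f, nu0 = %.2f)\n",
                x$params$mu, x$params$sigma, x$b, x$nu))
  } else {
    cat(sprintf("Two-state HMM (intermittent viewing), fit: %s\n", x$model))
    p <- x$params
    cat(sprintf("  stable:   mu_S = %.2f, sigma_S = %.2f, p_SS = %.2f\n",
                p$mu_S, p$sigma_S, p$p_SS))
    cat(sprintf("  unstable: mu_U = %.2f, sigma_U = %.2f, p_UU = %.2f\n",
                p$mu_U, p$sigma_U, p$p_UU))
  }
  cat(sprintf("  log-likelihood %.2f on n = %d dominance times\n",
              x$loglik, x$n))
  invisible(x)
}

#' @export
coef.bphmm <- function(object, ...) {
  unlist(object$params)
}

#' @export
logLik.bphmm <- function(object, ...) {
  df <- if (object$model == "two_state") 6 else 2
  structure(object$loglik, df = df, nobs = object$n, class = "logLik")
}

#' @export
summary.bphmm <- function(object, ...) {
  out <- list(fit = object)
  if (object$model %in% c("two_state", "stable_only", "unstable_only"))
    out$phi_S <- tryCatch(phi_stable(object$params), error = function(e) NA)
  if (object$model == "two_state")
    out$states <- viterbi(object$series,
                          do.call(hmm_params, object$params[1:6]))
  out$alternation_rate <- object$n / object$series$duration_total
  class(out) <- "summary.bphmm"
  out
}

#' @export
print.summary.bphmm <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$phi_S) && is.finite(x$phi_S))
    cat(sprintf("  expected fraction of time stable phi_S = %.3f\n", x$phi_S))
  if (!is.null(x$states))
    cat(sprintf("  Viterbi: %d stable / %d unstable intervals\n",
                sum(x$states == "S"), sum(x$states == "U")))
  cat(sprintf("  empirical alternation rate = %.3f /s\n",
              x$alternation_rate))
  invisible(x)
}

#' @export
simulate.bphmm <- function(object, nsim = 1, seed = NULL, T = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(T)) T <- object$series$duration_total
  sims <- lapply(seq_len(nsim), function(k) {
    if (object$model == "one_state") {
      sim_ig_run(object$params$mu, object$params$sigma, T)
    } else if (object$model == "two_state") {
      simulate_hmm(do.call(hmm_params, object$params[1:6]), T)
    } else {
      p <- object$params
      if (isTRUE(p$p_SS == 1)) sim_ig_run(p$mu_S, p$sigma_S, T)
      else sim_ig_run(p$mu_U, p$sigma_U, T)
    }
  })
  if (nsim == 1) sims[[1]] else sims
}

#' @export
simulate.bphbm <- function(object, nsim = 1, seed = NULL, T = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(T)) T <- object$series$duration_total
  sims <- lapply(seq_len(nsim), function(k) {
    if (object$model == "hbmc") {
      sim_ig_run(object$ig$mu, object$ig$sigma, T)
    } else {
      simulate_hbmi(object$params, T)
    }
  })
  if (nsim == 1) sims[[1]] else sims
}

# i.i.d. inverse-Gaussian run truncated at T
sim_ig_run <- function(mu, sigma, T) {
  # draw in blocks sized by the expected count
  dur <- numeric(0)
  total <- 0
  repeat {
    blk <- rinvgauss(max(16L, ceiling(1.3 * (T - total) / mu)), mu, sigma)
    cs <- total + cumsum(blk)
    over <- which(cs > T)
    if (length(over) > 0) {
      dur <- c(dur, blk[seq_len(over[1] - 1L)])
      break
    }
    dur <- c(dur, blk)
    total <- cs[length(cs)]
  }
  if (length(dur) == 0) dur <- T  # no switch: one censored interval
  dominance_series(dur, rep(c("L", "R"), length.out = length(dur)),
                   condition = "continuous", duration_total = T,
                   truncated = TRUE)
}

#' @export
print.bphbm <- function(x, ...) {
  if (x$model == "hbmc") {
    cat("Drift-diffusion model (continuous viewing)\n")
    cat(sprintf("  border b = %.2f, drift nu0 = %.2f  (mu = %.2f, sigma = %.2f)\n",
                x$params$b, x$params$nu0, x$ig$mu, x$ig$sigma))
  } else {
    cat(sprintf("Hierarchical Brownian model (intermittent viewing), fit: %s\n",
                x$model))
    p <- x$params
    cat(sprintf("  b_S = %.2f, nu_S* = %.3f, b_U = %.2f, nu_U* = %.3f\n",
                p$b_S, p$nu_S_star, p$b_U, p$nu_U_star))
    cat(sprintf("  btilde_S = %.2f, btilde_U = %.2f, nu_B* = %.3f\n",
                p$btilde_S, p$btilde_U, p$nu_B_star))
    d <- x$derived
    cat(sprintf("  derived: mu_S* = %.2f, mu_U* = %.2f, p_SS* = %.3f, p_UU* = %.3f\n",
                d$mu_S_star, d$mu_U_star, d$p_SS_star, d$p_UU_star))
  }
  cat(sprintf("  log-likelihood %.2f on n = %d dominance times\n",
              x$loglik, x$n))
  invisible(x)
}

#' @export
coef.bphbm <- function(object, ...) {
  if (object$model == "hbmc") unlist(object$params)
  else unlist(object$params[c("b_S", "nu_S_star", "b_U", "nu_U_star",
                              "btilde_S", "btilde_U", "nu_B_star")])
}

#' @export
logLik.bphbm <- function(object, ...) {
  df <- if (object$model == "hbmi") 7 else 2
  structure(object$loglik, df = df, nobs = object$n, class = "logLik")
}

#' @export
summary.bphbm <- function(object, ...) {
  out <- list(fit = object)
  if (object$model != "hbmc") {
    out$derived <- object$derived
    out$rho <- object$derived$rho
  } else {
    out$rho <- 1 / object$ig$mu
  }
  out$alternation_rate <- object$n / object$series$duration_total
  class(out) <- "summary.bphbm"
  out
}

#' @export
print.summary.bphbm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  model alternation rate rho = %.4f /s (empirical %.4f /s)\n",
              x$rho, x$alternation_rate))
  invisible(x)
}

#' Plot a fitted response pattern
#'
#' Draws the observed dominance times as a percept step function over time
#' and, for two-regime fits, shades the decoded stable intervals.
#'
#' @param x a `bphmm` or `bphbm` fit.
#' @param ... ignored.
#' @export
plot.bphmm <- function(x, ...) {
  plot_pattern(x$series, fit = x)
}

#' @export
plot.bphbm <- function(x, ...) {
  plot_pattern(x$series, fit = NULL)
}

plot_pattern <- function(series, fit = NULL) {
  d <- series$durations
  edges <- c(0, cumsum(d))
  perc <- series$percepts
  if (is.null(perc)) perc <- rep(c("L", "R"), length.out = length(d))
  y <- ifelse(perc == "L", 1, -1)
  plot(NA, xlim = c(0, series$duration_total), ylim = c(-1.5, 1.5),
       xlab = "time (s)", ylab = "percept", yaxt = "n",
       main = sprintf("%s viewing", series$condition))
  axis(2, at = c(-1, 1), labels = c("R", "L"))
  if (!is.null(fit) && identical(fit$model, "two_state")) {
    st <- viterbi(series, do.call(hmm_params, fit$params[1:6]))
    for (i in which(st == "S"))
      rect(edges[i], -1.5, edges[i + 1], 1.5, col = "grey90", border = NA)
  }
  segments(edges[-length(edges)], y, edges[-1], y, lwd = 2)
  invisible(NULL)
}
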