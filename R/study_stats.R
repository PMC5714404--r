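#' Likelihood-ratio test for equality of two inverse-Gaussian samples
#'
#' Tests the null hypothesis that two samples of dominance times share the
#' same inverse-Gaussian mean and standard deviation. With sample means
#' `mu_i` and reciprocal sums `S_i = sum(1/d_ij - 1/mu_i)`, the pooled term
#' is `S3 = n1/mu1 + n2/mu2 - n^2 / (n1 mu1 + n2 mu2)` (so that
#' `S = S1 + S2 + S3` equals the reciprocal sum about the pooled mean) and
#' the likelihood ratio is
#' `Qn = prod_i (n/n_i)^(n_i/2) (S_i/S)^(n_i/2)`. The Bartlett-corrected
#' statistic `Qn_star = -2 (1 - (1/n1 + 1/n2)/6 - 1/(12 n)) log(Qn)` is
#' compared with the chi-square distribution with two degrees of freedom;
#' the null is rejected at the 5% level when `Qn_star` exceeds its 95%
#' quantile.
#'
#' @param d1,d2 numeric vectors of dominance times (each of length >= 2,
#'   not all equal).
#' @return list of class `ig_lrt` with `Qn`, `Qn_star`, `S1`, `S2`, `S3`,
#'   `S`, `p_value`, `reject`, `n1`, `n2`.
#' @export
lrt_ig_equal <- function(d1, d2) {
  if (length(d1) < 2 || length(d2) < 2)
    stop("both samples need at least two dominance times")
  if (any(c(d1, d2) <= 0)) stop("dominance times must be positive")
  n1 <- length(d1); n2 <- length(d2); n <- n1 + n2
  mu1 <- mean(d1); mu2 <- mean(d2)
  S1 <- sum(1 / d1 - 1 / mu1)
  S2 <- sum(1 / d2 - 1 / mu2)
  if (S1 <= 0 || S2 <= 0)
    stop("degenerate sample: zero reciprocal dispersion")
  S3 <- n1 / mu1 + n2 / mu2 - n^2 / (n1 * mu1 + n2 * mu2)
  S <- S1 + S2 + S3
  logQn <- (n1 / 2) * (log(n / n1) + log(S1 / S)) +
    (n2 / 2) * (log(n / n2) + log(S2 / S))
  Qn_star <- -2 * (1 - (1 / n1 + 1 / n2) / 6 - 1 / (12 * n)) * logQn
  p <- pchisq(Qn_star, df = 2, lower.tail = FALSE)
  structure(list(Qn = exp(logQn), Qn_star = Qn_star, S1 = S1, S2 = S2,
                 S3 = S3, S = S, p_value = p,
                 reject = Qn_star > qchisq(0.95, 2), n1 = n1, n2 = n2),
            class = "ig_lrt")
}

#' @export
print.ig_lrt <- function(x, ...) {
  cat("Likelihood-ratio test: equality of two inverse-Gaussian samples\n")
  cat(sprintf("  Qn* = %.3f, df = 2, p = %.4f (%s at 5%%)\n", x$Qn_star,
              x$p_value, if (x$reject) "rejected" else "not rejected"))
  invisible(x)
}

#' Parametric bootstrap study of estimation precision
#'
#' Simulates `n_sim` response patterns of length `T` from a known parameter
#' set, refits each with the corresponding estimator, and summarizes the
#' per-parameter errors: relative errors `|est - true| / true` for means,
#' standard deviations and borders, absolute errors for transition
#' probabilities and starred drifts. A constellation is conventionally
#' called reliably estimable when the mean of the per-parameter median
#' errors is below 0.25.
#'
#' @param true_params generating parameters: a list with `mu`, `sigma` for
#'   `model = "one_state"`, an `hmm_params` for `"two_state"`, an
#'   `hbmi_params` for `"hbmi"`.
#' @param model which fitter/simulator pair to study.
#' @param T run length of each simulated pattern (s).
#' @param n_sim number of bootstrap replicates.
#' @param seed optional integer seed.
#' @param ... passed to the fitter (e.g. `n_polish` for `"hbmi"`).
#' @return list of class `precision_report`: `median_errors` (named; for
#'   `"hbmi"` two vectors, `raw` and `derived`), `mean_error` (mean of the
#'   medians; for `"hbmi"` one per parameterization), `pass` (mean error
#'   < 0.25), `n_sim`, `n_fail` (replicates whose fit degenerated or
#'   errored, excluded from the medians) and `T`.
#' @export
bootstrap_precision <- function(true_params,
                                model = c("one_state", "two_state", "hbmi"),
                                T, n_sim = 1000, seed = NULL, ...) {
  model <- match.arg(model)
  stopifnot(n_sim >= 1, T > 0)
  if (!is.null(seed)) set.seed(seed)

  if (model == "one_state") {
    truth <- c(mu = true_params$mu, sigma = true_params$sigma)
    err <- matrix(NA_real_, n_sim, 2, dimnames = list(NULL, names(truth)))
    n_fail <- 0L
    for (k in seq_len(n_sim)) {
      est <- tryCatch({
        s <- sim_ig_run(truth["mu"], truth["sigma"], T)
        invgauss_mle(s$durations)
      }, error = function(e) NULL)
      if (is.null(est)) { n_fail <- n_fail + 1L; next }
      err[k, ] <- abs(c(est$mu, est$sigma) - truth) / truth
    }
    med <- apply(err, 2, median, na.rm = TRUE)
    return(structure(list(median_errors = med, mean_error = mean(med),
                          pass = mean(med) < 0.25, n_sim = n_sim,
                          n_fail = n_fail, T = T, model = model),
                     class = "precision_report"))
  }

  if (model == "two_state") {
    p <- true_params
    truth <- c(mu_S = p$mu_S, sigma_S = p$sigma_S, mu_U = p$mu_U,
               sigma_U = p$sigma_U, p_SS = p$p_SS, p_UU = p$p_UU)
    rel <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
    err <- matrix(NA_real_, n_sim, 6, dimnames = list(NULL, names(truth)))
    n_fail <- 0L
    for (k in seq_len(n_sim)) {
      fit <- tryCatch({
        s <- simulate_hmm(p, T)
        fit_two_state(s$durations, ...)
      }, error = function(e) NULL)
      if (is.null(fit) || fit$model != "two_state") {
        n_fail <- n_fail + 1L
        next
      }
      est <- unlist(fit$params[names(truth)])
      err[k, ] <- ifelse(rel, abs(est - truth) / truth, abs(est - truth))
    }
    med <- apply(err, 2, median, na.rm = TRUE)
    return(structure(list(median_errors = med, mean_error = mean(med),
                          pass = mean(med) < 0.25, n_sim = n_sim,
                          n_fail = n_fail, T = T, model = model),
                     class = "precision_report"))
  }

  # hbmi: errors in the raw (borders/drifts) and the derived
  # (means/sds/transition probabilities) parameterizations
  p <- true_params
  stopifnot(inherits(p, "hbmi_params"))
  truth_raw <- c(b_S = p$b_S, b_U = p$b_U, btilde_S = p$btilde_S,
                 btilde_U = p$btilde_U, nu_S_star = p$nu_S_star,
                 nu_U_star = p$nu_U_star, nu_B_star = p$nu_B_star)
  rel_raw <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  dtrue <- derived_params(p)
  truth_der <- c(mu_S_star = dtrue$mu_S_star, sigma_S_star = dtrue$sigma_S_star,
                 mu_U_star = dtrue$mu_U_star, sigma_U_star = dtrue$sigma_U_star,
                 p_SS_star = dtrue$p_SS_star, p_UU_star = dtrue$p_UU_star)
  rel_der <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  err_raw <- matrix(NA_real_, n_sim, 7, dimnames = list(NULL, names(truth_raw)))
  err_der <- matrix(NA_real_, n_sim, 6, dimnames = list(NULL, names(truth_der)))
  n_fail <- 0L
  for (k in seq_len(n_sim)) {
    fit <- tryCatch({
      s <- simulate_hbmi(p, T)
      fit_hbmi(s$durations, l_p = p$l_p, l_b = p$l_b, ...)
    }, error = function(e) NULL)
    if (is.null(fit) || fit$model != "hbmi") { n_fail <- n_fail + 1L; next }
    q <- fit$params
    est_raw <- c(q$b_S, q$b_U, q$btilde_S, q$btilde_U, q$nu_S_star,
                 q$nu_U_star, q$nu_B_star)
    err_raw[k, ] <- ifelse(rel_raw, abs(est_raw - truth_raw) / truth_raw,
                           abs(est_raw - truth_raw))
    dd <- fit$derived
    est_der <- c(dd$mu_S_star, dd$sigma_S_star, dd$mu_U_star,
                 dd$sigma_U_star, dd$p_SS_star, dd$p_UU_star)
    err_der[k, ] <- ifelse(rel_der, abs(est_der - truth_der) / truth_der,
                           abs(est_der - truth_der))
  }
  med_raw <- apply(err_raw, 2, median, na.rm = TRUE)
  med_der <- apply(err_der, 2, median, na.rm = TRUE)
  structure(list(median_errors = list(raw = med_raw, derived = med_der),
                 mean_error = c(raw = mean(med_raw), derived = mean(med_der)),
                 pass = c(raw = mean(med_raw) < 0.25,
                          derived = mean(med_der) < 0.25),
                 n_sim = n_sim, n_fail = n_fail, T = T, model = model),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("Parametric bootstrap precision (%s, T = %g s, %d replicates, %d failures)\n",
              x$model, x$T, x$n_sim, x$n_fail))
  if (is.list(x$median_errors)) {
    cat("  median errors (raw):     ")
    print(round(x$median_errors$raw, 3))
    cat("  median errors (derived): ")
    print(round(x$median_errors$derived, 3))
  } else {
    cat("  median errors: ")
    print(round(x$median_errors, 3))
  }
  cat("  mean error: ", paste(round(x$mean_error, 3), collapse = " / "),
      "; pass(<0.25): ", paste(x$pass, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Cumulative-history correlation with a permutation null
#'
#' Measures long-term dependence of dominance times on an exponentially
#' filtered trace of past dominance. For each percept a history variable
#' relaxes toward 1 while that percept is dominant and toward 0 otherwise,
#' with time constant `tau`; the statistic `c_H` is the Pearson correlation
#' between each dominance time and the history of its own percept evaluated
#' at its onset. Significance is assessed one-sidedly against `n_perm`
#' permutations of the dominance times (percept sequence kept fixed), with
#' the observed statistic included in the null set.
#'
#' @param series a `dominance_series` with percept labels and at least five
#'   dominance times.
#' @param tau history time constant (s); defaults to the mean dominance
#'   time of the series.
#' @param n_perm number of permutations (0: statistic only, no p-value).
#' @param seed optional integer seed.
#' @return list of class `history_result` with `c_H`, `p_perm`, `n_perm`,
#'   `tau`.
#' @export
cumulative_history <- function(series, tau = NULL, n_perm = 1000,
                               seed = NULL) {
  stopifnot(inherits(series, "dominance_series"))
  d <- series$durations
  if (length(d) < 5)
    stop("excluded: fewer than five dominance times")
  perc <- series$percepts
  if (is.null(perc)) stop("percept labels are required")
  if (is.null(tau)) tau <- mean(d)
  if (!is.null(seed)) set.seed(seed)

  ch <- history_corr(d, perc, tau)
  p <- NA_real_
  if (n_perm > 0) {
    perm <- replicate(n_perm, history_corr(sample(d), perc, tau))
    p <- (1 + sum(perm >= ch)) / (n_perm + 1)
  }
  structure(list(c_H = ch, p_perm = p, n_perm = n_perm, tau = tau),
            class = "history_result")
}

# correlation of dominance times with the history of their own percept at
# onset; the first interval has no defined history and is skipped
history_corr <- function(d, perc, tau) {
  n <- length(d)
  h <- c(0, 0)
  lab <- unique(perc)
  H <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    j <- match(perc[i], lab)
    dec <- exp(-d[i] / tau)
    h[j] <- 1 + (h[j] - 1) * dec
    h[-j] <- h[-j] * dec
    H[i] <- h[match(perc[i + 1], lab)]
  }
  suppressWarnings(cor(d[-1], H))
}

#' @export
print.history_result <- function(x, ...) {
  cat(sprintf("Cumulative-history correlation c_H = %.3f (tau = %.1f s)\n",
              x$c_H, x$tau))
  if (!is.na(x$p_perm))
    cat(sprintf("  one-sided permutation p = %.4f (%d permutations)\n",
                x$p_perm, x$n_perm))
  invisible(x)
}

#' Two-group comparison of a per-subject metric
#'
#' Two-sided Wilcoxon rank-sum comparison with the group medians and
#' quartiles used in the figures of two-group dominance-time studies.
#'
#' @param metric numeric vector, one value per subject.
#' @param group factor or character vector of group labels (two levels).
#' @return list with `p_value`, `medians`, `q25`, `q75`, `n` (per group).
#' @export
group_compare <- function(metric, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  keep <- is.finite(metric)
  metric <- metric[keep]; group <- droplevels(group[keep])
  if (any(table(group) == 0)) stop("both groups must be non-empty")
  w <- suppressWarnings(wilcox.test(metric ~ group))
  list(p_value = w$p.value,
       medians = tapply(metric, group, median),
       q25 = tapply(metric, group, quantile, probs = 0.25),
       q75 = tapply(metric, group, quantile, probs = 0.75),
       n = table(group))
}
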