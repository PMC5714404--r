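#' Read and write dominance-time data as CSV
#'
#' The on-disk schema is one row per dominance time with columns
#' `subject_id`, `condition` ("continuous"/"intermittent"), `run_id`,
#' `duration_s` and optionally `percept` ("L"/"R"). Rows are grouped by
#' subject, condition and run into `dominance_series` objects; timing
#' metadata (`l_p`, `l_b`) use the package defaults of 0.6 s and 0.8 s
#' unless matching columns are present.
#'
#' @param path file path.
#' @return `read_dominance_csv`: a named list of `dominance_series`
#'   (names `subject.condition.run`).
#' @export
read_dominance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"run_id" %in% names(df)) df$run_id <- 1L
  bad <- which(!is.finite(df$duration_s) | df$duration_s <= 0)
  if (length(bad) > 0)
    stop("non-positive or missing duration_s in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(!df$condition %in% c("continuous", "intermittent"))
  if (length(bad) > 0)
    stop("unknown condition in rows: ", paste(utils::head(bad, 10),
                                              collapse = ", "))
  key <- interaction(df$subject_id, df$condition, df$run_id, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    dominance_series(
      g$duration_s,
      percepts = if ("percept" %in% names(df)) g$percept else NULL,
      condition = g$condition[1],
      l_p = if ("l_p" %in% names(df)) g$l_p[1] else 0.6,
      l_b = if ("l_b" %in% names(df)) g$l_b[1] else 0.8,
      duration_total = if ("T" %in% names(df)) g$T[1] else NULL,
      subject = as.character(g$subject_id[1]))
  })
  out
}

#' @param series_list a named list of `dominance_series` (as returned by
#'   [read_dominance_csv()] or [generate_cohort()]).
#' @rdname read_dominance_csv
#' @export
write_dominance_csv <- function(series_list, path) {
  if (inherits(series_list, "dominance_series"))
    series_list <- list(series_list)
  rows <- lapply(seq_along(series_list), function(k) {
    s <- series_list[[k]]
    data.frame(
      subject_id = if (!is.na(s$subject)) s$subject else as.character(k),
      condition = s$condition,
      run_id = 1L,
      duration_s = s$durations,
      percept = if (!is.null(s$percepts)) s$percepts else NA_character_,
      l_p = s$l_p, l_b = s$l_b, T = s$duration_total)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Convert a raw response stream to dominance times
#'
#' Two stream types are supported. An event stream (continuous viewing)
#' is a vector of button-press times: dominance times are the spans between
#' consecutive presses; the leading span before the first press is
#' undefined and dropped, the span running into the end of the trial is
#' truncated and dropped (flagged). Coincident events are resolved by
#' keeping the latest. A slot stream (intermittent viewing) is a vector of
#' percept reports on a regular grid of `slot` seconds with `NA` for
#' missing responses: missing slots are imputed by carrying the preceding
#' response forward, leading missing slots are dropped, and dominance times
#' are the lengths of constant-percept runs times the slot length; the
#' final, ongoing run is truncated and dropped.
#'
#' @param times event times (s), for an event stream.
#' @param percepts percept labels: one per event (event stream) or one per
#'   slot with `NA` for missing (slot stream).
#' @param slot slot length (s) of the report grid (default 1.4 = 0.6 + 0.8).
#' @param T trial length (s); required for event streams.
#' @param l_p,l_b timing stored in the result.
#' @return a `dominance_series` with `truncated = TRUE`.
#' @export
stream_to_dominance <- function(times = NULL, percepts = NULL, slot = 1.4,
                                T = NULL, l_p = 0.6, l_b = 0.8) {
  if (!is.null(times)) {
    if (is.null(T)) T <- max(times)
    o <- order(times)
    times <- times[o]
    if (!is.null(percepts)) percepts <- percepts[o]
    dup <- duplicated(times, fromLast = TRUE)   # keep the latest event
    times <- times[!dup]
    if (!is.null(percepts)) {
      percepts <- percepts[!dup]
      # an event repeating the current percept is not a percept change
      change <- c(TRUE, percepts[-1] != percepts[-length(percepts)])
      times <- times[change]
      percepts <- percepts[change]
    }
    if (length(times) < 2)
      stop("need at least two events to define a dominance time")
    dur <- diff(times)
    perc <- if (!is.null(percepts)) percepts[-length(percepts)] else NULL
    return(dominance_series(dur, perc, condition = "continuous",
                            duration_total = T, truncated = TRUE))
  }
  if (is.null(percepts) || all(is.na(percepts)))
    stop("all responses missing: cannot build a dominance series")
  first <- which(!is.na(percepts))[1]
  percepts <- percepts[first:length(percepts)]   # drop leading undefined span
  filled <- percepts
  for (i in seq_along(filled))
    if (is.na(filled[i])) filled[i] <- filled[i - 1]
  r <- rle(filled)
  if (length(r$lengths) < 2)
    stop("no percept change: cannot build a dominance series")
  keep <- seq_len(length(r$lengths) - 1)         # final run is ongoing
  dominance_series(r$lengths[keep] * slot, r$values[keep],
                   condition = "intermittent", l_p = l_p, l_b = l_b,
                   duration_total = length(percepts) * slot,
                   truncated = TRUE)
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults emulate the structure of a two-group bistable-perception study:
#' 32 controls and 29 patients, one continuous run of 240 s and one
#' intermittent run of 1200 s per subject (presentations of 0.6 s, blanks
#' of 0.8 s). Subject-level parameters are drawn from log-normal
#' hyper-distributions centred on typical fitted values; the group effects
#' reproduce the reported directions: patients have longer continuous
#' dominance times (lower alternation rate), a larger stable background
#' border (hence a lower probability of staying stable and a higher
#' intermittent alternation rate) and longer unstable dominance times.
#'
#' @param n_control,n_patient group sizes.
#' @param T_continuous,T_intermittent run lengths (s).
#' @param l_p,l_b presentation and blank lengths (s).
#' @param mu_cont median continuous mean dominance time of controls (s).
#' @param cv_cont mean coefficient of variation of continuous dominance
#'   times.
#' @param mu_S,cv_S median stable-state mean (s) and CV (intermittent).
#' @param mu_U,cv_U median unstable-state mean (s) and CV.
#' @param btilde_S,btilde_U,nu_B median background borders and drift.
#' @param effect_mu_cont,effect_btilde_S,effect_mu_U multiplicative patient
#'   effects (1 = no effect).
#' @param sdlog log-scale spread of the subject-level draws.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 32, n_patient = 29,
                        T_continuous = 240, T_intermittent = 1200,
                        l_p = 0.6, l_b = 0.8,
                        mu_cont = 8, cv_cont = 0.79,
                        mu_S = 150, cv_S = 0.25, mu_U = 5, cv_U = 0.7,
                        btilde_S = 40, btilde_U = 2, nu_B = 0.4,
                        effect_mu_cont = 1.5, effect_btilde_S = 2.5,
                        effect_mu_U = 1.4, sdlog = 0.35) {
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort of dominance-time series
#'
#' Draws subject-level parameters from the hyper-distributions of a
#' [cohort_spec()], simulates one continuous (i.i.d. inverse-Gaussian,
#' equivalently drift-diffusion first passages) and one intermittent
#' (hierarchical Brownian) run per subject, and keeps the generating
#' parameters as ground truth for recovery studies.
#'
#' @param spec a `cohort_spec`.
#' @param seed optional integer seed.
#' @return list of class `bp_cohort` with `subjects` (data.frame:
#'   `subject_id`, `group`), `continuous` and `intermittent` (named lists
#'   of `dominance_series`), and `truth` (per-subject generating
#'   parameters).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  groups <- c(rep("control", spec$n_control), rep("patient", spec$n_patient))
  ids <- sprintf("s%02d", seq_along(groups))
  continuous <- intermittent <- truth <- vector("list", length(ids))
  names(continuous) <- names(intermittent) <- names(truth) <- ids

  rln <- function(center, sdlog = spec$sdlog) rlnorm(1, log(center), sdlog)
  for (k in seq_along(ids)) {
    patient <- groups[k] == "patient"
    # continuous: one-state IG
    mu_c <- rln(spec$mu_cont * if (patient) spec$effect_mu_cont else 1)
    cv_c <- min(max(rnorm(1, spec$cv_cont, 0.08), 0.35), 1.3)
    sig_c <- cv_c * mu_c
    bar <- ig_to_barrier(mu_c, sig_c)
    # intermittent: hierarchical model, built from target means and CVs
    mu_S <- rln(spec$mu_S)
    cv_S <- min(max(rnorm(1, spec$cv_S, 0.05), 0.1), 0.6)
    mu_U <- rln(spec$mu_U * if (patient) spec$effect_mu_U else 1, 0.25)
    cv_U <- min(max(rnorm(1, spec$cv_U, 0.1), 0.3), 1.1)
    barS <- ig_to_barrier(mu_S, cv_S * mu_S)
    barU <- ig_to_barrier(mu_U, cv_U * mu_U)
    btS <- rln(spec$btilde_S * if (patient) spec$effect_btilde_S else 1, 0.25)
    btU <- rln(spec$btilde_U, 0.3)
    nuB <- rln(spec$nu_B, 0.25)
    pars <- hbmi_params(barS$b, barS$nu, min(barU$b, barS$b), barU$nu,
                        btS, btU, nuB, pi_S = 0.5, nu0 = bar$nu,
                        l_p = spec$l_p, l_b = spec$l_b)
    # start the run from the model's long-run state occupancy so that short
    # windows are not biased by an arbitrary initial state
    dv <- derived_params(pars)
    pars$pi_S <- dv$phi_S_star
    continuous[[k]] <- sim_ig_run(mu_c, sig_c, spec$T_continuous)
    continuous[[k]]$subject <- ids[k]
    intermittent[[k]] <- simulate_hbmi(pars, spec$T_intermittent)
    intermittent[[k]]$subject <- ids[k]
    truth[[k]] <- list(mu_cont = mu_c, sigma_cont = sig_c, b = bar$b,
                       nu0 = bar$nu, hbmi = pars, derived = dv)
  }
  structure(list(spec = spec,
                 subjects = data.frame(subject_id = ids, group = groups,
                                       stringsAsFactors = FALSE),
                 continuous = continuous, intermittent = intermittent,
                 truth = truth),
            class = "bp_cohort")
}

#' @export
print.bp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d controls, %d patients\n",
              sum(x$subjects$group == "control"),
              sum(x$subjects$group == "patient")))
  cat(sprintf("  continuous runs of %g s, intermittent runs of %g s\n",
              x$spec$T_continuous, x$spec$T_intermittent))
  invisible(x)
}
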