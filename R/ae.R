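#' Ordinal adverse-event model parameters
#'
#' Parameters of the proportional-odds Grade 0/1/2 adverse-event model with
#' Markov components. Transition logits depend on the previous grade through
#' an anchor/increment pair on the cumulative-logit scale, and on plasma
#' concentration through a saturable (Emax) logit shift whose maximum depends
#' on whether the previous grade was 0 or >= 1.
#'
#' With previous grade `g` and drug effect `DE`, the cumulative logits are
#' `L1 = anchor(g) + DE` for grade >= 1 and `L2 = anchor(g) + increment(g) +
#' DE` for grade >= 2, with mapping `g = 0 -> (b01, b02)`, `g = 1 -> (b11,
#' b12)`, `g = 2 -> (b21, b22)`. Defaults are the example-scenario estimates
#' (B01 -6.59, B02 -1.80, B11 0.311, B12 -6.70, B21 -0.563, B22 -0.684, Emax0
#' 4.73, Emax1 1.09, EC50 6.05 ng/mL, 10% IIV on every parameter). The
#' `emax_scale` multiplier scales both Emax parameters together and is the
#' drug-effect magnitude knob of the study grid.
#'
#' @param b01,b02,b11,b12,b21,b22 transition logit parameters (logit scale).
#'   The increments `b02`, `b12`, `b22` must be <= 0 at typical values so that
#'   the cumulative probabilities are ordered.
#' @param emax0 maximal logit drug effect when the previous grade is 0.
#' @param emax1 maximal logit drug effect when the previous grade is >= 1.
#' @param ec50 concentration of half-maximal effect (ng/mL).
#' @param cv fractional IIV applied to every AE parameter.
#' @param emax_scale dimensionless multiplier applied to both Emax parameters.
#' @return An object of class `ae_parameters`.
#' @examples
#' ae_parameters(emax_scale = 0.5)
#' @export
ae_parameters <- function(b01 = -6.59, b02 = -1.80, b11 = 0.311, b12 = -6.70,
                          b21 = -0.563, b22 = -0.684,
                          emax0 = 4.73, emax1 = 1.09, ec50 = 6.05,
                          cv = 0.10, emax_scale = 1) {
  stopifnot(ec50 > 0, emax_scale >= 0, cv >= 0)
  if (b02 > 0 || b12 > 0 || b22 > 0) {
    stop("cumulative-logit increments (b02, b12, b22) must be <= 0 at typical values",
         call. = FALSE)
  }
  structure(
    list(b01 = b01, b02 = b02, b11 = b11, b12 = b12, b21 = b21, b22 = b22,
         emax0 = emax0, emax1 = emax1, ec50 = ec50, cv = cv,
         emax_scale = emax_scale),
    class = "ae_parameters"
  )
}

#' @export
print.ae_parameters <- function(x, ...) {
  cat("Proportional-odds Markov adverse-event parameters\n")
  cat(sprintf("  anchors    B01 %7.3f  B11 %7.3f  B21 %7.3f\n", x$b01, x$b11, x$b21))
  cat(sprintf("  increments B02 %7.3f  B12 %7.3f  B22 %7.3f\n", x$b02, x$b12, x$b22))
  cat(sprintf("  Emax0 %.3f  Emax1 %.3f  (scale %.3g)  EC50 %.3f ng/mL  IIV CV %.1f%%\n",
              x$emax0, x$emax1, x$emax_scale, x$ec50, 100 * x$cv))
  invisible(x)
}

#' Sample individual adverse-event parameters
#'
#' Strictly positive parameters (Emax0, Emax1, EC50) are perturbed
#' log-normally with `sigma^2 = log(1 + CV^2)`; sign-indefinite logit
#' parameters (B01..B22) are perturbed additively with a normal deviate of
#' standard deviation `CV * |typical|` (a log-normal is undefined for negative
#' typical values). Per-subject sub-streams as in [sample_individual_pk()].
#' The `emax_scale` multiplier carries no IIV.
#'
#' @param params an [ae_parameters()] object.
#' @param n number of subjects (>= 1).
#' @param seed master seed.
#' @return A data frame of class `individual_ae`, one row per subject, with
#'   realized values of the nine model parameters plus `emax_scale`.
#' @examples
#' sample_individual_ae(ae_parameters(), n = 3, seed = 1)
#' @export
sample_individual_ae <- function(params, n, seed) {
  stopifnot(inherits(params, "ae_parameters"))
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  logit_names <- c("b01", "b02", "b11", "b12", "b21", "b22")
  pos_names <- c("emax0", "emax1", "ec50")
  s_log <- sqrt(log(1 + params$cv^2))
  draws <- matrix(0, nrow = n, ncol = 9)
  for (i in seq_len(n)) {
    draws[i, ] <- with_local_seed(
      derive_seed(seed, .STREAM_AE, i),
      stats::rnorm(9)
    )
  }
  out <- data.frame(subject_id = seq_len(n))
  for (j in seq_along(logit_names)) {
    typ <- params[[logit_names[j]]]
    out[[logit_names[j]]] <- typ + params$cv * abs(typ) * draws[, j]
  }
  for (j in seq_along(pos_names)) {
    typ <- params[[pos_names[j]]]
    out[[pos_names[j]]] <- typ * exp(s_log * draws[, 6 + j])
  }
  out$emax_scale <- rep(params$emax_scale, n)
  class(out) <- c("individual_ae", "data.frame")
  out
}

# one subject's AE parameters as a list (internal)
as_ae_subject <- function(ind) {
  if (is.data.frame(ind)) {
    if (nrow(ind) != 1L) stop("expected a single subject (one row)", call. = FALSE)
    ind <- as.list(ind)
  }
  ind
}

#' Concentration-dependent logit drug effect
#'
#' Saturable Emax shift applied to the transition logits:
#' `DE = s * Emax_prev * C / (EC50 + C)` with `Emax_prev = emax0` if the
#' previous grade is 0 and `emax1` otherwise. Non-negative, bounded above by
#' `s * Emax_prev`, half-maximal at `C = EC50`.
#'
#' @param conc concentration(s) in ng/mL, non-negative; vectorised.
#' @param prev_grade previous grade, 0, 1 or 2.
#' @param ind one subject's AE parameters (row of `individual_ae` or list).
#' @return Logit shift(s), same length as `conc`.
#' @export
drug_effect <- function(conc, prev_grade, ind) {
  if (any(conc < 0)) stop("`conc` must be non-negative", call. = FALSE)
  if (!prev_grade %in% c(0, 1, 2)) stop("`prev_grade` must be 0, 1 or 2", call. = FALSE)
  ind <- as_ae_subject(ind)
  emax <- if (prev_grade == 0) ind$emax0 else ind$emax1
  ind$emax_scale * emax * conc / (ind$ec50 + conc)
}

#' Grade transition probabilities
#'
#' Cumulative-logit (proportional-odds) construction conditioned on the
#' previous grade: `P(grade >= 1) = plogis(anchor + DE)`,
#' `P(grade >= 2) = plogis(anchor + increment + DE)`, with the
#' anchor/increment mapping described in [ae_parameters()]. The >= 2 logit is
#' clamped at the >= 1 logit so the cumulative probabilities remain ordered
#' even under extreme additive IIV draws; the clamp is inactive at typical
#' values, where every increment is negative.
#'
#' @param prev_grade previous grade, 0, 1 or 2.
#' @param de logit drug effect from [drug_effect()].
#' @param ind one subject's AE parameters.
#' @return Named numeric triple `(p0, p1, p2)` summing to 1.
#' @examples
#' ind <- sample_individual_ae(ae_parameters(cv = 0), 1, seed = 1)
#' transition_probabilities(0, de = 0, ind)
#' @export
transition_probabilities <- function(prev_grade, de, ind) {
  if (!prev_grade %in% c(0, 1, 2)) stop("`prev_grade` must be 0, 1 or 2", call. = FALSE)
  ind <- as_ae_subject(ind)
  pars <- switch(as.character(prev_grade),
    "0" = c(ind$b01, ind$b02),
    "1" = c(ind$b11, ind$b12),
    "2" = c(ind$b21, ind$b22)
  )
  l1 <- pars[1] + de
  l2 <- min(pars[1] + pars[2] + de, l1)
  p_ge1 <- stats::plogis(l1)
  p_ge2 <- stats::plogis(l2)
  c(p0 = 1 - p_ge1, p1 = p_ge1 - p_ge2, p2 = p_ge2)
}

#' Simulate one subject's adverse-event trajectory
#'
#' First-order Markov chain on the assessment grid `t_k = k *
#' assessment_interval`, `k = 1, ..., EoT / assessment_interval`. The state at
#' `t_k` is drawn from [transition_probabilities()] with the previous state
#' and the drug effect evaluated at the concentration at `t_k` (with once-daily
#' dosing and weekly assessments this is the pre-dose trough). The initial
#' state before the first assessment is grade 0. No events are generated after
#' EoT; follow-up time enters the analysis only through exposure imputation.
#'
#' @param ind_pk one subject's PK parameters.
#' @param ind_ae one subject's AE parameters.
#' @param regimen a [dosing_regimen()].
#' @param assessment_interval spacing of assessments (h); must divide EoT.
#'   Default 24 h (daily, matching the once-daily dosing grid).
#' @param seed seed for this subject's chain.
#' @return An object of class `event_history`: a list with `subject_id`,
#'   `times` (h) and `grades` (integer 0/1/2 per assessment).
#' @export
simulate_event_history <- function(ind_pk, ind_ae, regimen,
                                   assessment_interval = 24, seed) {
  eot <- end_of_treatment(regimen)
  n_assess <- eot / assessment_interval
  if (abs(n_assess - round(n_assess)) > 1e-9) {
    stop("`assessment_interval` must divide the end-of-treatment time",
         call. = FALSE)
  }
  n_assess <- as.integer(round(n_assess))
  times <- seq_len(n_assess) * assessment_interval
  conc <- concentration(ind_pk, regimen, times)
  u <- with_local_seed(seed, stats::runif(n_assess))
  ind_ae <- as_ae_subject(ind_ae)
  grades <- integer(n_assess)
  prev <- 0L
  for (k in seq_len(n_assess)) {
    de <- drug_effect(conc[k], prev, ind_ae)
    p <- transition_probabilities(prev, de, ind_ae)
    grades[k] <- as.integer((u[k] > p[1]) + (u[k] > p[1] + p[2]))
    prev <- grades[k]
  }
  pid <- ind_pk$subject_id
  structure(
    list(subject_id = if (is.null(pid)) NA_integer_ else pid,
         times = times, grades = grades),
    class = "event_history"
  )
}

#' @export
print.event_history <- function(x, ...) {
  fe <- first_event(x)
  cat(sprintf("Event history, subject %s: %d assessments, ",
              x$subject_id, length(x$times)))
  if (is.null(fe)) {
    cat("no event (censored)\n")
  } else {
    cat(sprintf("first event grade %d at t = %g h\n", fe$grade, fe$time))
  }
  invisible(x)
}

#' First any-grade event of a trajectory
#'
#' Grade 1 and 2 events are grouped into a single any-grade category; the
#' earliest assessment with grade >= 1 defines the event time. Subjects with
#' grade 0 throughout are censored.
#'
#' @param history an `event_history`.
#' @return `NULL` if censored, else a list with `time` (h) and `grade`.
#' @export
first_event <- function(history) {
  idx <- which(history$grades >= 1L)
  if (length(idx) == 0L) return(NULL)
  k <- idx[1L]
  list(time = history$times[k], grade = history$grades[k])
}

#' Simulate a full cohort
#'
#' Samples individual PK and AE parameters and simulates every subject's event
#' history with per-subject sub-streams derived from one master seed (stages
#' use disjoint streams, so PK draws, AE-parameter draws and chain draws never
#' interact). The Markov chains are advanced for all subjects at once, which
#' is algebraically identical to calling [simulate_event_history()] per
#' subject (same sub-seeds, same draws) but much faster for replicated grids.
#'
#' @param pk_params a [pk_parameters()] object.
#' @param ae_params an [ae_parameters()] object.
#' @param n cohort size.
#' @param regimen a [dosing_regimen()].
#' @param assessment_interval assessment spacing (h).
#' @param seed master seed.
#' @return A list with elements `pk` (`individual_pk`), `ae` (`individual_ae`)
#'   and `histories` (list of `event_history`).
#' @export
simulate_cohort <- function(pk_params, ae_params, n, regimen = dosing_regimen(),
                            assessment_interval = 24, seed) {
  pk <- sample_individual_pk(pk_params, n, seed)
  ae <- sample_individual_ae(ae_params, n, seed)
  eot <- end_of_treatment(regimen)
  n_assess <- eot / assessment_interval
  if (abs(n_assess - round(n_assess)) > 1e-9) {
    stop("`assessment_interval` must divide the end-of-treatment time",
         call. = FALSE)
  }
  n_assess <- as.integer(round(n_assess))
  times <- seq_len(n_assess) * assessment_interval

  # n x K concentration matrix at the assessment times
  conc <- t(vapply(seq_len(n),
                   function(i) concentration(pk[i, ], regimen, times),
                   numeric(n_assess)))
  # per-subject uniforms from each subject's chain sub-stream
  u <- t(vapply(seq_len(n), function(i) {
    with_local_seed(derive_seed(seed, .STREAM_CHAIN, i),
                    stats::runif(n_assess))
  }, numeric(n_assess)))

  anchors <- cbind(ae$b01, ae$b11, ae$b21) # column = prev grade + 1
  increments <- cbind(ae$b02, ae$b12, ae$b22)
  emax <- cbind(ae$emax0, ae$emax1, ae$emax1)
  s <- ae$emax_scale
  rows <- seq_len(n)
  grades <- matrix(0L, n, n_assess)
  prev <- rep(1L, n) # column index: previous grade + 1
  for (k in seq_len(n_assess)) {
    ck <- conc[, k]
    de <- s * emax[cbind(rows, prev)] * ck / (ae$ec50 + ck)
    l1 <- anchors[cbind(rows, prev)] + de
    l2 <- pmin(l1 + increments[cbind(rows, prev)], l1)
    p_ge1 <- stats::plogis(l1)
    p_ge2 <- stats::plogis(l2)
    # same uniform-to-grade mapping as simulate_event_history():
    # grade >= 1 iff u > p0 = 1 - P(>=1); grade 2 iff u > p0 + p1 = 1 - P(>=2)
    g <- (u[, k] > 1 - p_ge1) + (u[, k] > 1 - p_ge2)
    grades[, k] <- as.integer(g)
    prev <- g + 1L
  }
  histories <- lapply(seq_len(n), function(i) {
    structure(list(subject_id = pk$subject_id[i], times = times,
                   grades = grades[i, ]),
              class = "event_history")
  })
  list(pk = pk, ae = ae, histories = histories)
}
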