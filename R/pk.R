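#' Population pharmacokinetic parameters
#'
#' Typical values and inter-individual variability (IIV) for a one-compartment
#' oral model with first-order absorption, absorption lag time and first-order
#' elimination. Defaults are the example-scenario estimates: CL 17.7 L/h
#' (54.0% CV), V 229 L (34.1% CV), Ka 4.23 /h (95.5% CV), Alag 0.154 h (no
#' IIV). Bioavailability is not reported for the example drug and defaults to
#' 1; it is kept explicit because steady-state AUC is Dose x F / CL.
#'
#' @param cl typical clearance (L/h).
#' @param v typical central volume (L).
#' @param ka typical first-order absorption rate constant (1/h).
#' @param alag absorption lag time (h), identical across subjects.
#' @param f bioavailable fraction in (0, 1].
#' @param cv_cl,cv_v,cv_ka IIV of CL, V and Ka as fractional coefficients of
#'   variation (0.54 means 54%).
#' @return An object of class `pk_parameters`.
#' @examples
#' pk_parameters()
#' @export
pk_parameters <- function(cl = 17.7, v = 229, ka = 4.23, alag = 0.154,
                          f = 1, cv_cl = 0.540, cv_v = 0.341, cv_ka = 0.955) {
  stopifnot(cl > 0, v > 0, ka > 0, alag >= 0, f > 0, f <= 1,
            cv_cl >= 0, cv_v >= 0, cv_ka >= 0)
  structure(
    list(cl = cl, v = v, ka = ka, alag = alag, f = f,
         cv_cl = cv_cl, cv_v = cv_v, cv_ka = cv_ka),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("One-compartment oral PK parameters\n")
  cat(sprintf("  CL   %8.3f L/h   (CV %.1f%%)\n", x$cl, 100 * x$cv_cl))
  cat(sprintf("  V    %8.3f L     (CV %.1f%%)\n", x$v, 100 * x$cv_v))
  cat(sprintf("  Ka   %8.3f /h    (CV %.1f%%)\n", x$ka, 100 * x$cv_ka))
  cat(sprintf("  Alag %8.3f h     (fixed)\n", x$alag))
  cat(sprintf("  F    %8.3f\n", x$f))
  invisible(x)
}

#' Repeated oral dosing regimen
#'
#' @param dose dose amount (mg).
#' @param tau dosing interval (h).
#' @param n_doses number of administered doses.
#' @param first_dose_time time of the first dose (h).
#' @return An object of class `dosing_regimen`. End of treatment (EoT) is
#'   `first_dose_time + n_doses * tau`, i.e. the end of the last dosing
#'   interval. The default regimen is 60 mg once daily for four 28-day cycles
#'   (112 doses, EoT = 2688 h).
#' @examples
#' reg <- dosing_regimen()
#' end_of_treatment(reg)
#' @export
dosing_regimen <- function(dose = 60, tau = 24, n_doses = 112,
                           first_dose_time = 0) {
  stopifnot(dose > 0, tau > 0, n_doses >= 1, first_dose_time >= 0)
  structure(
    list(dose = dose, tau = tau, n_doses = as.integer(n_doses),
         first_dose_time = first_dose_time),
    class = "dosing_regimen"
  )
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("%g mg q%gh x %d doses (EoT = %g h)\n",
              x$dose, x$tau, x$n_doses, end_of_treatment(x)))
  invisible(x)
}

#' End-of-treatment time of a regimen
#'
#' @param regimen a [dosing_regimen()].
#' @return EoT in hours: `first_dose_time + n_doses * tau`.
#' @export
end_of_treatment <- function(regimen) {
  regimen$first_dose_time + regimen$n_doses * regimen$tau
}

#' Sample individual PK parameters
#'
#' Draws subject-level CL, V and Ka log-normally around the typical values
#' with variance `sigma^2 = log(1 + CV^2)` on the log scale, the standard
#' population-PK convention for CV-parameterised IIV; the median of each
#' marginal equals the typical value. Alag and F carry no IIV. Each subject
#' uses an independent sub-stream derived from `seed` (see [derive_seed()]),
#' so subject k's draws do not depend on cohort size or on other subjects.
#'
#' @param params a [pk_parameters()] object.
#' @param n number of subjects (>= 1).
#' @param seed master seed.
#' @return A data frame of class `individual_pk` with one row per subject and
#'   columns `subject_id`, `cl`, `v`, `ka`, `alag`, `f` and the derived
#'   elimination rate `ke = cl / v` (1/h).
#' @examples
#' sample_individual_pk(pk_parameters(), n = 3, seed = 1)
#' @export
sample_individual_pk <- function(params, n, seed) {
  stopifnot(inherits(params, "pk_parameters"))
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  sd_log <- function(cv) sqrt(log(1 + cv^2))
  s <- c(sd_log(params$cv_cl), sd_log(params$cv_v), sd_log(params$cv_ka))
  draws <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    draws[i, ] <- with_local_seed(
      derive_seed(seed, .STREAM_PK, i),
      stats::rnorm(3)
    )
  }
  cl <- params$cl * exp(s[1] * draws[, 1])
  v <- params$v * exp(s[2] * draws[, 2])
  ka <- params$ka * exp(s[3] * draws[, 3])
  out <- data.frame(
    subject_id = seq_len(n),
    cl = cl, v = v, ka = ka,
    alag = rep(params$alag, n),
    f = rep(params$f, n),
    ke = cl / v
  )
  class(out) <- c("individual_pk", "data.frame")
  out
}

# Coerce a single subject (one-row data frame or list) to a plain list with
# fields cl, v, ka, alag, f. (internal)
as_subject <- function(ind) {
  if (is.data.frame(ind)) {
    if (nrow(ind) != 1L) {
      stop("expected a single subject (one row); use per-row access for cohorts",
           call. = FALSE)
    }
    ind <- as.list(ind)
  }
  need <- c("cl", "v", "ka", "alag", "f")
  miss <- setdiff(need, names(ind))
  if (length(miss)) {
    stop("subject is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ind
}

# mg/L -> ng/mL
.CONC_UNIT <- 1000

# relative tolerance below which ka and ke are treated as equal and the
# analytic flip-flop limit is used instead of the generic biexponential
.KA_KE_RTOL <- 1e-9

#' Plasma concentration under repeated oral dosing
#'
#' Closed-form superposition of one-compartment first-order absorption
#' profiles. Dose i (administered at `first_dose_time + (i-1) * tau`)
#' contributes, for effective time `u = t - t_i - alag > 0`,
#' `F * D * ka / (V * (ka - ke)) * (exp(-ke u) - exp(-ka u))`; doses not yet
#' absorbed contribute nothing. When `ka` and `ke` coincide within a relative
#' tolerance of 1e-9 the analytic limit `F * D / V * ke * u * exp(-ke u)` is
#' used. Dose in mg and volume in L are reported as ng/mL.
#'
#' @param ind a single subject: one row of an `individual_pk` data frame, or a
#'   list with fields `cl`, `v`, `ka`, `alag`, `f`.
#' @param regimen a [dosing_regimen()].
#' @param t time(s) since first dose (h), vectorised; must be non-negative.
#' @return Concentration(s) in ng/mL, same length as `t`.
#' @examples
#' ind <- sample_individual_pk(pk_parameters(cv_cl = 0, cv_v = 0, cv_ka = 0),
#'                             n = 1, seed = 1)
#' concentration(ind, dosing_regimen(n_doses = 1), t = 24)
#' @export
concentration <- function(ind, regimen, t) {
  ind <- as_subject(ind)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  ke <- ind$cl / ind$v
  dose_times <- regimen$first_dose_time + (seq_len(regimen$n_doses) - 1) * regimen$tau
  # u: length(t) x n_doses matrix of effective absorption times
  u <- outer(t, dose_times + ind$alag, "-")
  pos <- u > 0
  u[!pos] <- 0
  amt <- .CONC_UNIT * ind$f * regimen$dose / ind$v # ng/mL scale
  if (abs(ind$ka - ke) <= .KA_KE_RTOL * max(ind$ka, ke)) {
    contrib <- amt * ke * u * exp(-ke * u)
  } else {
    contrib <- amt * ind$ka / (ind$ka - ke) * (exp(-ke * u) - exp(-ind$ka * u))
  }
  contrib[!pos] <- 0
  rowSums(contrib)
}

#' Cumulative area under the concentration curve
#'
#' Closed-form integral of [concentration()] from time 0 to `t`. Dose i with
#' effective time `u = t - t_i - alag > 0` contributes
#' `F * D * ka / (V (ka - ke)) * ((1 - exp(-ke u))/ke - (1 - exp(-ka u))/ka)`,
#' which tends to `F * D / CL` as `u -> Inf`. Non-decreasing in `t`.
#'
#' @inheritParams concentration
#' @return Cumulative AUC(s) in ng.h/mL, same length as `t`.
#' @examples
#' ind <- sample_individual_pk(pk_parameters(cv_cl = 0, cv_v = 0, cv_ka = 0),
#'                             n = 1, seed = 1)
#' cumulative_auc(ind, dosing_regimen(n_doses = 1), t = 1e6) # ~ F*D/CL
#' @export
cumulative_auc <- function(ind, regimen, t) {
  ind <- as_subject(ind)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  ke <- ind$cl / ind$v
  dose_times <- regimen$first_dose_time + (seq_len(regimen$n_doses) - 1) * regimen$tau
  u <- outer(t, dose_times + ind$alag, "-")
  pos <- u > 0
  u[!pos] <- 0
  amt <- .CONC_UNIT * ind$f * regimen$dose / ind$v
  if (abs(ind$ka - ke) <= .KA_KE_RTOL * max(ind$ka, ke)) {
    # integral of ke * u * exp(-ke u) is (1 - (1 + ke u) exp(-ke u)) / ke
    contrib <- amt * (1 - (1 + ke * u) * exp(-ke * u)) / ke
  } else {
    contrib <- amt * ind$ka / (ind$ka - ke) *
      ((1 - exp(-ke * u)) / ke - (1 - exp(-ind$ka * u)) / ind$ka)
  }
  contrib[!pos] <- 0
  rowSums(contrib)
}

#' Average steady-state concentration
#'
#' `Cav,ss = AUCss / tau` with `AUCss = Dose x F / CL`, i.e.
#' `F * Dose / (CL * tau)` reported in ng/mL. Vectorised over the rows of a
#' cohort data frame.
#'
#' @param ind an `individual_pk` data frame (any number of rows) or a
#'   single-subject list.
#' @param regimen a [dosing_regimen()].
#' @return Cav,ss in ng/mL, one value per subject.
#' @examples
#' ind <- sample_individual_pk(pk_parameters(cv_cl = 0, cv_v = 0, cv_ka = 0),
#'                             n = 1, seed = 1)
#' cav_ss(ind, dosing_regimen()) # 60 / (17.7 * 24) mg/L = 141.2 ng/mL
#' @export
cav_ss <- function(ind, regimen) {
  .CONC_UNIT * ind$f * regimen$dose / (ind$cl * regimen$tau)
}
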