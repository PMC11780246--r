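#' Imputation policies for censored event times
#'
#' A censored subject (no event by end of treatment) has no event time, so the
#' reference time for the time-averaged exposure must be imputed. The policies
#' studied here are EoT itself and EoT plus 7, 14, 21 or 28 days of follow-up.
#'
#' @param extra_follow_up_days additional follow-up beyond EoT, in days; a
#'   non-negative multiple of 7 from `{0, 7, 14, 21, 28}` (extensible to other
#'   non-negative values).
#' @return An object of class `imputation_policy` with fields `name` (one of
#'   `"EOT"`, `"EOT7"`, ...) and `extra_follow_up` (days).
#' @examples
#' imputation_policy(28)
#' @export
imputation_policy <- function(extra_follow_up_days = 0) {
  stopifnot(length(extra_follow_up_days) == 1L, extra_follow_up_days >= 0)
  name <- if (extra_follow_up_days == 0) "EOT" else paste0("EOT", extra_follow_up_days)
  structure(
    list(name = name, extra_follow_up = extra_follow_up_days),
    class = "imputation_policy"
  )
}

#' @export
print.imputation_policy <- function(x, ...) {
  cat(sprintf("Imputation policy %s: reference time = EoT + %g days\n",
              x$name, x$extra_follow_up))
  invisible(x)
}

#' The five standard imputation policies
#'
#' @return Named list of [imputation_policy()] objects for EoT and EoT + 7,
#'   14, 21 and 28 days.
#' @export
cavte_policies <- function() {
  pol <- lapply(c(0, 7, 14, 21, 28), imputation_policy)
  names(pol) <- vapply(pol, `[[`, "", "name")
  pol
}

#' Imputed reference time of a policy
#'
#' @param policy an [imputation_policy()].
#' @param regimen a [dosing_regimen()].
#' @return `EoT + 24 * extra_follow_up` in hours.
#' @examples
#' imputed_reference_time(imputation_policy(28), dosing_regimen()) # 3360 h
#' @export
imputed_reference_time <- function(policy, regimen) {
  end_of_treatment(regimen) + 24 * policy$extra_follow_up
}

#' Time-averaged concentration up to a reference time
#'
#' `CavTE(t_ref) = AUC(0, t_ref) / t_ref`: the cumulative AUC from treatment
#' start divided by the reference time. For responders `t_ref` is the first
#' event time; for censored subjects it is an imputed time at or beyond EoT.
#' Beyond EoT the washout tail is included (concentration keeps decaying with
#' no further doses), so CavTE strictly decreases with longer imputed
#' follow-up once the concentration falls below the running average.
#'
#' @param ind one subject's PK parameters.
#' @param regimen a [dosing_regimen()].
#' @param t_ref reference time(s) in h, strictly positive; vectorised.
#' @return CavTE in ng/mL, same length as `t_ref`.
#' @export
cav_te <- function(ind, regimen, t_ref) {
  if (any(t_ref <= 0)) stop("`t_ref` must be strictly positive", call. = FALSE)
  cumulative_auc(ind, regimen, t_ref) / t_ref
}

# metric labels with stable CSV schemas
.METRIC_LABELS <- c("CAVTE_EOT", "CAVTE_EOT7", "CAVTE_EOT14", "CAVTE_EOT21",
                    "CAVTE_EOT28", "CAVSS")

metric_label <- function(metric, policy) {
  if (metric == "CAVSS") return("CAVSS")
  paste0("CAVTE_", policy$name)
}

#' Assemble an analysis-ready exposure-response dataset
#'
#' One record per subject with the exposure metric value and the binary
#' responder flag (1 = any-grade event on treatment). For `metric = "CAVTE"`,
#' responders get CavTE at their first event time and censored subjects get
#' CavTE at the policy's imputed reference time; for `metric = "CAVSS"` every
#' subject gets the average steady-state concentration and no imputation is
#' involved.
#'
#' @param cohort_pk an `individual_pk` data frame.
#' @param histories list of `event_history` objects aligned with `cohort_pk`
#'   by `subject_id`.
#' @param regimen a [dosing_regimen()].
#' @param metric `"CAVTE"` or `"CAVSS"`.
#' @param policy an [imputation_policy()]; required for CAVTE, ignored for
#'   CAVSS.
#' @return A data frame of class `er_dataset` with columns `subject_id`,
#'   `metric`, `exposure_ng_ml`, `responder`, `event_time_h` (`NA` if
#'   censored) and attributes `n_event` and `n_censored`.
#' @export
build_er_dataset <- function(cohort_pk, histories, regimen,
                             metric = c("CAVTE", "CAVSS"), policy = NULL) {
  metric <- match.arg(metric)
  n <- nrow(cohort_pk)
  hist_ids <- vapply(histories, `[[`, numeric(1), "subject_id")
  idx <- match(cohort_pk$subject_id, hist_ids)
  if (anyNA(idx)) {
    stop("missing event history for subject(s): ",
         paste(cohort_pk$subject_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  histories <- histories[idx]
  if (metric == "CAVTE" && is.null(policy)) {
    stop("CAVTE requires an imputation `policy`", call. = FALSE)
  }
  exposure <- numeric(n)
  responder <- integer(n)
  event_time <- rep(NA_real_, n)
  t_imp <- if (metric == "CAVTE") imputed_reference_time(policy, regimen) else NA
  for (i in seq_len(n)) {
    fe <- first_event(histories[[i]])
    if (!is.null(fe)) {
      responder[i] <- 1L
      event_time[i] <- fe$time
    }
    exposure[i] <- if (metric == "CAVSS") {
      cav_ss(cohort_pk[i, ], regimen)
    } else if (responder[i] == 1L) {
      cav_te(cohort_pk[i, ], regimen, fe$time)
    } else {
      cav_te(cohort_pk[i, ], regimen, t_imp)
    }
  }
  out <- data.frame(
    subject_id = cohort_pk$subject_id,
    metric = metric_label(metric, policy),
    exposure_ng_ml = exposure,
    responder = responder,
    event_time_h = event_time
  )
  attr(out, "n_event") <- sum(responder)
  attr(out, "n_censored") <- n - sum(responder)
  class(out) <- c("er_dataset", "data.frame")
  out
}

#' Write / read an exposure-response dataset as CSV
#'
#' Plain CSV with header `subject_id, metric, exposure_ng_ml, responder,
#' event_time_h`; numeric columns round-trip losslessly to at least 12
#' significant digits.
#'
#' @param dataset an `er_dataset`.
#' @param path file path.
#' @return `write_er_dataset` returns `path` invisibly; `read_er_dataset`
#'   returns an `er_dataset`.
#' @export
write_er_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$exposure_ng_ml <- sprintf("%.15g", df$exposure_ng_ml)
  df$event_time_h <- ifelse(is.na(df$event_time_h), "",
                            sprintf("%.15g", df$event_time_h))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_er_dataset
#' @export
read_er_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "metric", "exposure_ng_ml", "responder", "event_time_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("ER dataset CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$event_time_h <- as.numeric(df$event_time_h)
  attr(df, "n_event") <- sum(df$responder)
  attr(df, "n_censored") <- nrow(df) - sum(df$responder)
  class(df) <- c("er_dataset", "data.frame")
  df
}
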