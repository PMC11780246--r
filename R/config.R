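#' Read a study configuration from YAML
#'
#' The file may contain any of the blocks `pk`, `ae`, `regimen` and `study`;
#' unknown keys raise an error, absent keys keep their defaults. Key names
#' mirror the usual parameter table: in `pk` CL, V, KA, ALAG, F and IIV CVs;
#' in `ae` B01..B22, EMAX0, EMAX1, EC50, IIV, EMAX_SCALE; in `regimen` DOSE,
#' TAU, N_DOSES; in `study` N_SUBJECTS, EMAX_SCALES, FOLLOW_UP_DAYS,
#' INCLUDE_CAVSS, ASSESS_INTERVAL_DAYS, SEED, N_REPLICATES,
#' BALANCE_THRESHOLD.
#'
#' @param path path to a YAML file.
#' @return A [scenario_config()] built from the file's values.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c("pk", "ae", "regimen", "study"))
  if (length(bad)) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pick <- function(block, map, builder, defaults) {
    args <- defaults
    if (!is.null(block)) {
      bad <- setdiff(names(block), names(map))
      if (length(bad)) {
        stop("unknown config key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      for (k in names(block)) args[[map[[k]]]] <- block[[k]]
    }
    do.call(builder, args)
  }
  pk <- pick(cfg$pk,
             list(CL = "cl", V = "v", KA = "ka", ALAG = "alag", F = "f",
                  CV_CL = "cv_cl", CV_V = "cv_v", CV_KA = "cv_ka"),
             pk_parameters, list())
  ae <- pick(cfg$ae,
             list(B01 = "b01", B02 = "b02", B11 = "b11", B12 = "b12",
                  B21 = "b21", B22 = "b22", EMAX0 = "emax0", EMAX1 = "emax1",
                  EC50 = "ec50", IIV = "cv", EMAX_SCALE = "emax_scale"),
             ae_parameters, list())
  regimen <- pick(cfg$regimen,
                  list(DOSE = "dose", TAU = "tau", N_DOSES = "n_doses",
                       FIRST_DOSE_TIME = "first_dose_time"),
                  dosing_regimen, list())
  study <- cfg$study
  if (is.null(study)) study <- list()
  bad <- setdiff(names(study),
                 c("N_SUBJECTS", "EMAX_SCALES", "FOLLOW_UP_DAYS",
                   "INCLUDE_CAVSS", "ASSESS_INTERVAL_DAYS", "SEED",
                   "N_REPLICATES", "BALANCE_THRESHOLD"))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  grab <- function(key, default) if (is.null(study[[key]])) default else study[[key]]
  policies <- lapply(grab("FOLLOW_UP_DAYS", c(0, 7, 14, 21, 28)),
                     imputation_policy)
  names(policies) <- vapply(policies, `[[`, "", "name")
  scenario_config(
    n_subjects = grab("N_SUBJECTS", c(50, 100, 200)),
    emax_scale = grab("EMAX_SCALES", c(0.25, 0.5, 0.75, 1, 1.25, 1.5)),
    policies = policies,
    include_cavss = grab("INCLUDE_CAVSS", TRUE),
    assessment_interval_days = grab("ASSESS_INTERVAL_DAYS", 1),
    pk_params = pk, ae_params = ae, regimen = regimen,
    seed = grab("SEED", 20240101),
    n_replicates = grab("N_REPLICATES", 200),
    balance_threshold = grab("BALANCE_THRESHOLD", 0.05)
  )
}

#' Write simulated individual parameters as CSV
#'
#' @param ind an `individual_pk` or `individual_ae` data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(ind, path) {
  df <- as.data.frame(ind)
  if (inherits(ind, "individual_pk")) {
    df <- df[, c("subject_id", "cl", "v", "ka", "alag")]
    names(df) <- c("subject_id", "CL", "V", "KA", "ALAG")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write event histories as long CSV
#'
#' One row per subject and assessment: `subject_id, time_h, grade`.
#'
#' @param histories list of `event_history` objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_event_histories <- function(histories, path) {
  df <- do.call(rbind, lapply(histories, function(h) {
    data.frame(subject_id = h$subject_id, time_h = h$times, grade = h$grades)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
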