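test_that("the balance rule implements the <5% skip criterion symmetrically", {
  d <- data.frame(responder = c(rep(1, 97), rep(0, 3)))
  chk <- censoring_balance_check(d, 0.05)
  expect_false(chk$proceed)
  expect_equal(chk$fraction_censored, 0.03)

  half <- data.frame(responder = rep(c(0, 1), 25))
  expect_true(censoring_balance_check(half, 0.05)$proceed)
  expect_equal(censoring_balance_check(half, 0.05)$fraction_censored, 0.5)

  none <- data.frame(responder = rep(0, 50))
  chk0 <- censoring_balance_check(none, 0.05)
  expect_false(chk0$proceed)
  expect_equal(chk0$fraction_censored, 1)
})

test_that("trials are reproducible and policies share responder flags", {
  cfg <- scenario_config(n_subjects = 60, emax_scale = 0.75,
                         n_replicates = 1, seed = 5)
  r1 <- run_trial(cfg, 1234)
  r2 <- run_trial(cfg, 1234)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 6) # five policies + CAVSS
  expect_equal(length(unique(r1$n_event)), 1)
  expect_equal(length(unique(r1$n_censored)), 1)
})

test_that("an eventless cohort is skipped as single-class", {
  cfg <- scenario_config(
    n_subjects = 20, emax_scale = 0,
    ae_params = ae_parameters(b01 = -40, b02 = -1, b11 = -40, b12 = -1,
                              b21 = -40, b22 = -1, cv = 0, emax_scale = 0),
    n_replicates = 1, seed = 1
  )
  r <- run_trial(cfg, 99)
  expect_true(all(r$skipped))
  expect_true(all(r$skip_reason == "single-class"))
  expect_true(all(is.na(r$p_slope)))
})

test_that("the grid is a pure function of the configuration and cell", {
  cfg_a <- scenario_config(n_subjects = c(50, 80), emax_scale = c(0.5, 1),
                           n_replicates = 2, seed = 77, include_cavss = FALSE)
  cfg_b <- scenario_config(n_subjects = c(80, 50), emax_scale = c(1, 0.5),
                           n_replicates = 2, seed = 77, include_cavss = FALSE)
  ga <- run_grid(cfg_a)
  gb <- run_grid(cfg_b)
  key <- function(g) g[order(g$n_subjects, g$emax_scale, g$replicate, g$metric), ]
  ka <- key(ga)
  kb <- key(gb)
  rownames(ka) <- rownames(kb) <- NULL
  expect_equal(ka, kb)
  # one row per replicate x cell x metric
  expect_equal(nrow(ga), 2 * 2 * 2 * 5)
})

test_that("replicate summaries aggregate p-values and skip rates", {
  tab <- data.frame(
    replicate = 1:3, n_subjects = 100, emax_scale = 0.5,
    metric = "CAVTE_EOT", beta0 = 0, beta = 1, se_beta = 1,
    p_slope = c(0.2, 0.04, 0.01), n_event = 50, n_censored = 50,
    frac_censored = 0.5, skipped = FALSE, skip_reason = NA
  )
  s <- replicate_summary(tab, alpha = 0.05)
  expect_equal(s$median_p, 0.04)
  expect_equal(s$prop_significant, 2 / 3)
  expect_equal(s$skip_rate, 0)

  tab$skipped <- TRUE
  tab$p_slope <- NA
  s2 <- replicate_summary(tab)
  expect_equal(s2$skip_rate, 1)
  expect_true(is.na(s2$median_p))
})

test_that("the pivoted matrix is labelled by follow-up policy", {
  cfg <- scenario_config(n_subjects = 80, emax_scale = 0.75,
                         n_replicates = 1, seed = 10)
  g <- run_grid(cfg)
  m <- table2_matrix(g, value = "p_slope")
  expect_equal(names(m), c("n_subjects", "emax_scale",
                           "EoT", "EoT+7", "EoT+14", "EoT+21", "EoT+28"))
  expect_equal(nrow(m), 1)
  expect_true(all(is.finite(unlist(m[, 3:7]))))
})

test_that("YAML configuration round-trips into a scenario config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "pk:",
    "  CL: 10.0",
    "  CV_CL: 0.3",
    "ae:",
    "  EC50: 5.0",
    "  EMAX_SCALE: 0.5",
    "regimen:",
    "  DOSE: 30",
    "study:",
    "  N_SUBJECTS: [40]",
    "  EMAX_SCALES: [0.5]",
    "  FOLLOW_UP_DAYS: [0, 28]",
    "  N_REPLICATES: 3",
    "  SEED: 9"
  ), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$pk_params$cl, 10)
  expect_equal(cfg$pk_params$cv_cl, 0.3)
  expect_equal(cfg$pk_params$v, 229) # untouched default
  expect_equal(cfg$ae_params$ec50, 5)
  expect_equal(cfg$regimen$dose, 30)
  expect_equal(names(cfg$policies), c("EOT", "EOT28"))
  expect_equal(cfg$n_replicates, 3)

  writeLines(c("pk:", "  CLEARANCE: 10"), path)
  expect_error(read_study_config(path), "unknown config key")
})

test_that("parameter tables and histories export to plain CSV", {
  coh <- simulate_cohort(pk_parameters(), ae_parameters(), 5,
                         dosing_regimen(n_doses = 3), 24, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(coh$pk, p1)
  tab <- read.csv(p1)
  expect_equal(names(tab), c("subject_id", "CL", "V", "KA", "ALAG"))
  expect_equal(nrow(tab), 5)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_event_histories(coh$histories, p2)
  long <- read.csv(p2)
  expect_equal(names(long), c("subject_id", "time_h", "grade"))
  expect_equal(nrow(long), 5 * 3)
  expect_true(all(long$grade %in% 0:2))
})
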