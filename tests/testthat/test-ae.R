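test_that("drug effect is saturable with half-maximum at EC50", {
  ind <- typical_ae()
  expect_equal(drug_effect(0, 0, ind), 0)
  expect_equal(drug_effect(6.05, 0, ind), 4.73 / 2)
  expect_equal(drug_effect(6.05, 1, ind), 1.09 / 2)
  expect_equal(drug_effect(1e9, 0, ind), 4.73, tolerance = 1e-7)
  expect_error(drug_effect(-1, 0, ind), "non-negative")
  # scale multiplies both Emax parameters
  ind2 <- typical_ae(emax_scale = 0.5)
  expect_equal(drug_effect(6.05, 0, ind2), 0.5 * 4.73 / 2)
})

test_that("transition probabilities conserve mass and keep cumulative ordering", {
  ind <- typical_ae()
  # baseline hazard from grade 0 equals the logistic of the anchor
  p <- transition_probabilities(0, de = 0, ind)
  expect_equal(unname(sum(p)), 1)
  expect_equal(unname(p["p1"] + p["p2"]), plogis(-6.59)) # 1.372155e-3
  expect_equal(unname(p["p1"] + p["p2"]), 0.001372154568, tolerance = 1e-8)

  set.seed(2)
  cohort <- sample_individual_ae(ae_parameters(cv = 0.3), 50, seed = 8)
  for (i in 1:50) {
    for (g in 0:2) {
      de <- runif(1, 0, 6)
      p <- transition_probabilities(g, de, cohort[i, ])
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(unname(sum(p)), 1)
      # P(>=2) <= P(>=1)
      expect_lte(p[["p2"]], p[["p1"]] + p[["p2"]] + 1e-15)
    }
  }
  # monotone in the drug effect
  p_lo <- transition_probabilities(0, 1, ind)
  p_hi <- transition_probabilities(0, 2, ind)
  expect_gt(p_hi[["p1"]] + p_hi[["p2"]], p_lo[["p1"]] + p_lo[["p2"]])
  expect_gt(p_hi[["p2"]], p_lo[["p2"]])
  expect_error(transition_probabilities(3, 0, ind), "prev_grade")
})

test_that("AE parameter sampling follows the stated IIV conventions", {
  typ <- sample_individual_ae(ae_parameters(cv = 0), 4, seed = 5)
  expect_equal(typ$b01, rep(-6.59, 4))
  expect_equal(typ$emax0, rep(4.73, 4))

  big <- sample_individual_ae(ae_parameters(), 10000, seed = 6)
  # additive normal on logit parameters: sd = 0.10 * |typical|
  expect_equal(sd(big$b01), 0.659, tolerance = 0.05)
  expect_equal(mean(big$b01), -6.59, tolerance = 0.01)
  # log-normal on positive parameters: always positive, median = typical
  expect_true(all(big$ec50 > 0))
  expect_true(all(big$emax0 > 0))
  expect_equal(median(big$ec50), 6.05, tolerance = 0.03)
  expect_error(sample_individual_ae(ae_parameters(), 0, seed = 1), "n")
})

test_that("event histories are reproducible and silent when logits vanish", {
  pk <- typical_pk()
  reg <- dosing_regimen(n_doses = 14)
  quiet <- sample_individual_ae(
    ae_parameters(b01 = -40, b02 = -1, b11 = -40, b12 = -1, b21 = -40,
                  b22 = -1, cv = 0, emax_scale = 0), 1, seed = 1)
  h <- simulate_event_history(pk, quiet, reg, 24, seed = 3)
  expect_true(all(h$grades == 0))
  expect_null(first_event(h))

  ae <- typical_ae()
  h1 <- simulate_event_history(pk, ae, reg, 24, seed = 9)
  h2 <- simulate_event_history(pk, ae, reg, 24, seed = 9)
  expect_identical(h1, h2)
  expect_true(all(h1$times <= end_of_treatment(reg)))
  expect_error(simulate_event_history(pk, ae, reg, 100, seed = 1), "divide")
})

test_that("first_event picks the earliest any-grade assessment", {
  h <- structure(list(subject_id = 1, times = (1:5) * 168,
                      grades = c(0L, 0L, 2L, 1L, 0L)),
                 class = "event_history")
  fe <- first_event(h)
  expect_equal(fe$time, 3 * 168)
  expect_equal(fe$grade, 2)
})

test_that("vectorised cohort simulation equals the per-subject reference", {
  reg <- dosing_regimen(n_doses = 28)
  coh <- simulate_cohort(pk_parameters(), ae_parameters(emax_scale = 0.75),
                         25, reg, 24, seed = 13)
  for (i in c(1, 7, 25)) {
    ref <- simulate_event_history(coh$pk[i, ], coh$ae[i, ], reg, 24,
                                  seed = derive_seed(13, 303L, i))
    expect_identical(ref$grades, coh$histories[[i]]$grades)
  }
})

test_that("drug-free censoring matches the exact Markov absorption probability", {
  # emax_scale = 0 removes the drug effect, so each assessment is an
  # independent Bernoulli with p = plogis(b01): P(no event over K) = (1-p)^K
  n <- 10000
  reg <- dosing_regimen(n_doses = 10)
  coh <- simulate_cohort(pk_parameters(),
                         ae_parameters(b01 = -2.2, cv = 0, emax_scale = 0),
                         n, reg, 24, seed = 21)
  censored <- mean(vapply(coh$histories, function(h) is.null(first_event(h)),
                          TRUE))
  p_true <- (1 - plogis(-2.2))^10
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(censored - p_true), 3 * se)
})

test_that("stronger drug effect never reduces the cohort event count", {
  reg <- dosing_regimen(n_doses = 28)
  counts <- vapply(c(0.25, 0.5, 1, 1.5), function(s) {
    # common random numbers: identical seed, so identical PK draws and chain
    # uniforms across scales
    coh <- simulate_cohort(pk_parameters(), ae_parameters(emax_scale = s),
                           300, reg, 24, seed = 17)
    sum(vapply(coh$histories, function(h) !is.null(first_event(h)), TRUE))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("censoring decreases monotonically in the Emax scale at defaults", {
  cens <- vapply(c(0.25, 0.5, 0.75, 1, 1.25, 1.5), function(s) {
    coh <- simulate_cohort(pk_parameters(), ae_parameters(emax_scale = s),
                           400, dosing_regimen(), 24, seed = 99)
    mean(vapply(coh$histories, function(h) is.null(first_event(h)), TRUE))
  }, numeric(1))
  expect_true(all(diff(cens) < 0))
})
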