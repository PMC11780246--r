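# shared fixtures built in code

# typical subject: no IIV, so realized parameters equal the typical values
typical_pk <- function() {
  sample_individual_pk(pk_parameters(cv_cl = 0, cv_v = 0, cv_ka = 0),
                       n = 1, seed = 1)
}

typical_ae <- function(emax_scale = 1) {
  sample_individual_ae(ae_parameters(cv = 0, emax_scale = emax_scale),
                       n = 1, seed = 1)
}

default_regimen <- function() dosing_regimen() # 60 mg q24h x 112

single_dose <- function() dosing_regimen(n_doses = 1)

# ODE oracle for the one-compartment oral model: doses enter the gut
# compartment at t_i + alag; concentration = central amount / V in ng/mL
ode_concentration <- function(cl, v, ka, alag, f, dose, dose_times, tout) {
  rhs <- function(t, y, p) list(c(-ka * y[1], ka * y[1] - (cl / v) * y[2]))
  ev <- data.frame(var = "gut", time = dose_times + alag,
                   value = f * dose, method = "add")
  times <- sort(unique(c(0, tout, ev$time)))
  out <- deSolve::lsoda(c(gut = 0, cent = 0), times, rhs, NULL,
                        events = list(data = ev), rtol = 1e-12, atol = 1e-12)
  stats::approx(out[, 1], out[, "cent"] / v * 1000, xout = tout)$y
}

# analytic negative log-likelihood of the two-parameter logistic model,
# independent of the IRLS path
logistic_nll <- function(beta, x, y) {
  eta <- beta[1] + beta[2] * x
  -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

logistic_nll_grad <- function(beta, x, y) {
  mu <- plogis(beta[1] + beta[2] * x)
  -c(sum(y - mu), sum((y - mu) * x))
}

# random small ER dataset with both outcome classes present
random_er_data <- function(n, seed) {
  set.seed(seed)
  repeat {
    x <- rexp(n, 1 / 50)
    y <- rbinom(n, 1, plogis(-1 + 0.02 * x))
    if (any(y == 0) && any(y == 1)) return(data.frame(x = x, y = y))
  }
}
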