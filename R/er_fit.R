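#' Fit a time-invariant logistic exposure-response model
#'
#' Fits `logit P(responder_i = 1) = beta0 + beta * X_i` by maximum likelihood
#' with Newton-Raphson / iteratively reweighted least squares. The exposure
#' enters untransformed (linear on the logit scale) and is not centred; the
#' slope p-value is invariant to rescaling of the exposure, so no
#' standardisation is applied to the data.
#'
#' Convergence is declared when the relative change in log-likelihood falls
#' below `tol` (default 1e-10) within `max_iter` iterations. Quasi-complete or
#' complete separation is flagged when the coefficient magnitude on the
#' standardised-exposure scale exceeds 1e3 while the iterations keep improving
#' the likelihood; estimates then diverge and the Wald test is meaningless,
#' so `p_slope` is `NA` for separated fits.
#'
#' @param formula model formula, `response ~ exposure`, with a binary 0/1
#'   response and a single numeric exposure. The default matches the column
#'   names of an `er_dataset`.
#' @param data a data frame; an [build_er_dataset()] result can be passed
#'   directly (as the first unnamed argument, too).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return An object of class `er_logistic` with components `coefficients`
#'   (`(Intercept)`, slope), `se`, `vcov`, `z`, `p_slope` (two-sided Wald),
#'   `p_lr` (likelihood-ratio test of the slope, reported alongside),
#'   `loglik`, `n`, `n_event`, `n_censored`, `converged`,
#'   `separation_detected`, `iterations`, and the model frame.
#' @examples
#' set.seed(1)
#' x <- rexp(100, 1 / 100)
#' y <- rbinom(100, 1, plogis(-2 + 0.015 * x))
#' fit <- er_logistic(y ~ x, data.frame(x = x, y = y))
#' summary(fit)
#' @export
er_logistic <- function(formula = responder ~ exposure_ng_ml, data,
                        tol = 1e-10, max_iter = 100L) {
  if (missing(data) && is.data.frame(formula)) {
    data <- formula
    formula <- responder ~ exposure_ng_ml
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (ncol(X) != 2L) {
    stop("`formula` must specify exactly one exposure covariate plus intercept",
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1", call. = FALSE)
  n <- length(y)
  n_event <- sum(y == 1)
  if (n_event == 0L || n_event == n) {
    stop("degenerate data: all responses are in one outcome class",
         call. = FALSE)
  }
  x <- X[, 2L]
  if (stats::sd(x) == 0) stop("exposure is constant", call. = FALSE)

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    # log(1 + exp(eta)) computed without overflow for large |eta|
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  beta <- c(stats::qlogis(mean(y)), 0)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    # Newton step via weighted least squares on the working response
    z <- eta + (y - mu) / w
    fit_w <- stats::lm.wfit(X, z, w)
    beta_new <- fit_w$coefficients
    if (anyNA(beta_new)) break # collinear weighted design; keep last iterate
    ll_new <- loglik(beta_new)
    # step-halving if the Newton step overshoots
    halvings <- 0L
    while ((!is.finite(ll_new) || ll_new < ll) && halvings < 20L) {
      beta_new <- (beta + beta_new) / 2
      ll_new <- loglik(beta_new)
      halvings <- halvings + 1L
    }
    if (!is.finite(ll_new)) break
    done <- abs(ll_new - ll) < tol * (abs(ll) + tol)
    beta <- beta_new
    ll <- ll_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  # separation: either the coefficients diverge on the standardised-exposure
  # scale, or the likelihood has been driven to its supremum of 0 (every
  # observation fitted with probability ~ its outcome), which is only
  # attainable when a threshold on x perfectly splits the classes
  beta_std <- c(beta[1] + beta[2] * mean(x), beta[2] * stats::sd(x))
  separation <- max(abs(beta_std)) > 1e3 || ll > -1e-4
  if (separation) converged <- FALSE

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w) # observed = expected information for logit link
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(diag(vc))
  z_stat <- unname(beta[2] / se[2])
  p_slope <- if (separation || !is.finite(z_stat)) NA_real_ else wald_p(z_stat, 1)

  # likelihood-ratio test of the slope against the intercept-only model
  ll0 <- n_event * log(n_event / n) + (n - n_event) * log1p(-n_event / n)
  p_lr <- if (separation) NA_real_ else stats::pchisq(2 * (ll - ll0), df = 1,
                                                      lower.tail = FALSE)

  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta, se = se, vcov = vc, z = z_stat,
         p_slope = p_slope, p_lr = p_lr, loglik = ll, null_loglik = ll0,
         n = n, n_event = n_event, n_censored = n - n_event,
         converged = converged, separation_detected = separation,
         iterations = iter, model = mf, formula = formula),
    class = "er_logistic"
  )
}

#' Two-sided Wald p-value for a slope
#'
#' @param beta estimated slope.
#' @param se its standard error (> 0).
#' @return `2 * pnorm(-|beta / se|)`.
#' @examples
#' wald_p(1.959964, 1)
#' @export
wald_p <- function(beta, se) {
  if (any(se <= 0)) stop("`se` must be strictly positive", call. = FALSE)
  2 * stats::pnorm(-abs(beta / se))
}

#' @export
print.er_logistic <- function(x, digits = 4, ...) {
  cat("Logistic exposure-response model: logit P(event) = beta0 + beta * X\n")
  cat(sprintf("  n = %d (%d events, %d censored)\n", x$n, x$n_event, x$n_censored))
  print(signif(x$coefficients, digits))
  cat(sprintf("  slope p-value (Wald) = %.4g\n", x$p_slope))
  if (x$separation_detected) cat("  WARNING: separation detected; estimates diverge\n")
  else if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' @export
coef.er_logistic <- function(object, ...) object$coefficients

#' @export
vcov.er_logistic <- function(object, ...) object$vcov

#' @export
logLik.er_logistic <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
summary.er_logistic <- function(object, ...) {
  zs <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `z value` = zs,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zs)))
  structure(list(coefficients = tab, fit = object), class = "summary.er_logistic")
}

#' @export
print.summary.er_logistic <- function(x, ...) {
  f <- x$fit
  cat("Logistic exposure-response model\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nn = %d (%d events, %d censored); log-likelihood %.4f\n",
              f$n, f$n_event, f$n_censored, f$loglik))
  cat(sprintf("slope p (Wald) = %.4g; slope p (likelihood ratio) = %.4g\n",
              f$p_slope, f$p_lr))
  if (f$separation_detected) cat("separation detected: estimates diverge\n")
  invisible(x)
}

#' @export
predict.er_logistic <- function(object, newdata = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- stats::model.matrix(object$formula, object$model)
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  }
  eta <- drop(X %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.er_logistic <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- stats::model.response(object$model)
  mu <- predict(object, type = "response")
  if (type == "pearson") {
    (y - mu) / sqrt(mu * (1 - mu))
  } else {
    sign(y - mu) * sqrt(-2 * (y * log(mu) + (1 - y) * log1p(-mu)))
  }
}

#' @export
simulate.er_logistic <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, type = "response")
  out <- as.data.frame(
    matrix(stats::rbinom(length(mu) * nsim, 1, rep(mu, nsim)),
           ncol = nsim, dimnames = list(NULL, paste0("sim_", seq_len(nsim))))
  )
  out
}

#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return Numeric vector `c(lo, hi)`.
#' @keywords internal
#' @noRd
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Event proportions by exposure quartile
#'
#' Splits the cohort into exposure quartiles (type-7 sample quantiles, the R
#' default) and reports the per-quartile event proportion with a Wilson 95%
#' confidence interval — the numeric content of the usual quartile overlay on
#' exposure-response regression plots.
#'
#' @param dataset an `er_dataset` or any data frame with columns
#'   `exposure_ng_ml` and `responder`; at least 4 subjects.
#' @param conf confidence level of the Wilson interval.
#' @return A data frame with one row per quartile: `quartile`, `lo`, `hi`
#'   (bin edges), `median_exposure`, `n`, `events`, `prop`, `ci_lo`, `ci_hi`.
#' @export
quartile_summary <- function(dataset, conf = 0.95) {
  x <- dataset$exposure_ng_ml
  y <- dataset$responder
  n <- length(x)
  if (n < 4) stop("at least 4 subjects are required", call. = FALSE)
  breaks <- stats::quantile(x, probs = seq(0, 1, 0.25), type = 7)
  # guard against ties collapsing the breaks
  breaks <- unique(breaks)
  bin <- cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(q) {
    sel <- bin == q
    k <- sum(y[sel])
    ci <- wilson_ci(k, sum(sel), conf)
    data.frame(quartile = q, lo = breaks[q], hi = breaks[q + 1L],
               median_exposure = stats::median(x[sel]), n = sum(sel),
               events = k, prop = k / sum(sel), ci_lo = ci[1], ci_hi = ci[2])
  }))
  rownames(out) <- NULL
  out
}
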