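beta_names <- function() c("intercept", "fit", "sqrt_fit", "age", "sex_male")

# numerically stable log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

design_matrix_raw <- function(fit, age, male01) {
  if (any(fit < 0)) {
    abort("FIT concentration must be >= 0", class = "fitscreen_input_error")
  }
  cbind(
    intercept = 1, fit = fit, sqrt_fit = sqrt(fit),
    age = age, sex_male = male01
  )
}

#' Design matrix of the advanced-neoplasia risk model
#'
#' Expands a cohort into the model's design rows
#' `(1, FIT, sqrt(FIT), age, male)`: FIT in ug Hb/g faeces, the square root
#' of FIT capturing the concave dose-response of AN risk in quantitative
#' FIT, age in years, and sex coded male = 1, female = 0.
#'
#' @param data A cohort data frame with columns `fit_ug_g`, `age_years`,
#'   `sex` ("M"/"F").
#' @return A numeric matrix with columns
#'   `intercept`, `fit`, `sqrt_fit`, `age`, `sex_male`.
#' @export
design_matrix <- function(data) {
  stopifnot(all(c("fit_ug_g", "age_years", "sex") %in% names(data)))
  design_matrix_raw(
    data$fit_ug_g, data$age_years, as.numeric(data$sex == "M")
  )
}

new_risk_model <- function(beta, cov, penalty_lambda, n_obs, n_events,
                           converged, loglik = NA_real_, df_eff = NA_real_,
                           aicc = NA_real_, terms = beta_names()[-1]) {
  names(beta) <- c("intercept", terms)
  dimnames(cov) <- list(names(beta), names(beta))
  structure(
    list(
      beta = beta, cov = cov, penalty_lambda = penalty_lambda,
      n_obs = n_obs, n_events = n_events, converged = converged,
      loglik = loglik, df_eff = df_eff, aicc = aicc, terms = terms
    ),
    class = "an_risk_model"
  )
}

#' Published COCOS risk-model coefficients
#'
#' The coefficient vector (and standard errors) of the penalized logistic
#' model for advanced neoplasia developed on the colonoscopy arm of the
#' COCOS screening trial: logit P(AN) =
#' intercept + b_fit * FIT + b_sqrtfit * sqrt(FIT) + b_age * age +
#' b_sex * male. `cocos_risk_model()` wraps them in a fitted-model object
#' so they can be used directly with [predict_risk()], [invert_cutoff()]
#' and [cutoff_table()].
#'
#' @return `cocos_coefficients()` returns the named length-5 coefficient
#'   vector; `cocos_risk_model()` an `an_risk_model` whose covariance is
#'   diagonal in the published standard errors.
#' @export
#' @examples
#' m <- cocos_risk_model()
#' predict_risk(m, tibble::tibble(fit_ug_g = 36.9, age_years = 50, sex = "F"))
cocos_coefficients <- function() {
  c(
    intercept = -5.2473, fit = -0.0141, sqrt_fit = 0.4555,
    age = 0.0383, sex_male = 0.0233
  )
}

#' @rdname cocos_coefficients
#' @export
cocos_risk_model <- function() {
  se <- c(1.1246, 0.0039, 0.0669, 0.0181, 0.2250)
  new_risk_model(
    beta = cocos_coefficients(), cov = diag(se^2),
    penalty_lambda = NA_real_, n_obs = 1112L, n_events = 101L,
    converged = TRUE
  )
}

#' Fit the penalized logistic risk model for advanced neoplasia
#'
#' Fits logit P(AN) = b0 + b1 FIT + b2 sqrt(FIT) + b3 age + b4 male by
#' penalized maximum likelihood: a ridge penalty `(lambda/2) * sum_j (b_j
#' s_j)^2` on the non-intercept coefficients, with `s_j` the sample SD of
#' predictor `j` so that shrinkage acts on the standardized scale. The
#' penalty weight is selected from `penalty_grid` by the corrected
#' (effective-degrees-of-freedom) AIC, with the effective df the trace of
#' the ridge hat matrix. Optimization is Newton--Raphson with step-halving
#' (at most 100 iterations); convergence requires a gradient max-norm
#' below 1e-8.
#'
#' @param data Cohort data frame with columns `fit_ug_g`, `age_years`,
#'   `sex` and outcome `advanced_neoplasia` (0/1).
#' @param penalty_grid Non-negative ridge weights to search; `0` gives the
#'   unpenalized maximum-likelihood fit.
#' @param terms Predictors to include, a subset of
#'   `c("fit", "sqrt_fit", "age", "sex_male")`. The intercept is always
#'   included.
#' @return An object of class `an_risk_model` with elements `beta`, `cov`
#'   (inverse of the penalized information matrix), `penalty_lambda`,
#'   `n_obs`, `n_events`, `converged`, `loglik` (unpenalized log-likelihood
#'   at the fit), `df_eff` and `aicc`. Supports [tidy()], [glance()],
#'   [augment()], [predict_risk()] and [odds_ratios()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1, n = 2000))
#' fit <- fit_risk_model(cohort)
#' tidy(fit)
fit_risk_model <- function(data,
                           penalty_grid = c(0, 0.5, 1, 2, 4, 8, 16),
                           terms = c("fit", "sqrt_fit", "age", "sex_male")) {
  validate_cohort(data)
  stopifnot(length(penalty_grid) > 0, all(penalty_grid >= 0))
  terms <- match.arg(terms, beta_names()[-1], several.ok = TRUE)
  y <- as.numeric(data$advanced_neoplasia)
  if (length(unique(y)) < 2) {
    abort("outcome has a single class; both AN and non-AN rows are required",
      class = "fitscreen_fit_error"
    )
  }
  X <- design_matrix(data)[, c("intercept", terms), drop = FALSE]
  sds <- apply(X[, -1, drop = FALSE], 2, sd)
  fits <- lapply(penalty_grid, function(lambda) {
    newton_logistic(X, y, lambda, sds)
  })
  if (!any(vapply(fits, `[[`, TRUE, "converged"))) {
    abort("penalized logistic fit failed to converge at every lambda",
      class = "fitscreen_fit_error"
    )
  }
  aiccs <- vapply(fits, `[[`, 0, "aicc")
  aiccs[!vapply(fits, `[[`, TRUE, "converged")] <- Inf
  best <- which.min(aiccs)
  f <- fits[[best]]
  new_risk_model(
    beta = f$beta, cov = f$cov, penalty_lambda = penalty_grid[best],
    n_obs = length(y), n_events = as.integer(sum(y)),
    converged = f$converged, loglik = f$loglik, df_eff = f$df_eff,
    aicc = f$aicc, terms = terms
  )
}

# Newton-Raphson for ridge-penalized logistic regression. The penalty
# matrix is lambda * diag(0, sds^2): penalizing beta_j * s_j is the same as
# a plain ridge on the standardized coefficients.
newton_logistic <- function(X, y, lambda, sds, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  P <- diag(c(0, lambda * sds^2), nrow = p)
  beta <- c(qlogis(mean(y)), rep(0, p - 1))
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1pexp(eta)) - 0.5 * drop(t(b) %*% P %*% b)
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- drop(t(X) %*% (y - mu)) - drop(P %*% beta)
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    w <- mu * (1 - mu)
    H <- t(X) %*% (X * w) + P
    step <- solve(H, grad)
    # step-halving: retreat until the penalized log-likelihood improves
    for (h in 0:30) {
      cand <- beta + step / 2^h
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    beta <- cand
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  info <- t(X) %*% (X * w)
  H <- info + P
  Hinv <- solve(H)
  df_eff <- sum(diag(Hinv %*% info))
  loglik <- sum(y * eta - log1pexp(eta))
  n <- length(y)
  aicc <- -2 * loglik + 2 * df_eff +
    2 * df_eff * (df_eff + 1) / max(n - df_eff - 1, 1)
  list(
    beta = beta, cov = Hinv, converged = converged,
    loglik = loglik, df_eff = df_eff, aicc = aicc
  )
}

#' Predicted probability of advanced neoplasia
#'
#' Applies the fitted (or published) risk model to participant profiles:
#' the inverse logit of the linear predictor over
#' `(1, FIT, sqrt(FIT), age, male)`. Probabilities are strictly inside
#' (0, 1) for finite inputs.
#'
#' @param model An `an_risk_model`.
#' @param data A data frame with columns `fit_ug_g`, `age_years`, `sex`.
#' @return A numeric vector of probabilities, one per row of `data`.
#' @seealso [add_risk()] to append the prediction as a column.
#' @export
predict_risk <- function(model, data) {
  stopifnot(inherits(model, "an_risk_model"))
  X <- design_matrix(data)[, names(model$beta), drop = FALSE]
  plogis(drop(X %*% model$beta))
}

#' @rdname predict_risk
#' @param ... Unused.
#' @param newdata Data frame of participant profiles.
#' @export
predict.an_risk_model <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Append model risk to a cohort
#'
#' @param data Cohort data frame.
#' @param model An `an_risk_model`.
#' @return `data` as a tibble with an added `.risk` column.
#' @export
add_risk <- function(data, model) {
  dplyr::mutate(tibble::as_tibble(data), .risk = predict_risk(model, data))
}

#' Odds ratios of the fitted risk model
#'
#' Exponentiates the coefficients and their Wald 95% confidence limits
#' (`exp(beta +/- 1.96 SE)`), the scale on which screening models are
#' conventionally reported: per ug Hb/g for FIT, per unit sqrt(FIT),
#' per year of age, and male vs female.
#'
#' @param model An `an_risk_model`.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `odds_ratio`, `or_low`, `or_high`.
#' @export
odds_ratios <- function(model) {
  stopifnot(inherits(model, "an_risk_model"))
  se <- sqrt(diag(model$cov))
  tibble::tibble(
    term = names(model$beta),
    estimate = unname(model$beta),
    std_error = unname(se),
    odds_ratio = exp(unname(model$beta)),
    or_low = exp(unname(model$beta) - 1.96 * se),
    or_high = exp(unname(model$beta) + 1.96 * se)
  )
}

#' Generalized likelihood-ratio test between nested risk models
#'
#' Compares goodness-of-fit of two nested predictor sets. Both models are
#' refit unpenalized (lambda = 0) on the same cohort, because
#' likelihood-ratio asymptotics do not hold under shrinkage. The statistic
#' is twice the log-likelihood gain of the larger model, referred to a
#' chi-square with df equal to the number of added predictors.
#'
#' @param data Cohort data frame.
#' @param nested,full Character vectors of predictor names (subsets of
#'   `c("fit", "sqrt_fit", "age", "sex_male")`); `nested` must be a strict
#'   subset of `full`.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, and the two
#'   log-likelihoods.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 2, n = 2000))
#' lr_test(cohort, nested = c("fit", "sqrt_fit"), full = c("fit", "sqrt_fit", "age"))
lr_test <- function(data, nested, full) {
  if (!all(nested %in% full)) {
    abort("`nested` must be a subset of `full`", class = "fitscreen_input_error")
  }
  m0 <- fit_risk_model(data, penalty_grid = 0, terms = nested)
  m1 <- fit_risk_model(data, penalty_grid = 0, terms = full)
  stat <- max(2 * (m1$loglik - m0$loglik), 0)
  df <- length(full) - length(nested)
  tibble::tibble(
    statistic = stat, df = df,
    p_value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE),
    loglik_nested = m0$loglik, loglik_full = m1$loglik
  )
}

#' @export
print.an_risk_model <- function(x, ...) {
  cat("<an_risk_model> logit P(AN) ~", paste(x$terms, collapse = " + "), "\n")
  cat(sprintf(
    "  n = %d (%d events), lambda = %s, converged = %s\n",
    x$n_obs, x$n_events, format(x$penalty_lambda), x$converged
  ))
  print(odds_ratios(x), n = Inf)
  invisible(x)
}

#' @export
tidy.an_risk_model <- function(x, exponentiate = FALSE, ...) {
  or <- odds_ratios(x)
  if (exponentiate) {
    dplyr::select(or, "term",
      estimate = "odds_ratio", std_error = "std_error",
      conf_low = "or_low", conf_high = "or_high"
    )
  } else {
    dplyr::transmute(or,
      term = .data$term, estimate = .data$estimate,
      std_error = .data$std_error,
      statistic = .data$estimate / .data$std_error,
      conf_low = .data$estimate - 1.96 * .data$std_error,
      conf_high = .data$estimate + 1.96 * .data$std_error
    )
  }
}

#' @export
glance.an_risk_model <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_events = x$n_events,
    penalty_lambda = x$penalty_lambda, df_eff = x$df_eff,
    loglik = x$loglik, aicc = x$aicc, converged = x$converged
  )
}

#' @export
augment.an_risk_model <- function(x, data, ...) {
  add_risk(data, x)
}
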