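#' Analytic moments of a generator configuration
#'
#' Computes, without simulation, the tail probability P(FIT >= x) of the
#' two-part FIT mixture and the marginal prevalence of advanced neoplasia
#' implied by a [cohort_config()] — the expectation of
#' `plogis(true_beta . design_row)` over the joint covariate distribution
#' (truncated-normal age, Bernoulli sex, mixture FIT). Integration uses
#' Gauss--Legendre quadrature on each continuous coordinate, so the result
#' is deterministic and is the yardstick the Monte-Carlo generator is
#' checked against.
#'
#' @param config A [cohort_config()].
#' @param fit_tail_at Concentration (ug Hb/g) at which the upper-tail
#'   probability of FIT is evaluated (default 20, the conventional
#'   positivity cut-off).
#' @return A one-row tibble with `p_fit_ge_tail`, `an_prevalence`, and
#'   `p_an_fit_lt_5` (the model-implied share of AN cases with FIT below
#'   5 ug Hb/g).
#' @export
config_moments <- function(config, fit_tail_at = 20) {
  config <- validate_cohort_config(config)
  pi0 <- config$fit_zero_mass
  mu <- config$fit_lognormal_mu
  sg <- config$fit_lognormal_sigma
  # tail of the mixture: the uniform component lives on [0, lod)
  tail_unif <- if (fit_tail_at >= config$fit_lod) {
    0
  } else {
    (config$fit_lod - fit_tail_at) / config$fit_lod
  }
  p_tail <- pi0 * tail_unif +
    (1 - pi0) * pnorm((log(fit_tail_at) - mu) / sg, lower.tail = FALSE)

  q <- mixture_quadrature(config)
  risk <- plogis(drop(
    design_matrix_raw(q$fit, q$age, q$male) %*% config$true_beta
  ))
  prev <- sum(q$w * risk)
  p_an_lt5 <- sum(q$w * risk * (q$fit < 5)) / prev
  tibble::tibble(
    p_fit_ge_tail = p_tail,
    an_prevalence = prev,
    p_an_fit_lt_5 = p_an_lt5
  )
}

# Tensor quadrature grid over (fit, age, sex) with joint weights summing
# to 1. FIT: Gauss-Legendre on [0, lod) for the sub-detection mass and on
# z in [-8, 8] (standard-normal scale) for the lognormal body; age:
# Gauss-Legendre against the truncated-normal density.
mixture_quadrature <- function(config, n_fit = 96, n_age = 48) {
  gl_fit_u <- pracma::gaussLegendre(24, 0, config$fit_lod)
  w_u <- config$fit_zero_mass * gl_fit_u$w / config$fit_lod
  gl_fit_z <- pracma::gaussLegendre(n_fit, -8, 8)
  w_l <- (1 - config$fit_zero_mass) * gl_fit_z$w * dnorm(gl_fit_z$x)
  fit_nodes <- c(gl_fit_u$x, exp(
    config$fit_lognormal_mu + config$fit_lognormal_sigma * gl_fit_z$x
  ))
  fit_w <- c(w_u, w_l)
  fit_w <- fit_w / sum(fit_w)

  b <- config$age_bounds
  gl_age <- pracma::gaussLegendre(n_age, b[1], b[2])
  age_w <- gl_age$w * dnorm(gl_age$x, config$age_mean, config$age_sd)
  age_w <- age_w / sum(age_w)

  grid <- expand.grid(
    i_fit = seq_along(fit_nodes), i_age = seq_along(gl_age$x), male = 0:1
  )
  list(
    fit = fit_nodes[grid$i_fit],
    age = gl_age$x[grid$i_age],
    male = grid$male,
    w = fit_w[grid$i_fit] * age_w[grid$i_age] *
      ifelse(grid$male == 1, config$p_male, 1 - config$p_male)
  )
}

#' Calibrate the FIT mixture to published cohort margins
#'
#' Tunes the FIT-mixture parameters of a generator configuration so that,
#' analytically (see [config_moments()]), the cohort reproduces two
#' published margins: the fraction of participants with FIT >= 20 ug Hb/g
#' and the marginal prevalence of advanced neoplasia under `true_beta`.
#'
#' The search is deterministic and exactly identified: the sub-detection
#' mass `pi` is kept at its `config0` value; given `(pi, sigma)`, the
#' lognormal location `mu` is solved in closed form from the tail target,
#' `mu = log(20) - sigma * qnorm(1 - target / (1 - pi))`; and `sigma` is
#' found by 1-D root bracketing ([stats::uniroot]) on the analytic
#' prevalence, which is monotone decreasing in `sigma` once the tail is
#' pinned (a wider lognormal moves mass out of the moderate
#' concentrations where the model's AN risk is highest). A two-parameter
#' search against two targets avoids the indeterminacy of tuning all
#' three mixture parameters at once.
#'
#' @param target_frac_ge_20 Target P(FIT >= 20), in (0, 1).
#' @param target_prevalence Target marginal AN prevalence, in (0, 1).
#' @param config0 Starting [cohort_config()]; all non-mixture parameters
#'   are carried over unchanged.
#' @param tol Absolute tolerance on both targets (default 0.005).
#' @return A `cohort_config` whose analytic moments match the targets
#'   within `tol`.
#' @export
#' @examples
#' cfg <- calibrate_fit_mixture(0.052, 0.091, cohort_config())
#' config_moments(cfg)
calibrate_fit_mixture <- function(target_frac_ge_20, target_prevalence,
                                  config0 = cohort_config(), tol = 0.005) {
  stopifnot(
    target_frac_ge_20 > 0, target_frac_ge_20 < 1,
    target_prevalence > 0, target_prevalence < 1
  )
  config0 <- validate_cohort_config(config0)
  pi0 <- config0$fit_zero_mass
  if (target_frac_ge_20 >= 1 - pi0) {
    abort("tail target exceeds the mass above the detection floor",
      class = "fitscreen_calibration_error"
    )
  }

  with_sigma <- function(sg) {
    cfg <- config0
    cfg$fit_lognormal_sigma <- sg
    cfg$fit_lognormal_mu <-
      log(20) - sg * qnorm(1 - target_frac_ge_20 / (1 - pi0))
    cfg
  }
  prev_resid <- function(sg) {
    config_moments(with_sigma(sg))$an_prevalence - target_prevalence
  }
  bracket <- c(0.2, 6)
  lo <- prev_resid(bracket[1])
  hi <- prev_resid(bracket[2])
  if (sign(lo) == sign(hi)) {
    abort(
      sprintf(
        "calibration infeasible: prevalence residual spans [%.4f, %.4f] over sigma in [%g, %g]",
        min(lo, hi), max(lo, hi), bracket[1], bracket[2]
      ),
      class = "fitscreen_calibration_error"
    )
  }
  root <- stats::uniroot(prev_resid, bracket, tol = 1e-10)
  cfg <- with_sigma(root$root)
  m <- config_moments(cfg)
  if (abs(m$p_fit_ge_tail - target_frac_ge_20) > tol ||
    abs(m$an_prevalence - target_prevalence) > tol) {
    abort(
      sprintf(
        "calibration failed: residuals %.4g (tail), %.4g (prevalence)",
        m$p_fit_ge_tail - target_frac_ge_20,
        m$an_prevalence - target_prevalence
      ),
      class = "fitscreen_calibration_error"
    )
  }
  cfg
}
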