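#' Configuration for the synthetic screening-cohort generator
#'
#' Builds and validates the parameter set that [generate_cohort()] consumes.
#' The defaults emulate the colonoscopy arm of the COCOS screening trial:
#' 1112 participants aged 50--75 (mean 60.6, SD 6.2), 51.2% male, and a
#' quantitative FIT distribution calibrated (see [calibrate_fit_mixture()])
#' so that analytically 5.2% of participants have FIT >= 20 ug Hb/g and the
#' marginal prevalence of advanced neoplasia (AN) is 9.1%.
#'
#' FIT concentration is drawn from a two-part mixture: with probability
#' `fit_zero_mass` a value uniform on `[0, fit_lod)` (the sub-detection
#' mass), otherwise lognormal with parameters `fit_lognormal_mu` and
#' `fit_lognormal_sigma` on the log scale. AN labels are drawn from a
#' logistic model in FIT, sqrt(FIT), age and sex with coefficient vector
#' `true_beta`, so the generating mechanism matches the model the package
#' fits and parameter recovery is well posed.
#'
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   cohort.
#' @param n Number of participants.
#' @param age_mean,age_sd Mean and SD (years) of the age distribution before
#'   truncation.
#' @param age_bounds Length-2 numeric, inclusive age truncation bounds.
#' @param p_male Probability a participant is male.
#' @param fit_zero_mass Probability the FIT value falls below the assay
#'   detection floor (drawn uniform on `[0, fit_lod)`).
#' @param fit_lod Detection floor in ug Hb/g faeces.
#' @param fit_lognormal_mu,fit_lognormal_sigma Log-scale parameters of the
#'   continuous FIT component.
#' @param true_beta Named length-5 coefficient vector
#'   `(intercept, fit, sqrt_fit, age, sex_male)` on the logit scale used to
#'   draw AN labels. Defaults to the published COCOS coefficients
#'   (see [cocos_risk_model()]).
#' @param p_crc_given_an Probability an AN case is colorectal cancer rather
#'   than an advanced adenoma (default 7/101, the published case mix).
#'
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()], [calibrate_fit_mixture()]
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1, n = 500)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(seed = 1L,
                          n = 1112L,
                          age_mean = 60.6,
                          age_sd = 6.2,
                          age_bounds = c(50, 75),
                          p_male = 0.512,
                          fit_zero_mass = 0.1,
                          fit_lod = 2,
                          fit_lognormal_mu = -2.2865977,
                          fit_lognormal_sigma = 3.3566201,
                          true_beta = cocos_coefficients(),
                          p_crc_given_an = 7 / 101) {
  cfg <- structure(
    list(
      seed = as.integer(seed), n = as.integer(n),
      age_mean = age_mean, age_sd = age_sd, age_bounds = as.numeric(age_bounds),
      p_male = p_male,
      fit_zero_mass = fit_zero_mass, fit_lod = fit_lod,
      fit_lognormal_mu = fit_lognormal_mu,
      fit_lognormal_sigma = fit_lognormal_sigma,
      true_beta = true_beta,
      p_crc_given_an = p_crc_given_an
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      abort(sprintf("invalid `%s`: %s", field, msg),
        class = "fitscreen_config_error"
      )
    }
  }
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
    "seed", "must be a single finite integer")
  chk(is.numeric(cfg$n) && length(cfg$n) == 1 && cfg$n >= 0,
    "n", "must be a single count >= 0")
  for (p in c("p_male", "fit_zero_mass", "p_crc_given_an")) {
    chk(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1 &&
      cfg[[p]] >= 0 && cfg[[p]] <= 1, p, "must be a probability in [0, 1]")
  }
  chk(is.numeric(cfg$age_sd) && cfg$age_sd > 0, "age_sd", "must be > 0")
  chk(is.numeric(cfg$age_mean) && is.finite(cfg$age_mean),
    "age_mean", "must be finite")
  chk(is.numeric(cfg$age_bounds) && length(cfg$age_bounds) == 2 &&
    cfg$age_bounds[1] < cfg$age_bounds[2],
    "age_bounds", "must be an increasing length-2 numeric")
  chk(is.numeric(cfg$fit_lod) && cfg$fit_lod > 0, "fit_lod", "must be > 0")
  chk(is.numeric(cfg$fit_lognormal_sigma) && cfg$fit_lognormal_sigma > 0,
    "fit_lognormal_sigma", "must be > 0")
  chk(is.numeric(cfg$fit_lognormal_mu) && is.finite(cfg$fit_lognormal_mu),
    "fit_lognormal_mu", "must be finite")
  chk(is.numeric(cfg$true_beta) && length(cfg$true_beta) == 5 &&
    !anyNA(cfg$true_beta),
    "true_beta", "must be a length-5 numeric coefficient vector")
  names(cfg$true_beta) <- beta_names()
  cfg
}

#' Read or write a generator configuration as JSON
#'
#' The JSON document is flat with snake_case keys matching the arguments of
#' [cohort_config()]; unknown keys are rejected so silently misspelled
#' parameters cannot slip through.
#'
#' @param path File path.
#' @param config A `cohort_config` object.
#' @return `read_cohort_config()` returns a validated `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")),
      class = "fitscreen_config_error"
    )
  }
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf(
    "  age ~ truncN(%.1f, %.1f) on [%g, %g]; P(male) = %.3f\n",
    x$age_mean, x$age_sd, x$age_bounds[1], x$age_bounds[2], x$p_male
  ))
  cat(sprintf(
    "  FIT ~ %.3f * U[0, %g) + %.3f * logN(%.4f, %.4f)\n",
    x$fit_zero_mass, x$fit_lod, 1 - x$fit_zero_mass,
    x$fit_lognormal_mu, x$fit_lognormal_sigma
  ))
  cat("  true_beta:", paste(sprintf("%.4f", x$true_beta), collapse = " "), "\n")
  invisible(x)
}
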