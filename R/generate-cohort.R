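#' Generate a synthetic screening cohort
#'
#' Draws a cohort of screening participants with the joint
#' (age, sex, FIT, advanced-neoplasia) structure described by a
#' [cohort_config()]: truncated-normal age (rejection sampling), Bernoulli
#' sex, two-part mixture FIT (sub-detection uniform mass plus a lognormal
#' body), and AN labels drawn from the logistic risk model defined by
#' `config$true_beta`. Among AN cases, the lesion is CRC with probability
#' `config$p_crc_given_an`, otherwise an advanced adenoma.
#'
#' The generator is fully deterministic given the config (including its
#' seed) and does not disturb the caller's RNG state.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant and columns
#'   `id` (character), `age_years`, `sex` ("M"/"F"), `fit_ug_g`,
#'   `advanced_neoplasia` (0/1 integer), `lesion` ("none"/"AA"/"CRC").
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7, n = 200))
#' cohort_summary(cohort)
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  n <- config$n
  if (n == 0) {
    return(tibble::tibble(
      id = character(), age_years = numeric(), sex = character(),
      fit_ug_g = numeric(), advanced_neoplasia = integer(),
      lesion = character()
    ))
  }
  withr::with_seed(config$seed, {
    age <- rtruncnorm(n, config$age_mean, config$age_sd, config$age_bounds)
    male <- rbinom(n, 1L, config$p_male)
    below <- rbinom(n, 1L, config$fit_zero_mass) == 1L
    fit <- numeric(n)
    fit[below] <- runif(sum(below), 0, config$fit_lod)
    fit[!below] <- exp(rnorm(
      sum(!below),
      config$fit_lognormal_mu, config$fit_lognormal_sigma
    ))
    risk <- plogis(
      design_matrix_raw(fit, age, male) %*% config$true_beta
    )[, 1]
    an <- rbinom(n, 1L, risk)
    lesion <- rep("none", n)
    n_an <- sum(an)
    if (n_an > 0) {
      crc <- rbinom(n_an, 1L, config$p_crc_given_an)
      lesion[an == 1L] <- ifelse(crc == 1L, "CRC", "AA")
    }
    tibble::tibble(
      id = sprintf("P%06d", seq_len(n)),
      age_years = age,
      sex = ifelse(male == 1L, "M", "F"),
      fit_ug_g = fit,
      advanced_neoplasia = as.integer(an),
      lesion = lesion
    )
  })
}

# Truncated-normal sampling by rejection; vectorised rounds, deterministic
# given the RNG state. Acceptance probability for the default config is
# ~0.95 so the loop terminates almost immediately.
rtruncnorm <- function(n, mean, sd, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 1L)
    draw <- rnorm(ceiling(m * 1.5) + 8L, mean, sd)
    draw <- draw[draw >= bounds[1] & draw <= bounds[2]]
    out <- c(out, draw)
  }
  out[seq_len(n)]
}

#' Summarise a screening cohort
#'
#' Computes the baseline margins used to characterise a screening cohort:
#' size, age distribution, sex split, AN prevalence, the share of
#' participants at or above the conventional 20 ug Hb/g FIT positivity
#' cut-off, and the share of AN cases with FIT below 5 ug Hb/g (the
#' low-FIT cases a uniform cut-off cannot reach).
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @return A one-row tibble with columns `n`, `age_mean`, `age_sd`,
#'   `pct_male`, `an_prevalence_pct`, `n_fit_ge_20`, `pct_fit_ge_20`,
#'   `pct_an_fit_lt_5`.
#' @export
cohort_summary <- function(cohort) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0) {
    abort("cannot summarise an empty cohort", class = "fitscreen_input_error")
  }
  an <- cohort$advanced_neoplasia == 1L
  tibble::tibble(
    n = nrow(cohort),
    age_mean = mean(cohort$age_years),
    age_sd = sd(cohort$age_years),
    pct_male = 100 * mean(cohort$sex == "M"),
    an_prevalence_pct = 100 * mean(an),
    n_fit_ge_20 = sum(cohort$fit_ug_g >= 20),
    pct_fit_ge_20 = 100 * mean(cohort$fit_ug_g >= 20),
    pct_an_fit_lt_5 = if (any(an)) {
      100 * mean(cohort$fit_ug_g[an] < 5)
    } else {
      NA_real_
    }
  )
}

validate_cohort <- function(cohort, check_ranges = TRUE) {
  required <- c(
    "id", "age_years", "sex", "fit_ug_g", "advanced_neoplasia", "lesion"
  )
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    abort(
      sprintf("cohort is missing column(s): %s", paste(missing, collapse = ", ")),
      class = "fitscreen_input_error"
    )
  }
  if (check_ranges && nrow(cohort) > 0) {
    bad_age <- which(!is.finite(cohort$age_years) |
      cohort$age_years < 50 | cohort$age_years > 75)
    if (length(bad_age) > 0) {
      abort(sprintf("row %d: `age_years` must lie in [50, 75]", bad_age[1]),
        class = "fitscreen_input_error"
      )
    }
    bad_fit <- which(!is.finite(cohort$fit_ug_g) | cohort$fit_ug_g < 0)
    if (length(bad_fit) > 0) {
      abort(sprintf("row %d: `fit_ug_g` must be a finite value >= 0", bad_fit[1]),
        class = "fitscreen_input_error"
      )
    }
    bad_sex <- which(!cohort$sex %in% c("M", "F"))
    if (length(bad_sex) > 0) {
      abort(sprintf("row %d: `sex` must be 'M' or 'F'", bad_sex[1]),
        class = "fitscreen_input_error"
      )
    }
    bad_an <- which(!cohort$advanced_neoplasia %in% c(0L, 1L))
    if (length(bad_an) > 0) {
      abort(sprintf("row %d: `advanced_neoplasia` must be 0 or 1", bad_an[1]),
        class = "fitscreen_input_error"
      )
    }
    bad_lesion <- which(
      (cohort$advanced_neoplasia == 0L & cohort$lesion != "none") |
        (cohort$advanced_neoplasia == 1L & !cohort$lesion %in% c("AA", "CRC"))
    )
    if (length(bad_lesion) > 0) {
      abort(
        sprintf(
          "row %d: `lesion` inconsistent with `advanced_neoplasia` (none <=> 0; AA/CRC <=> 1)",
          bad_lesion[1]
        ),
        class = "fitscreen_input_error"
      )
    }
  }
  invisible(cohort)
}
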