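#' Classify a FIT result against a concentration cut-off
#'
#' Positivity is "equal or higher than" the cut-off, mirroring the
#' convention of FIT-based screening programmes (a result of exactly
#' 20 ug Hb/g is positive at the 20 ug Hb/g cut-off).
#'
#' @param fit_conc FIT concentration(s), ug Hb/g faeces, >= 0.
#' @param cutoff Cut-off concentration, ug Hb/g faeces, >= 0.
#' @return Logical vector: `TRUE` where `fit_conc >= cutoff`.
#' @export
classify_fit <- function(fit_conc, cutoff) {
  stopifnot(all(fit_conc >= 0), all(cutoff >= 0))
  fit_conc >= cutoff
}

new_risk_threshold <- function(risk, criterion, achieved_specificity,
                               n_positives, reference_fit_cutoff = NA_real_) {
  tibble::new_tibble(
    tibble::tibble(
      risk = risk, criterion = criterion,
      reference_fit_cutoff = reference_fit_cutoff,
      achieved_specificity = achieved_specificity,
      n_positives = as.integer(n_positives)
    ),
    class = "risk_threshold"
  )
}

#' Select a uniform risk threshold matched on specificity
#'
#' Chooses, among the observed predicted risks, the classification
#' threshold (positive iff risk >= threshold) whose specificity over the
#' disease-negative participants is closest to `target_specificity`. Ties
#' are broken toward the lower threshold, i.e. the more sensitive rule.
#' This is how a risk-based rule is matched to the specificity of a
#' uniform FIT cut-off so the two strategies refer comparable fractions of
#' disease-free participants.
#'
#' @param risks Predicted probabilities, one per participant.
#' @param labels Outcome indicator (logical or 0/1): advanced neoplasia.
#' @param target_specificity Target specificity in `[0, 1]`.
#' @param reference_fit_cutoff Optional: the uniform FIT cut-off whose
#'   specificity is being matched, recorded in the result.
#' @return A one-row tibble (class `risk_threshold`) with columns `risk`,
#'   `criterion`, `reference_fit_cutoff`, `achieved_specificity`,
#'   `n_positives`.
#' @export
#' @examples
#' threshold_matched_specificity(c(.1, .2, .3, .4), c(0, 0, 0, 1), 2 / 3)
threshold_matched_specificity <- function(risks, labels, target_specificity,
                                          reference_fit_cutoff = NA_real_) {
  labels <- as.logical(labels)
  if (length(risks) == 0 || length(risks) != length(labels)) {
    abort("`risks` and `labels` must be non-empty and aligned",
      class = "fitscreen_input_error"
    )
  }
  if (!any(!labels)) {
    abort("at least one disease-negative participant is required",
      class = "fitscreen_input_error"
    )
  }
  # candidates: every observed risk, plus one above the maximum so that
  # "nobody positive" (specificity 1) is attainable
  candidates <- sort(unique(risks))
  candidates <- c(candidates, max(candidates) + (1 - max(candidates)) / 2)
  neg <- risks[!labels]
  spec <- vapply(candidates, function(th) mean(neg < th), 0)
  gap <- abs(spec - target_specificity)
  best <- which(gap == min(gap))[1] # candidates ascending: first = lowest
  th <- candidates[best]
  new_risk_threshold(
    risk = th, criterion = "matched_specificity",
    achieved_specificity = spec[best],
    n_positives = sum(risks >= th),
    reference_fit_cutoff = reference_fit_cutoff
  )
}

#' Select a uniform risk threshold matched on the number of positives
#'
#' Sets the threshold at the k-th largest predicted risk so that the
#' risk-based rule refers (at least) `k` participants — the
#' "identical number of colonoscopies" comparison. If several
#' participants tie at the boundary risk, all of them are referred and the
#' realised count is recorded.
#'
#' @param risks Predicted probabilities, one per participant.
#' @param k Number of positives to match, `0 <= k <= length(risks)`.
#' @inheritParams threshold_matched_specificity
#' @return A one-row `risk_threshold` tibble; `n_positives >= k`, with
#'   equality whenever the k-th and (k+1)-th largest risks differ.
#' @export
threshold_matched_positives <- function(risks, k,
                                        reference_fit_cutoff = NA_real_) {
  n <- length(risks)
  if (k > n || k < 0) {
    abort("`k` must lie in [0, length(risks)]", class = "fitscreen_input_error")
  }
  if (k == 0) {
    th <- max(risks) + (1 - max(risks)) / 2
  } else {
    th <- sort(risks, decreasing = TRUE)[k]
  }
  new_risk_threshold(
    risk = th, criterion = "matched_positives",
    achieved_specificity = NA_real_,
    n_positives = sum(risks >= th),
    reference_fit_cutoff = reference_fit_cutoff
  )
}

#' Logit of a risk
#'
#' @param risk Probability strictly inside (0, 1).
#' @return `log(risk / (1 - risk))`.
#' @export
risk_to_logit <- function(risk) {
  if (any(risk <= 0 | risk >= 1)) {
    abort("`risk` must lie strictly inside (0, 1)",
      class = "fitscreen_input_error"
    )
  }
  qlogis(risk)
}

#' Invert the risk model into an individualized FIT cut-off
#'
#' For a participant profile (age, sex), finds the FIT concentration at
#' which the model-predicted risk of advanced neoplasia equals
#' `risk_threshold`. Writing `x = sqrt(F)`, the linear predictor equation
#' `b_fit F + b_sqrtfit x = L - offset` (with `L` the logit of the
#' threshold and `offset` the age/sex part) is the quadratic
#' `|b_fit| x^2 - b_sqrtfit x + c = 0`; the smaller positive root lies on
#' the rising branch of the risk-versus-FIT curve and is the
#' screening-relevant solution. When the fitted signs do not have the
#' expected shape (`b_fit < 0 < b_sqrtfit`), the cut-off falls back to
#' monotone 1-D root bracketing of the predicted risk.
#'
#' Flags: `"always_positive"` (cut-off 0) when the age/sex profile alone
#' already reaches the threshold risk; `"unreachable"` when no FIT
#' concentration on the rising branch attains it; `"below_lod"` when the
#' cut-off is positive but below the assay detection floor `lod`;
#' otherwise `"ok"`.
#'
#' @param model An `an_risk_model` (fitted or [cocos_risk_model()]).
#' @param age Age(s), years.
#' @param sex `"M"`/`"F"`, recycled against `age`.
#' @param risk_threshold Risk threshold in (0, 1).
#' @param lod Assay limit of detection, ug Hb/g (default 2).
#' @return A tibble with columns `age_years`, `sex`, `fit_cutoff_ug_g`
#'   (`NA` when unreachable) and `flag`.
#' @export
#' @examples
#' invert_cutoff(cocos_risk_model(), age = 50, sex = "F", risk_threshold = 0.2524)
invert_cutoff <- function(model, age, sex, risk_threshold, lod = 2) {
  stopifnot(inherits(model, "an_risk_model"))
  if (length(risk_threshold) != 1 ||
    risk_threshold <= 0 || risk_threshold >= 1) {
    abort("`risk_threshold` must be a single value in (0, 1)",
      class = "fitscreen_input_error"
    )
  }
  prof <- vctrs_recycle(age, sex)
  b <- full_beta(model)
  L <- risk_to_logit(risk_threshold)
  male01 <- as.numeric(prof$sex == "M")
  cc <- unname(L - (b["intercept"] + b["age"] * prof$age + b["sex_male"] * male01))

  solve_one <- function(c_i, age_i, male_i) {
    if (c_i <= 0) {
      return(list(cut = 0, flag = "always_positive"))
    }
    if (b["fit"] < 0 && b["sqrt_fit"] > 0) {
      a <- -b["fit"]
      disc <- b["sqrt_fit"]^2 - 4 * a * c_i
      if (disc < 0) {
        return(list(cut = NA_real_, flag = "unreachable"))
      }
      x <- (b["sqrt_fit"] - sqrt(disc)) / (2 * a)
      cut <- unname(x^2)
    } else {
      # monotone fallback: bracket the threshold on a rising risk curve
      f <- function(F) {
        b["fit"] * F + b["sqrt_fit"] * sqrt(F) - c_i
      }
      hi <- 1
      while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
      if (f(hi) < 0) {
        return(list(cut = NA_real_, flag = "unreachable"))
      }
      cut <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
    }
    flag <- if (cut > 0 && cut < lod) "below_lod" else "ok"
    list(cut = cut, flag = flag)
  }
  sol <- purrr::pmap(
    list(cc, prof$age, male01),
    function(c_i, age_i, male_i) solve_one(c_i, age_i, male_i)
  )
  tibble::tibble(
    age_years = prof$age,
    sex = prof$sex,
    fit_cutoff_ug_g = purrr::map_dbl(sol, "cut"),
    flag = purrr::map_chr(sol, "flag")
  )
}

# recycle age/sex to common length
vctrs_recycle <- function(age, sex) {
  n <- max(length(age), length(sex))
  list(age = rep_len(age, n), sex = rep_len(sex, n))
}

# coefficient vector padded with zeros for terms absent from the fit
full_beta <- function(model) {
  b <- stats::setNames(numeric(5), beta_names())
  b[names(model$beta)] <- model$beta
  b
}

#' Individualized FIT cut-off table over an age range
#'
#' Tabulates [invert_cutoff()] for every combination of integer age and
#' sex at a fixed risk threshold — the screening programme's lookup table
#' of personal FIT cut-off concentrations. Raw cut-offs are retained in
#' `fit_cutoff_ug_g`; `fit_cutoff_display` rounds to 0.1 ug Hb/g for
#' reporting.
#'
#' @inheritParams invert_cutoff
#' @param ages Integer ages to tabulate (default 50:75).
#' @return A tibble of class `fit_cutoff_table`, rows sorted by sex then
#'   age, with attributes `risk_threshold` and `lod`.
#' @export
#' @examples
#' head(cutoff_table(cocos_risk_model(), risk_threshold = 0.2524))
cutoff_table <- function(model, risk_threshold, ages = 50:75, lod = 2) {
  if (any(ages < 50 | ages > 75)) {
    abort("`ages` must lie within [50, 75]", class = "fitscreen_input_error")
  }
  grid <- tidyr::expand_grid(sex = c("F", "M"), age = as.numeric(ages))
  out <- invert_cutoff(model, grid$age, grid$sex, risk_threshold, lod = lod)
  out <- dplyr::arrange(out, .data$sex, .data$age_years)
  out$fit_cutoff_display <- round(out$fit_cutoff_ug_g, 1)
  attr(out, "risk_threshold") <- risk_threshold
  attr(out, "lod") <- lod
  class(out) <- c("fit_cutoff_table", class(out))
  out
}
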