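#' Confusion counts at a score threshold
#'
#' Cross-tabulates a continuous score (FIT concentration or predicted
#' risk) against the outcome at a threshold, with positivity defined as
#' score >= threshold.
#'
#' @param scores Numeric scores, one per participant.
#' @param labels Outcome indicator (logical or 0/1).
#' @param threshold Positivity threshold on the score scale.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`, `n_positives`.
#' @export
confusion <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  if (length(scores) == 0 || length(scores) != length(labels)) {
    abort("`scores` and `labels` must be non-empty and aligned",
      class = "fitscreen_input_error"
    )
  }
  pos <- scores >= threshold
  tibble::tibble(
    tp = sum(pos & labels), fp = sum(pos & !labels),
    tn = sum(!pos & !labels), fn = sum(!pos & labels),
    n_positives = sum(pos)
  )
}

#' Diagnostic performance from confusion counts
#'
#' Point estimates of sensitivity, specificity, and predictive values. A
#' metric whose denominator is zero is returned as `NA` and listed in the
#' `undefined` column rather than raising an error.
#'
#' @param counts A one-row data frame with columns `tp`, `fp`, `tn`, `fn`
#'   (as from [confusion()]).
#' @return A one-row tibble with `sensitivity`, `specificity`, `ppv`,
#'   `npv` (proportions), `n_positives`, and `undefined` (comma-separated
#'   names of undefined metrics, `""` if none).
#' @export
#' @examples
#' performance(tibble::tibble(tp = 28, fp = 30, tn = 981, fn = 73))
performance <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble::tibble(
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp),
    ppv = ratio(counts$tp, counts$tp + counts$fp),
    npv = ratio(counts$tn, counts$tn + counts$fn),
    n_positives = counts$tp + counts$fp
  )
  und <- names(out)[1:4][is.na(unlist(out[1, 1:4]))]
  out$undefined <- paste(und, collapse = ",")
  out
}

#' Percentile bootstrap confidence intervals for cohort statistics
#'
#' Nonparametric bootstrap over participants: the cohort rows are
#' resampled with replacement `B` times, `stat_fn` is recomputed on each
#' resample, and the 2.5/97.5 percentiles are reported. Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param data Cohort data frame (rows are the resampling unit).
#' @param stat_fn Function of one resampled data frame returning a named
#'   numeric vector of statistics.
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per statistic: `metric`, `estimate` (on
#'   the full cohort), `ci_low`, `ci_high`, plus `B` and `seed`. Errors if
#'   a statistic is undefined (`NA`) in more than 20% of resamples.
#' @export
bootstrap_ci <- function(data, stat_fn, B = 2000, seed = 1L, conf = 0.95) {
  if (B < 100) {
    abort("`B` must be at least 100", class = "fitscreen_input_error")
  }
  n <- nrow(data)
  est <- stat_fn(data)
  draws <- withr::with_seed(seed, {
    vapply(
      seq_len(B),
      function(i) stat_fn(data[sample.int(n, n, replace = TRUE), , drop = FALSE]),
      numeric(length(est))
    )
  })
  draws <- matrix(draws, nrow = length(est))
  na_frac <- rowMeans(is.na(draws))
  if (any(na_frac > 0.2)) {
    abort(
      sprintf(
        "metric `%s` undefined in %.0f%% of bootstrap resamples",
        names(est)[which.max(na_frac)], 100 * max(na_frac)
      ),
      class = "fitscreen_bootstrap_error"
    )
  }
  alpha <- (1 - conf) / 2
  tibble::tibble(
    metric = names(est),
    estimate = unname(est),
    ci_low = apply(draws, 1, quantile, probs = alpha, na.rm = TRUE),
    ci_high = apply(draws, 1, quantile, probs = 1 - alpha, na.rm = TRUE),
    B = B, seed = as.integer(seed)
  )
}

#' Reclassification between uniform-FIT and risk-based screening rules
#'
#' Cross-classifies every participant by FIT class (FIT >= `fit_cutoff`)
#' and risk class (model risk >= `risk_threshold`), stratified by AN
#' status. The discordant cells are the participants the two strategies
#' disagree about; their total is the number reclassified.
#'
#' @param data Cohort data frame.
#' @param model An `an_risk_model`.
#' @param fit_cutoff Uniform FIT cut-off, ug Hb/g (default 20).
#' @param risk_threshold Risk threshold in (0, 1).
#' @return A tibble of class `reclassification_table` with columns
#'   `an_stratum` ("with AN"/"without AN"), `fit_class`, `risk_class`,
#'   `n`; attributes `n_reclassified`, `ppv_fit`, `ppv_risk`.
#' @export
reclassification <- function(data, model, fit_cutoff = 20, risk_threshold) {
  validate_cohort(data)
  risk <- predict_risk(model, data)
  fit_pos <- classify_fit(data$fit_ug_g, fit_cutoff)
  risk_pos <- risk >= risk_threshold
  an <- data$advanced_neoplasia == 1L
  tab <- tidyr::expand_grid(
    an_stratum = c("with AN", "without AN"),
    risk_class = c("risk+", "risk-"),
    fit_class = c("FIT+", "FIT-")
  )
  tab$n <- purrr::pmap_int(tab, function(an_stratum, risk_class, fit_class) {
    sum(
      (an == (an_stratum == "with AN")) &
        (risk_pos == (risk_class == "risk+")) &
        (fit_pos == (fit_class == "FIT+"))
    )
  })
  tab <- tab[, c("an_stratum", "fit_class", "risk_class", "n")]
  attr(tab, "n_reclassified") <- sum(
    tab$n[(tab$fit_class == "FIT+") != (tab$risk_class == "risk+")]
  )
  attr(tab, "ppv_fit") <- sum(an & fit_pos) / sum(fit_pos)
  attr(tab, "ppv_risk") <- sum(an & risk_pos) / sum(risk_pos)
  class(tab) <- c("reclassification_table", class(tab))
  tab
}

#' @export
print.reclassification_table <- function(x, ...) {
  NextMethod()
  cat(sprintf(
    "n reclassified = %d; PPV FIT = %.3f, PPV risk = %.3f\n",
    attr(x, "n_reclassified"), attr(x, "ppv_fit"), attr(x, "ppv_risk")
  ))
  invisible(x)
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' The concordance (c-statistic) form of the AUC — the probability a
#' random case scores above a random non-case, with 0.5 credit for ties —
#' with the DeLong variance for the confidence interval. Computation is
#' delegated to \pkg{pROC}.
#'
#' @param scores Numeric scores.
#' @param labels Outcome indicator (logical or 0/1); both classes must be
#'   present.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble with `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    abort("both outcome classes are required", class = "fitscreen_input_error")
  }
  r <- pROC::roc(
    response = labels, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )
  ci <- pROC::ci.auc(r, conf.level = conf, method = "delong")
  tibble::tibble(
    auc = as.numeric(pROC::auc(r)),
    ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3])
  )
}

#' DeLong test for two paired AUCs
#'
#' Tests whether two scores measured on the same participants
#' discriminate the outcome equally well, using DeLong's placement-value
#' covariance for the paired AUC difference (two-sided normal
#' approximation). Delegated to \pkg{pROC}.
#'
#' @param scores_a,scores_b Paired scores on identical participants.
#' @param labels Outcome indicator; both classes must be present.
#' @return A one-row tibble with `auc_a`, `auc_b`, `statistic` (Z for
#'   AUC_a - AUC_b), `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(scores_b))
  if (length(unique(labels)) < 2) {
    abort("both outcome classes are required", class = "fitscreen_input_error")
  }
  mk <- function(s) {
    pROC::roc(
      response = labels, predictor = s,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )
  }
  ra <- mk(scores_a)
  rb <- mk(scores_b)
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    # identical scores: zero difference with zero variance, read as no
    # evidence of any difference
    return(tibble::tibble(
      auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(ra)),
      statistic = 0, p_value = 1
    ))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  if (!is.finite(tst$statistic)) {
    abort("AUC difference has zero variance", class = "fitscreen_input_error")
  }
  tibble::tibble(
    auc_a = as.numeric(pROC::auc(ra)),
    auc_b = as.numeric(pROC::auc(rb)),
    statistic = unname(tst$statistic),
    p_value = unname(tst$p.value)
  )
}

#' Compare ROC discrimination of the risk model and FIT alone
#'
#' @param data Cohort data frame.
#' @param model An `an_risk_model`.
#' @return A one-row tibble with AUCs and DeLong CIs for the model risk
#'   and for raw FIT concentration, plus the paired DeLong test.
#' @export
roc_comparison <- function(data, model) {
  validate_cohort(data)
  labels <- data$advanced_neoplasia == 1L
  risk <- predict_risk(model, data)
  a_model <- roc_auc(risk, labels)
  a_fit <- roc_auc(data$fit_ug_g, labels)
  dl <- delong_test(risk, data$fit_ug_g, labels)
  tibble::tibble(
    auc_model = a_model$auc,
    auc_model_low = a_model$ci_low, auc_model_high = a_model$ci_high,
    auc_fit = a_fit$auc,
    auc_fit_low = a_fit$ci_low, auc_fit_high = a_fit$ci_high,
    delong_statistic = dl$statistic, delong_p = dl$p_value
  )
}

#' Sensitivity of FIT and the risk model at matched specificity
#'
#' For each uniform reference FIT cut-off: computes FIT's
#' sensitivity/specificity at that cut-off, selects the risk threshold
#' whose specificity matches it ([threshold_matched_specificity()]), and
#' computes the risk rule's sensitivity/specificity at that threshold.
#'
#' @param data Cohort data frame.
#' @param model An `an_risk_model`.
#' @param reference_cutoffs Uniform FIT cut-offs, ug Hb/g.
#' @return A tibble with one row per reference cut-off: FIT and risk-rule
#'   operating characteristics side by side.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 3, n = 3000))
#' fit <- fit_risk_model(cohort)
#' matched_sensitivity_table(cohort, fit, c(10, 15, 20, 50))
matched_sensitivity_table <- function(data, model,
                                      reference_cutoffs = c(10, 15, 20, 50)) {
  validate_cohort(data)
  labels <- data$advanced_neoplasia == 1L
  risk <- predict_risk(model, data)
  purrr::map_dfr(reference_cutoffs, function(cut) {
    fit_perf <- performance(confusion(data$fit_ug_g, labels, cut))
    th <- threshold_matched_specificity(
      risk, labels, fit_perf$specificity,
      reference_fit_cutoff = cut
    )
    risk_perf <- performance(confusion(risk, labels, th$risk))
    tibble::tibble(
      reference_cutoff = cut,
      fit_sensitivity = fit_perf$sensitivity,
      fit_specificity = fit_perf$specificity,
      fit_n_positives = fit_perf$n_positives,
      risk_threshold = th$risk,
      risk_sensitivity = risk_perf$sensitivity,
      risk_specificity = risk_perf$specificity,
      risk_n_positives = risk_perf$n_positives
    )
  })
}
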