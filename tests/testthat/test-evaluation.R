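test_that("confusion counts reproduce the published 2x2 margins", {
  cohort <- table2_cohort()
  cc <- confusion(cohort$fit_ug_g, cohort$advanced_neoplasia, 20)
  expect_equal(cc$tp, 28)
  expect_equal(cc$fn, 73)
  expect_equal(cc$fp, 30)
  expect_equal(cc$tn, 981)
  expect_equal(cc$n_positives, 58)

  # degenerate thresholds
  hi <- confusion(cohort$fit_ug_g, cohort$advanced_neoplasia, 1e9)
  expect_equal(hi$tp + hi$fp, 0)
  lo <- confusion(cohort$fit_ug_g, cohort$advanced_neoplasia, 0)
  expect_equal(lo$n_positives, nrow(cohort))

  # conservation at arbitrary thresholds
  for (t in c(3, 5, 20, 26)) {
    cc <- confusion(cohort$fit_ug_g, cohort$advanced_neoplasia, t)
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, nrow(cohort))
    expect_equal(cc$tp + cc$fn, 101)
    expect_equal(cc$tn + cc$fp, 1011)
  }
  expect_error(confusion(1:3, c(0, 1), 1), class = "fitscreen_input_error")
})

test_that("performance metrics match the published percentages", {
  p <- performance(confusion(
    table2_cohort()$fit_ug_g, table2_cohort()$advanced_neoplasia, 20
  ))
  expect_equal(round(100 * p$sensitivity, 1), 27.7)
  expect_equal(round(100 * p$specificity, 1), 97.0)
  expect_equal(round(100 * p$ppv, 1), 48.3)
  expect_equal(p$undefined, "")

  und <- performance(tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 2))
  expect_true(is.na(und$ppv))
  expect_match(und$undefined, "ppv")
})

test_that("bootstrap CIs are deterministic, stable, and degenerate-safe", {
  cohort <- generate_cohort(cohort_config(seed = 31, n = 1500))
  sens <- function(d) {
    p <- performance(confusion(d$fit_ug_g, d$advanced_neoplasia, 20))
    c(sensitivity = p$sensitivity, specificity = p$specificity)
  }
  a <- bootstrap_ci(cohort, sens, B = 400, seed = 5)
  b <- bootstrap_ci(cohort, sens, B = 400, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$ci_low <= a$estimate & a$estimate <= a$ci_high))

  # two seeds agree within Monte-Carlo noise at B = 2000
  c1 <- bootstrap_ci(cohort, sens, B = 2000, seed = 1)
  c2 <- bootstrap_ci(cohort, sens, B = 2000, seed = 2)
  expect_true(all(abs(c1$ci_low - c2$ci_low) < 0.02))
  expect_true(all(abs(c1$ci_high - c2$ci_high) < 0.02))

  # constant metric: zero-width interval
  const <- bootstrap_ci(cohort, function(d) c(n_frac = mean(d$fit_ug_g >= 0)),
    B = 200, seed = 3
  )
  expect_equal(const$ci_low, const$ci_high)

  expect_error(bootstrap_ci(cohort, sens, B = 50), class = "fitscreen_input_error")
  mostly_na <- function(d) {
    c(bad = if (mean(d$advanced_neoplasia) > 0.99) 1 else NA_real_)
  }
  expect_error(bootstrap_ci(cohort, mostly_na, B = 150, seed = 1),
    class = "fitscreen_bootstrap_error"
  )
})

test_that("reclassification table conserves strata and counts discordance", {
  cohort <- generate_cohort(cohort_config(seed = 32, n = 2000))
  model <- fit_risk_model(cohort)
  risk <- predict_risk(model, cohort)
  th <- threshold_matched_positives(risk, sum(cohort$fit_ug_g >= 20))
  tab <- reclassification(cohort, model, fit_cutoff = 20, risk_threshold = th$risk)

  by_stratum <- tapply(tab$n, tab$an_stratum, sum)
  expect_equal(unname(by_stratum["with AN"]), sum(cohort$advanced_neoplasia))
  expect_equal(unname(by_stratum["without AN"]), sum(1 - cohort$advanced_neoplasia))

  # discordance identity: |FIT+| + |risk+| - 2|both+|
  fit_pos <- cohort$fit_ug_g >= 20
  risk_pos <- risk >= th$risk
  expect_equal(
    attr(tab, "n_reclassified"),
    sum(fit_pos) + sum(risk_pos) - 2 * sum(fit_pos & risk_pos)
  )
  expect_equal(attr(tab, "ppv_fit"), sum(fit_pos & cohort$advanced_neoplasia) / sum(fit_pos))

  # toy cohort with a single covariate profile: risk is monotone in FIT, so
  # the matched risk threshold makes the two classes coincide exactly
  toy <- make_cohort(
    fit = c(1, 5, 10, 25, 40), age = 60, sex = "F",
    an = c(0L, 0L, 1L, 0L, 1L)
  )
  m <- cocos_risk_model()
  th_eq <- predict_risk(m, make_cohort(fit = 20, age = 60, sex = "F"))
  trivial <- reclassification(toy, m, fit_cutoff = 20, risk_threshold = th_eq)
  expect_equal(attr(trivial, "n_reclassified"), 0)
  discordant <- (trivial$fit_class == "FIT+") != (trivial$risk_class == "risk+")
  expect_true(all(trivial$n[discordant] == 0))
})

test_that("AUC matches an exhaustive pairwise oracle and is rank-invariant", {
  set.seed(9)
  scores <- c(rnorm(25, 1), rnorm(25))
  labels <- rep(c(TRUE, FALSE), each = 25)
  scores[1:5] <- scores[26:30] # inject ties across classes

  auc_oracle <- function(s, l) {
    pos <- s[l]
    neg <- s[!l]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  a <- roc_auc(scores, labels)
  expect_equal(a$auc, auc_oracle(scores, labels), tolerance = 1e-12)
  expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)

  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(scores / 4), labels)$auc, a$auc, tolerance = 1e-12)
  expect_equal(roc_auc(3 * scores + 7, labels)$auc, a$auc, tolerance = 1e-12)

  # degenerate fixtures
  expect_equal(roc_auc(rep(1, 50), labels)$auc, 0.5)
  expect_equal(suppressWarnings(roc_auc(as.numeric(labels), labels)$auc), 1)
  expect_error(roc_auc(scores, rep(TRUE, 50)), class = "fitscreen_input_error")
})

test_that("DeLong test is symmetric and internally consistent", {
  set.seed(10)
  n <- 120
  signal <- rnorm(n)
  labels <- rbinom(n, 1, plogis(signal)) == 1
  a <- signal + rnorm(n, 0, 0.5)
  b <- signal + rnorm(n, 0, 0.8)

  res <- delong_test(a, b, labels)
  expect_equal(res$auc_a, roc_auc(a, labels)$auc, tolerance = 1e-12)
  expect_equal(res$auc_b, roc_auc(b, labels)$auc, tolerance = 1e-12)

  flipped <- delong_test(b, a, labels)
  expect_equal(flipped$statistic, -res$statistic, tolerance = 1e-10)
  expect_equal(flipped$p_value, res$p_value, tolerance = 1e-10)

  # identical scores: zero difference, no evidence of one
  same <- delong_test(a, a, labels)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("matched-sensitivity table pairs the strategies at equal specificity", {
  cohort <- generate_cohort(cohort_config(seed = 33, n = 4000))
  model <- fit_risk_model(cohort)
  tab <- matched_sensitivity_table(cohort, model, c(10, 15, 20, 50))
  expect_equal(nrow(tab), 4)
  expect_true(all(abs(tab$risk_specificity - tab$fit_specificity) < 0.01))
  # FIT sensitivity is non-increasing in the cut-off
  expect_true(all(diff(tab$fit_sensitivity) <= 0))

  # reference cut-off 0: everyone positive under both rules
  tab0 <- matched_sensitivity_table(cohort, model, c(1e-9))
  expect_equal(tab0$fit_sensitivity, 1)
  expect_equal(tab0$risk_sensitivity, 1)
})
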