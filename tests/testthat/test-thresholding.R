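test_that("FIT positivity is 'equal or higher than' the cut-off", {
  expect_true(classify_fit(20.0, 20.0))
  expect_false(classify_fit(19.99, 20.0))
  expect_true(classify_fit(0, 0))
  expect_equal(classify_fit(c(1, 20, 25), 20), c(FALSE, TRUE, TRUE))
})

test_that("matched-specificity threshold is optimal by exhaustive enumeration", {
  th <- threshold_matched_specificity(
    c(0.1, 0.2, 0.3, 0.4), c(0, 0, 0, 1), 2 / 3
  )
  expect_equal(th$risk, 0.3)
  expect_equal(th$achieved_specificity, 2 / 3)
  expect_equal(th$n_positives, 2L)

  # target specificity 1: threshold must clear every negative
  th1 <- threshold_matched_specificity(
    c(0.05, 0.1, 0.2, 0.9), c(0, 0, 0, 1), 1
  )
  expect_equal(th1$achieved_specificity, 1)
  expect_true(th1$risk > 0.2)

  # property: no candidate does strictly better, on random fixtures
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    risks <- round(runif(n), 2) # force ties
    labels <- rbinom(n, 1, 0.3)
    if (all(labels == 1)) labels[1] <- 0
    target <- runif(1)
    th <- threshold_matched_specificity(risks, labels, target)
    neg <- risks[labels == 0]
    cand <- c(sort(unique(risks)), 1)
    best_gap <- min(abs(vapply(cand, function(t) mean(neg < t), 0) - target))
    expect_equal(abs(th$achieved_specificity - target), best_gap)
    # tie-break: every candidate strictly below the chosen threshold is
    # strictly worse (otherwise the lower one should have been picked)
    lower <- cand[cand < th$risk]
    if (length(lower) > 0) {
      expect_true(all(
        abs(vapply(lower, function(t) mean(neg < t), 0) - target) > best_gap
      ))
    }
    expect_equal(th$n_positives, sum(risks >= th$risk))
  }
})

test_that("matched-positives threshold honours k and expands ties", {
  th <- threshold_matched_positives(c(0.1, 0.5, 0.9), 1)
  expect_equal(th$risk, 0.9)
  expect_equal(th$n_positives, 1L)

  th <- threshold_matched_positives(c(0.2, 0.5, 0.5, 0.7), 2)
  expect_equal(th$risk, 0.5)
  expect_equal(th$n_positives, 3L)

  expect_error(threshold_matched_positives(c(0.1, 0.2), 3),
    class = "fitscreen_input_error"
  )

  # sort-based oracle on random fixtures
  set.seed(7)
  for (i in 1:20) {
    risks <- round(runif(50), 2)
    k <- sample(0:50, 1)
    th <- threshold_matched_positives(risks, k)
    expect_gte(th$n_positives, k)
    srt <- sort(risks, decreasing = TRUE)
    if (k > 0 && k < 50 && srt[k] != srt[k + 1]) {
      expect_equal(th$n_positives, k)
    }
    expect_equal(th$n_positives, sum(risks >= th$risk))
  }
})

test_that("risk_to_logit is the exact inverse link", {
  expect_equal(risk_to_logit(0.5), 0)
  expect_equal(risk_to_logit(0.2524), log(0.2524 / 0.7476))
  p <- c(1e-6, 0.2, 0.77, 1 - 1e-6)
  expect_equal(plogis(risk_to_logit(p)), p, tolerance = 1e-12)
  expect_error(risk_to_logit(0), class = "fitscreen_input_error")
  expect_error(risk_to_logit(1), class = "fitscreen_input_error")
})

test_that("cut-off inversion reproduces the published worked examples", {
  m <- cocos_risk_model()
  inv <- invert_cutoff(m, c(50, 75), c("F", "M"), 0.2524)
  expect_equal(round(inv$fit_cutoff_ug_g[1], 1), 36.9)
  expect_lt(abs(inv$fit_cutoff_ug_g[2] - 9.5), 0.1)
  expect_equal(inv$flag, c("ok", "ok"))
})

test_that("inversion round-trips and matches a bisection oracle", {
  m <- cocos_risk_model()
  grid <- tidyr::expand_grid(
    age = c(50, 55, 60.5, 65, 70, 75), sex = c("F", "M"),
    thr = c(0.05, 0.1, 0.2524, 0.4)
  )
  for (thr in unique(grid$thr)) {
    g <- grid[grid$thr == thr, ]
    inv <- invert_cutoff(m, g$age, g$sex, thr)
    ok <- inv$flag %in% c("ok", "below_lod")
    # round-trip: predicted risk at the cut-off equals the threshold
    r <- predict_risk(m, make_cohort(
      fit = inv$fit_cutoff_ug_g[ok], age = inv$age_years[ok], sex = inv$sex[ok]
    ))
    expect_true(all(abs(r - thr) < 1e-9))
    # bisection oracle over the rising branch
    for (j in which(ok)) {
      f <- function(F) {
        predict_risk(m, make_cohort(fit = F, age = inv$age_years[j], sex = inv$sex[j])) - thr
      }
      oracle <- stats::uniroot(f, c(0, 260), tol = 1e-10)$root
      expect_lt(abs(inv$fit_cutoff_ug_g[j] - oracle), 1e-6)
    }
  }
})

test_that("inversion flags degenerate regimes", {
  m <- cocos_risk_model()
  # risk threshold below the zero-FIT risk of an old male: always positive
  base_risk <- predict_risk(m, make_cohort(fit = 0, age = 75, sex = "M"))
  low <- invert_cutoff(m, 75, "M", base_risk * 0.5)
  expect_equal(low$flag, "always_positive")
  expect_equal(low$fit_cutoff_ug_g, 0)

  # threshold above the peak of the risk curve: unreachable
  peak <- predict_risk(m, make_cohort(fit = 261, age = 50, sex = "F"))
  high <- invert_cutoff(m, 50, "F", min(peak + 0.1, 0.999))
  expect_equal(high$flag, "unreachable")
  expect_true(is.na(high$fit_cutoff_ug_g))

  # a cut-off between 0 and the LOD is usable but flagged
  thr_small <- predict_risk(m, make_cohort(fit = 1, age = 75, sex = "M"))
  small <- invert_cutoff(m, 75, "M", thr_small, lod = 2)
  expect_equal(small$flag, "below_lod")
  expect_lt(small$fit_cutoff_ug_g, 2)
})

test_that("fallback root bracketing handles non-quadratic coefficient shapes", {
  m <- cocos_risk_model()
  m$beta["fit"] <- 0.001 # rising linear term: monotone increasing risk
  inv <- invert_cutoff(m, 60, "F", 0.3)
  r <- predict_risk(m, make_cohort(
    fit = inv$fit_cutoff_ug_g, age = 60, sex = "F"
  ))
  expect_lt(abs(r - 0.3), 1e-9)
})

test_that("cut-off tables are monotone and covariate-consistent", {
  m <- cocos_risk_model()
  tab <- cutoff_table(m, 0.2524)
  expect_s3_class(tab, "fit_cutoff_table")
  expect_equal(nrow(tab), 52)
  expect_equal(max(tab$fit_cutoff_display), 36.9)
  expect_equal(tab$fit_cutoff_display[tab$sex == "M" & tab$age_years == 75], 9.4)
  # decreasing in age within sex (beta_age > 0), male below female (beta_sex > 0)
  for (s in c("F", "M")) {
    cuts <- tab$fit_cutoff_ug_g[tab$sex == s]
    expect_true(all(diff(cuts) < 0))
  }
  expect_true(all(
    tab$fit_cutoff_ug_g[tab$sex == "M"] < tab$fit_cutoff_ug_g[tab$sex == "F"]
  ))

  # inert covariates give identical rows
  m0 <- m
  m0$beta["age"] <- 0
  m0$beta["sex_male"] <- 0
  tab0 <- cutoff_table(m0, 0.2524)
  expect_equal(length(unique(round(tab0$fit_cutoff_ug_g, 9))), 1)

  expect_error(cutoff_table(m, 0.2524, ages = 45:75),
    class = "fitscreen_input_error"
  )
})
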