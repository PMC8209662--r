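# hand-buildable cohort rows for unit fixtures
make_cohort <- function(fit, age = 60, sex = "F", an = 0L) {
  n <- max(length(fit), length(age), length(sex), length(an))
  an <- as.integer(rep_len(an, n))
  tibble::tibble(
    id = sprintf("X%03d", seq_len(n)),
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    fit_ug_g = rep_len(fit, n),
    advanced_neoplasia = an,
    lesion = ifelse(an == 1L, "AA", "none")
  )
}

# a score/label multiset with the published 2x2 margins at cut-off 20:
# tp=28, fn=73, fp=30, tn=981 (scores 25 = positive, 5 = negative)
table2_cohort <- function() {
  make_cohort(
    fit = c(rep(25, 28), rep(5, 73), rep(25, 30), rep(5, 981)),
    an = c(rep(1L, 101), rep(0L, 1011))
  )
}
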