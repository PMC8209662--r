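#' Read or write a screening cohort CSV
#'
#' The cohort schema is comma-separated with a header row and columns
#' exactly `id, age_years, sex, fit_ug_g, advanced_neoplasia, lesion`
#' (sex `M`/`F`, parsed case-insensitively; `advanced_neoplasia` 0/1;
#' `lesion` one of none/AA/CRC, empty allowed and read as `none` for
#' unaffected participants). Validation errors name the offending row and
#' field.
#'
#' @param path CSV path.
#' @param cohort A cohort tibble.
#' @return `read_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cohort file not found: %s", path),
      class = "fitscreen_io_error"
    )
  }
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      age_years = readr::col_double(),
      sex = readr::col_character(),
      fit_ug_g = readr::col_double(),
      advanced_neoplasia = readr::col_integer(),
      lesion = readr::col_character()
    ),
    progress = FALSE
  ))
  required <- c(
    "id", "age_years", "sex", "fit_ug_g", "advanced_neoplasia", "lesion"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(
      sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
      class = "fitscreen_io_error"
    )
  }
  raw$sex <- toupper(raw$sex)
  raw$lesion[is.na(raw$lesion) | raw$lesion == ""] <- "none"
  attr(raw, "spec") <- NULL
  attr(raw, "problems") <- NULL
  validate_cohort(raw)
  raw
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Read or write a fitted risk model as JSON
#'
#' Flat JSON with snake_case keys and unrounded numbers: coefficient
#' vector, covariance matrix, penalty weight, sample sizes, and the
#' package version that produced it. A re-read model reproduces
#' predictions exactly.
#'
#' @param model An `an_risk_model`.
#' @param path File path.
#' @param seed Optional seed to record alongside the model.
#' @return `read_model()` returns an `an_risk_model`; `write_model()`
#'   returns `path` invisibly.
#' @export
write_model <- function(model, path, seed = NA_integer_) {
  stopifnot(inherits(model, "an_risk_model"))
  jsonlite::write_json(
    list(
      beta = as.list(model$beta), cov = unname(model$cov),
      penalty_lambda = model$penalty_lambda, n_obs = model$n_obs,
      n_events = model$n_events, converged = model$converged,
      loglik = model$loglik, df_eff = model$df_eff, seed = seed,
      software_version = as.character(utils::packageVersion("fitscreen"))
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(j$beta)
  new_risk_model(
    beta = beta, cov = matrix(unlist(j$cov), length(beta), length(beta)),
    penalty_lambda = j$penalty_lambda, n_obs = j$n_obs,
    n_events = j$n_events, converged = j$converged,
    loglik = j$loglik %||% NA_real_, df_eff = j$df_eff %||% NA_real_,
    terms = names(beta)[-1]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of an end-to-end screening analysis run
#'
#' Bundles everything [run_pipeline()] needs. Exactly one of `generator`
#' (a [cohort_config()], to simulate the cohort) or `cohort_path` (a
#' cohort CSV, to analyse existing data) must be supplied.
#'
#' @param generator A [cohort_config()], or `NULL`.
#' @param cohort_path Path to a cohort CSV, or `NULL`.
#' @param reference_fit_cutoffs Uniform FIT cut-offs (ug Hb/g) whose
#'   specificity the risk rule is matched against; must be positive and
#'   sorted increasing.
#' @param penalty_grid Ridge weights for [fit_risk_model()].
#' @param bootstrap_B Bootstrap resamples for the performance CIs.
#' @param lod Assay limit of detection, ug Hb/g.
#' @param seed Master seed; every stochastic stage consumes a sub-seed
#'   derived deterministically from it.
#' @param outdir Output directory for [write_outputs()], or `NULL`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(generator = NULL, cohort_path = NULL,
                       reference_fit_cutoffs = c(10, 15, 20, 50),
                       penalty_grid = c(0, 0.5, 1, 2, 4, 8, 16),
                       bootstrap_B = 2000, lod = 2, seed = 1L,
                       outdir = NULL) {
  if (is.null(generator) == is.null(cohort_path)) {
    abort("supply exactly one of `generator` or `cohort_path`",
      class = "fitscreen_config_error"
    )
  }
  if (any(reference_fit_cutoffs <= 0) ||
    is.unsorted(reference_fit_cutoffs, strictly = TRUE)) {
    abort("`reference_fit_cutoffs` must be positive and strictly increasing",
      class = "fitscreen_config_error"
    )
  }
  structure(
    list(
      generator = generator, cohort_path = cohort_path,
      reference_fit_cutoffs = reference_fit_cutoffs,
      penalty_grid = penalty_grid, bootstrap_B = bootstrap_B,
      lod = lod, seed = as.integer(seed), outdir = outdir
    ),
    class = "run_config"
  )
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[fitscreen] %s: %s", stage, sprintf(fmt, ...)))
}

#' Run the full risk-based screening analysis
#'
#' Executes the whole pipeline: obtain the cohort (simulate or read), fit
#' the penalized risk model, and for each reference FIT cut-off select
#' the matched-specificity risk threshold, tabulate individualized FIT
#' cut-offs, and evaluate both strategies (performance with bootstrap
#' CIs, reclassification); finally compare ROC discrimination of the
#' model against FIT alone. If `config$outdir` is set the results are
#' also written to disk via [write_outputs()].
#'
#' @param config A [run_config()].
#' @return A list of class `fitscreen_run` with elements `cohort`,
#'   `summary`, `model`, `thresholds`, `cutoffs` (one `fit_cutoff_table`
#'   per reference cut-off), `performance`, `reclassification`, `roc`,
#'   `matched_sensitivity`, and `config`.
#' @export
#' @examples
#' cfg <- run_config(
#'   generator = cohort_config(seed = 5, n = 800),
#'   reference_fit_cutoffs = c(20), bootstrap_B = 200
#' )
#' res <- run_pipeline(cfg)
#' res$thresholds
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
        class = "fitscreen_pipeline_error", parent = e
      )
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- sub_seed(config$seed, 1L)
      pipeline_log("cohort", "simulating n=%d (seed %d)", gen$n, gen$seed)
      generate_cohort(gen)
    } else {
      pipeline_log("cohort", "reading %s", config$cohort_path)
      read_cohort(config$cohort_path)
    }
  })
  summary <- stage("summary", cohort_summary(cohort))

  model <- stage("model", {
    pipeline_log(
      "model", "penalized logistic fit, grid {%s}",
      paste(config$penalty_grid, collapse = ", ")
    )
    fit_risk_model(cohort, penalty_grid = config$penalty_grid)
  })
  risk <- predict_risk(model, cohort)
  labels <- cohort$advanced_neoplasia == 1L

  per_cutoff <- stage("thresholds", {
    purrr::map(config$reference_fit_cutoffs, function(cut) {
      fit_perf <- performance(confusion(cohort$fit_ug_g, labels, cut))
      th <- threshold_matched_specificity(
        risk, labels, fit_perf$specificity,
        reference_fit_cutoff = cut
      )
      pipeline_log(
        "thresholds", "FIT %g ug/g: spec %.3f -> risk threshold %.4f",
        cut, fit_perf$specificity, th$risk
      )
      list(cutoff = cut, fit_perf = fit_perf, threshold = th)
    })
  })
  thresholds <- purrr::map_dfr(per_cutoff, "threshold")

  cutoffs <- stage("cutoffs", {
    purrr::map(per_cutoff, function(pc) {
      cutoff_table(model, pc$threshold$risk, lod = config$lod)
    })
  })
  names(cutoffs) <- as.character(config$reference_fit_cutoffs)

  perf <- stage("performance", {
    purrr::imap_dfr(per_cutoff, function(pc, i) {
      boot_seed <- sub_seed(config$seed, 10L + which(
        config$reference_fit_cutoffs == pc$cutoff
      ))
      fit_stats <- function(d) {
        p <- performance(confusion(
          d$fit_ug_g, d$advanced_neoplasia == 1L, pc$cutoff
        ))
        c(
          sensitivity = p$sensitivity, specificity = p$specificity,
          ppv = p$ppv, npv = p$npv
        )
      }
      risk_stats <- function(d) {
        r <- predict_risk(model, d)
        p <- performance(confusion(
          r, d$advanced_neoplasia == 1L, pc$threshold$risk
        ))
        c(
          sensitivity = p$sensitivity, specificity = p$specificity,
          ppv = p$ppv, npv = p$npv
        )
      }
      dplyr::bind_rows(
        dplyr::mutate(
          bootstrap_ci(cohort, fit_stats, B = config$bootstrap_B, seed = boot_seed),
          strategy = "fit", reference_cutoff = pc$cutoff,
          threshold = pc$cutoff
        ),
        dplyr::mutate(
          bootstrap_ci(cohort, risk_stats, B = config$bootstrap_B, seed = boot_seed),
          strategy = "risk", reference_cutoff = pc$cutoff,
          threshold = pc$threshold$risk
        )
      )
    })
  })

  reclass <- stage("reclassification", {
    out <- purrr::map(per_cutoff, function(pc) {
      reclassification(cohort, model,
        fit_cutoff = pc$cutoff, risk_threshold = pc$threshold$risk
      )
    })
    names(out) <- as.character(config$reference_fit_cutoffs)
    out
  })

  roc <- stage("roc", roc_comparison(cohort, model))
  matched <- stage(
    "matched_sensitivity",
    matched_sensitivity_table(cohort, model, config$reference_fit_cutoffs)
  )

  res <- structure(
    list(
      cohort = cohort, summary = summary, model = model,
      thresholds = thresholds, cutoffs = cutoffs, performance = perf,
      reclassification = reclass, roc = roc,
      matched_sensitivity = matched, config = config
    ),
    class = "fitscreen_run"
  )
  if (!is.null(config$outdir)) {
    write_outputs(res, config$outdir)
  }
  res
}

#' Write the artifacts of a pipeline run
#'
#' Writes `cohort.csv`, `model.json` (coefficients, covariance, penalty,
#' sample sizes, seed, package version), `cutoffs.csv` (individualized
#' cut-off table per reference cut-off), `performance.json`,
#' `reclassification.csv`, `roc.csv` (full ROC coordinates for both
#' strategies) and a human-readable `report.md` whose every number is
#' also present in a machine-readable artifact.
#'
#' @param results A `fitscreen_run` from [run_pipeline()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_outputs <- function(results, outdir) {
  stopifnot(inherits(results, "fitscreen_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    abort(sprintf("cannot create output directory %s", outdir),
      class = "fitscreen_io_error"
    )
  }
  paths <- c(
    cohort = file.path(outdir, "cohort.csv"),
    model = file.path(outdir, "model.json"),
    cutoffs = file.path(outdir, "cutoffs.csv"),
    performance = file.path(outdir, "performance.json"),
    reclassification = file.path(outdir, "reclassification.csv"),
    roc = file.path(outdir, "roc.csv"),
    report = file.path(outdir, "report.md")
  )
  write_cohort(results$cohort, paths["cohort"])

  write_model(results$model, paths["model"], seed = results$config$seed)

  cut_tab <- purrr::imap_dfr(results$cutoffs, function(tab, ref) {
    tibble::tibble(
      reference_cutoff = as.numeric(ref),
      risk_threshold = attr(tab, "risk_threshold"),
      age_years = tab$age_years, sex = tab$sex,
      fit_cutoff_ug_g = tab$fit_cutoff_display, flag = tab$flag
    )
  })
  readr::write_csv(cut_tab, paths["cutoffs"], progress = FALSE)

  jsonlite::write_json(
    results$performance, paths["performance"],
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
  )

  reclass_tab <- purrr::imap_dfr(results$reclassification, function(tab, ref) {
    dplyr::mutate(tibble::as_tibble(tab),
      reference_cutoff = as.numeric(ref),
      n_reclassified = attr(tab, "n_reclassified"),
      .before = 1
    )
  })
  readr::write_csv(reclass_tab, paths["reclassification"], progress = FALSE)

  labels <- results$cohort$advanced_neoplasia == 1L
  risk <- predict_risk(results$model, results$cohort)
  roc_coords <- dplyr::bind_rows(
    roc_points(risk, labels, "risk"),
    roc_points(results$cohort$fit_ug_g, labels, "fit")
  )
  readr::write_csv(roc_coords, paths["roc"], progress = FALSE)

  writeLines(render_report(results), paths["report"])
  invisible(paths)
}

# empirical ROC coordinates at every observed threshold
roc_points <- function(scores, labels, strategy) {
  th <- c(sort(unique(scores)), Inf)
  purrr::map_dfr(th, function(t) {
    cc <- confusion(scores, labels, t)
    tibble::tibble(
      strategy = strategy, threshold = t,
      fpr = cc$fp / (cc$fp + cc$tn), tpr = cc$tp / (cc$tp + cc$fn)
    )
  })
}

render_report <- function(results) {
  s <- results$summary
  m <- results$model
  fmt_pct <- function(x) sprintf("%.1f%%", 100 * x)
  or <- odds_ratios(m)
  lines <- c(
    "# Risk-based FIT screening analysis",
    "",
    "## Cohort",
    sprintf(
      "- n = %d; mean age %.1f (SD %.1f); %s male", s$n, s$age_mean,
      s$age_sd, fmt_pct(s$pct_male / 100)
    ),
    sprintf(
      "- AN prevalence %s; FIT >= 20 ug/g in %d (%s); AN cases with FIT < 5: %s",
      fmt_pct(s$an_prevalence_pct / 100), s$n_fit_ge_20,
      fmt_pct(s$pct_fit_ge_20 / 100), fmt_pct(s$pct_an_fit_lt_5 / 100)
    ),
    "",
    "## Model (see model.json)",
    sprintf(
      "- lambda = %s, effective df = %.2f, log-likelihood = %.3f",
      format(m$penalty_lambda), m$df_eff, m$loglik
    ),
    sprintf(
      "- %s: coef %.4f (SE %.4f), OR %.2f (%.2f-%.2f)",
      or$term, or$estimate, or$std_error, or$odds_ratio, or$or_low, or$or_high
    ),
    "",
    "## Risk thresholds (matched specificity; see performance.json, cutoffs.csv)",
    sprintf(
      "- FIT %g ug/g -> risk threshold %.4f (achieved specificity %s, %d positives)",
      results$thresholds$reference_fit_cutoff, results$thresholds$risk,
      fmt_pct(results$thresholds$achieved_specificity),
      results$thresholds$n_positives
    ),
    "",
    "## Discrimination (see roc.csv)",
    sprintf(
      "- AUC model %.2f (%.2f-%.2f) vs FIT %.2f (%.2f-%.2f); DeLong p = %.3f",
      results$roc$auc_model, results$roc$auc_model_low,
      results$roc$auc_model_high, results$roc$auc_fit,
      results$roc$auc_fit_low, results$roc$auc_fit_high, results$roc$delong_p
    ),
    "",
    "## Reclassification (see reclassification.csv)",
    sprintf(
      "- FIT %s ug/g: %d participants reclassified",
      names(results$reclassification),
      purrr::map_int(results$reclassification, attr, "n_reclassified")
    )
  )
  lines
}

#' @export
print.fitscreen_run <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
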