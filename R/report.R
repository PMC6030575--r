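#' Run the full study pipeline on a synthetic cohort
#'
#' One-command end-to-end analysis: generate a cohort, apply the
#' eligibility filters, fit the joint two-level factor model with fit
#' indices, compute the reliability report, run the three demographic
#' invariance comparisons, fit the four outcome-prediction models, and
#' collect everything — with full provenance — into a study report.
#' Deterministic given `(gen_cfg, cfg, seed)`.
#'
#' @param gen_cfg a `phq_gen_config`.
#' @param cfg a `phq_run_config`.
#' @param seed integer seed for cohort generation.
#' @param fit_indices compute saturated/independence fits and fit indices
#'   (the saturated fit is the slowest stage; disable for quick runs).
#' @param invariance_vars demographic splits to test (character vector;
#'   empty to skip).
#' @param se compute standard errors on the main fit.
#' @return List of class `phq_study_report` with sections `descriptives`,
#'   `fit`, `indices`, `reliability`, `invariance`, `prediction`,
#'   `provenance`.
#' @export
run_study <- function(gen_cfg = generator_config(), cfg = run_config(),
                      seed = cfg$seed, fit_indices = TRUE,
                      invariance_vars = c("gender", "age_band", "minority"),
                      se = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cohort <- stage("simulate", generate_cohort(gen_cfg, seed = seed))
  flt <- stage("filter",
               apply_sample_filters(cohort$daily, cohort$panel, cfg))
  daily <- flt$daily
  panel <- flt$panel

  n_persons <- length(unique(daily$person_id))
  base_rows <- panel[panel$week == 0L, , drop = FALSE]
  descriptives <- list(
    n_persons = n_persons,
    n_observations = nrow(daily),
    mean_ratings_per_person = nrow(daily) / n_persons,
    baseline_mean = mean(base_rows$phq9_sum, na.rm = TRUE),
    baseline_sd = stats::sd(base_rows$phq9_sum, na.rm = TRUE),
    n_excluded = nrow(flt$exclusions))

  spec <- model_spec(n_items = length(gen_cfg$params$lambda_q))
  fit <- stage("fit-mlcfa",
               fit_mlcfa(daily, panel, spec, cfg$anchor_week, se = se,
                         control = list(max_iter = cfg$max_iter,
                                        reltol = cfg$reltol)))
  indices <- NULL
  if (fit_indices) {
    sat <- stage("fit-saturated",
                 fit_saturated(daily, panel, cfg$anchor_week, spec$n_items))
    nul <- stage("fit-baseline",
                 fit_baseline(daily, panel, cfg$anchor_week, spec$n_items))
    indices <- fit_indices(fit, sat, nul, n_persons)
  }
  rel <- stage("reliability", reliability_report(fit, n_bar = "auto"))

  inv <- list()
  for (v in invariance_vars)
    inv[[v]] <- stage(paste0("invariance-", v),
                      compare_groups(daily, panel, v, spec,
                                     cfg$anchor_week))

  summaries <- stage("summarize-daily", summarize_daily(daily))
  pred <- stage("predict",
                predict_report(panel, summaries, models = 1:4,
                               anchor_week = cfg$anchor_week,
                               outcome_week = cfg$outcome_week))

  structure(list(descriptives = descriptives, fit = fit,
                 indices = indices, reliability = rel, invariance = inv,
                 prediction = pred, exclusions = flt$exclusions,
                 provenance = list(seed = seed, gen_config = gen_cfg,
                                   run_config = cfg,
                                   package_version =
                                     as.character(utils::packageVersion("dailyphq")),
                                   schema = "phq-study-report/1")),
            class = "phq_study_report")
}

#' @export
print.phq_study_report <- function(x, ...) {
  d <- x$descriptives
  cat("Study report (synthetic cohort)\n")
  cat(sprintf("  %d persons, %d daily observations (%.1f per person)\n",
              d$n_persons, d$n_observations, d$mean_ratings_per_person))
  cat(sprintf("  baseline sum: mean %.1f (SD %.1f)\n", d$baseline_mean,
              d$baseline_sd))
  if (!is.null(x$indices))
    cat(sprintf("  model fit: chi2(%d) = %.1f, CFI %.3f, TLI %.3f, RMSEA %.3f\n",
                x$indices$df, x$indices$chi2, x$indices$cfi, x$indices$tli,
                x$indices$rmsea))
  cat(sprintf("  latent correlation r = %.3f\n", x$fit$params$r))
  cat("  reliabilities:\n")
  for (i in seq_len(nrow(x$reliability)))
    cat(sprintf("    %s = %.3f\n", x$reliability$quantity[i],
                x$reliability$estimate[i]))
  for (v in names(x$invariance)) {
    t <- x$invariance[[v]]$lrt
    cat(sprintf("  invariance %s: chi2(%d) = %.1f, p = %.3f\n", v,
                t$df, t$chi2, t$p))
  }
  tab <- x$prediction$table
  r2 <- unique(tab[, c("model", "outcome", "r2", "n")])
  cat("  prediction R2:\n")
  for (i in seq_len(nrow(r2)))
    cat(sprintf("    model %d, %s: R2 = %.3f (n = %d)\n", r2$model[i],
                r2$outcome[i], r2$r2[i], r2$n[i]))
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes the numeric content of the report (descriptives, estimates,
#' reliabilities, LRTs, prediction table, provenance) as pretty JSON.
#'
#' @param report a `phq_study_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  inv <- lapply(report$invariance, function(iv)
    list(lrt = iv$lrt, by_group = iv$by_group))
  out <- list(
    schema = report$provenance$schema,
    descriptives = report$descriptives,
    estimates = as.list(report$fit$estimates),
    se = as.list(report$fit$se),
    loglik = report$fit$loglik,
    indices = report$indices,
    reliability = report$reliability,
    invariance = inv,
    prediction = report$prediction$table,
    provenance = list(seed = report$provenance$seed,
                      package_version = report$provenance$package_version))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}
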