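#' Extract a two-level grouping from the panel
#'
#' @param panel panel table with demographic columns.
#' @param group_var one of `"gender"`, `"age_band"`, `"minority"` (or any
#'   panel column with exactly two observed levels).
#' @return Named character vector: person_id -> group label, with the
#'   attribute `levels` giving the two levels (reference level first).
#' @keywords internal
person_groups <- function(panel, group_var) {
  if (!group_var %in% names(panel))
    stop("unknown grouping variable: ", group_var, call. = FALSE)
  tab <- unique(panel[!is.na(panel[[group_var]]),
                      c("person_id", group_var)])
  if (anyDuplicated(tab$person_id))
    stop("inconsistent group labels within person", call. = FALSE)
  g <- tab[[group_var]]
  names(g) <- tab$person_id
  lv <- sort(unique(g))
  if (length(lv) != 2L)
    stop("grouping variable must have exactly 2 observed levels",
         call. = FALSE)
  attr(g, "levels") <- lv
  g
}

subset_persons <- function(daily, panel, ids) {
  list(daily = daily[daily$person_id %in% ids, , drop = FALSE],
       panel = panel[panel$person_id %in% ids, , drop = FALSE])
}

#' Fit the joint model to two groups
#'
#' Unconstrained: every measurement parameter and the latent correlation
#' estimated independently per group (equivalently, two separate fits;
#' the joint log-likelihood is their sum). Constrained: loadings,
#' intercepts and residual variances shared across groups; the latent
#' correlation remains group-specific and, following standard invariance
#' practice once loadings are equated, the three latent variances are
#' re-freed in the second group (fixed to 1 in the first). Free-parameter
#' counts are derived from the packing itself, so likelihood-ratio degrees
#' of freedom are counted symbolically, never hard-coded.
#'
#' @param daily,panel filtered tables.
#' @param group_var grouping column name in the panel.
#' @param spec a `phq_model_spec`.
#' @param constrained logical.
#' @param anchor_week anchor questionnaire week.
#' @param se compute per-group standard errors (unconstrained only).
#' @param start optional `phq_params` of starting values for the shared
#'   measurement block of the constrained model; when omitted, a pooled
#'   single-group fit supplies them.
#' @param control optimizer control list.
#' @return Object of class `phq_group_fit`: `loglik`, `npar`,
#'   `constrained`, `group_var`, `levels`, and `fits` (per-group
#'   `phq_fit`s for the unconstrained model) or `params` (per-group
#'   parameter sets for the constrained model).
#' @export
fit_multigroup <- function(daily, panel, group_var, spec = model_spec(),
                           constrained = FALSE, anchor_week = 4L,
                           se = FALSE, start = NULL, control = list()) {
  g <- person_groups(panel, group_var)
  lv <- attr(g, "levels")
  ids1 <- names(g)[g == lv[1]]
  ids2 <- names(g)[g == lv[2]]
  if (length(ids1) < 2L || length(ids2) < 2L)
    stop("each group needs at least 2 persons", call. = FALSE)
  d1 <- subset_persons(daily, panel, ids1)
  d2 <- subset_persons(daily, panel, ids2)

  if (!constrained) {
    f1 <- fit_mlcfa(d1$daily, d1$panel, spec, anchor_week, se = se,
                    start = start, control = control)
    f2 <- fit_mlcfa(d2$daily, d2$panel, spec, anchor_week, se = se,
                    start = start, control = control)
    return(structure(list(loglik = f1$loglik + f2$loglik,
                          npar = f1$npar + f2$npar,
                          constrained = FALSE, group_var = group_var,
                          levels = lv, fits = list(f1, f2)),
                     class = "phq_group_fit"))
  }

  dat1 <- prepare_cfa_data(d1$daily, d1$panel, anchor_week, spec$n_items)
  dat2 <- prepare_cfa_data(d2$daily, d2$panel, anchor_week, spec$n_items)
  # pooled single-group fit provides starting values for the shared block
  if (is.null(start))
    start <- fit_mlcfa(daily, panel, spec, anchor_week, se = FALSE,
                       control = control)$params
  meas0 <- pack_model(start, spec)
  k <- length(meas0) - 1L # shared measurement block (drop atanh r)
  par0 <- c(meas0[seq_len(k)], atanh(start$r), atanh(start$r), 0, 0, 0)
  unpack2 <- function(par) {
    p1 <- unpack_model(c(par[seq_len(k)], par[k + 1L]), spec)
    psi2 <- exp(par[k + 2L + 1:3])
    p2 <- unpack_model(c(par[seq_len(k)], par[k + 2L]), spec,
                       psi = psi2)
    list(p1, p2)
  }
  negll <- function(par) {
    ps <- unpack2(par)
    finite_or_big(-(blocks_loglik_safe(implied_blocks(ps[[1]]), dat1) +
                    blocks_loglik_safe(implied_blocks(ps[[2]]), dat2)))
  }
  opt <- minimize(negll, par0, max_iter = control$max_iter %||% 500L,
                  reltol = control$reltol %||% 1e-12,
                  restarts = control$restarts %||% 4L)
  ps <- unpack2(opt$par)
  structure(list(loglik = -opt$value, npar = length(par0),
                 constrained = TRUE, group_var = group_var, levels = lv,
                 params = ps,
                 convergence = list(converged = opt$converged,
                                    gradient_norm = opt$gnorm)),
            class = "phq_group_fit")
}

#' Likelihood-ratio test of nested multiple-group fits
#'
#' @param constrained,unconstrained `phq_group_fit`s (or any lists with
#'   `loglik` and `npar`) on the same data, constrained nested in
#'   unconstrained.
#' @return List with `chi2`, `df`, `p`.
#' @export
lrt <- function(constrained, unconstrained) {
  chi2 <- 2 * (unconstrained$loglik - constrained$loglik)
  df <- unconstrained$npar - constrained$npar
  if (df <= 0) stop("models are not nested (df <= 0)", call. = FALSE)
  if (chi2 < -1e-4)
    stop(sprintf(
      "negative LRT chi-square (%.5f): refit with tighter tolerances", chi2),
      call. = FALSE)
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Compare constrained and unconstrained multiple-group fits
#'
#' Runs the full invariance comparison for one demographic split: the
#' unconstrained model (all measurement parameters group-specific), the
#' constrained model (measurement parameters equated), the likelihood-ratio
#' test, and per-group latent correlations and reliabilities from the
#' unconstrained fits.
#'
#' @inheritParams fit_multigroup
#' @return List of class `phq_invariance` with `group_var`, `levels`,
#'   `unconstrained`, `constrained`, `lrt`, `by_group` (data frame of
#'   per-group r and reliabilities).
#' @export
compare_groups <- function(daily, panel, group_var, spec = model_spec(),
                           anchor_week = 4L, se = FALSE, control = list()) {
  un <- fit_multigroup(daily, panel, group_var, spec, constrained = FALSE,
                       anchor_week = anchor_week, se = se, control = control)
  co <- fit_multigroup(daily, panel, group_var, spec, constrained = TRUE,
                       anchor_week = anchor_week, control = control)
  test <- lrt(co, un)
  rows <- lapply(seq_along(un$levels), function(i) {
    f <- un$fits[[i]]
    rel <- reliability_report(f, n_bar = "auto")
    data.frame(group = un$levels[i], r = f$params$r,
               omega_questionnaire = rel$estimate[1],
               omega_within = rel$estimate[2],
               rho_between = rel$estimate[3],
               n_persons = f$n_persons, stringsAsFactors = FALSE)
  })
  structure(list(group_var = group_var, levels = un$levels,
                 unconstrained = un, constrained = co, lrt = test,
                 by_group = do.call(rbind, rows)),
            class = "phq_invariance")
}

#' @export
print.phq_invariance <- function(x, ...) {
  cat(sprintf("Measurement invariance: %s (%s vs %s)\n", x$group_var,
              x$levels[1], x$levels[2]))
  cat(sprintf("  LRT chi2(%d) = %.1f, p = %.3f\n", x$lrt$df, x$lrt$chi2,
              x$lrt$p))
  print(x$by_group, row.names = FALSE)
  invisible(x)
}
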