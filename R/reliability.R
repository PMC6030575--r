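#' Composite (omega) reliability of a factor-scored item set
#'
#' The fraction of the unit-weight composite's variance attributable to
#' the common factor:
#' `(sum lambda)^2 psi / ((sum lambda)^2 psi + sum theta)`.
#'
#' @param loadings vector of factor loadings.
#' @param residual_variances vector of residual variances (same length).
#' @param factor_variance latent variance (default 1).
#' @return Reliability in \[0, 1\].
#' @export
omega_composite <- function(loadings, residual_variances,
                            factor_variance = 1) {
  if (length(loadings) != length(residual_variances))
    stop("loadings and residual variances differ in length", call. = FALSE)
  stopifnot(all(residual_variances >= 0), factor_variance > 0)
  com <- sum(loadings)^2 * factor_variance
  com / (com + sum(residual_variances))
}

#' Questionnaire composite reliability
#' @param params a `phq_params` object.
#' @return Omega of the questionnaire item set.
#' @export
omega_questionnaire <- function(params) {
  omega_composite(params$lambda_q, params$theta_q, params$psi_q)
}

#' Within-person (day-to-day) reliability of the daily composite
#'
#' Omega of the 2-item daily composite at the within level: the
#' reliability of a single day's deviation from the person's own mean.
#'
#' @param params a `phq_params` object.
#' @return Within-level omega.
#' @export
omega_within_daily <- function(params) {
  omega_composite(rep(params$lambda_w, 2L), params$theta_w, params$psi_w)
}

#' Between-person reliability of the person-mean daily composite
#'
#' Reliability of a person's daily-composite mean over `n_bar` days: the
#' between-level common variance over itself plus between-level residual
#' variance plus the within-level (common + residual) variance shrunk by
#' `1/n_bar`:
#' `(sum lambda_b)^2 psi_b / ((sum lambda_b)^2 psi_b + sum theta_b +
#'   ((sum lambda_w)^2 psi_w + sum theta_w) / n_bar)`.
#' Increasing in `n_bar`, with limit the level-specific between omega.
#'
#' @param params a `phq_params` object.
#' @param n_bar mean number of ratings per person (> 0). The arithmetic
#'   mean cluster size is the package default (see
#'   [reliability_report()]).
#' @return Person-mean reliability.
#' @export
rho_person_mean <- function(params, n_bar) {
  stopifnot(n_bar > 0)
  lb <- rep(params$lambda_b, 2L)
  lw <- rep(params$lambda_w, 2L)
  com_b <- sum(lb)^2 * params$psi_b
  within_tot <- sum(lw)^2 * params$psi_w + sum(params$theta_w)
  com_b / (com_b + sum(params$theta_b) + within_tot / n_bar)
}

reliabilities_of <- function(params, n_bar) {
  c(omega_questionnaire = omega_questionnaire(params),
    omega_within = omega_within_daily(params),
    rho_between = rho_person_mean(params, n_bar))
}

#' Reliability report with delta-method confidence intervals
#'
#' Computes the three reported reliabilities — questionnaire omega,
#' within-person (day-to-day) daily omega, and between-person person-mean
#' reliability — from a fitted model or a bare parameter set. When a
#' `phq_fit` with a parameter covariance is supplied, 95% confidence
#' intervals are obtained by the delta method (numeric gradient of each
#' reliability with respect to the free parameters).
#'
#' @param fit a `phq_fit`, or a `phq_params` for point values only.
#' @param n_bar mean ratings per person; `"auto"` (with a fit) uses the
#'   arithmetic mean cluster size of the fitted data. The harmonic mean is
#'   available via `n_bar_type = "harmonic"`.
#' @param n_bar_type `"arithmetic"` or `"harmonic"` (used with `"auto"`).
#' @return Data frame with columns `quantity`, `estimate`, `se`, `lower`,
#'   `upper`, `n_bar`.
#' @export
reliability_report <- function(fit, n_bar = "auto",
                               n_bar_type = c("arithmetic", "harmonic")) {
  n_bar_type <- match.arg(n_bar_type)
  if (inherits(fit, "phq_params")) {
    if (identical(n_bar, "auto"))
      stop("n_bar must be numeric when only parameters are supplied",
           call. = FALSE)
    vals <- reliabilities_of(fit, n_bar)
    return(data.frame(quantity = names(vals), estimate = unname(vals),
                      se = NA_real_, lower = NA_real_, upper = NA_real_,
                      n_bar = n_bar, stringsAsFactors = FALSE))
  }
  stopifnot(inherits(fit, "phq_fit"))
  if (identical(n_bar, "auto")) {
    sizes <- unlist(lapply(fit$data$groups, function(g)
      rep(g$n_days, g$m)))
    sizes <- sizes[sizes > 0]
    n_bar <- if (n_bar_type == "arithmetic") mean(sizes)
             else 1 / mean(1 / sizes)
  }
  vals <- reliabilities_of(fit$params, n_bar)
  se <- rep(NA_real_, 3L)
  if (!is.null(fit$vcov_t)) {
    # delta method on the transformed (optimization) scale
    grad_fn <- function(x) reliabilities_of(unpack_model(x, fit$spec), n_bar)
    Jt <- num_jacobian(grad_fn, fit$par_t)
    Vr <- Jt %*% fit$vcov_t %*% t(Jt)
    se <- sqrt(pmax(diag(Vr), 0))
  }
  est <- unname(vals)
  data.frame(quantity = names(vals), estimate = est, se = se,
             lower = pmax(est - 1.96 * se, 0),
             upper = pmin(est + 1.96 * se, 1),
             n_bar = n_bar, stringsAsFactors = FALSE)
}
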