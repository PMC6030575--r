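#' Measurement parameter set for the joint daily/questionnaire factor model
#'
#' Container for all parameters of the joint model: a single-level factor
#' model for a multi-item questionnaire (loadings `lambda_q`, intercepts
#' `tau_q`, residual variances `theta_q`) coupled with a two-level factor
#' model for a 2-item daily measure. At the between-person level the daily
#' items load on a stable depression factor `eta_b` with a loading
#' `lambda_b` shared by both items; at the within-person (day-to-day) level
#' they load on a daily fluctuation factor with shared loading `lambda_w`.
#' `r` is the correlation between the questionnaire factor and the
#' between-person daily factor. Latent variances (`psi_q`, `psi_b`,
#' `psi_w`) default to 1 and latent means to 0, the identification
#' convention used throughout the package.
#'
#' @param lambda_q numeric vector of questionnaire loadings (one per item).
#' @param tau_q questionnaire item intercepts, same length as `lambda_q`.
#' @param theta_q questionnaire residual variances, same length, all > 0.
#' @param lambda_b scalar between-level daily loading (shared by the 2 items).
#' @param nu length-2 daily item intercepts.
#' @param theta_b length-2 between-level daily residual variances, > 0.
#' @param lambda_w scalar within-level daily loading (shared).
#' @param theta_w length-2 within-level daily residual variances, > 0.
#' @param r latent correlation between questionnaire and between-level daily
#'   factors, in \[-1, 1\].
#' @param psi_q,psi_b,psi_w latent factor variances (fixed at 1 for
#'   identification in single-group fits; freed in the second group of a
#'   constrained multiple-group fit).
#' @return An object of class `phq_params`.
#' @export
parameter_set <- function(lambda_q, tau_q, theta_q,
                          lambda_b, nu, theta_b,
                          lambda_w, theta_w, r,
                          psi_q = 1, psi_b = 1, psi_w = 1) {
  p <- length(lambda_q)
  stopifnot(length(tau_q) == p, length(theta_q) == p,
            length(lambda_b) == 1L, length(nu) == 2L,
            length(theta_b) == 2L, length(lambda_w) == 1L,
            length(theta_w) == 2L, length(r) == 1L)
  if (any(c(theta_q, theta_b, theta_w) <= 0))
    stop("all residual variances must be strictly positive", call. = FALSE)
  if (abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  if (any(c(psi_q, psi_b, psi_w) <= 0))
    stop("latent variances must be strictly positive", call. = FALSE)
  structure(
    list(lambda_q = as.numeric(lambda_q), tau_q = as.numeric(tau_q),
         theta_q = as.numeric(theta_q), lambda_b = as.numeric(lambda_b),
         nu = as.numeric(nu), theta_b = as.numeric(theta_b),
         lambda_w = as.numeric(lambda_w), theta_w = as.numeric(theta_w),
         r = as.numeric(r), psi_q = as.numeric(psi_q),
         psi_b = as.numeric(psi_b), psi_w = as.numeric(psi_w)),
    class = "phq_params")
}

#' Reference measurement parameters
#'
#' Published point estimates from a factor analysis of a large remote
#' mobile-health depression cohort (moderately depressed community adults):
#' 9 questionnaire items scored 0-3, daily 2-item mood ratings scored 1-5.
#' Used as the package's default generating values for synthetic cohorts
#' and as inputs to the reliability arithmetic.
#'
#' @return A `phq_params` object with 9 questionnaire items.
#' @export
default_measurement_params <- function() {
  parameter_set(
    lambda_q = c(0.60, 0.63, 0.59, 0.65, 0.65, 0.70, 0.56, 0.34, 0.37),
    tau_q    = c(1.07, 1.12, 1.25, 1.39, 1.07, 1.03, 0.90, 0.34, 0.34),
    theta_q  = c(0.20, 0.22, 0.53, 0.40, 0.58, 0.44, 0.45, 0.32, 0.36),
    lambda_b = 0.85, nu = c(2.20, 2.20), theta_b = c(0.05, 0.05),
    lambda_w = 0.66, theta_w = c(0.20, 0.20),
    r = 0.80)
}

#' Empirical distribution of daily-rating counts per person
#'
#' Number of participants submitting k = 1..14 daily ratings in the
#' reference cohort (545 persons, 2992 ratings in a 14-day window; mean 5.5
#' ratings per person). Used by the cluster-size sampler, and exactly
#' reproduced by its fixture mode.
#'
#' @return Integer vector of length 14 (counts for 1..14 ratings).
#' @export
reference_cluster_size_counts <- function() {
  c(40L, 22L, 27L, 45L, 79L, 109L, 199L, 18L, 2L, 2L, 1L, 1L, 0L, 0L)
}

#' @export
print.phq_params <- function(x, ...) {
  p <- length(x$lambda_q)
  cat("Joint daily/questionnaire measurement parameters\n")
  cat(sprintf("  questionnaire: %d items, loadings [%s]\n", p,
              paste(format(x$lambda_q, digits = 2), collapse = ", ")))
  cat(sprintf("  daily between: lambda_b = %.3f, theta_b = (%.3f, %.3f), psi_b = %.2f\n",
              x$lambda_b, x$theta_b[1], x$theta_b[2], x$psi_b))
  cat(sprintf("  daily within : lambda_w = %.3f, theta_w = (%.3f, %.3f), psi_w = %.2f\n",
              x$lambda_w, x$theta_w[1], x$theta_w[2], x$psi_w))
  cat(sprintf("  latent correlation r = %.3f\n", x$r))
  invisible(x)
}

# Model-implied moment blocks of the joint marginal Gaussian:
#   mu_q  (p)    questionnaire means
#   mu_y  (2)    daily item means
#   S_qq  (p x p) questionnaire covariance
#   S_qy  (p x 2) covariance between questionnaire items and any day's items
#   S_b   (2 x 2) between-person (shared across days) daily covariance
#   S_w   (2 x 2) within-person (day-specific) daily covariance
implied_blocks <- function(params) {
  lq <- params$lambda_q
  lb <- rep(params$lambda_b, 2L)
  lw <- rep(params$lambda_w, 2L)
  list(
    mu_q = params$tau_q,
    mu_y = params$nu,
    S_qq = params$psi_q * tcrossprod(lq) + diag(params$theta_q, length(lq)),
    S_qy = params$r * sqrt(params$psi_q * params$psi_b) * (lq %o% lb),
    S_b  = params$psi_b * tcrossprod(lb) + diag(params$theta_b, 2L),
    S_w  = params$psi_w * tcrossprod(lw) + diag(params$theta_w, 2L))
}

#' Model-implied variance of the questionnaire sum score
#'
#' Variance of the sum of the questionnaire items under the factor model
#' with continuous indicators: `(sum lambda)^2 psi + sum theta`. Used to
#' calibrate outcome-regression residual variances to a target R-squared.
#'
#' @param params a `phq_params` object.
#' @return Scalar variance of the item sum.
#' @export
implied_sum_variance <- function(params) {
  sum(params$lambda_q)^2 * params$psi_q + sum(params$theta_q)
}
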