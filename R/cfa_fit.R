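#' Specification of the joint factor model
#'
#' Encodes the identification convention (latent means 0, latent variances
#' 1, daily loadings equated within each level) and the optional equality
#' of the two daily items' intercepts and residual variances.
#'
#' @param n_items questionnaire roster size (default 9).
#' @param equal_daily_items if `TRUE`, the two daily items share one
#'   intercept, one between-level residual variance and one within-level
#'   residual variance (in addition to the always-shared loadings).
#' @return Object of class `phq_model_spec`.
#' @export
model_spec <- function(n_items = 9L, equal_daily_items = FALSE) {
  structure(list(n_items = as.integer(n_items),
                 equal_daily_items = isTRUE(equal_daily_items)),
            class = "phq_model_spec")
}

#' Count free parameters of a model specification
#' @param spec a `phq_model_spec`.
#' @return Integer count of free parameters in a single-group fit.
#' @export
n_free_params <- function(spec) {
  p <- spec$n_items
  daily <- if (spec$equal_daily_items) 1L + 1L + 1L + 1L + 1L else
    1L + 2L + 2L + 1L + 2L # lambda_b, nu, theta_b, lambda_w, theta_w
  3L * p + daily + 1L # + r
}

# --- transformed parameter packing --------------------------------------

pack_model <- function(params, spec) {
  d <- if (spec$equal_daily_items) 1L else 2L
  c(params$lambda_q, params$tau_q, log(params$theta_q),
    params$lambda_b, params$nu[seq_len(d)], log(params$theta_b[seq_len(d)]),
    params$lambda_w, log(params$theta_w[seq_len(d)]),
    atanh(params$r))
}

unpack_model <- function(par, spec, psi = c(1, 1, 1)) {
  p <- spec$n_items
  i <- 0L
  take <- function(k) { v <- par[i + seq_len(k)]; i <<- i + k; v }
  lambda_q <- take(p); tau_q <- take(p); theta_q <- exp(take(p))
  lambda_b <- take(1L)
  d <- if (spec$equal_daily_items) 1L else 2L
  nu <- rep_len(take(d), 2L)
  theta_b <- rep_len(exp(take(d)), 2L)
  lambda_w <- take(1L)
  theta_w <- rep_len(exp(take(d)), 2L)
  r <- tanh(take(1L))
  parameter_set(lambda_q, tau_q, theta_q, lambda_b, nu, theta_b,
                lambda_w, theta_w, r,
                psi_q = psi[1], psi_b = psi[2], psi_w = psi[3])
}

param_names_model <- function(spec) {
  p <- spec$n_items
  d <- if (spec$equal_daily_items) "" else c("1", "2")
  c(paste0("lambda_q", seq_len(p)), paste0("tau_q", seq_len(p)),
    paste0("theta_q", seq_len(p)),
    "lambda_b", paste0("nu", d), paste0("theta_b", d),
    "lambda_w", paste0("theta_w", d), "r")
}

# original-scale vector (for SEs / recovery checks)
unpack_model_orig <- function(par, spec) {
  pp <- unpack_model(par, spec)
  d <- if (spec$equal_daily_items) 1L else 2L
  c(pp$lambda_q, pp$tau_q, pp$theta_q, pp$lambda_b, pp$nu[seq_len(d)],
    pp$theta_b[seq_len(d)], pp$lambda_w, pp$theta_w[seq_len(d)], pp$r)
}

# --- generic optimization helpers ---------------------------------------

num_grad <- function(fn, x, h = 1e-5) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    hk <- h * (1 + abs(x[k]))
    xp <- x; xp[k] <- x[k] + hk
    xm <- x; xm[k] <- x[k] - hk
    g[k] <- (fn(xp) - fn(xm)) / (2 * hk)
  }
  g
}

num_jacobian <- function(fn, x, h = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    hk <- h * (1 + abs(x[k]))
    xp <- x; xp[k] <- x[k] + hk
    xm <- x; xm[k] <- x[k] - hk
    J[, k] <- (fn(xp) - fn(xm)) / (2 * hk)
  }
  J
}

# Quasi-Newton minimization with restarts: BFGS is restarted from its own
# optimum until the objective stops improving, which in practice drives the
# (numerically estimated) gradient norm to the noise floor of the
# finite-difference objective.
minimize <- function(negll, start, max_iter = 500L, reltol = 1e-12,
                     restarts = 4L) {
  best <- stats::optim(start, negll, method = "BFGS",
                       control = list(maxit = max_iter, reltol = reltol))
  for (k in seq_len(max(restarts, 0L))) {
    nxt <- stats::optim(best$par, negll, method = "BFGS",
                        control = list(maxit = max_iter, reltol = reltol))
    improved <- best$value - nxt$value
    if (nxt$value <= best$value) best <- nxt
    if (improved < 1e-8 * (1 + abs(best$value))) break
  }
  g <- num_grad(negll, best$par, h = 1e-4)
  best$gnorm <- max(abs(g))
  best$converged <- best$convergence == 0 &&
    best$gnorm < 1e-4 * (1 + abs(best$value))
  best
}

finite_or_big <- function(x) if (is.finite(x)) x else 1e10

# --- model fit ----------------------------------------------------------

#' Fit the joint two-level factor model by full-information ML
#'
#' Maximizes the person-marginal Gaussian likelihood (latents integrated
#' analytically) over the free parameters: questionnaire loadings,
#' intercepts and residual variances; daily between- and within-level
#' loadings (shared across the 2 items within each level), intercepts and
#' residual variances; and the latent correlation. Variances are optimized
#' on the log scale and the correlation on the inverse-hyperbolic-tangent
#' scale. Standard errors come from the inverse of a numerically
#' differentiated Hessian on the transformed scale, mapped back by the
#' delta method.
#'
#' @param daily,panel filtered tables (see [apply_sample_filters()]).
#' @param spec a `phq_model_spec`.
#' @param anchor_week anchor questionnaire week.
#' @param se compute standard errors (skipped for speed inside large
#'   simulation loops).
#' @param start optional `phq_params` of starting values.
#' @param control list with `max_iter`, `reltol`.
#' @return Object of class `phq_fit` with elements `params`, `loglik`,
#'   `npar`, `estimates` (named original-scale vector), `se`, `vcov`,
#'   `convergence`, `n_persons`.
#' @export
fit_mlcfa <- function(daily, panel, spec = model_spec(), anchor_week = 4L,
                      se = TRUE, start = NULL, control = list()) {
  data <- prepare_cfa_data(daily, panel, anchor_week = anchor_week,
                           n_items = spec$n_items)
  max_iter <- control$max_iter %||% 500L
  reltol <- control$reltol %||% 1e-12

  if (is.null(start)) {
    # scale-equivariant defaults: loadings at half an item SD, residual
    # variances at half (questionnaire) / quarter (daily levels) of the
    # item variances, intercepts at the item means, r at 0
    p <- spec$n_items
    ysd <- sqrt(mean(data$y_vars))
    start <- parameter_set(
      lambda_q = 0.5 * sqrt(pmax(data$q_vars, 1e-6)), tau_q = data$q_means,
      theta_q = pmax(data$q_vars / 2, 1e-3),
      lambda_b = 0.5 * ysd, nu = data$y_means,
      theta_b = pmax(data$y_vars / 4, 1e-3),
      lambda_w = 0.5 * ysd, theta_w = pmax(data$y_vars / 4, 1e-3), r = 0)
  }
  par0 <- pack_model(start, spec)
  negll <- function(par)
    finite_or_big(-blocks_loglik_safe(implied_blocks(unpack_model(par, spec)),
                                      data))
  opt <- minimize(negll, par0, max_iter = max_iter, reltol = reltol,
                  restarts = control$restarts %||% 4L)
  params <- unpack_model(opt$par, spec)
  nm <- param_names_model(spec)
  est <- unpack_model_orig(opt$par, spec)
  names(est) <- nm

  se_vec <- vcov_o <- V_t <- NULL
  if (se) {
    H <- stats::optimHess(opt$par, negll)
    V_t <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V_t)) {
      J <- num_jacobian(function(x) unpack_model_orig(x, spec), opt$par)
      vcov_o <- J %*% V_t %*% t(J)
      dimnames(vcov_o) <- list(nm, nm)
      dg <- diag(vcov_o)
      se_vec <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
      names(se_vec) <- nm
    }
  }
  boundary <- abs(params$r) > 0.999
  structure(list(params = params, spec = spec, loglik = -opt$value,
                 npar = length(par0), estimates = est, se = se_vec,
                 vcov = vcov_o, vcov_t = V_t, par_t = opt$par,
                 convergence = list(converged = opt$converged,
                                    gradient_norm = opt$gnorm,
                                    iterations = opt$counts[1],
                                    boundary_r = boundary),
                 n_persons = data$n_persons, data = data),
            class = "phq_fit")
}

#' @export
print.phq_fit <- function(x, ...) {
  cat("Joint two-level factor model fit (FIML)\n")
  cat(sprintf("  persons: %d, free parameters: %d\n", x$n_persons, x$npar))
  cat(sprintf("  log-likelihood: %.3f (converged: %s)\n", x$loglik,
              x$convergence$converged))
  cat(sprintf("  latent correlation r = %.3f\n", x$params$r))
  invisible(x)
}

# --- saturated and independence models ----------------------------------

pack_chol <- function(S) {
  U <- chol(S)
  d <- nrow(S)
  out <- numeric(d * (d + 1) / 2)
  i <- 0L
  for (col in seq_len(d)) {
    for (row in seq_len(col)) {
      i <- i + 1L
      out[i] <- if (row == col) log(U[row, col]) else U[row, col]
    }
  }
  out
}

unpack_chol <- function(v, d) {
  U <- matrix(0, d, d)
  i <- 0L
  for (col in seq_len(d)) {
    for (row in seq_len(col)) {
      i <- i + 1L
      U[row, col] <- if (row == col) exp(v[i]) else v[i]
    }
  }
  crossprod(U)
}

#' Fit the unrestricted (saturated) two-level mean/covariance structure
#'
#' The saturated counterpart of the joint model: an arbitrary positive
#' definite between-level covariance over the questionnaire items and the
#' person-level components of the 2 daily items (dimension p+2), an
#' arbitrary 2x2 within-level covariance, and p+2 free means —
#' Cholesky-parameterized and maximized under the same person-marginal
#' likelihood. Its log-likelihood upper-bounds every structured model's
#' and anchors the chi-square behind the fit indices.
#'
#' @param daily,panel filtered tables.
#' @param anchor_week anchor questionnaire week.
#' @param n_items questionnaire roster size.
#' @param control list with `max_iter`, `reltol`.
#' @return List with `loglik`, `npar`, `blocks`, `convergence`.
#' @export
fit_saturated <- function(daily, panel, anchor_week = 4L, n_items = 9L,
                          control = list()) {
  data <- prepare_cfa_data(daily, panel, anchor_week = anchor_week,
                           n_items = n_items)
  p <- n_items
  d <- p + 2L
  start <- saturated_start(daily, panel, anchor_week, n_items)
  nb <- d * (d + 1L) / 2L
  unpack <- function(par) {
    mu <- par[seq_len(d)]
    B <- unpack_chol(par[d + seq_len(nb)], d)
    W <- unpack_chol(par[d + nb + seq_len(3L)], 2L)
    list(mu_q = mu[seq_len(p)], mu_y = mu[p + 1:2],
         S_qq = B[seq_len(p), seq_len(p), drop = FALSE],
         S_qy = B[seq_len(p), p + 1:2, drop = FALSE],
         S_b = B[p + 1:2, p + 1:2, drop = FALSE], S_w = W)
  }
  par0 <- c(start$mu, pack_chol(start$B), pack_chol(start$W))
  negll <- function(par)
    finite_or_big(-blocks_loglik_safe(unpack(par), data))
  opt <- minimize(negll, par0, max_iter = control$max_iter %||% 1000L,
                  reltol = control$reltol %||% 1e-12)
  list(loglik = -opt$value, npar = length(par0), blocks = unpack(opt$par),
       convergence = list(converged = opt$converged,
                          gradient_norm = opt$gnorm))
}

# Moment-based starting values for the saturated fit.
saturated_start <- function(daily, panel, anchor_week, n_items) {
  item_cols <- panel_item_cols()[seq_len(n_items)]
  pr <- panel[panel$week == anchor_week, , drop = FALSE]
  pr <- pr[stats::complete.cases(pr[, item_cols]), , drop = FALSE]
  z <- as.matrix(pr[, item_cols, drop = FALSE])
  f <- factor(daily$person_id)
  ybar <- cbind(tapply(daily$item1, f, mean), tapply(daily$item2, f, mean))
  nj <- as.integer(table(f))
  # pooled within covariance over persons with >= 2 days
  W <- matrix(0, 2, 2); dfw <- 0
  for (id in levels(f)[nj >= 2]) {
    Y <- as.matrix(daily[daily$person_id == id, c("item1", "item2")])
    Yc <- sweep(Y, 2, colMeans(Y))
    W <- W + crossprod(Yc); dfw <- dfw + nrow(Y) - 1L
  }
  W <- if (dfw > 0) W / dfw else diag(0.3, 2)
  common <- intersect(pr$person_id, levels(f))
  Z <- z[match(common, pr$person_id), , drop = FALSE]
  Yb <- ybar[match(common, levels(f)), , drop = FALSE]
  V <- stats::cov(cbind(Z, Yb))
  nbar <- mean(nj[match(common, levels(f))])
  V[n_items + 1:2, n_items + 1:2] <-
    V[n_items + 1:2, n_items + 1:2] - W / nbar
  e <- eigen(V, symmetric = TRUE)
  V <- e$vectors %*% diag(pmax(e$values, 0.02), nrow(V)) %*% t(e$vectors)
  list(mu = c(colMeans(z), colMeans(ybar)), B = V,
       W = W + diag(1e-3, 2))
}

#' Fit the independence (null) model
#'
#' Diagonal covariances at both levels, zero cross-block covariance, free
#' means and variances: the conventional baseline for incremental fit
#' indices.
#'
#' @inheritParams fit_saturated
#' @return List with `loglik`, `npar`, `convergence`.
#' @export
fit_baseline <- function(daily, panel, anchor_week = 4L, n_items = 9L,
                         control = list()) {
  data <- prepare_cfa_data(daily, panel, anchor_week = anchor_week,
                           n_items = n_items)
  p <- n_items
  unpack <- function(par) {
    mu <- par[seq_len(p + 2L)]
    vb <- exp(par[p + 2L + seq_len(p + 2L)])
    vw <- exp(par[2L * (p + 2L) + 1:2])
    list(mu_q = mu[seq_len(p)], mu_y = mu[p + 1:2],
         S_qq = diag(vb[seq_len(p)], p), S_qy = matrix(0, p, 2L),
         S_b = diag(vb[p + 1:2], 2L), S_w = diag(vw, 2L))
  }
  par0 <- c(data$q_means, data$y_means,
            log(pmax(c(data$q_vars, data$y_vars / 2), 1e-3)),
            log(pmax(data$y_vars / 2, 1e-3)))
  negll <- function(par)
    finite_or_big(-blocks_loglik_safe(unpack(par), data))
  opt <- minimize(negll, par0, max_iter = control$max_iter %||% 500L,
                  reltol = control$reltol %||% 1e-12)
  list(loglik = -opt$value, npar = length(par0),
       convergence = list(converged = opt$converged,
                          gradient_norm = opt$gnorm))
}

#' Chi-square and incremental fit indices
#'
#' @param model a `phq_fit` (or any list with `loglik` and `npar`).
#' @param saturated,baseline results of [fit_saturated()] and
#'   [fit_baseline()] on the same data.
#' @param n_persons number of independent units (persons) for the RMSEA
#'   denominator.
#' @return List with `chi2`, `df`, `chi2_baseline`, `df_baseline`, `cfi`,
#'   `tli`, `rmsea`, and `defined` (FALSE when df <= 0).
#' @export
fit_indices <- function(model, saturated, baseline, n_persons) {
  chi2_m <- 2 * (saturated$loglik - model$loglik)
  df_m <- saturated$npar - model$npar
  chi2_b <- 2 * (saturated$loglik - baseline$loglik)
  df_b <- saturated$npar - baseline$npar
  if (df_m <= 0 || df_b <= 0)
    return(list(chi2 = chi2_m, df = df_m, chi2_baseline = chi2_b,
                df_baseline = df_b, cfi = NA_real_, tli = NA_real_,
                rmsea = NA_real_, defined = FALSE))
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- ((chi2_b / df_b) - (chi2_m / df_m)) / ((chi2_b / df_b) - 1)
  rmsea <- sqrt(max(chi2_m - df_m, 0) / (df_m * n_persons))
  list(chi2 = chi2_m, df = df_m, chi2_baseline = chi2_b, df_baseline = df_b,
       cfi = cfi, tli = tli, rmsea = rmsea, defined = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
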