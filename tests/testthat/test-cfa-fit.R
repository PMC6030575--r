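# balanced-case closed-form ML for the saturated two-level structure:
# within covariance from the pooled within scatter, between covariance from
# the per-person (z, ybar) sample covariance minus the shrunk within part
balanced_saturated_oracle <- function(daily, panel, n, n_items = 9L) {
  item_cols <- paste0("phq9_item", seq_len(n_items))
  pr <- panel[panel$week == 4, , drop = FALSE]
  ids <- sort(unique(daily$person_id))
  Z <- as.matrix(pr[match(ids, pr$person_id), item_cols])
  ybar <- cbind(tapply(daily$item1, daily$person_id, mean)[ids],
                tapply(daily$item2, daily$person_id, mean)[ids])
  m <- length(ids)
  W <- matrix(0, 2, 2)
  for (id in ids) {
    Y <- as.matrix(daily[daily$person_id == id, c("item1", "item2")])
    W <- W + crossprod(sweep(Y, 2, colMeans(Y)))
  }
  S_w <- W / (m * (n - 1))
  V <- cbind(Z, ybar)
  mu <- colMeans(V)
  B <- crossprod(sweep(V, 2, mu)) / m
  B[n_items + 1:2, n_items + 1:2] <-
    B[n_items + 1:2, n_items + 1:2] - S_w / n
  list(mu_q = mu[seq_len(n_items)], mu_y = mu[n_items + 1:2],
       S_qq = B[seq_len(n_items), seq_len(n_items)],
       S_qy = B[seq_len(n_items), n_items + 1:2],
       S_b = B[n_items + 1:2, n_items + 1:2], S_w = S_w)
}

test_that("FIML recovers generating parameters on a moderate cohort", {
  flt <- filtered_cohort(21, small_gen_config(n_persons = 800L))
  fit <- fit_mlcfa(flt$daily, flt$panel, se = FALSE)
  truth <- default_measurement_params()
  expect_true(fit$convergence$converged)
  expect_lt(max(abs(fit$params$lambda_q - truth$lambda_q)), 0.1)
  expect_lt(abs(fit$params$lambda_b - truth$lambda_b), 0.1)
  expect_lt(abs(fit$params$lambda_w - truth$lambda_w), 0.05)
  expect_lt(abs(fit$params$r - truth$r), 0.08)
})

test_that("null-loading data yield near-zero recovered loadings", {
  cfg <- small_gen_config(n_persons = 300L)
  cfg$params <- parameter_set(lambda_q = rep(0, 9),
                              tau_q = cfg$params$tau_q,
                              theta_q = cfg$params$theta_q,
                              lambda_b = 0, nu = cfg$params$nu,
                              theta_b = c(0.3, 0.3), lambda_w = 0,
                              theta_w = cfg$params$theta_w, r = 0)
  flt <- filtered_cohort(22, cfg)
  fit <- fit_mlcfa(flt$daily, flt$panel, se = FALSE)
  nul <- fit_baseline(flt$daily, flt$panel)
  # the independence model is true here, so the 12 extra factor
  # parameters buy only chi-square-scale likelihood (boundary ridges in
  # the unidentified loadings/correlation included)
  expect_lt(2 * (fit$loglik - nul$loglik), 45)
  expect_lt(median(abs(fit$params$lambda_q)), 0.12)
  expect_lt(abs(fit$params$lambda_w), 0.12)
})

test_that("duplicating every person leaves estimates fixed and shrinks SEs by sqrt(2)", {
  flt <- filtered_cohort(23, small_gen_config(n_persons = 250L))
  fit1 <- fit_mlcfa(flt$daily, flt$panel)
  d2 <- flt$daily
  p2 <- flt$panel
  d2$person_id <- paste0(d2$person_id, "_dup")
  p2$person_id <- paste0(p2$person_id, "_dup")
  daily2 <- validate_long_daily(rbind(flt$daily, d2), continuous = TRUE)
  panel2 <- validate_panel(rbind(flt$panel, p2), continuous = TRUE)
  fit2 <- fit_mlcfa(daily2, panel2)
  expect_equal(fit2$estimates, fit1$estimates, tolerance = 1e-3)
  ratio <- fit2$se / fit1$se
  expect_equal(median(ratio), 1 / sqrt(2), tolerance = 0.02)
})

test_that("the nesting chain baseline <= model <= saturated holds", {
  flt <- filtered_cohort(24, small_gen_config(n_persons = 150L,
                                              max_days = 4L))
  fit <- fit_mlcfa(flt$daily, flt$panel, se = FALSE)
  sat <- fit_saturated(flt$daily, flt$panel)
  nul <- fit_baseline(flt$daily, flt$panel)
  expect_lte(nul$loglik, fit$loglik + 1e-6)
  expect_lte(fit$loglik, sat$loglik + 1e-6)
  # free-parameter bookkeeping: 11 means + 66 between + 3 within = 80;
  # independence model: 11 means + 11 between + 2 within variances = 24
  expect_equal(sat$npar, 80L)
  expect_equal(nul$npar, 24L)
  expect_equal(fit$npar, n_free_params(model_spec()))
})

test_that("balanced-cluster saturated fit matches the moment oracle", {
  n <- 4L
  cfg <- small_gen_config(n_persons = 120L)
  cfg$cluster_sizes <- c(0, 0, 0, 1, rep(0, 10)) # all clusters of 4
  flt <- filtered_cohort(25, cfg)
  sat <- fit_saturated(flt$daily, flt$panel)
  oracle <- balanced_saturated_oracle(flt$daily, flt$panel, n)
  dat <- prepare_cfa_data(flt$daily, flt$panel)
  ll_oracle <- dailyphq:::blocks_loglik(oracle, dat)
  expect_equal(sat$loglik, ll_oracle, tolerance = 1e-4)
  expect_gte(sat$loglik, ll_oracle - 1e-4)
})

test_that("fit indices follow their defining formulas", {
  model <- list(loglik = -100, npar = 36L)
  sat <- list(loglik = 0, npar = 136L)
  base <- list(loglik = -550, npar = 16L)
  # chi2_M = 200 on df 100; chi2_B = 1100 on df 120
  fi <- fit_indices(model, sat, base, n_persons = 500L)
  expect_equal(fi$chi2, 200)
  expect_equal(fi$df, 100L)
  expect_equal(fi$cfi, 1 - 100 / 980, tolerance = 1e-10)
  expect_equal(fi$tli, (1100 / 120 - 2) / (1100 / 120 - 1),
               tolerance = 1e-10)
  expect_equal(fi$rmsea, sqrt(100 / (100 * 500)), tolerance = 1e-10)
  # saturated-as-model limit
  fi0 <- fit_indices(sat, sat, base, 500L)
  expect_equal(fi0$defined, FALSE) # df = 0: indices undefined, flagged
  near <- fit_indices(list(loglik = -50.5, npar = 35L), sat, base, 500L)
  expect_gt(near$cfi, 0.99)
  expect_gt(near$tli, 0.99)
})

test_that("rescaling the daily items rescales only their parameters", {
  n_items <- 3L
  cfg <- small_gen_config(n_persons = 200L, n_items = n_items)
  flt <- filtered_cohort(26, cfg)
  spec <- model_spec(n_items = n_items)
  fit1 <- fit_mlcfa(flt$daily, flt$panel, spec, se = FALSE)
  cc <- 2.5
  d2 <- flt$daily
  d2$item1 <- d2$item1 * cc
  d2$item2 <- d2$item2 * cc
  fit2 <- fit_mlcfa(d2, flt$panel, spec, se = FALSE)
  expect_equal(fit2$params$lambda_b, cc * fit1$params$lambda_b,
               tolerance = 1e-3)
  expect_equal(fit2$params$lambda_w, cc * fit1$params$lambda_w,
               tolerance = 1e-3)
  expect_equal(sqrt(fit2$params$theta_w), cc * sqrt(fit1$params$theta_w),
               tolerance = 1e-3)
  expect_equal(fit2$params$r, fit1$params$r, tolerance = 1e-4)
  expect_equal(fit2$params$lambda_q, fit1$params$lambda_q,
               tolerance = 1e-3)
  # chi-square against the saturated structure is scale-free
  sat1 <- fit_saturated(flt$daily, flt$panel, n_items = n_items)
  sat2 <- fit_saturated(d2, flt$panel, n_items = n_items)
  chi1 <- 2 * (sat1$loglik - fit1$loglik)
  chi2 <- 2 * (sat2$loglik - fit2$loglik)
  expect_equal(chi1, chi2, tolerance = 0.02 * max(1, abs(chi1)))
})

test_that("releasing a constraint never lowers the likelihood", {
  flt <- filtered_cohort(27, small_gen_config(n_persons = 120L))
  tied <- fit_mlcfa(flt$daily, flt$panel,
                    model_spec(equal_daily_items = TRUE), se = FALSE)
  free <- fit_mlcfa(flt$daily, flt$panel, model_spec(), se = FALSE)
  expect_gte(free$loglik, tied$loglik - 1e-6)
  expect_equal(free$npar - tied$npar, 3L)
})
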