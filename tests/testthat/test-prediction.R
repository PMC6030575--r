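daily_of <- function(days, s1, s2, id = "a") {
  validate_long_daily(data.frame(person_id = id, day = days,
                                 item1 = s1, item2 = s2),
                      continuous = TRUE)
}

test_that("daily summaries match hand calculations", {
  # constant series
  s <- summarize_daily(daily_of(20:22, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 0)
  expect_equal(s$min, 2)
  expect_equal(s$max, 2)
  expect_equal(s$slope, 0)
  expect_equal(s$n_days, 3)
  # composite scores 1 and 3 on consecutive days: two-point least squares
  s2 <- summarize_daily(daily_of(20:21, c(1, 3), c(1, 3)))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(s2$slope, 2)
  # a gap doubles the day span, halving the slope
  s2b <- summarize_daily(daily_of(c(20, 24), c(1, 3), c(1, 3)))
  expect_equal(s2b$slope, 0.5)
  # single rating: sd and slope undefined
  s1 <- summarize_daily(daily_of(20, 4, 2))
  expect_equal(s1$mean, 3)
  expect_equal(s1$min, 3)
  expect_equal(s1$max, 3)
  expect_true(is.na(s1$sd) && is.na(s1$slope))
})

test_that("model matrices carry the documented predictor rosters and Ns", {
  flt <- filtered_cohort(51, small_gen_config(n_persons = 250L))
  summ <- summarize_daily(flt$daily)
  m1 <- build_model_matrices(flt$panel, summ, 1)
  expect_equal(colnames(m1$X), c("(Intercept)", "phq9_week4"))
  m4 <- build_model_matrices(flt$panel, summ, 4)
  expect_equal(ncol(m4$X), 6L)
  m2 <- build_model_matrices(flt$panel, summ, 2)
  expect_lte(m4$n, m2$n) # persons with n_days < 2 drop from model 4 only
  # persons missing a week-8 outcome are excluded listwise
  wk8 <- flt$panel[flt$panel$week == 8, ]
  n_complete <- sum(stats::complete.cases(wk8[, c("phq9_sum", "sds_sum")]))
  expect_equal(m2$n, sum(!is.na(merge(
    wk8[stats::complete.cases(wk8[, c("phq9_sum", "sds_sum")]), "person_id",
        drop = FALSE],
    summ, by = "person_id")$mean)))
  expect_lte(m1$n, n_complete)
  expect_error(build_model_matrices(flt$panel, summ, 7), "model_id")
})

test_that("SUR with identical regressors equals OLS to numerical precision", {
  flt <- filtered_cohort(52, small_gen_config(n_persons = 300L))
  summ <- summarize_daily(flt$daily)
  mm <- build_model_matrices(flt$panel, summ, 3)
  s <- fit_sur(mm$X, mm$Y)
  for (j in 1:2) {
    ols <- qr.coef(qr(mm$X), mm$Y[, j])
    expect_lt(max(abs(s$equations[[j]]$coefficients - ols)), 1e-10)
  }
})

test_that("exactly linear outcomes give unit R-squared", {
  set.seed(53)
  X <- cbind(1, rnorm(100), rnorm(100))
  colnames(X) <- c("(Intercept)", "a", "b")
  Y <- cbind(X %*% c(1, 2, -1), X %*% c(0, 1, 1))
  s <- fit_sur(X, Y)
  expect_equal(unname(s$r2), c(1, 1), tolerance = 1e-12)
})

test_that("singular designs are rejected with the collinear column named", {
  set.seed(54)
  x <- rnorm(50)
  X <- cbind(`(Intercept)` = 1, x = x, x2 = 2 * x)
  Y <- cbind(rnorm(50), rnorm(50))
  expect_error(fit_sur(X, Y), "collinear column")
})

test_that("iterated FGLS never decreases the joint Gaussian likelihood", {
  # different regressors per equation so iteration actually moves
  set.seed(55)
  n <- 200L
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  e1 <- rnorm(n); e2 <- 0.8 * e1 + 0.6 * rnorm(n)
  Y <- cbind(1 + 2 * x1 + e1, 0.5 - x2 + 0.7 * x3 + e2)
  Xs <- list(cbind(1, x1), cbind(1, x2, x3))
  joint_ll <- function(fit) {
    E <- sapply(1:2, function(j) Y[, j] - Xs[[j]] %*% fit$equations[[j]]$coefficients)
    S <- crossprod(E) / n
    -n / 2 * (2 * log(2 * pi) + determinant(S)$modulus[1] + 2)
  }
  two_step <- fit_sur(Xs, Y)
  iterated <- fit_sur(Xs, Y, iterate = TRUE)
  expect_gte(joint_ll(iterated), joint_ll(two_step) - 1e-8)
  expect_gte(iterated$iterations, two_step$iterations)
})

test_that("R-squared is invariant to affine predictor rescaling", {
  flt <- filtered_cohort(56, small_gen_config(n_persons = 300L))
  summ <- summarize_daily(flt$daily)
  mm <- build_model_matrices(flt$panel, summ, 3)
  s0 <- fit_sur(mm$X, mm$Y)
  X2 <- mm$X
  X2[, "phq9_week4"] <- 10 * X2[, "phq9_week4"] - 7
  X2[, "phq2_mean"] <- -0.2 * X2[, "phq2_mean"] + 3
  s1 <- fit_sur(X2, mm$Y)
  expect_equal(s1$r2, s0$r2, tolerance = 1e-10)
})

test_that("SUR recovers generating outcome coefficients within 3 SEs", {
  cfg <- small_gen_config(n_persons = 2000L, missing_week8 = 0)
  cfg$beta_phq <- c(1.5, 0.7, 0.4)
  cfg$beta_sds <- c(3.0, 2.7, 1.0)
  flt <- filtered_cohort(57, cfg)
  summ <- summarize_daily(flt$daily)
  mm <- build_model_matrices(flt$panel, summ, 3)
  s <- fit_sur(mm$X, mm$Y)
  for (j in 1:2) {
    beta_true <- if (j == 1) cfg$beta_phq else cfg$beta_sds
    eq <- s$equations[[j]]
    expect_true(all(abs(eq$coefficients - beta_true) < 3 * eq$se))
  }
})

test_that("incremental R-squared reflects whether a daily effect was planted", {
  # outcomes driven by the anchor sum only: model 3 adds nothing
  cfg0 <- small_gen_config(n_persons = 4000L, missing_week8 = 0)
  flt0 <- filtered_cohort(58, cfg0)
  pr0 <- predict_report(flt0$panel, summarize_daily(flt0$daily),
                        models = c(1, 3))
  inc0 <- pr0$fits[["3"]]$r2[1] - pr0$fits[["1"]]$r2[1]
  expect_lt(abs(inc0), 0.01)
  # an independent daily-mean effect shows up as a real increment
  cfg1 <- small_gen_config(n_persons = 4000L, missing_week8 = 0)
  cfg1$beta_phq <- c(1.5, 0.7, 2.0)
  cfg1$beta_sds <- c(3.0, 2.7, 4.0)
  flt1 <- filtered_cohort(58, cfg1)
  pr1 <- predict_report(flt1$panel, summarize_daily(flt1$daily),
                        models = c(1, 3))
  inc1 <- pr1$fits[["3"]]$r2[1] - pr1$fits[["1"]]$r2[1]
  expect_gt(inc1, inc0 + 0.005)
})

test_that("the prediction table mirrors the four-model layout", {
  flt <- filtered_cohort(59, small_gen_config(n_persons = 250L))
  pr <- predict_report(flt$panel, summarize_daily(flt$daily))
  tab <- pr$table
  expect_setequal(unique(tab$model), 1:4)
  expect_setequal(unique(tab$outcome), c("phq9_wk8", "sds_wk8"))
  terms4 <- tab$term[tab$model == 4 & tab$outcome == "phq9_wk8"]
  expect_equal(terms4, c("(Intercept)", "phq2_mean", "phq2_slope",
                         "phq2_max", "phq2_min", "phq2_sd"))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
})
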