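test_that("fixture cluster sizes reproduce the reference multiset", {
  sizes <- sample_cluster_sizes(545L, "fixture", seed = 1)
  expect_equal(sum(sizes), 2992L)
  expect_equal(as.integer(table(factor(sizes, levels = 1:14))),
               reference_cluster_size_counts())
  expect_error(sample_cluster_sizes(100L, "fixture"), "must be 545")
})

test_that("cluster-size sampling follows the supplied distribution", {
  deg <- c(1, rep(0, 13))
  expect_true(all(sample_cluster_sizes(200L, deg, seed = 2) == 1L))
  props <- reference_cluster_size_counts() / 545
  draws <- sample_cluster_sizes(100000L, props, seed = 3)
  expect_lt(abs(mean(draws) - 2992 / 545), 0.05)
})

test_that("latent pairs have the requested correlation structure", {
  l1 <- generate_latents(100L, r = 1, seed = 4)
  expect_equal(l1[, "eta_b"], l1[, "xi"])
  l0 <- generate_latents(50000L, r = 0, seed = 5)
  expect_lt(abs(cor(l0[, 1], l0[, 2])), 0.02)
  l8 <- generate_latents(50000L, r = 0.8, seed = 6)
  expect_lt(abs(cor(l8[, 1], l8[, 2]) - 0.8), 0.02)
  expect_error(generate_latents(10L, r = 1.2), "<= 1")
})

test_that("daily items degenerate to their intercepts without signal", {
  params <- parameter_set(lambda_q = rep(0, 9), tau_q = rep(1, 9),
                          theta_q = rep(1e-12, 9),
                          lambda_b = 0, nu = c(2.2, 2.4),
                          theta_b = c(1e-12, 1e-12), lambda_w = 0,
                          theta_w = c(1e-12, 1e-12), r = 0)
  lat <- generate_latents(20L, 0, seed = 7)
  tab <- generate_daily_items(lat, rep(3L, 20L), params, seed = 7)
  expect_equal(tab$item1, rep(2.2, 60), tolerance = 1e-4)
  expect_equal(tab$item2, rep(2.4, 60), tolerance = 1e-4)
})

test_that("a person with 14 ratings occupies the whole window", {
  lat <- generate_latents(1L, 0.5, seed = 8)
  tab <- generate_daily_items(lat, 14L, default_measurement_params(),
                              seed = 8)
  expect_equal(sort(tab$day), 14:27)
})

test_that("continuous-mode moments match the model-implied within covariance", {
  params <- default_measurement_params()
  n <- 20000L
  lat <- generate_latents(n, params$r, seed = 9)
  tab <- generate_daily_items(lat, rep(4L, n), params, seed = 9)
  # pooled within-person covariance of the two items
  w1 <- tab$item1 - ave(tab$item1, tab$person_id)
  w2 <- tab$item2 - ave(tab$item2, tab$person_id)
  W <- crossprod(cbind(w1, w2)) / (nrow(tab) - n)
  expected_diag <- params$lambda_w^2 + params$theta_w[1]
  expected_off <- params$lambda_w^2
  expect_lt(abs(W[1, 1] / expected_diag - 1), 0.02)
  expect_lt(abs(W[2, 2] / expected_diag - 1), 0.02)
  expect_lt(abs(W[1, 2] / expected_off - 1), 0.02)
})

test_that("questionnaire items follow the single-level factor structure", {
  params <- default_measurement_params()
  degenerate <- parameter_set(lambda_q = rep(0, 9), tau_q = params$tau_q,
                              theta_q = rep(1e-12, 9), lambda_b = 0.85,
                              nu = params$nu, theta_b = params$theta_b,
                              lambda_w = 0.66, theta_w = params$theta_w,
                              r = 0)
  lat <- generate_latents(10L, 0, seed = 10)
  z <- generate_questionnaire(lat, degenerate, seed = 10)
  expect_equal(unname(rowSums(z)), rep(8.51, 10L), tolerance = 1e-4)

  n <- 20000L
  lat <- generate_latents(n, params$r, seed = 111)
  z <- generate_questionnaire(lat, params, seed = 11)
  expect_lt(abs(cov(z[, 1], z[, 2]) / (0.60 * 0.63) - 1), 0.02)

  # shifting the latent by +1 shifts every item mean by its loading
  lat_shift <- lat
  lat_shift[, "xi"] <- lat[, "xi"] + 1
  z2 <- generate_questionnaire(lat_shift, params, seed = 11)
  expect_equal(unname(colMeans(z2) - colMeans(z)), params$lambda_q,
               tolerance = 1e-6)
})

test_that("baseline generator hits the post-truncation target mean", {
  x <- generate_baseline(20000L, 13.9, 5.0, eligibility_floor = -Inf,
                         seed = 12)
  expect_lt(abs(mean(x) - 13.9), 0.1)
  y <- generate_baseline(20000L, 13.9, 5.0, eligibility_floor = 5,
                         seed = 13)
  expect_true(all(y >= 5))
  expect_lt(abs(mean(y) - 13.9), 0.1)
  # truncation from below raises the mean, so calibration must lower it
  expect_lt(calibrate_baseline_mean(13.9, 5.0, floor = 5), 13.9)
  expect_error(calibrate_baseline_mean(3, 1, floor = 10), "infeasible")
})

test_that("outcome generation respects its calibrated error structure", {
  set.seed(14)
  x <- rnorm(500, 14, 5)
  dm <- rnorm(500, 2.2, 0.9)
  out <- generate_outcomes(x, dm, beta_phq = c(1, 0.7, 0.2),
                           beta_sds = c(2, 2.7, 1),
                           sigma_phq = 1e-12, sigma_sds = 1e-12,
                           seed = 14)
  expect_equal(out$phq9_wk8, 1 + 0.7 * x + 0.2 * dm, tolerance = 1e-6)
  expect_equal(out$sds_wk8, 2 + 2.7 * x + 1 * dm, tolerance = 1e-6)

  out2 <- generate_outcomes(x, dm, c(0, 1, 0), c(0, 1, 0), 3, 3,
                            missing_week8 = 0.35, seed = 15)
  p_obs <- mean(out2$observed)
  expect_lt(abs(p_obs - 0.65), 3 * sqrt(0.35 * 0.65 / 500))
})

test_that("cohorts are seed-deterministic and seed-sensitive", {
  cfg <- small_gen_config(n_persons = 60L)
  a <- generate_cohort(cfg, seed = 16)
  b <- generate_cohort(cfg, seed = 16)
  c <- generate_cohort(cfg, seed = 17)
  expect_identical(a, b)
  expect_false(identical(a$daily$item1, c$daily$item1))
})

test_that("discretization attenuates covariances", {
  cfg_c <- small_gen_config(n_persons = 4000L, max_days = 5L)
  cfg_d <- small_gen_config(n_persons = 4000L, max_days = 5L,
                            discretize = TRUE)
  a <- generate_cohort(cfg_c, seed = 18)
  b <- generate_cohort(cfg_d, seed = 18)
  za <- a$panel[a$panel$week == 4, paste0("phq9_item", 1:2)]
  zb <- b$panel[b$panel$week == 4, paste0("phq9_item", 1:2)]
  expect_lt(abs(cov(zb[, 1], zb[, 2])), abs(cov(za[, 1], za[, 2])))
})

test_that("regressing generated data on retained latents recovers loadings", {
  cfg <- small_gen_config(n_persons = 4000L)
  coh <- generate_cohort(cfg, seed = 19)
  z1 <- coh$panel[coh$panel$week == 4, "phq9_item1"]
  b <- coef(lm(z1 ~ coh$truth$xi))[2]
  expect_lt(abs(b - 0.60), 0.04)
  # person means of daily items recover the between loading
  pm <- tapply(coh$daily$item1, coh$daily$person_id, mean)
  b2 <- coef(lm(pm[coh$truth$person_id] ~ coh$truth$eta_b))[2]
  expect_lt(abs(b2 - 0.85), 0.04)
})
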