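#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the reference remote mobile-health depression cohort:
#' 545 persons, the empirical distribution of daily-rating counts (1-14
#' per person, mean 5.5), the reference measurement parameters with latent
#' correlation 0.80, baseline eligibility truncation (sum score >= 5,
#' post-truncation mean 13.9, SD 5.0), and week-8 outcome regressions whose
#' residual variances are calibrated so the population R-squared of the
#' anchor-sum-only model matches the reference values (0.49 for the week-8
#' depression sum, 0.37 for the disability sum).
#'
#' @param n_persons number of persons to generate.
#' @param cluster_sizes `"fixture"` (exact reference multiset of rating
#'   counts; requires `n_persons = 545`) or a probability vector over 1-14.
#' @param params a `phq_params` object of generating measurement values;
#'   its `r` is the latent correlation between the between-person daily
#'   factor and the questionnaire factor.
#' @param discretize logical; round-and-clip responses to their ordinal
#'   scales (1-5 daily, 0-3 questionnaire). Continuous mode (default) keeps
#'   normal-theory indicators so sample moments match model-implied moments.
#' @param baseline_mean,baseline_sd target post-truncation mean and
#'   pre-truncation SD of the baseline questionnaire sum.
#' @param eligibility_floor minimum baseline sum (draws below are rejected);
#'   `-Inf` disables truncation.
#' @param beta_phq,beta_sds outcome-equation coefficients
#'   `c(intercept, anchor-week questionnaire sum, daily composite mean)` for
#'   the week-8 depression and disability equations.
#' @param r2_phq,r2_sds population R-squared targets used to calibrate the
#'   outcome residual variances (given the anchor-sum coefficient and the
#'   model-implied predictor variance); set to `NA` to use
#'   `sigma_phq`/`sigma_sds` directly.
#' @param sigma_phq,sigma_sds residual SDs of the two outcome equations
#'   (ignored when the R-squared targets are given).
#' @param resid_cor cross-equation residual correlation of the outcomes.
#' @param missing_week8 MCAR deletion probability for week-8 outcome rows.
#' @param prop_woman,prop_minority,prop_55plus group-label proportions
#'   (independent Bernoulli draws).
#' @param group_offsets optional named list of per-group deviations from
#'   `params` for the second level of a grouping variable, e.g.
#'   `list(gender = list(lambda_q = -0.3))`: the named components are added
#'   to the corresponding parameter of `params` for persons in the second
#'   level (woman / 55+ / minority = yes). Defaults to none, so measurement
#'   invariance holds exactly.
#' @param window_length_days,anchor_week,outcome_week study timing (see
#'   [run_config()]).
#' @return A list of class `phq_gen_config`.
#' @export
generator_config <- function(n_persons = 545L,
                             cluster_sizes = "fixture",
                             params = default_measurement_params(),
                             discretize = FALSE,
                             baseline_mean = 13.9, baseline_sd = 5.0,
                             eligibility_floor = 5,
                             beta_phq = c(1.5, 0.7, 0),
                             beta_sds = c(3.0, 2.7, 0),
                             r2_phq = 0.49, r2_sds = 0.37,
                             sigma_phq = NA, sigma_sds = NA,
                             resid_cor = 0.3,
                             missing_week8 = 0.35,
                             prop_woman = 0.783, prop_minority = 0.381,
                             prop_55plus = 0.061,
                             group_offsets = list(),
                             window_length_days = 14L, anchor_week = 4L,
                             outcome_week = 8L) {
  stopifnot(n_persons >= 1, inherits(params, "phq_params"))
  if (is.numeric(cluster_sizes)) {
    if (length(cluster_sizes) != 14L || any(cluster_sizes < 0) ||
        abs(sum(cluster_sizes) - 1) > 1e-8)
      stop("cluster_sizes must be 'fixture' or a probability vector over 1..14",
           call. = FALSE)
  } else if (!identical(cluster_sizes, "fixture")) {
    stop("cluster_sizes must be 'fixture' or a probability vector over 1..14",
         call. = FALSE)
  }
  stopifnot(baseline_sd > 0, missing_week8 >= 0, missing_week8 < 1,
            length(beta_phq) == 3L, length(beta_sds) == 3L,
            abs(resid_cor) < 1)
  structure(list(
    n_persons = as.integer(n_persons), cluster_sizes = cluster_sizes,
    params = params, discretize = discretize,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    eligibility_floor = eligibility_floor,
    beta_phq = beta_phq, beta_sds = beta_sds,
    r2_phq = r2_phq, r2_sds = r2_sds,
    sigma_phq = sigma_phq, sigma_sds = sigma_sds, resid_cor = resid_cor,
    missing_week8 = missing_week8,
    prop_woman = prop_woman, prop_minority = prop_minority,
    prop_55plus = prop_55plus, group_offsets = group_offsets,
    window_length_days = as.integer(window_length_days),
    anchor_week = as.integer(anchor_week),
    outcome_week = as.integer(outcome_week)),
    class = "phq_gen_config")
}

#' Sample per-person daily-rating counts
#'
#' @param n_persons number of persons.
#' @param distribution `"fixture"` for the exact reference multiset of
#'   counts (545 persons, 2992 ratings) or a probability vector over 1-14.
#' @param seed optional integer seed.
#' @return Integer vector of counts in 1-14, one per person. Fixture mode
#'   returns the reference multiset (in shuffled person order).
#' @export
sample_cluster_sizes <- function(n_persons, distribution = "fixture",
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (identical(distribution, "fixture")) {
    counts <- reference_cluster_size_counts()
    if (n_persons != sum(counts))
      stop(sprintf("fixture cluster sizes are exact: n_persons must be %d",
                   sum(counts)), call. = FALSE)
    sizes <- rep.int(seq_len(14L), counts)
    return(sample(sizes, length(sizes)))
  }
  stopifnot(length(distribution) == 14L, all(distribution >= 0),
            abs(sum(distribution) - 1) < 1e-8)
  sample.int(14L, n_persons, replace = TRUE, prob = distribution)
}

#' Draw per-person latent factor scores
#'
#' Bivariate standard normal pairs `(eta_b, xi)` with correlation `r`:
#' `eta_b` is the stable between-person daily-mood factor, `xi` the
#' questionnaire depression factor.
#'
#' @param n_persons number of persons.
#' @param r latent correlation in \[-1, 1\].
#' @param seed optional integer seed.
#' @return Matrix with columns `eta_b`, `xi`.
#' @export
generate_latents <- function(n_persons, r, seed = NULL) {
  if (abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n_persons)
  z2 <- stats::rnorm(n_persons)
  cbind(eta_b = z1, xi = r * z1 + sqrt(1 - r^2) * z2)
}

#' Generate the daily-ratings table
#'
#' For person j on day i the item pair is
#' `y_ji = nu + lambda_b * eta_bj + eps_bj + lambda_w * eta_wij + eps_wij`
#' with the day factor `eta_wij ~ N(0, psi_w)` and day residuals
#' `eps_wij ~ N(0, theta_w)` drawn fresh each day, while the person
#' residual `eps_bj ~ N(0, theta_b)` is shared across a person's days. Day
#' positions are sampled uniformly without replacement from the window
#' `[anchor - window, anchor)`.
#'
#' @param latents matrix from [generate_latents()] (column `eta_b` used).
#' @param sizes integer vector of per-person rating counts (1-14).
#' @param params a `phq_params` object.
#' @param discretize round-and-clip responses to 1-5.
#' @param window_length_days,anchor_day window geometry.
#' @param person_ids optional character ids (default `p0001`...).
#' @param seed optional integer seed.
#' @return A validated long daily table.
#' @export
generate_daily_items <- function(latents, sizes, params,
                                 discretize = FALSE,
                                 window_length_days = 14L, anchor_day = 28L,
                                 person_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(latents)
  stopifnot(length(sizes) == n, all(sizes >= 1),
            all(sizes <= window_length_days))
  if (is.null(person_ids))
    person_ids <- sprintf("p%05d", seq_len(n))
  total <- sum(sizes)
  pid <- rep(person_ids, sizes)
  window <- seq.int(anchor_day - window_length_days, anchor_day - 1L)
  days <- unlist(lapply(sizes, function(k)
    sort(sample(window, k, replace = FALSE))), use.names = FALSE)
  eps_b1 <- rep(stats::rnorm(n, 0, sqrt(params$theta_b[1])), sizes)
  eps_b2 <- rep(stats::rnorm(n, 0, sqrt(params$theta_b[2])), sizes)
  eta_w <- stats::rnorm(total, 0, sqrt(params$psi_w))
  # latents are standard normal; sqrt(psi_b) scales to the configured
  # latent variance
  b_part <- params$lambda_b * sqrt(params$psi_b) * rep(latents[, "eta_b"], sizes)
  y1 <- params$nu[1] + b_part + eps_b1 +
    params$lambda_w * eta_w + stats::rnorm(total, 0, sqrt(params$theta_w[1]))
  y2 <- params$nu[2] + b_part + eps_b2 +
    params$lambda_w * eta_w + stats::rnorm(total, 0, sqrt(params$theta_w[2]))
  if (discretize) {
    y1 <- pmin(pmax(round(y1), 1), 5)
    y2 <- pmin(pmax(round(y2), 1), 5)
  }
  validate_long_daily(
    data.frame(person_id = pid, day = days, item1 = y1, item2 = y2,
               stringsAsFactors = FALSE),
    continuous = !discretize)
}

#' Generate anchor-week questionnaire item responses
#'
#' `z_j = tau + lambda_q * xi_j + delta_j`, `delta_j ~ N(0, theta_q)`.
#'
#' @param latents matrix from [generate_latents()] (column `xi` used).
#' @param params a `phq_params` object.
#' @param discretize round-and-clip items to 0-3.
#' @param seed optional integer seed.
#' @return Matrix (persons x items) of questionnaire responses.
#' @export
generate_questionnaire <- function(latents, params, discretize = FALSE,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(latents)
  p <- length(params$lambda_q)
  xi <- sqrt(params$psi_q) * latents[, "xi"]
  z <- matrix(params$tau_q, n, p, byrow = TRUE) +
    xi %o% params$lambda_q +
    matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(params$theta_q), p)
  if (discretize) z <- pmin(pmax(round(z), 0), 3)
  colnames(z) <- panel_item_cols()[seq_len(p)]
  z
}

# Mean of min(X, cap) conditional on X >= floor, X ~ N(mu, sd^2).
truncated_clipped_mean <- function(mu, sd, floor, cap) {
  a <- (floor - mu) / sd
  g <- (cap - mu) / sd
  p_tail <- stats::pnorm(a, lower.tail = FALSE)
  if (p_tail < 1e-12) return(NA_real_)
  num <- mu * (stats::pnorm(g) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(g)) +
    cap * stats::pnorm(g, lower.tail = FALSE)
  num / p_tail
}

#' Calibrate the pre-truncation mean of the baseline generator
#'
#' Finds the mean `mu0` of a normal with the given SD such that, after
#' rejecting draws below `floor` and capping at `cap`, the expected retained
#' score equals `target_mean`. Truncation from below raises the mean, so the
#' calibrated `mu0` is below `target_mean` whenever the floor binds.
#'
#' @param target_mean desired post-truncation mean.
#' @param sd pre-truncation standard deviation.
#' @param floor eligibility floor (`-Inf` for none).
#' @param cap upper clip of the score scale.
#' @return Calibrated pre-truncation mean.
#' @export
calibrate_baseline_mean <- function(target_mean, sd, floor = 5, cap = 27) {
  stopifnot(sd > 0)
  if (is.finite(floor) && floor > target_mean + 3 * sd)
    stop("infeasible baseline calibration: floor exceeds target mean + 3 sd",
         call. = FALSE)
  if (!is.finite(floor) && !is.finite(cap)) return(target_mean)
  if (is.finite(cap) && target_mean >= cap)
    stop("infeasible baseline calibration: target mean at or above the scale cap",
         call. = FALSE)
  # below floor - 6 sd the conditional mean is pinned at the floor anyway
  lo <- if (is.finite(floor)) floor - 6 * sd else target_mean - 10 * sd
  f <- function(mu) truncated_clipped_mean(mu, sd,
                                           if (is.finite(floor)) floor else -Inf,
                                           if (is.finite(cap)) cap else Inf) -
    target_mean
  stats::uniroot(f, lower = lo, upper = target_mean + 10 * sd,
                 tol = 1e-10)$root
}

#' Generate baseline questionnaire sum scores under eligibility truncation
#'
#' Draws from a normal whose pre-truncation mean is calibrated so that the
#' retained (>= floor) scores have mean `baseline_mean`; scores are clipped
#' to the 0-27 sum scale. Sampling is by inverse-CDF on the truncated
#' region, so no draws are wasted.
#'
#' @param n_persons number of scores.
#' @param baseline_mean target post-truncation mean.
#' @param baseline_sd pre-truncation SD.
#' @param eligibility_floor minimum retained score (`-Inf` for none).
#' @param seed optional integer seed.
#' @return Numeric vector of baseline sum scores.
#' @export
generate_baseline <- function(n_persons, baseline_mean = 13.9,
                              baseline_sd = 5.0, eligibility_floor = 5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu0 <- calibrate_baseline_mean(baseline_mean, baseline_sd,
                                 floor = eligibility_floor, cap = 27)
  p_lo <- if (is.finite(eligibility_floor))
    stats::pnorm(eligibility_floor, mu0, baseline_sd) else 0
  u <- stats::runif(n_persons, p_lo, 1)
  x <- stats::qnorm(u, mu0, baseline_sd)
  pmin(pmax(x, 0), 27)
}

#' Calibrate an outcome residual variance to a population R-squared
#'
#' With outcome `y = b'x + e`, `R^2 = var(b'x) / (var(b'x) + sigma^2)`, so
#' `sigma^2 = var(b'x) (1 - R^2) / R^2`.
#'
#' @param explained_var population variance of the linear predictor.
#' @param r2 target population R-squared in (0, 1).
#' @return Residual variance.
#' @export
calibrate_outcome_variance <- function(explained_var, r2) {
  stopifnot(explained_var > 0, r2 > 0, r2 < 1)
  explained_var * (1 - r2) / r2
}

#' Generate week-8 outcome scores
#'
#' Joint linear outcome model for the two follow-up scores: each outcome is
#' `b0 + b1 * anchor_sum + b2 * daily_mean + e`, with the two equations'
#' errors drawn jointly from a bivariate normal with the configured residual
#' covariance. Optional MCAR deletion removes a fraction of persons' week-8
#' rows entirely.
#'
#' @param anchor_sum anchor-week questionnaire sum per person.
#' @param daily_mean per-person mean of the daily composite.
#' @param beta_phq,beta_sds coefficient triples (intercept, anchor sum,
#'   daily mean).
#' @param sigma_phq,sigma_sds residual SDs.
#' @param resid_cor residual correlation between equations.
#' @param missing_week8 MCAR missingness probability.
#' @param seed optional integer seed.
#' @return Data frame with columns `phq9_wk8`, `sds_wk8`, `observed`.
#' @export
generate_outcomes <- function(anchor_sum, daily_mean,
                              beta_phq, beta_sds,
                              sigma_phq, sigma_sds, resid_cor = 0.3,
                              missing_week8 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(anchor_sum)
  stopifnot(length(daily_mean) == n, sigma_phq > 0, sigma_sds > 0,
            abs(resid_cor) < 1)
  e1 <- stats::rnorm(n)
  e2 <- resid_cor * e1 + sqrt(1 - resid_cor^2) * stats::rnorm(n)
  X <- cbind(1, anchor_sum, daily_mean)
  data.frame(
    phq9_wk8 = drop(X %*% beta_phq) + sigma_phq * e1,
    sds_wk8 = drop(X %*% beta_sds) + sigma_sds * e2,
    observed = stats::runif(n) >= missing_week8)
}

#' Generate a full synthetic cohort
#'
#' Runs every generator stage under a single seed: cluster sizes, latent
#' factors, daily items, anchor-week questionnaire, baseline sums, group
#' labels and week-8 outcomes. Group labels are independent Bernoulli
#' draws; optional `group_offsets` in the config shift measurement
#' parameters for the second level of one grouping variable, which breaks
#' measurement invariance for that split.
#'
#' @param cfg a `phq_gen_config`.
#' @param seed integer seed; the cohort is a deterministic function of
#'   (cfg, seed).
#' @return List with `daily` (long daily table), `panel` (weeks 0, anchor
#'   and outcome), and `truth` (per-person latent values and generating
#'   summaries kept for recovery tests).
#' @export
generate_cohort <- function(cfg = generator_config(), seed = 1L) {
  set.seed(seed)
  n <- cfg$n_persons
  params <- cfg$params
  person_ids <- sprintf("p%05d", seq_len(n))
  anchor_day <- 7L * cfg$anchor_week

  gender <- ifelse(stats::runif(n) < cfg$prop_woman, "woman", "man")
  age_band <- ifelse(stats::runif(n) < cfg$prop_55plus, "55+", "<55")
  minority <- ifelse(stats::runif(n) < cfg$prop_minority, "yes", "no")
  labels <- data.frame(gender = gender, age_band = age_band,
                       minority = minority, stringsAsFactors = FALSE)

  sizes <- sample_cluster_sizes(n, cfg$cluster_sizes)
  latents <- generate_latents(n, params$r)

  # Per-person parameter shift for non-invariant groups: generate the
  # shifted persons from an offset parameter set.
  offset_of <- function(var) {
    off <- cfg$group_offsets[[var]]
    if (is.null(off)) NULL else off
  }
  second_level <- c(gender = "woman", age_band = "55+", minority = "yes")
  shifted <- rep(FALSE, n)
  params2 <- params
  for (var in names(cfg$group_offsets)) {
    off <- offset_of(var)
    sel <- labels[[var]] == second_level[[var]]
    shifted <- shifted | sel
    for (nm in names(off)) params2[[nm]] <- params2[[nm]] + off[[nm]]
  }
  params2 <- do.call(parameter_set, params2[c(
    "lambda_q", "tau_q", "theta_q", "lambda_b", "nu", "theta_b",
    "lambda_w", "theta_w", "r", "psi_q", "psi_b", "psi_w")])

  gen_block <- function(sel, par) {
    idx <- which(sel)
    list(daily = generate_daily_items(
           latents[idx, , drop = FALSE], sizes[idx], par,
           discretize = cfg$discretize,
           window_length_days = cfg$window_length_days,
           anchor_day = anchor_day, person_ids = person_ids[idx]),
         z = generate_questionnaire(latents[idx, , drop = FALSE], par,
                                    discretize = cfg$discretize))
  }
  if (any(shifted)) {
    b1 <- gen_block(!shifted, params)
    b2 <- gen_block(shifted, params2)
    daily <- validate_long_daily(rbind(b1$daily, b2$daily),
                                 continuous = !cfg$discretize)
    z <- matrix(NA_real_, n, length(params$lambda_q),
                dimnames = list(NULL, colnames(b1$z)))
    z[!shifted, ] <- b1$z
    z[shifted, ] <- b2$z
  } else {
    b <- gen_block(rep(TRUE, n), params)
    daily <- b$daily
    z <- b$z
  }

  phq9_sum4 <- rowSums(z)
  baseline <- generate_baseline(n, cfg$baseline_mean, cfg$baseline_sd,
                                cfg$eligibility_floor)

  # daily composite mean per person (mean over days of the two-item mean)
  comp <- (daily$item1 + daily$item2) / 2
  daily_mean <- tapply(comp, factor(daily$person_id, levels = person_ids),
                       mean)
  sigma_phq <- cfg$sigma_phq
  sigma_sds <- cfg$sigma_sds
  vx <- implied_sum_variance(params)
  if (!is.na(cfg$r2_phq))
    sigma_phq <- sqrt(calibrate_outcome_variance(cfg$beta_phq[2]^2 * vx,
                                                 cfg$r2_phq))
  if (!is.na(cfg$r2_sds))
    sigma_sds <- sqrt(calibrate_outcome_variance(cfg$beta_sds[2]^2 * vx,
                                                 cfg$r2_sds))
  out <- generate_outcomes(phq9_sum4, as.numeric(daily_mean),
                           cfg$beta_phq, cfg$beta_sds,
                           sigma_phq, sigma_sds, cfg$resid_cor,
                           cfg$missing_week8)
  if (cfg$discretize) {
    out$phq9_wk8 <- pmin(pmax(round(out$phq9_wk8), 0), 27)
    out$sds_wk8 <- pmin(pmax(round(out$sds_wk8), 0), 30)
  }

  p <- length(params$lambda_q)
  item_na <- matrix(NA_real_, n, p, dimnames = list(NULL, panel_item_cols()[seq_len(p)]))
  row_block <- function(week, items, phq9_sum, sds_sum) {
    cbind(data.frame(person_id = person_ids, week = week,
                     stringsAsFactors = FALSE),
          as.data.frame(items),
          data.frame(phq9_sum = phq9_sum, sds_sum = sds_sum),
          labels)
  }
  panel <- rbind(
    row_block(0L, item_na, baseline, NA_real_),
    row_block(cfg$anchor_week, z, phq9_sum4, NA_real_),
    row_block(cfg$outcome_week, item_na,
              ifelse(out$observed, out$phq9_wk8, NA_real_),
              ifelse(out$observed, out$sds_wk8, NA_real_)))
  panel <- validate_panel(panel, continuous = TRUE)

  truth <- data.frame(person_id = person_ids,
                      eta_b = latents[, "eta_b"], xi = latents[, "xi"],
                      n_ratings = sizes, daily_mean = as.numeric(daily_mean),
                      shifted_group = shifted,
                      stringsAsFactors = FALSE)
  list(daily = daily, panel = panel, truth = truth,
       sigma_phq = sigma_phq, sigma_sds = sigma_sds)
}
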