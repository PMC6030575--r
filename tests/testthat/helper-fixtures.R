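# Small cohorts and hand-written tables used across test files.

# desk-scale generator config: modest cohort, short clusters, optional
# reduced questionnaire roster for fast model fits
small_gen_config <- function(n_persons = 150L, n_items = 9L,
                             max_days = 5L, r = 0.8,
                             missing_week8 = 0.35, ...) {
  params <- default_measurement_params()
  if (n_items < 9L) {
    params <- parameter_set(
      lambda_q = params$lambda_q[seq_len(n_items)],
      tau_q = params$tau_q[seq_len(n_items)],
      theta_q = params$theta_q[seq_len(n_items)],
      lambda_b = params$lambda_b, nu = params$nu,
      theta_b = params$theta_b, lambda_w = params$lambda_w,
      theta_w = params$theta_w, r = r)
  } else {
    params$r <- r
  }
  probs <- c(rep(1 / max_days, max_days), rep(0, 14L - max_days))
  generator_config(n_persons = n_persons, cluster_sizes = probs,
                   params = params, missing_week8 = missing_week8, ...)
}

filtered_cohort <- function(seed, cfg = small_gen_config()) {
  coh <- generate_cohort(cfg, seed = seed)
  flt <- apply_sample_filters(coh$daily, coh$panel)
  flt$truth <- coh$truth
  flt
}

# minimal hand-written daily CSV
write_tiny_daily_csv <- function(path,
                                 lines = c("person_id,day,item1,item2",
                                           "a,14,1,2", "a,15,3,3",
                                           "a,16,5,4")) {
  writeLines(lines, path)
  path
}
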