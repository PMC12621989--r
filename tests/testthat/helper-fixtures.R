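# Shared fixtures: small bilateral tables and truths built in code.

make_bilateral_df <- function() {
  data.frame(
    subject_id = rep(c("s1", "s2"), each = 4),
    cohort_id = "c1",
    age = rep(c(30, 40), each = 4),
    sex = rep(c("female", "male"), each = 4),
    tract = rep(c("AF", "AF", "CST", "CST"), 2),
    hemisphere = rep(c("left", "right"), 4),
    feature = "FA",
    value = c(0.48, 0.46, 0.50, 0.52, 0.44, 0.47, 0.55, 0.55)
  )
}

write_tmp_table <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  data.table::fwrite(df, path, sep = sep)
  path
}

# Central-difference gradient, independent of the analytic path.
numDeriv_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# A quick homoscedastic linear truth for fitter tests.
linear_truth <- function(n = 2000, seed = 7001, sigma = 0.04, sex_mu = 0,
                         n_cohorts = 1) {
  synthetic_truth(
    mu_fp = 1, mu_coef = c(-0.03, 0.006),
    sigma_fp = 1, sigma_coef = c(log(sigma), 0),
    sex_effect_mu = sex_mu,
    cohort_sd_mu = if (n_cohorts > 1) 0.01 else 0,
    cohort_sd_sigma = if (n_cohorts > 1) 0.05 else 0,
    n_cohorts = n_cohorts, n_subjects = n, seed = seed
  )
}
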