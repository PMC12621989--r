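# Synthetic multi-cohort lifespan cohorts with known ground truth.
# The generator inverts the normative model: LI ~ N(mu(age, sex, cohort),
# sigma(age, sex, cohort)) with FP smooths for mu and log sigma, so every
# downstream stage can be scored against the generating truth.

#' Define a synthetic ground truth
#'
#' Specifies the generating location-scale model for a synthetic lifespan
#' cohort: FP smooths with coefficients for the mean and for
#' `log(sigma)`, sex effects, cohort-offset SDs, cohort structure, sample
#' size, age range and sex mix. The default female fraction (0.444)
#' matches the sex mix of large multi-site lifespan consortia.
#'
#' @param mu_fp,sigma_fp [fp_spec()] (or power vectors) for the mean and
#'   log-scale age smooths.
#' @param mu_coef Coefficients for the mean: intercept then one per FP
#'   term of `mu_fp`.
#' @param sigma_coef Coefficients for `log(sigma)`: intercept then one
#'   per FP term of `sigma_fp`.
#' @param sex_effect_mu,sex_effect_sigma Additive male effect on the mean
#'   and on `log(sigma)` (female = 0, male = 1).
#' @param cohort_sd_mu,cohort_sd_sigma SDs of the centered per-cohort
#'   offsets on the mean and on `log(sigma)`.
#' @param n_cohorts,n_subjects Cohort count and total sample size.
#' @param age_range Length-2 ages in years; subjects are drawn uniformly.
#' @param female_fraction Probability a subject is female.
#' @param seed Integer RNG seed; everything is reproducible from it.
#' @param transform [age_transform()] under which the FP smooths are
#'   evaluated.
#' @param tract,feature Labels stamped on generated tables.
#' @return An object of class `wmasym_truth`.
#' @export
synthetic_truth <- function(mu_fp, mu_coef, sigma_fp, sigma_coef,
                            sex_effect_mu = 0, sex_effect_sigma = 0,
                            cohort_sd_mu = 0, cohort_sd_sigma = 0,
                            n_cohorts = 1, n_subjects = 1000,
                            age_range = c(0, 100), female_fraction = 0.444,
                            seed = 20260101, transform = age_transform(),
                            tract = "AF", feature = "FA") {
  if (!inherits(mu_fp, "fp_spec")) mu_fp <- fp_spec(mu_fp)
  if (!inherits(sigma_fp, "fp_spec")) sigma_fp <- fp_spec(sigma_fp)
  if (female_fraction < 0 || female_fraction > 1) {
    stop_wmasym("female_fraction must be in [0, 1]", "wmasym_validation_error")
  }
  if (length(age_range) != 2 || age_range[1] > age_range[2] || age_range[1] < 0) {
    stop_wmasym("invalid age_range", "wmasym_validation_error")
  }
  truth <- structure(
    list(mu_fp = mu_fp, mu_coef = as.numeric(mu_coef),
         sigma_fp = sigma_fp, sigma_coef = as.numeric(sigma_coef),
         sex_effect_mu = sex_effect_mu, sex_effect_sigma = sex_effect_sigma,
         cohort_sd_mu = cohort_sd_mu, cohort_sd_sigma = cohort_sd_sigma,
         n_cohorts = as.integer(n_cohorts), n_subjects = as.integer(n_subjects),
         age_range = as.numeric(age_range), female_fraction = female_fraction,
         seed = as.integer(seed), transform = transform,
         tract = tract, feature = feature),
    class = "wmasym_truth"
  )
  if (length(truth$mu_coef) != 1 + fp_n_terms(mu_fp) ||
      length(truth$sigma_coef) != 1 + fp_n_terms(sigma_fp)) {
    stop_wmasym("coefficient length must be 1 + number of FP terms",
                "wmasym_validation_error")
  }
  # the log link guarantees sigma > 0; still guard against blow-ups
  grid <- seq(age_range[1], age_range[2], length.out = 201)
  sg <- truth_sigma(truth, grid, male = 0.5)
  if (any(!is.finite(sg)) || any(sg <= 0)) {
    stop_wmasym("implied sigma is not positive and finite over age_range",
                "wmasym_validation_error")
  }
  truth
}

fp_n_terms <- function(spec) if (length(unclass(spec)) == 1) 1L else 2L

truth_mu <- function(truth, age, male, offset = 0) {
  X <- cbind(1, fp_terms(age_to_t(age, truth$transform), truth$mu_fp))
  drop(X %*% truth$mu_coef) + truth$sex_effect_mu * male + offset
}

truth_sigma <- function(truth, age, male, offset = 0) {
  X <- cbind(1, fp_terms(age_to_t(age, truth$transform), truth$sigma_fp))
  exp(drop(X %*% truth$sigma_coef) + truth$sex_effect_sigma * male + offset)
}

#' True population median trajectory of a synthetic truth
#'
#' @param truth A `wmasym_truth`.
#' @param ages Ages in years.
#' @param sex_mode `"pooled"` (equal-weight sex average), `"female"` or
#'   `"male"`.
#' @return Data frame with `age` and `value` (cohort offsets zeroed).
#' @export
true_median <- function(truth, ages, sex_mode = "pooled") {
  male <- switch(sex_mode, pooled = 0.5, female = 0, male = 1,
                 stop_wmasym("unknown sex_mode", "wmasym_validation_error"))
  data.frame(age = ages, value = truth_mu(truth, ages, male))
}

# Offsets are drawn on their own derived seed so that subsetting or
# re-drawing subjects never shifts the cohort configuration.
draw_cohort_offsets <- function(truth) {
  K <- truth$n_cohorts
  if (K <= 1) {
    return(list(u_mu = numeric(0), u_sigma = numeric(0)))
  }
  off_seed <- (truth$seed + 1000003L) %% .Machine$integer.max
  with_seed(off_seed, {
    um <- rnorm(K, 0, truth$cohort_sd_mu)
    us <- rnorm(K, 0, truth$cohort_sd_sigma)
    um <- um - mean(um)   # re-centered: population curve is the average
    us <- us - mean(us)
    list(u_mu = setNames(um, cohort_ids(K)), u_sigma = setNames(us, cohort_ids(K)))
  })
}

cohort_ids <- function(K) sprintf("C%02d", seq_len(K))

#' Simulate a laterality modeling table from a known truth
#'
#' Ages are uniform over the truth's range, sex is Bernoulli with the
#' stated female fraction, cohort assignment cycles so cohorts are
#' balanced, cohort offsets are drawn once (centered to sum to zero), and
#' `LI ~ N(mu, sigma)` from the generating model. Fully reproducible from
#' the truth's seed.
#'
#' @param truth A [synthetic_truth()].
#' @return Data frame in the modeling-table layout of [build_li_table()]
#'   with attributes `truth` and `cohort_offsets`.
#' @export
simulate_li_table <- function(truth) {
  stopifnot(inherits(truth, "wmasym_truth"))
  n <- truth$n_subjects
  off <- draw_cohort_offsets(truth)
  K <- truth$n_cohorts
  cohort_idx <- rep_len(seq_len(K), n)
  with_seed(truth$seed, {
    age <- runif(n, truth$age_range[1], truth$age_range[2])
    male <- rbinom(n, 1, 1 - truth$female_fraction)
    o_mu <- if (K > 1) off$u_mu[cohort_idx] else 0
    o_sg <- if (K > 1) off$u_sigma[cohort_idx] else 0
    mu <- truth_mu(truth, age, male, o_mu)
    sg <- truth_sigma(truth, age, male, o_sg)
    li <- rnorm(n, mu, sg)
    out <- data.frame(
      subject_id = sprintf("S%06d", seq_len(n)),
      cohort_id = cohort_ids(K)[cohort_idx],
      age = age,
      sex = ifelse(male == 1, "male", "female"),
      tract = truth$tract, feature = truth$feature,
      li = li
    )
    attr(out, "truth") <- truth
    attr(out, "cohort_offsets") <- off
    out
  })
}

#' Simulate a bilateral feature table from a known truth
#'
#' Inverts the laterality index: with drawn asymmetry `l` and a positive
#' base feature trajectory `B(age)`, the hemispheric values are
#' `R = B * (1 + l)` and `L = B * (1 - l)`, so [build_li_table()] on the
#' output reproduces `l` exactly. Draws with `|l| >= 0.999` are truncated
#' to keep both hemispheres positive (count logged).
#'
#' @param truth A [synthetic_truth()].
#' @param base_feature_curve Function of age returning the positive base
#'   feature value `B(age)`; default constant 1.
#' @return Data frame of bilateral records (two rows per subject), as
#'   consumed by [build_li_table()] / written by [write_bilateral_table()].
#' @export
simulate_bilateral_table <- function(truth, base_feature_curve = function(age) rep(1, length(age))) {
  li_tab <- simulate_li_table(truth)
  B <- base_feature_curve(li_tab$age)
  if (any(!is.finite(B)) || any(B <= 0)) {
    stop_wmasym("base feature curve must be positive and finite",
                "wmasym_validation_error")
  }
  l <- li_tab$li
  n_trunc <- sum(abs(l) > 0.999)
  if (n_trunc > 0) {
    message("simulate_bilateral_table: truncated ", n_trunc, " draws at |LI| = 0.999")
    l <- pmax(pmin(l, 0.999), -0.999)
  }
  long <- rbind(
    data.frame(li_tab[c("subject_id", "cohort_id", "age", "sex", "tract", "feature")],
               hemisphere = "left", value = B * (1 - l)),
    data.frame(li_tab[c("subject_id", "cohort_id", "age", "sex", "tract", "feature")],
               hemisphere = "right", value = B * (1 + l))
  )
  long <- long[order(long$subject_id, long$hemisphere), ]
  rownames(long) <- NULL
  attr(long, "truth") <- truth
  long
}

#' Named synthetic scenarios
#'
#' A small catalog exercising the phenomena the charts must capture:
#' \describe{
#'   \item{flat_symmetric}{No asymmetry, constant spread (0.05); the null
#'     reference.}
#'   \item{linear_drift}{Median drifts linearly with transformed age from
#'     leftward to rightward; mild sex effect; 3 cohorts.}
#'   \item{log_growth_reversal}{Median grows logarithmically and crosses
#'     zero at exactly age 30 (leftward to rightward) - the root is
#'     placed analytically.}
#'   \item{heteroscedastic_u_shape}{Strongly nonlinear median (log +
#'     linear FP terms) with a U-shaped spread, wider in early childhood
#'     and old age; 3 cohorts.}
#'   \item{multi_cohort_shift}{6 cohorts with clearly separated offsets
#'     on both the mean and the spread.}
#' }
#'
#' @param name Scenario name (see above).
#' @param n_subjects,seed Optional overrides of the catalog values.
#' @return A [synthetic_truth()].
#' @export
scenario <- function(name, n_subjects = NULL, seed = NULL) {
  truth <- switch(
    name,
    flat_symmetric = synthetic_truth(
      mu_fp = 1, mu_coef = c(0, 0),
      sigma_fp = 1, sigma_coef = c(log(0.05), 0),
      n_cohorts = 1, n_subjects = 10000, seed = 48103
    ),
    linear_drift = synthetic_truth(
      mu_fp = 1, mu_coef = c(-0.035, 0.005),
      sigma_fp = 1, sigma_coef = c(log(0.04), 0),
      sex_effect_mu = 0.002,
      cohort_sd_mu = 0.005, cohort_sd_sigma = 0.02,
      n_cohorts = 3, n_subjects = 10000, seed = 48104
    ),
    log_growth_reversal = synthetic_truth(
      # mu = b * (log t - log t30) with t30 = t(30): root exactly at 30 y
      mu_fp = 0, mu_coef = c(-0.04 * log(3.1), 0.04),
      sigma_fp = 1, sigma_coef = c(log(0.04), 0),
      n_cohorts = 1, n_subjects = 10000, seed = 48105
    ),
    heteroscedastic_u_shape = synthetic_truth(
      mu_fp = c(0, 1), mu_coef = c(-0.02, 0.08, -0.02),
      sigma_fp = c(1, 2), sigma_coef = c(-3.4, -0.2, 0.02),
      sex_effect_mu = 0.002,
      cohort_sd_mu = 0.004, cohort_sd_sigma = 0.05,
      n_cohorts = 3, n_subjects = 10000, seed = 48106
    ),
    multi_cohort_shift = synthetic_truth(
      mu_fp = 1, mu_coef = c(-0.02, 0.003),
      sigma_fp = 1, sigma_coef = c(log(0.05), 0),
      cohort_sd_mu = 0.01, cohort_sd_sigma = 0.1,
      n_cohorts = 6, n_subjects = 12000, seed = 48107
    ),
    stop_wmasym(paste0("unknown scenario '", name, "'"), "wmasym_lookup_error")
  )
  if (!is.null(n_subjects)) truth$n_subjects <- as.integer(n_subjects)
  if (!is.null(seed)) truth$seed <- as.integer(seed)
  truth
}

#' @rdname scenario
#' @export
scenario_names <- function() {
  c("flat_symmetric", "linear_drift", "log_growth_reversal",
    "heteroscedastic_u_shape", "multi_cohort_shift")
}

#' Assemble a fit object directly from known parameters
#'
#' Builds a `wmasym_fit` from a [synthetic_truth()] (or from published
#' coefficients wrapped in one) without estimation - useful for
#' calibration checks against a known distribution and for rebuilding
#' charts from archived coefficients. Cohort offsets are the truth's
#' deterministically drawn offsets; likelihood fields are `NA`.
#'
#' @param truth A `wmasym_truth`.
#' @return A `wmasym_fit`.
#' @export
fit_from_truth <- function(truth) {
  stopifnot(inherits(truth, "wmasym_truth"))
  off <- draw_cohort_offsets(truth)
  beta_mu <- c(truth$mu_coef, truth$sex_effect_mu)
  beta_sg <- c(truth$sigma_coef, truth$sex_effect_sigma)
  names(beta_mu) <- c("(Intercept)", colnames(fp_terms(1, truth$mu_fp)), "sexmale")
  names(beta_sg) <- c("(Intercept)", colnames(fp_terms(1, truth$sigma_fp)), "sexmale")
  structure(
    list(
      spec = model_spec(truth$mu_fp, truth$sigma_fp, include_sex = TRUE,
                        transform = truth$transform),
      beta_mu = beta_mu, beta_sigma = beta_sg,
      u_mu = off$u_mu, u_sigma = off$u_sigma,
      loglik = NA_real_, n_params = length(beta_mu) + length(beta_sg) +
        2L * max(truth$n_cohorts - 1L, 0L),
      n_obs = truth$n_subjects, bic = NA_real_,
      converged = TRUE, grad_norm = 0, near_sigma_floor = FALSE,
      age_range = truth$age_range,
      tract = truth$tract, feature = truth$feature
    ),
    class = "wmasym_fit"
  )
}
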