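const_fit <- function(mu, sigma, sex_mu = 0) {
  fit_from_truth(synthetic_truth(
    mu_fp = 1, mu_coef = c(mu, 0), sigma_fp = 1, sigma_coef = c(log(sigma), 0),
    sex_effect_mu = sex_mu, n_subjects = 100, seed = 5
  ))
}

test_that("rightward prevalence matches the normal tail probability", {
  expect_equal(prevalence_rightward(const_fit(0, 0.03), 30), 0.5)
  # 1 - Phi(2/3) for mu = -0.02, sigma = 0.03
  p <- prevalence_rightward(const_fit(-0.02, 0.03), 30)
  expect_equal(p, pnorm(-0.02 / 0.03))
  expect_equal(p, 0.2524925, tolerance = 1e-6)
  # reflection symmetry
  expect_equal(prevalence_rightward(const_fit(0.02, 0.03), 30), 1 - p)
})

test_that("prevalence is increasing in mu and anchored at one half", {
  mus <- seq(-0.05, 0.05, by = 0.01)
  ps <- vapply(mus, function(m) prevalence_rightward(const_fit(m, 0.04), 50), 0)
  expect_true(all(diff(ps) > 0))
  expect_equal(ps[mus == 0], 0.5)
})

test_that("milestone summary reports median and percent-right consistently", {
  fit <- const_fit(0, 0.05)
  mil <- milestone_summary(fit)
  expect_equal(nrow(mil), 4)
  expect_equal(mil$age, c(3, 12, 30, 50))
  expect_equal(mil$median_li, rep(0, 4))
  expect_equal(mil$pct_right, rep(50, 4))
  # sign agreement between median and prevalence
  fit2 <- fit_from_truth(scenario("heteroscedastic_u_shape"))
  mil2 <- milestone_summary(fit2)
  expect_true(all(sign(mil2$median_li) == sign(mil2$pct_right - 50)))
  # milestones outside support are skipped with a warning
  fit3 <- const_fit(0, 0.05); fit3$age_range <- c(5, 45)
  expect_warning(mil3 <- milestone_summary(fit3), "outside")
  expect_equal(mil3$age, c(12, 30))
})

test_that("reversal detection interpolates the crossing age", {
  cur <- data.frame(age = c(29, 31), value = c(-0.005, 0.005))
  ev <- detect_reversals(cur)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$age_at_crossing, 30)
  expect_equal(ev$direction, "left_to_right")
  # asymmetric magnitudes move the interpolated root
  cur2 <- data.frame(age = c(0, 1), value = c(-0.03, 0.01))
  expect_equal(detect_reversals(cur2)$age_at_crossing, 0.75)
})

test_that("reversal detection handles no-crossing, exact zeros and multiples", {
  ages <- seq(0, 100, by = 0.25)
  expect_equal(nrow(detect_reversals(data.frame(age = ages, value = ages + 1))), 0)
  # sine-like curve with two crossings, found by brute-force sign scan
  v <- 0.02 * sin((ages - 20.1) / 18)
  ev <- detect_reversals(data.frame(age = ages, value = v))
  brute <- which(v[-1] * v[-length(v)] < 0)
  expect_equal(nrow(ev), length(brute))
  expect_true(all(abs(ev$age_at_crossing - ages[brute]) <= 0.25))
  expect_equal(ev$direction, c("left_to_right", "right_to_left"))
  # mirrored curve: same ages, flipped directions
  ev2 <- detect_reversals(data.frame(age = ages, value = -v))
  expect_equal(ev2$age_at_crossing, ev$age_at_crossing)
  expect_equal(ev2$direction,
               ifelse(ev$direction == "left_to_right", "right_to_left", "left_to_right"))
  # exact zero at a grid point attaches to the following sign change
  cur0 <- data.frame(age = c(10, 11, 12), value = c(-0.01, 0, 0.01))
  ev0 <- detect_reversals(cur0)
  expect_equal(ev0$age_at_crossing, 11)
  expect_equal(ev0$direction, "left_to_right")
  # epsilon suppresses numerically trivial wiggles
  tiny <- data.frame(age = 1:10, value = c(rep(-1e-6, 5), rep(1e-6, 5)))
  expect_equal(nrow(detect_reversals(tiny, epsilon = 1e-5)), 0)
})

test_that("window slope equals the endpoint identity on dense grids", {
  ages <- seq(0, 100, by = 0.25)
  m <- -0.002 * ages
  cur <- data.frame(age = ages, value = m)
  expect_equal(window_slope(cur, c(2, 12)), 0.002)     # |m| increasing
  expect_equal(window_slope(data.frame(age = ages, value = rep(0.01, length(ages))),
                            c(20, 40)), 0)
  # sign-crossing curve still matches (|m(b)| - |m(a)|)/(b - a)
  v <- 0.01 * (ages - 30)
  cur2 <- data.frame(age = ages, value = v)
  for (w in list(c(2, 12), c(12, 20), c(20, 40), c(40, 100))) {
    expect_equal(window_slope(cur2, w),
                 (abs(v[ages == w[2]]) - abs(v[ages == w[1]])) / (w[2] - w[1]),
                 tolerance = 1e-6)
  }
  expect_error(window_slope(cur, c(12, 2)), class = "wmasym_validation_error")
  expect_error(window_slope(cur, c(90, 120)), class = "wmasym_validation_error")
})

test_that("grid refinement converges to the endpoint identity", {
  f <- function(a) 0.03 * sin(a / 15)
  for (step in c(1, 0.5, 0.25)) {
    ages <- seq(0, 100, by = step)
    cur <- data.frame(age = ages, value = f(ages))
    expect_equal(window_slope(cur, c(20, 40)),
                 (abs(f(40)) - abs(f(20))) / 20, tolerance = 1e-9)
  }
})

test_that("lifespan slopes cover the four windows with directions", {
  fit <- fit_from_truth(scenario("log_growth_reversal"))
  sl <- lifespan_slopes(fit)
  expect_equal(nrow(sl), 4)
  expect_equal(sl$window, c("2-12", "12-20", "20-40", "40-100"))
  expect_true(all(sl$direction %in% c("strengthening", "attenuating", "neutral")))
  # |median| of the log-growth curve decreases before 30, increases after
  expect_equal(sl$direction[1], "attenuating")
  expect_equal(sl$direction[4], "strengthening")
  # zero fit: all slopes zero, neutral
  sl0 <- lifespan_slopes(const_fit(0, 0.05))
  expect_equal(sl0$mean_abs_slope, rep(0, 4))
  expect_equal(sl0$direction, rep("neutral", 4))
  # support clipping warns
  fitc <- const_fit(0.01, 0.05); fitc$age_range <- c(5, 60)
  w <- capture_warnings(slc <- lifespan_slopes(fitc))
  expect_true(all(grepl("clipped", w)) && length(w) >= 2)
  expect_equal(nrow(slc), 4)
})
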