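# Derived lifespan summaries: milestone asymmetry, rightward prevalence,
# lateralization reversals (median zero-crossings), age-window slopes.

default_milestones <- c(3, 12, 30, 50)
default_windows <- list(c(2, 12), c(12, 20), c(20, 40), c(40, 100))

as_median_curve <- function(curve) {
  if (inherits(curve, "wmasym_chart")) {
    med <- which.min(abs(curve$levels - 0.5))
    if (abs(curve$levels[med] - 0.5) > 1e-9) {
      stop_wmasym("chart has no 0.5 level", "wmasym_validation_error")
    }
    return(data.frame(age = curve$ages, value = curve$values[, med]))
  }
  if (!all(c("age", "value") %in% names(curve))) {
    stop_wmasym("median curve needs `age` and `value` columns",
                "wmasym_format_error")
  }
  curve[order(curve$age), c("age", "value")]
}

#' Model-based probability of rightward lateralization
#'
#' `P(LI > 0)` at a given age under the fitted Gaussian: `Phi(mu/sigma)`.
#' Pooled mode averages the two sex-specific probabilities with equal
#' weight. Exactly 0.5 when `mu = 0`, strictly increasing in `mu`.
#'
#' @param fit A `wmasym_fit`.
#' @param age Ages in years (vectorized), within the fitted support.
#' @param sex_mode `"pooled"`, `"female"` or `"male"`.
#' @return Probabilities in (0, 1).
#' @export
prevalence_rightward <- function(fit, age, sex_mode = "pooled") {
  stopifnot(inherits(fit, "wmasym_fit"))
  one <- function(sex) {
    p <- predict_mu_sigma(fit, age, sex)
    pnorm(p$mu / p$sigma)
  }
  if (identical(sex_mode, "pooled")) {
    (one("female") + one("male")) / 2
  } else {
    one(sex_mode)
  }
}

#' Asymmetry summary at milestone ages
#'
#' Population median LI and percent right-lateralized at representative
#' lifespan milestones (defaults: 3, 12, 30 and 50 years). Milestones
#' outside the fitted age support are skipped with a warning.
#'
#' @param fit A `wmasym_fit`.
#' @param ages Milestone ages in years.
#' @param sex_mode `"pooled"`, `"female"` or `"male"`.
#' @return Data frame with columns `tract`, `feature`, `age`,
#'   `median_li`, `pct_right`.
#' @export
milestone_summary <- function(fit, ages = default_milestones, sex_mode = "pooled") {
  stopifnot(inherits(fit, "wmasym_fit"))
  inside <- ages >= fit$age_range[1] & ages <= fit$age_range[2]
  if (any(!inside)) {
    warning("milestone ages outside fitted support skipped: ",
            paste(ages[!inside], collapse = ", "))
    ages <- ages[inside]
  }
  p <- pred_by_sex_mode(fit, ages, sex_mode)
  data.frame(
    tract = fit$tract, feature = fit$feature, age = ages,
    median_li = p$mu,
    pct_right = 100 * prevalence_rightward(fit, ages, sex_mode)
  )
}

#' Detect lateralization reversals (zero-crossings of the median)
#'
#' Scans a dense median LI trajectory for sign changes. Each adjacent
#' grid pair with strictly opposite signs yields one event at the
#' linearly interpolated crossing age; an exact zero at a grid point is
#' attached to the following sign change and reported at the zero's age.
#' Values with `|value| <= epsilon` are treated as zero, letting users
#' suppress numerically trivial crossings (default `epsilon = 0`: none).
#'
#' @param curve A `wmasym_chart` or a data frame with `age`, `value`
#'   (grid step at most 0.5 years recommended).
#' @param epsilon Nonnegative magnitude below which values count as zero.
#' @return Data frame with columns `age_at_crossing` and `direction`
#'   (`"left_to_right"` or `"right_to_left"`), empty if no crossing.
#' @examples
#' cur <- data.frame(age = c(29, 31), value = c(-0.005, 0.005))
#' detect_reversals(cur)  # one left_to_right event at age 30
#' @export
detect_reversals <- function(curve, epsilon = 0) {
  cur <- as_median_curve(curve)
  v <- cur$value; a <- cur$age
  s <- sign(v)
  s[abs(v) <= epsilon] <- 0
  nz <- which(s != 0)
  out <- list()
  if (length(nz) >= 2) {
    for (k in seq_len(length(nz) - 1L)) {
      i <- nz[k]; j <- nz[k + 1L]
      if (s[i] * s[j] < 0) {
        if (j == i + 1L) {
          # strict sign flip between adjacent grid points: interpolate
          x0 <- a[i] + (a[j] - a[i]) * abs(v[i]) / (abs(v[i]) + abs(v[j]))
        } else {
          # zeros in between: the crossing sits at the zero run
          x0 <- mean(a[(i + 1L):(j - 1L)])
        }
        out[[length(out) + 1L]] <- data.frame(
          age_at_crossing = x0,
          direction = if (s[i] < 0) "left_to_right" else "right_to_left"
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(age_at_crossing = numeric(0), direction = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$age_at_crossing), , drop = FALSE]
}

#' Mean slope of the absolute median LI over an age window
#'
#' The mean finite-difference derivative of `|median LI|` across the grid
#' points inside `[a, b]`. On a uniform grid the sum telescopes, so the
#' estimate equals `(|m(b)| - |m(a)|) / (b - a)` to grid accuracy.
#' Positive values mean the magnitude of asymmetry is increasing
#' (strengthening), negative decreasing (attenuating).
#'
#' @param curve A `wmasym_chart` or data frame with `age`, `value`.
#' @param window Length-2 numeric `(a, b)`, `a < b`, within the grid.
#' @return Slope in LI units per year.
#' @export
window_slope <- function(curve, window) {
  cur <- as_median_curve(curve)
  if (length(window) != 2 || window[1] >= window[2]) {
    stop_wmasym("window must be (a, b) with a < b", "wmasym_validation_error")
  }
  eps <- 1e-9
  if (window[1] < min(cur$age) - eps || window[2] > max(cur$age) + eps) {
    stop_wmasym("window outside the curve's age support", "wmasym_validation_error")
  }
  keep <- cur$age >= window[1] - eps & cur$age <= window[2] + eps
  a <- cur$age[keep]; v <- abs(cur$value[keep])
  if (length(a) < 2) {
    stop_wmasym("window contains fewer than 2 grid points", "wmasym_validation_error")
  }
  mean(diff(v) / diff(a))
}

#' Age-window slopes of the absolute median LI
#'
#' One summary per lifespan window (defaults: childhood 2-12, adolescence
#' 12-20, young adulthood 20-40, middle/late adulthood 40-100 years).
#' Windows extending beyond the fitted support are clipped with a
#' warning. Direction is `"strengthening"` for a positive mean slope of
#' `|median LI|`, `"attenuating"` for negative, `"neutral"` at exactly 0.
#'
#' @param fit A `wmasym_fit`.
#' @param sex_mode `"pooled"`, `"female"` or `"male"`.
#' @param windows List of length-2 numeric windows.
#' @param step Grid step (years) for the median evaluation.
#' @return Data frame with columns `tract`, `feature`, `window`,
#'   `mean_abs_slope`, `direction`.
#' @export
lifespan_slopes <- function(fit, sex_mode = "pooled",
                            windows = default_windows, step = 0.25) {
  stopifnot(inherits(fit, "wmasym_fit"))
  med <- population_median(fit, ages = default_age_grid(fit, step), sex_mode = sex_mode)
  grid_range <- range(med$age)
  rows <- lapply(windows, function(w) {
    wc <- c(max(w[1], grid_range[1]), min(w[2], grid_range[2]))
    if (!isTRUE(all.equal(wc, as.numeric(w)))) {
      warning("window [", w[1], ", ", w[2], "] clipped to fitted support [",
              wc[1], ", ", wc[2], "]")
    }
    if (wc[1] >= wc[2]) return(NULL)
    sl <- window_slope(med, wc)
    data.frame(
      tract = fit$tract, feature = fit$feature,
      window = paste0(w[1], "-", w[2]),
      mean_abs_slope = sl,
      direction = if (sl > 0) "strengthening" else if (sl < 0) "attenuating" else "neutral"
    )
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
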