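# Centile charts: age-dense quantile curves of the fitted LI distribution.

default_levels <- c(0.025, 0.25, 0.5, 0.75, 0.975)

pred_by_sex_mode <- function(fit, ages, sex_mode) {
  if (identical(sex_mode, "pooled")) {
    f <- predict_mu_sigma(fit, ages, "female")
    m <- predict_mu_sigma(fit, ages, "male")
    list(mu = (f$mu + m$mu) / 2, sigma = (f$sigma + m$sigma) / 2,
         mu_f = f$mu, sigma_f = f$sigma, mu_m = m$mu, sigma_m = m$sigma)
  } else {
    p <- predict_mu_sigma(fit, ages, sex_mode)
    c(p, list(mu_f = NULL))
  }
}

default_age_grid <- function(fit, step = 0.25) {
  g <- seq(fit$age_range[1], fit$age_range[2], by = step)
  # keep the upper support bound on the grid even when step does not divide
  if (g[length(g)] < fit$age_range[2]) g <- c(g, fit$age_range[2])
  g
}

#' Centile curves of the fitted LI distribution
#'
#' Evaluates `value(age, q) = mu(age) + z_q * sigma(age)` on a dense age
#' grid, with `z_q` the standard normal quantile. The grid is confined to
#' the fitted age support (FP tails are unstable outside it). The pooled
#' sex curve uses the equal-weight average of the two sex-specific `mu`
#' and of the two sex-specific `sigma` (an approximation to the mixture,
#' adequate for median-level summaries and recorded in the chart).
#'
#' @param fit A `wmasym_fit`.
#' @param ages Increasing age grid; default: fitted range, step 0.25 y.
#' @param levels Strictly increasing centile probabilities in (0, 1);
#'   default 2.5th, 25th, 50th, 75th and 97.5th.
#' @param sex `"pooled"` (default), `"female"` or `"male"`.
#' @return An object of class `wmasym_chart`: `tract`, `feature`, `sex`,
#'   `ages`, `levels`, and a `|ages| x |levels|` matrix `values`.
#' @export
centile_curves <- function(fit, ages = NULL, levels = default_levels,
                           sex = "pooled") {
  stopifnot(inherits(fit, "wmasym_fit"))
  if (any(levels <= 0) || any(levels >= 1)) {
    stop_wmasym("centile levels must lie strictly inside (0, 1)",
                "wmasym_validation_error")
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    stop_wmasym("centile levels must be strictly increasing",
                "wmasym_validation_error")
  }
  if (is.null(ages)) ages <- default_age_grid(fit)
  eps <- 1e-9
  if (any(ages < fit$age_range[1] - eps) || any(ages > fit$age_range[2] + eps)) {
    stop_wmasym("age grid extends beyond the fitted age support",
                "wmasym_validation_error")
  }
  if (is.unsorted(ages, strictly = TRUE)) {
    stop_wmasym("ages must be strictly increasing", "wmasym_validation_error")
  }
  p <- pred_by_sex_mode(fit, ages, sex)
  z <- qnorm(levels)
  values <- outer(p$mu, rep(1, length(levels))) +
    outer(p$sigma, rep(1, length(levels))) * matrix(z, nrow = length(ages),
                                                    ncol = length(levels), byrow = TRUE)
  colnames(values) <- format(levels)
  structure(
    list(tract = fit$tract, feature = fit$feature, sex = sex,
         ages = ages, levels = levels, values = values,
         transform = fit$spec$transform, age_range = fit$age_range,
         pooled_note = if (identical(sex, "pooled"))
           "pooled = equal-weight mean of sex-specific mu and sigma" else NULL),
    class = "wmasym_chart"
  )
}

#' @export
print.wmasym_chart <- function(x, ...) {
  cat("<wmasym_chart>", if (!is.na(x$tract)) paste0(x$tract, " ", x$feature),
      "sex:", x$sex, "\n")
  cat("  ", length(x$ages), " ages in [", x$ages[1], ", ",
      x$ages[length(x$ages)], "] x ", length(x$levels), " levels\n", sep = "")
  invisible(x)
}

#' Population median LI trajectory
#'
#' The 50th-percentile curve of the fitted distribution, which for the
#' Gaussian family equals `mu(age)`. Pooled mode averages the two
#' sex-specific medians with equal weight.
#'
#' @param fit A `wmasym_fit`.
#' @param ages Age grid (default: fitted range, step 0.25 y).
#' @param sex_mode `"pooled"`, `"female"` or `"male"`.
#' @return Data frame with columns `age` and `value`.
#' @export
population_median <- function(fit, ages = NULL, sex_mode = "pooled") {
  if (is.null(ages)) ages <- default_age_grid(fit)
  p <- pred_by_sex_mode(fit, ages, sex_mode)
  data.frame(age = ages, value = p$mu)
}

#' Export a centile chart as delimited text
#'
#' Long format (`age`, `level`, `value`) with `#`-prefixed header
#' metadata lines recording tract, feature, sex and the age transform.
#'
#' @param chart A `wmasym_chart`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_chart <- function(chart, path) {
  stopifnot(inherits(chart, "wmasym_chart"))
  hdr <- c(
    paste0("# tract: ", chart$tract), paste0("# feature: ", chart$feature),
    paste0("# sex: ", chart$sex),
    paste0("# age_transform: t = (age + ", chart$transform$shift, ") / ",
           chart$transform$scale)
  )
  long <- data.frame(
    age = rep(chart$ages, times = length(chart$levels)),
    level = rep(chart$levels, each = length(chart$ages)),
    value = as.vector(chart$values)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("age\tlevel\tvalue", con)
  writeLines(sprintf("%.6g\t%g\t%.17g", long$age, long$level, long$value), con)
  invisible(path)
}

#' Plot a centile chart
#'
#' Median trajectory with shaded centile bands, LI increasing left-to-
#' right on the vertical axis convention of asymmetry charts (negative =
#' leftward, positive = rightward).
#'
#' @param x A `wmasym_chart`.
#' @param main Title; defaults to tract and feature.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.wmasym_chart <- function(x, main = NULL, ...) {
  if (is.null(main)) {
    main <- paste(ifelse(is.na(x$tract), "", x$tract),
                  ifelse(is.na(x$feature), "", x$feature))
  }
  ylim <- range(x$values)
  graphics::plot(NA, xlim = range(x$ages), ylim = ylim, xlab = "Age (years)",
                 ylab = "Laterality index", main = main, ...)
  nl <- length(x$levels)
  n_bands <- nl %/% 2
  for (i in seq_len(n_bands)) {
    graphics::polygon(c(x$ages, rev(x$ages)),
                      c(x$values[, i], rev(x$values[, nl + 1 - i])),
                      col = grDevices::adjustcolor("steelblue", alpha.f = 0.15 + 0.1 * i),
                      border = NA)
  }
  med <- which.min(abs(x$levels - 0.5))
  graphics::lines(x$ages, x$values[, med], lwd = 2, col = "steelblue4")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
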