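#' Streamline-weighted mean of a per-voxel tract metric
#'
#' Collapses a voxel-wise diffusion metric (e.g. FA) to a single tract
#' value by averaging over the tract mask with each voxel weighted by the
#' number of streamlines passing through it.
#'
#' @param values Numeric vector of per-voxel metric values.
#' @param weights Nonnegative numeric vector of per-voxel streamline
#'   counts, same length as `values`; at least one must be positive.
#' @return The weighted mean `sum(w * v) / sum(w)`.
#' @examples
#' streamline_weighted_mean(c(1, 2), c(1, 3))            # 1.75
#' streamline_weighted_mean(c(0.4, 0.6, 0.8), c(2, 5, 3)) # 0.62
#' @export
streamline_weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop_wmasym("`values` and `weights` must have the same length", "wmasym_validation_error")
  }
  if (length(values) < 1L) {
    stop_wmasym("`values` must have length >= 1", "wmasym_validation_error")
  }
  if (any(!is.finite(values)) || any(!is.finite(weights))) {
    stop_wmasym("`values` and `weights` must be finite", "wmasym_validation_error")
  }
  if (any(weights < 0)) {
    stop_wmasym("`weights` must be nonnegative", "wmasym_validation_error")
  }
  if (all(weights == 0)) {
    stop_wmasym("all weights are zero: weighted mean undefined", "wmasym_degenerate_error")
  }
  sum(weights * values) / sum(weights)
}

#' Laterality index of a paired bilateral measurement
#'
#' `LI = (R - L) / (R + L)`. Zero means perfect symmetry; positive values
#' indicate rightward asymmetry (right exceeds left), negative values
#' leftward. For nonnegative inputs the index is bounded in \[-1, 1\].
#'
#' @param right,left Nonnegative feature values for the right and left
#'   hemisphere tract. Vectorized; recycled to a common length.
#' @return Numeric vector of laterality indices.
#' @examples
#' laterality_index(5, 5)  # 0: perfect symmetry
#' laterality_index(7, 0)  # 1: upper bound
#' laterality_index(3, 1)  # 0.5
#' @export
laterality_index <- function(right, left) {
  if (any(!is.finite(right)) || any(!is.finite(left))) {
    stop_wmasym("hemisphere values must be finite", "wmasym_validation_error")
  }
  if (any(right < 0) || any(left < 0)) {
    stop_wmasym("hemisphere values must be nonnegative", "wmasym_validation_error")
  }
  s <- right + left
  if (any(s == 0)) {
    stop_wmasym("right + left = 0: laterality index undefined", "wmasym_degenerate_error")
  }
  (right - left) / s
}

#' Build the laterality modeling table from bilateral records
#'
#' Pairs left and right hemisphere rows within each
#' (subject, tract, feature) and computes one laterality index per
#' complete pair. Incomplete pairs (a hemisphere missing, e.g. after a
#' segmentation failure) and degenerate pairs (`R + L = 0`, where LI is
#' undefined) are excluded; the per-reason counts are attached as the
#' `"exclusions"` attribute and reported via `message()`.
#'
#' @param records Data frame of bilateral records as returned by
#'   [load_bilateral_table()].
#' @return Data frame with columns `subject_id`, `cohort_id`, `age`,
#'   `sex`, `tract`, `feature`, `li`, one row per complete nondegenerate
#'   pair, with attribute `exclusions = c(incomplete = , degenerate = )`.
#' @examples
#' rec <- data.frame(
#'   subject_id = "s1", cohort_id = "c1", age = 30, sex = "female",
#'   tract = "AF", hemisphere = c("left", "right"), feature = "FA",
#'   value = c(0.48, 0.46)
#' )
#' build_li_table(rec)$li  # (0.46 - 0.48) / 0.94
#' @export
build_li_table <- function(records) {
  req <- c("subject_id", "cohort_id", "age", "sex", "tract", "feature",
           "hemisphere", "value")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    stop_wmasym(paste0("missing columns: ", paste(miss, collapse = ", ")),
                "wmasym_format_error")
  }
  # demographics must be unique per subject
  demo <- unique(records[, c("subject_id", "cohort_id", "age", "sex")])
  if (anyDuplicated(demo$subject_id)) {
    bad <- demo$subject_id[duplicated(demo$subject_id)][1]
    stop_wmasym(paste0("conflicting age/sex/cohort for subject '", bad, "'"),
                "wmasym_validation_error")
  }
  dt <- data.table::as.data.table(records)
  wide <- as.data.frame(data.table::dcast(
    dt, subject_id + cohort_id + age + sex + tract + feature ~ hemisphere,
    value.var = "value"
  ))
  if (!"left" %in% names(wide)) wide$left <- NA_real_
  if (!"right" %in% names(wide)) wide$right <- NA_real_
  complete <- !is.na(wide$left) & !is.na(wide$right)
  n_incomplete <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  degenerate <- (wide$left + wide$right) == 0
  n_degenerate <- sum(degenerate)
  wide <- wide[!degenerate, , drop = FALSE]
  out <- data.frame(
    subject_id = wide$subject_id, cohort_id = wide$cohort_id,
    age = wide$age, sex = wide$sex, tract = wide$tract,
    feature = wide$feature,
    li = if (nrow(wide)) laterality_index(wide$right, wide$left) else numeric(0)
  )
  excl <- c(incomplete = n_incomplete, degenerate = n_degenerate)
  if (sum(excl) > 0) {
    message("build_li_table: excluded ", n_incomplete, " incomplete and ",
            n_degenerate, " degenerate (R + L = 0) pairs")
  }
  attr(out, "exclusions") <- excl
  out
}
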