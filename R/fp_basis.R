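# Fractional polynomial (FP) smooth machinery for the age trend of the
# location (mu) and scale (log sigma) predictors.

# The canonical FP candidate power set.
fp_allowed_powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional polynomial power specification
#'
#' An FP smooth of order 1 or 2 over the transformed age `t > 0`, with
#' powers drawn from the canonical set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}.
#' Power 0 denotes `log(t)`; a repeated power pair `(p, p)` denotes the
#' pair of terms `t^p` and `t^p * log(t)` (for `(0, 0)`: `log(t)` and
#' `log(t)^2`).
#'
#' @param powers Numeric vector of length 1 or 2 with values in the
#'   permitted set. Pairs are stored sorted.
#' @return An object of class `fp_spec`.
#' @examples
#' fp_spec(1)        # linear in t
#' fp_spec(c(0, 1))  # log(t) and t
#' fp_spec(c(2, 2))  # t^2 and t^2 * log(t)
#' @export
fp_spec <- function(powers) {
  powers <- as.numeric(powers)
  if (!length(powers) %in% c(1L, 2L)) {
    stop_wmasym("FP spec must have 1 or 2 powers", "wmasym_validation_error")
  }
  if (!all(powers %in% fp_allowed_powers)) {
    stop_wmasym(
      paste0("FP powers must be in {", paste(fp_allowed_powers, collapse = ", "), "}"),
      "wmasym_validation_error"
    )
  }
  structure(sort(powers), class = "fp_spec")
}

#' @export
print.fp_spec <- function(x, ...) {
  cat("<fp_spec> powers (", paste(unclass(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Age transform for fractional polynomial evaluation
#'
#' FP terms require a strictly positive predictor, but the cohorts span
#' ages from birth, so raw age is shifted and rescaled:
#' `t = (age + shift) / scale`. The defaults (`shift = 1`, `scale = 10`)
#' make `t` positive at age 0 and keep `t^3` and `t^-2` in numerically
#' safe ranges over 0-100 years. The transform is stored inside every fit
#' so charts are reproducible.
#'
#' @param shift,scale Years. `scale` must be positive.
#' @return An object of class `age_transform`.
#' @export
age_transform <- function(shift = 1, scale = 10) {
  shift <- as.numeric(shift); scale <- as.numeric(scale)
  if (!is.finite(shift) || !is.finite(scale) || scale <= 0) {
    stop_wmasym("invalid age transform", "wmasym_validation_error")
  }
  structure(list(shift = shift, scale = scale), class = "age_transform")
}

#' @export
print.age_transform <- function(x, ...) {
  cat("<age_transform> t = (age + ", x$shift, ") / ", x$scale, "\n", sep = "")
  invisible(x)
}

#' Apply the age transform
#'
#' @param age Ages in years (vectorized), `age + shift` must be positive.
#' @param transform An [age_transform()].
#' @return Transformed ages `t = (age + shift) / scale`, all positive.
#' @examples
#' age_to_t(c(0, 9, 100))  # 0.1, 1.0, 10.1
#' @export
age_to_t <- function(age, transform = age_transform()) {
  t <- (age + transform$shift) / transform$scale
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop_wmasym("age + shift must be positive and finite", "wmasym_domain_error")
  }
  t
}

#' Evaluate fractional polynomial basis terms
#'
#' For each power `p != 0` the term is `t^p`; for `p = 0` it is `log(t)`.
#' A repeated pair `(p, p)` contributes `(t^p, t^p * log(t))`, with the
#' `(0, 0)` case contributing `(log(t), log(t)^2)`. A distinct pair
#' contributes the two single terms.
#'
#' @param t Positive transformed ages (vector).
#' @param spec An [fp_spec()].
#' @return Numeric matrix, `length(t)` rows and one column per term.
#' @examples
#' fp_terms(2, fp_spec(c(1, 2)))  # 2, 4
#' fp_terms(2, fp_spec(c(2, 2)))  # 4, 4 * log(2)
#' @export
fp_terms <- function(t, spec) {
  if (!inherits(spec, "fp_spec")) spec <- fp_spec(spec)
  if (any(t <= 0)) stop_wmasym("t must be positive", "wmasym_domain_error")
  p <- unclass(spec)
  single <- function(q) if (q == 0) log(t) else t^q
  if (length(p) == 1L) {
    m <- cbind(single(p[1]))
    colnames(m) <- fp_term_name(p[1])
  } else if (p[1] != p[2]) {
    m <- cbind(single(p[1]), single(p[2]))
    colnames(m) <- c(fp_term_name(p[1]), fp_term_name(p[2]))
  } else {
    # repeated power: second term picks up a log factor
    base <- single(p[1])
    m <- cbind(base, base * log(t))
    colnames(m) <- c(fp_term_name(p[1]), paste0(fp_term_name(p[1]), ".log(t)"))
  }
  m
}

fp_term_name <- function(p) if (p == 0) "log(t)" else paste0("t^", p)

#' Enumerate candidate fractional polynomial specifications
#'
#' Order 1 gives the 8 single powers; order 2 adds the 28 distinct
#' unordered pairs and the 8 repeated pairs, 44 specifications in total.
#'
#' @param max_order 1 or 2.
#' @return List of [fp_spec()] objects, unique, pairs sorted.
#' @examples
#' length(candidate_power_sets(1))  # 8
#' length(candidate_power_sets(2))  # 44
#' @export
candidate_power_sets <- function(max_order = 2) {
  if (!max_order %in% c(1, 2)) {
    stop_wmasym("max_order must be 1 or 2", "wmasym_validation_error")
  }
  specs <- lapply(fp_allowed_powers, fp_spec)
  if (max_order == 2) {
    pairs <- utils::combn(fp_allowed_powers, 2, simplify = FALSE)
    specs <- c(specs, lapply(pairs, fp_spec),
               lapply(fp_allowed_powers, function(p) fp_spec(c(p, p))))
  }
  specs
}
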