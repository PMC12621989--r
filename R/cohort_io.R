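# Reading/validating subject-level bilateral feature tables and the
# text-based (JSON) serialization of pipeline artifacts.

bilateral_columns <- c("subject_id", "cohort_id", "age", "sex", "tract",
                       "hemisphere", "feature", "value")

#' Load and validate a bilateral feature table
#'
#' Reads a delimited text file (comma or tab, sniffed automatically) in
#' long layout: one row per subject x tract x feature x hemisphere, with
#' columns `subject_id`, `cohort_id`, `age`, `sex`, `tract`,
#' `hemisphere`, `feature`, `value`. Rows are validated against the
#' record invariants: age in \[0, 120\], finite nonnegative value, sex
#' `female`/`male`, hemisphere `left`/`right`, known feature name.
#' Missing hemispheres are not a load error - pairing happens in
#' [build_li_table()].
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param strict If `TRUE` (default) any invalid row is an error; if
#'   `FALSE` invalid rows are dropped with a message reporting the count
#'   (also attached as attribute `n_dropped`). Duplicate
#'   (subject, tract, feature, hemisphere) keys are always an error.
#' @return Data frame of validated bilateral records.
#' @export
load_bilateral_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop_wmasym(paste0("file not found: ", path), "wmasym_format_error")
  }
  df <- as.data.frame(data.table::fread(path))
  miss <- setdiff(bilateral_columns, names(df))
  if (length(miss) > 0) {
    stop_wmasym(paste0("missing required columns: ", paste(miss, collapse = ", ")),
                "wmasym_format_error")
  }
  df <- df[bilateral_columns]
  for (col in c("subject_id", "cohort_id", "tract", "feature")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$sex <- tolower(as.character(df$sex))
  df$hemisphere <- tolower(as.character(df$hemisphere))
  df$age <- suppressWarnings(as.numeric(df$age))
  df$value <- suppressWarnings(as.numeric(df$value))

  key <- paste(df$subject_id, df$tract, df$feature, df$hemisphere, sep = "\r")
  if (anyDuplicated(key)) {
    k <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop_wmasym(paste0("duplicate record for (subject=", k[1], ", tract=", k[2],
                       ", feature=", k[3], ", hemisphere=", k[4], ")"),
                "wmasym_validation_error")
  }
  ok <- is.finite(df$age) & df$age >= 0 & df$age <= 120 &
    df$sex %in% wm_sexes &
    df$hemisphere %in% wm_hemispheres &
    df$feature %in% wm_features &
    is.finite(df$value) & df$value >= 0
  if (any(!ok)) {
    if (strict) {
      stop_wmasym(paste0(sum(!ok), " rows violate record invariants (first bad row: ",
                         which(!ok)[1], ")"), "wmasym_validation_error")
    }
    message("load_bilateral_table: dropped ", sum(!ok), " invalid rows")
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Write a bilateral feature table
#'
#' @param records Data frame of bilateral records.
#' @param path Output path; tab-separated with header.
#' @return `path`, invisibly.
#' @export
write_bilateral_table <- function(records, path) {
  data.table::fwrite(records[bilateral_columns], path, sep = "\t")
  invisible(path)
}

#' Write / read a laterality modeling table
#'
#' Same delimited-text dialect as the bilateral tables, with columns
#' `subject_id`, `cohort_id`, `age`, `sex`, `tract`, `feature`, `li`.
#'
#' @param samples Modeling table from [build_li_table()] or
#'   [simulate_li_table()].
#' @param path File path.
#' @return `write_li_table()`: `path` invisibly; `read_li_table()`: the
#'   modeling table.
#' @export
write_li_table <- function(samples, path) {
  cols <- c("subject_id", "cohort_id", "age", "sex", "tract", "feature", "li")
  data.table::fwrite(samples[cols], path, sep = "\t")
  invisible(path)
}

#' @rdname write_li_table
#' @export
read_li_table <- function(path) {
  if (!file.exists(path)) {
    stop_wmasym(paste0("file not found: ", path), "wmasym_format_error")
  }
  df <- as.data.frame(data.table::fread(path))
  req <- c("subject_id", "cohort_id", "age", "sex", "tract", "feature", "li")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop_wmasym(paste0("missing columns: ", paste(miss, collapse = ", ")),
                "wmasym_format_error")
  }
  df$li <- as.numeric(df$li)
  if (any(!is.finite(df$li)) || any(abs(df$li) > 1)) {
    stop_wmasym("li values must be finite and within [-1, 1]",
                "wmasym_validation_error")
  }
  df
}

# --- artifact serialization (JSON, one object per file) ----------------

artifact_schema <- function(x) {
  if (inherits(x, "wmasym_fit")) "wmasym.fit/1"
  else if (inherits(x, "wmasym_chart")) "wmasym.chart/1"
  else if (inherits(x, "wmasym_truth")) "wmasym.truth/1"
  else if (is.data.frame(x)) "wmasym.table/1"
  else stop_wmasym("unknown artifact type", "wmasym_format_error")
}

#' Serialize / deserialize pipeline artifacts
#'
#' Artifacts (fits, charts, truths, summary tables) are stored as JSON
#' with full numeric precision and an embedded schema-version tag, so
#' `read_artifact(write_artifact(x))` reproduces `x` field-for-field.
#'
#' @param x A `wmasym_fit`, `wmasym_chart`, `wmasym_truth`, or a summary
#'   data frame.
#' @param path File path (conventionally `.json`).
#' @return `write_artifact()`: `path` invisibly; `read_artifact()`: the
#'   reconstructed object.
#' @export
write_artifact <- function(x, path) {
  schema <- artifact_schema(x)
  body <- if (is.data.frame(x)) {
    list(columns = as.list(x))
  } else {
    lapply(unclass(x), strip_for_json)
  }
  payload <- c(list(schema = schema), body)
  # I(17) significant digits: exact round-trip for IEEE doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

strip_for_json <- function(v) {
  if (inherits(v, "model_spec")) {
    list(mu_fp = as.numeric(v$mu_fp),
         sigma_fp = if (is.null(v$sigma_fp)) NULL else as.numeric(v$sigma_fp),
         include_sex = v$include_sex, cohort_effect = v$cohort_effect,
         ridge_lambda = v$ridge_lambda,
         transform = list(shift = v$transform$shift, scale = v$transform$scale))
  } else if (inherits(v, "fp_spec")) {
    as.numeric(v)
  } else if (inherits(v, "age_transform")) {
    list(shift = v$shift, scale = v$scale)
  } else if (is.matrix(v)) {
    list(.matrix = TRUE, dim = dim(v), colnames = colnames(v), data = as.numeric(v))
  } else if (is.data.frame(v)) {
    list(.table = TRUE, columns = as.list(v))
  } else if (!is.null(names(v)) && is.numeric(v)) {
    list(.named = TRUE, names = names(v), values = as.numeric(v))
  } else v
}

#' @rdname write_artifact
#' @export
read_artifact <- function(path) {
  if (!file.exists(path)) {
    stop_wmasym(paste0("file not found: ", path), "wmasym_format_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- obj$schema
  if (is.null(schema) || !schema %in% c("wmasym.fit/1", "wmasym.chart/1",
                                        "wmasym.truth/1", "wmasym.table/1")) {
    stop_wmasym(paste0("unknown artifact schema: ",
                       if (is.null(schema)) "<missing>" else schema),
                "wmasym_format_error")
  }
  obj$schema <- NULL
  restore <- function(v) {
    if (is.list(v) && isTRUE(v$.matrix)) {
      m <- matrix(v$data, nrow = v$dim[1], ncol = v$dim[2])
      colnames(m) <- v$colnames
      m
    } else if (is.list(v) && isTRUE(v$.table)) {
      as.data.frame(v$columns, stringsAsFactors = FALSE)
    } else if (is.list(v) && isTRUE(v$.named)) {
      setNames(as.numeric(v$values), v$names)
    } else v
  }
  if (schema == "wmasym.table/1") {
    return(as.data.frame(obj$columns, stringsAsFactors = FALSE))
  }
  out <- lapply(obj, restore)
  if (schema == "wmasym.fit/1") {
    sp <- out$spec
    out$spec <- model_spec(
      fp_spec(sp$mu_fp),
      if (is.null(sp$sigma_fp)) NULL else fp_spec(sp$sigma_fp),
      include_sex = sp$include_sex, cohort_effect = sp$cohort_effect,
      ridge_lambda = sp$ridge_lambda,
      transform = age_transform(sp$transform$shift, sp$transform$scale)
    )
    if (length(out$u_mu) == 0) out$u_mu <- numeric(0)
    if (length(out$u_sigma) == 0) out$u_sigma <- numeric(0)
    out$age_range <- as.numeric(out$age_range)
    class(out) <- "wmasym_fit"
  } else if (schema == "wmasym.chart/1") {
    out$ages <- as.numeric(out$ages)
    out$levels <- as.numeric(out$levels)
    out$transform <- age_transform(out$transform$shift, out$transform$scale)
    out$age_range <- as.numeric(out$age_range)
    class(out) <- "wmasym_chart"
  } else if (schema == "wmasym.truth/1") {
    # rebuild through the constructor so types and invariants are restored
    out <- synthetic_truth(
      mu_fp = fp_spec(as.numeric(out$mu_fp)), mu_coef = as.numeric(out$mu_coef),
      sigma_fp = fp_spec(as.numeric(out$sigma_fp)),
      sigma_coef = as.numeric(out$sigma_coef),
      sex_effect_mu = as.numeric(out$sex_effect_mu),
      sex_effect_sigma = as.numeric(out$sex_effect_sigma),
      cohort_sd_mu = as.numeric(out$cohort_sd_mu),
      cohort_sd_sigma = as.numeric(out$cohort_sd_sigma),
      n_cohorts = out$n_cohorts, n_subjects = out$n_subjects,
      age_range = as.numeric(out$age_range),
      female_fraction = as.numeric(out$female_fraction),
      seed = out$seed,
      transform = age_transform(out$transform$shift, out$transform$scale),
      tract = out$tract, feature = out$feature
    )
  }
  out
}
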