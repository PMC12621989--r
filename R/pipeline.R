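# End-to-end orchestration: LI table -> per tract-feature model selection
# -> centile chart -> milestone / reversal / slope summaries, with a
# manifest, run log and reproducible seeding.

#' Pipeline run configuration
#'
#' Defaults reproduce the canonical analysis settings: centile levels
#' 2.5/25/50/75/97.5, milestone ages 3/12/30/50 years, slope windows
#' 2-12, 12-20, 20-40 and 40-100 years, grid step 0.25 years.
#'
#' @param li_table,bilateral_table Path to an input modeling table or a
#'   bilateral feature table (one of the two, or `scenario_name`).
#' @param scenario_name Name of a [scenario()] to simulate instead of
#'   reading input.
#' @param scenario_n Optional sample-size override for the scenario.
#' @param out_dir Output directory (created if needed).
#' @param tracts,features Optional filters (character vectors).
#' @param strategy,max_order,include_sex,cohort_effect,ridge_lambda,transform
#'   Model-selection options (see [select_model()]).
#' @param grid_step,levels,sex_mode Chart options.
#' @param milestone_ages,windows,reversal_epsilon Analysis options.
#' @param seed Integer seed driving any simulation.
#' @return A `wmasym_config` list.
#' @export
pipeline_config <- function(li_table = NULL, bilateral_table = NULL,
                            scenario_name = NULL, scenario_n = NULL,
                            out_dir = "wmasym_out",
                            tracts = NULL, features = NULL,
                            strategy = "staged", max_order = 2,
                            include_sex = TRUE,
                            cohort_effect = "sum_to_zero", ridge_lambda = 0,
                            transform = age_transform(),
                            grid_step = 0.25, levels = default_levels,
                            sex_mode = "pooled",
                            milestone_ages = default_milestones,
                            windows = default_windows,
                            reversal_epsilon = 0,
                            seed = 1L) {
  structure(
    list(li_table = li_table, bilateral_table = bilateral_table,
         scenario_name = scenario_name, scenario_n = scenario_n,
         out_dir = out_dir, tracts = tracts, features = features,
         strategy = strategy, max_order = max_order,
         include_sex = include_sex, cohort_effect = cohort_effect,
         ridge_lambda = ridge_lambda, transform = transform,
         grid_step = grid_step, levels = levels, sex_mode = sex_mode,
         milestone_ages = milestone_ages, windows = windows,
         reversal_epsilon = reversal_epsilon, seed = as.integer(seed)),
    class = "wmasym_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides` (e.g.
#' parsed command-line flags) win over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A `wmasym_config`.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals <- modifyList(vals, overrides[!vapply(overrides, is.null, TRUE)])
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop_wmasym(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
                "wmasym_format_error")
  }
  if (!is.null(vals$windows)) vals$windows <- lapply(vals$windows, as.numeric)
  do.call(pipeline_config, vals)
}

#' Run the full asymmetry-charting pipeline
#'
#' Per tract-feature group: BIC model selection, centile chart, and
#' milestone / reversal / slope summary tables, written under
#' `config$out_dir` together with a run log and a manifest listing every
#' produced file with its MD5 checksum, the selected FP powers,
#' convergence flags and excluded-sample counts. A failing group is
#' recorded in the manifest and the run continues.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "wmasym_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
    writeLines(line, log_con); message(line)
  }

  # --- input stage -----------------------------------------------------
  exclusions <- c(incomplete = 0, degenerate = 0)
  if (!is.null(config$scenario_name)) {
    truth <- scenario(config$scenario_name, n_subjects = config$scenario_n,
                      seed = config$seed)
    samples <- simulate_li_table(truth)
    write_li_table(samples, file.path(config$out_dir, "li_table.tsv"))
    write_artifact(truth, file.path(config$out_dir, "truth.json"))
    logmsg("simulated scenario '", config$scenario_name, "' (n = ",
           nrow(samples), ", seed = ", config$seed, ")")
  } else if (!is.null(config$li_table)) {
    samples <- read_li_table(config$li_table)
    logmsg("read LI table: ", nrow(samples), " rows")
  } else if (!is.null(config$bilateral_table)) {
    rec <- load_bilateral_table(config$bilateral_table, strict = FALSE)
    logmsg("read bilateral table: ", nrow(rec), " rows (",
           attr(rec, "n_dropped"), " invalid dropped)")
    samples <- suppressMessages(build_li_table(rec))
    exclusions <- attr(samples, "exclusions")
    logmsg("paired LI samples: ", nrow(samples), " (excluded ",
           exclusions[["incomplete"]], " incomplete, ",
           exclusions[["degenerate"]], " degenerate)")
    write_li_table(samples, file.path(config$out_dir, "li_table.tsv"))
  } else {
    stop_wmasym("config must supply li_table, bilateral_table or scenario_name",
                "wmasym_validation_error")
  }

  if (!is.null(config$tracts)) samples <- samples[samples$tract %in% config$tracts, ]
  if (!is.null(config$features)) samples <- samples[samples$feature %in% config$features, ]
  if (nrow(samples) == 0) {
    stop_wmasym("no samples left after tract/feature filters", "wmasym_validation_error")
  }

  groups <- unique(samples[, c("tract", "feature")])
  groups <- groups[order(groups$tract, groups$feature), , drop = FALSE]
  results <- list()

  for (gi in seq_len(nrow(groups))) {
    tr <- groups$tract[gi]; fe <- groups$feature[gi]
    tag <- paste0(tr, "_", fe)
    sub <- samples[samples$tract == tr & samples$feature == fe, ]
    res <- tryCatch({
      fit <- select_model(sub, strategy = config$strategy,
                          max_order = config$max_order,
                          include_sex = config$include_sex,
                          cohort_effect = config$cohort_effect,
                          ridge_lambda = config$ridge_lambda,
                          transform = config$transform)
      fit_path <- file.path(config$out_dir, paste0("fit_", tag, ".json"))
      sel <- fit$selection; fit$selection <- NULL
      write_artifact(fit, fit_path)

      grid <- seq(fit$age_range[1], fit$age_range[2], by = config$grid_step)
      chart <- centile_curves(fit, ages = grid, levels = config$levels,
                              sex = config$sex_mode)
      chart_path <- file.path(config$out_dir, paste0("chart_", tag, ".tsv"))
      export_chart(chart, chart_path)

      mil <- suppressWarnings(
        milestone_summary(fit, config$milestone_ages, config$sex_mode))
      med <- population_median(fit, ages = grid, sex_mode = config$sex_mode)
      rev <- detect_reversals(med, epsilon = config$reversal_epsilon)
      if (nrow(rev)) rev <- cbind(tract = tr, feature = fe, rev)
      slo <- suppressWarnings(
        lifespan_slopes(fit, config$sex_mode, config$windows, config$grid_step))
      logmsg(tag, ": selected mu FP (",
             paste(unclass(fit$spec$mu_fp), collapse = ", "), "), sigma FP (",
             paste(unclass(fit$spec$sigma_fp), collapse = ", "),
             "); BIC ", format(fit$bic, digits = 8),
             if (!fit$converged) " [NOT CONVERGED]" else "")
      list(status = "ok", fit = fit_path, chart = chart_path,
           mu_fp = as.numeric(fit$spec$mu_fp),
           sigma_fp = as.numeric(fit$spec$sigma_fp),
           converged = fit$converged,
           milestones = mil, reversals = rev, slopes = slo)
    }, error = function(e) {
      logmsg(tag, ": FAILED (", conditionMessage(e), ")")
      list(status = "failed", error = conditionMessage(e))
    })
    results[[tag]] <- res
  }

  ok <- Filter(function(r) r$status == "ok", results)
  bindrows <- function(field) {
    parts <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                    lapply(ok, `[[`, field))
    if (length(parts)) do.call(rbind, c(parts, make.row.names = FALSE)) else NULL
  }
  for (nm in c("milestones", "reversals", "slopes")) {
    tab <- bindrows(nm)
    if (is.null(tab)) {
      tab <- data.frame()
    }
    data.table::fwrite(tab, file.path(config$out_dir, paste0(nm, ".tsv")), sep = "\t")
  }

  manifest <- list(
    schema = "wmasym.manifest/1",
    seed = config$seed,
    sex_mode = config$sex_mode,
    exclusions = as.list(exclusions),
    groups = lapply(results, function(r) r[setdiff(names(r),
                                                   c("milestones", "reversals", "slopes"))]),
    n_failed = sum(vapply(results, function(r) r$status == "failed", TRUE))
  )
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   c("manifest.json", "run.log"))
  manifest$files <- lapply(files, function(f) {
    list(path = f, md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("done: ", length(ok), "/", length(results), " tract-features succeeded")
  invisible(manifest)
}
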