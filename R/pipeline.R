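# Pipeline orchestration: simulate -> extract -> score -> analyze, with
# on-disk interchange (SVC files, CSV tables, JSON manifests) so each
# stage can be run independently or from the command line.

.write_manifest <- function(dir, stage, config, seed = NULL,
                            inputs = NULL, outputs = NULL,
                            warnings = character(0)) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("graphomotor")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs, outputs = outputs,
    warnings = warnings,
    config = config
  )
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Writes per-participant-per-task SVC recordings (trajectory tier), the
#' covariates CSV, the physical-performance CSV, the generating truth as
#' JSON, and a run manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()].
#' @param tier Passed to [generate_cohort()] (default `"both"`).
#' @return The cohort, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = cohort_config(),
                         tier = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config, tier = tier)
  utils::write.csv(cohort$participants,
                   file.path(out_dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(cohort$physical,
                   file.path(out_dir, "physical.csv"), row.names = FALSE)
  write_feature_table(cohort$feature_table,
                      file.path(out_dir, "features_truth.csv"))
  n_svc <- 0L
  if (!is.null(cohort$recordings)) {
    svc_dir <- file.path(out_dir, "svc")
    dir.create(svc_dir, showWarnings = FALSE)
    for (pid in names(cohort$recordings)) {
      for (rec in cohort$recordings[[pid]]) {
        write_svc(rec, file.path(svc_dir,
                                 sprintf("%s_T%d.svc", pid, rec$task_id)))
        n_svc <- n_svc + 1L
      }
    }
  }
  truth <- list(group_effects = as.list(cohort$truth$group_effects),
                clip_counts = as.list(cohort$truth$clip_counts))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(out_dir, "simulate",
                  config = list(n_normal = config$n_normal,
                                n_altered = config$n_altered,
                                seed = config$seed, tier = tier),
                  seed = config$seed,
                  outputs = list(n_svc_files = n_svc,
                                 n_participants = nrow(cohort$participants)))
  invisible(cohort)
}

#' Extract features from a directory of SVC recordings
#'
#' Reads every `*.svc` file under `in_dir` (or `in_dir/svc`), extracts
#' the eight kinematic features per recording, joins the covariates CSV
#' and writes the feature table. Unreadable files are logged as warnings
#' and leave `NA` cells; the run completes.
#'
#' @param in_dir Cohort directory from [cmd_simulate()].
#' @param out_path Output CSV (default `features.csv` inside `in_dir`).
#' @param cfg A [kinematics_config()].
#' @return The feature table, invisibly.
#' @export
cmd_extract <- function(in_dir, out_path = file.path(in_dir, "features.csv"),
                        cfg = kinematics_config()) {
  svc_dir <- if (dir.exists(file.path(in_dir, "svc")))
    file.path(in_dir, "svc") else in_dir
  files <- list.files(svc_dir, pattern = "\\.svc$", full.names = TRUE)
  if (length(files) == 0L) stop("no SVC recordings found under ", in_dir)
  cov_path <- file.path(in_dir, "covariates.csv")
  if (!file.exists(cov_path)) stop("covariates.csv not found in ", in_dir)
  covariates <- utils::read.csv(cov_path, stringsAsFactors = FALSE)

  vars <- handwriting_variable_names()
  mat <- matrix(NA_real_, nrow = nrow(covariates), ncol = length(vars),
                dimnames = list(covariates$participant_id, vars))
  warn <- character(0)
  for (f in files) {
    rec <- tryCatch(read_svc(f), error = function(e) e)
    if (inherits(rec, "error")) {
      warn <- c(warn, sprintf("%s: %s", basename(f), conditionMessage(rec)))
      next
    }
    if (!rec$participant_id %in% rownames(mat)) {
      warn <- c(warn, sprintf("%s: unknown participant", basename(f)))
      next
    }
    fv <- extract_features(rec, cfg)
    mat[rec$participant_id, paste0("T", rec$task_id, "_", feature_names())] <- fv
  }
  features <- tibble::as_tibble(cbind(
    covariates[, c("participant_id", "age", "sex", "group")],
    as.data.frame(mat, row.names = NULL)
  ))
  write_feature_table(features, out_path)
  .write_manifest(dirname(out_path), "extract",
                  config = unclass(cfg),
                  inputs = list(n_svc_files = length(files)),
                  outputs = list(features = out_path),
                  warnings = warn)
  if (length(warn)) {
    message(length(warn), " recording(s) skipped; see extract manifest")
  }
  invisible(features)
}

#' Run the adjusted comparison and write results
#'
#' Writes the per-variable results CSV (group means/SDs, adjusted
#' coefficient, CI, raw and FDR-adjusted p), the category x feature
#' significance-count CSV and a markdown summary of variables that
#' remain significant after FDR.
#'
#' @param features_path Feature table CSV.
#' @param physical_path Optional physical table CSV (required for
#'   `family = "handwriting_plus_physical"`).
#' @param out_dir Output directory.
#' @param cfg An [analysis_config()].
#' @return The [run_analysis()] result, invisibly.
#' @export
cmd_analyze <- function(features_path, physical_path = NULL,
                        out_dir = dirname(features_path),
                        cfg = analysis_config()) {
  features <- read_feature_table(features_path)
  physical <- if (!is.null(physical_path) && file.exists(physical_path)) {
    tibble::as_tibble(utils::read.csv(physical_path, stringsAsFactors = FALSE))
  } else NULL
  res <- run_analysis(features, physical, cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$results, file.path(out_dir, "comparison_results.csv"),
                   row.names = FALSE)
  counts_df <- cbind(category = rownames(res$counts),
                     total_tasks = c(2L, 4L, 4L),
                     as.data.frame(res$counts))
  utils::write.csv(counts_df, file.path(out_dir, "significance_counts.csv"),
                   row.names = FALSE)

  sig <- res$results[!is.na(res$results$p_fdr) &
                       res$results$p_fdr < cfg$alpha, ]
  lines <- c("# Group comparison summary", "",
             sprintf("%d of %d variables significant after FDR (alpha = %.2f).",
                     nrow(sig), nrow(res$results), cfg$alpha), "")
  if (nrow(sig) > 0L) {
    lines <- c(lines, "| variable | beta | 95% CI | p (FDR) |",
               "|---|---|---|---|",
               sprintf("| %s | %.3f | %.2f to %.2f | %.3g |",
                       sig$variable, sig$beta, sig$ci_low, sig$ci_high,
                       sig$p_fdr))
  } else {
    lines <- c(lines, "No variables significant after FDR.")
  }
  writeLines(lines, file.path(out_dir, "summary.md"))
  .write_manifest(out_dir, "analyze", config = unclass(cfg),
                  inputs = list(features = features_path,
                                physical = physical_path),
                  outputs = list(results = "comparison_results.csv",
                                 counts = "significance_counts.csv"))
  invisible(res)
}
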