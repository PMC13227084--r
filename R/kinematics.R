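# Kinematic feature extraction: stroke segmentation and the 8 per-task
# features (time on air, time down, mean/max pressure, speed, acceleration).

#' The eight kinematic features, in canonical column order
#' @export
feature_names <- function() {
  c("time_on_air", "time_down", "mean_pressure", "max_pressure",
    "mean_speed", "max_speed", "mean_acceleration", "max_acceleration")
}

#' Canonical handwriting variable names (task x feature grid)
#'
#' `T1_time_on_air` ... `T10_max_acceleration`, 80 variables.
#' @export
handwriting_variable_names <- function() {
  as.vector(t(outer(paste0("T", 1:10), feature_names(), paste, sep = "_")))
}

#' Configuration for kinematic feature extraction
#'
#' @param units_per_mm Device units per millimetre (default 200, a
#'   typical high-resolution digitizer pitch). Speeds and accelerations
#'   scale inversely with this value; times and pressures do not.
#' @param max_gap_ms Inter-sample intervals longer than this are excluded
#'   from speed/acceleration and contribute at most `max_gap_ms` to time
#'   on air (guards against out-of-proximity dropouts; default 1000 ms).
#' @param speed_scope `"all_samples"` (default) computes speed over every
#'   interval including in-air movement and pen-down/up transitions;
#'   `"down_only"` restricts to intervals starting at a pen-down sample.
#' @return List of class `kinematics_config`.
#' @export
kinematics_config <- function(units_per_mm = 200, max_gap_ms = 1000,
                              speed_scope = c("all_samples", "down_only")) {
  speed_scope <- match.arg(speed_scope)
  if (units_per_mm <= 0) stop("units_per_mm must be > 0")
  if (max_gap_ms < 10) stop("max_gap_ms must be >= 10")
  structure(list(units_per_mm = units_per_mm, max_gap_ms = max_gap_ms,
                 speed_scope = speed_scope),
            class = "kinematics_config")
}

#' Segment a recording into maximal constant-status strokes
#'
#' A stroke is a maximal run of consecutive samples sharing pen status.
#' The interval between two samples of different status is attributed to
#' the earlier sample's status, so stroke durations partition the
#' recording span: each stroke's duration is the time from its first
#' sample to the first sample of the next stroke (the last stroke ends
#' at its own last sample).
#'
#' @param rec A [task_recording()] (time-sorted).
#' @return List of strokes, each a list with `status` (`"down"`/`"up"`),
#'   `samples` (data frame) and `duration_ms`.
#' @export
segment_strokes <- function(rec) {
  stopifnot(inherits(rec, "task_recording"))
  s <- rec$samples
  n <- nrow(s)
  if (n == 0L) return(list())
  run_id <- cumsum(c(1L, as.integer(diff(s$status) != 0)))
  idx <- split(seq_len(n), run_id)
  n_runs <- length(idx)
  lapply(seq_len(n_runs), function(k) {
    i <- idx[[k]]
    end_t <- if (k < n_runs) s$t[idx[[k + 1L]][1]] else s$t[i[length(i)]]
    list(status = if (s$status[i[1]] == 1L) "down" else "up",
         samples = s[i, , drop = FALSE],
         duration_ms = end_t - s$t[i[1]])
  })
}

#' Extract the eight kinematic features from a task recording
#'
#' Per-interval quantities are computed over consecutive sample pairs
#' (interval i runs from sample i to sample i+1, attributed to sample
#' i's pen status):
#' \itemize{
#'   \item time down: sum of pen-down intervals (ms);
#'   \item time on air: sum of pen-up intervals, each capped at
#'     `max_gap_ms` (ms);
#'   \item mean/max pressure over pen-down samples (au);
#'   \item speed v_i = Euclidean displacement (mm, via `units_per_mm`)
#'     divided by the interval (s), over intervals in `speed_scope` with
#'     interval length at most `max_gap_ms` (mm/s);
#'   \item acceleration a_i = |v_{i+1} - v_i| / dt_{i+1} over consecutive
#'     retained intervals (mm/s^2).
#' }
#' Recordings with fewer than 2 samples get zero speed/acceleration and
#' recordings with no pen-down sample get zero pressure; both set flags
#' in the `"flags"` attribute rather than failing.
#'
#' @param rec A [task_recording()].
#' @param cfg A [kinematics_config()].
#' @return Named numeric vector over [feature_names()], with an optional
#'   `"flags"` attribute listing degeneracies
#'   (`too_few_samples`, `no_down_samples`, `air_gap_capped`).
#' @export
extract_features <- function(rec, cfg = kinematics_config()) {
  stopifnot(inherits(rec, "task_recording"))
  s <- rec$samples
  n <- nrow(s)
  out <- setNames(numeric(8), feature_names())
  flags <- character(0)

  down_samples <- s$pressure[s$status == 1L]
  if (length(down_samples) > 0L) {
    out["mean_pressure"] <- mean(down_samples)
    out["max_pressure"] <- max(down_samples)
  } else {
    flags <- c(flags, "no_down_samples")
  }

  if (n < 2L) {
    if (n < 2L) flags <- c(flags, "too_few_samples")
    attr(out, "flags") <- flags
    return(out)
  }

  dt <- diff(s$t)                      # ms, interval i = sample i -> i+1
  if (any(dt < 0)) stop("unsorted recording: negative inter-sample interval")
  st <- s$status[-n]                   # attribution: earlier sample's status

  out["time_down"] <- sum(dt[st == 1L])
  air <- dt[st == 0L]
  capped <- air > cfg$max_gap_ms
  if (any(capped)) flags <- c(flags, "air_gap_capped")
  out["time_on_air"] <- sum(pmin(air, cfg$max_gap_ms))

  keep <- dt > 0 & dt <= cfg$max_gap_ms
  if (cfg$speed_scope == "down_only") keep <- keep & st == 1L
  if (any(keep)) {
    disp_mm <- sqrt(diff(s$x)^2 + diff(s$y)^2) / cfg$units_per_mm
    v <- disp_mm[keep] / (dt[keep] / 1000)
    out["mean_speed"] <- mean(v)
    out["max_speed"] <- max(v)
    dt_keep <- dt[keep]
    if (length(v) >= 2L) {
      a <- abs(diff(v)) / (dt_keep[-1] / 1000)
      out["mean_acceleration"] <- mean(a)
      out["max_acceleration"] <- max(a)
    }
  }
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Assemble the participant x variable feature table
#'
#' Builds the 80-column handwriting feature table (plus covariates) from
#' a cohort. Feature-tier cohorts already carry per-variable values and
#' are passed through; trajectory-tier cohorts are processed through
#' [extract_features()] on every recording. Participants missing a task
#' get `NA` in that task's eight columns.
#'
#' @param cohort A cohort from [generate_cohort()], or a list with
#'   `participants` (data frame with `participant_id, age, sex, group`)
#'   and `recordings` (named list: `recordings[[pid]][[task]]`).
#' @param cfg A [kinematics_config()].
#' @param use_recordings Force extraction from recordings even if the
#'   cohort has a feature-tier table.
#' @return A tibble with columns `participant_id, age, sex, group` and
#'   the 80 `T<task>_<feature>` columns.
#' @export
build_feature_table <- function(cohort, cfg = kinematics_config(),
                                use_recordings = FALSE) {
  parts <- cohort$participants
  if (anyDuplicated(parts$participant_id)) {
    stop("duplicate participant ids")
  }
  if (!use_recordings && !is.null(cohort$feature_table)) {
    return(cohort$feature_table)
  }
  if (is.null(cohort$recordings)) {
    stop("cohort has neither a feature table nor recordings")
  }
  vars <- handwriting_variable_names()
  mat <- matrix(NA_real_, nrow = nrow(parts), ncol = length(vars),
                dimnames = list(NULL, vars))
  for (i in seq_len(nrow(parts))) {
    pid <- parts$participant_id[i]
    recs <- cohort$recordings[[pid]]
    if (is.null(recs)) next
    for (rec in recs) {
      fv <- extract_features(rec, cfg)
      mat[i, paste0("T", rec$task_id, "_", feature_names())] <- fv
    }
  }
  tibble::as_tibble(cbind(parts[, c("participant_id", "age", "sex", "group")],
                          as.data.frame(mat)))
}

#' Write a feature table to CSV with the stable exported header
#' @param features Tibble from [build_feature_table()].
#' @param path Output CSV path. Missing values export as empty cells.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table CSV written by [write_feature_table()]
#' @param path CSV path.
#' @export
read_feature_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
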