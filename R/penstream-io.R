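# Column order of the SVC dialect used throughout the package.
.svc_cols <- c("x", "y", "t", "status", "azimuth", "altitude", "pressure")

#' Task taxonomy: category implied by task number
#'
#' Tasks 1-2 are cognitive-effort tasks (pentagon copy, house drawing),
#' 3-6 fine motor control (spiral, straight line, spring, concentric
#' circles), 7-10 mechanical (signatures, capital letters, phrase copy).
#'
#' @param task_id Integer vector of task numbers in 1..10.
#' @return Character vector: `"cognitive"`, `"fine_motor"` or `"mechanical"`.
#' @export
#' @examples
#' task_category(c(1, 4, 9))
task_category <- function(task_id) {
  task_id <- as.integer(task_id)
  if (any(is.na(task_id)) || any(task_id < 1L | task_id > 10L)) {
    stop("task_id must be an integer in 1..10")
  }
  out <- character(length(task_id))
  out[task_id <= 2L] <- "cognitive"
  out[task_id >= 3L & task_id <= 6L] <- "fine_motor"
  out[task_id >= 7L] <- "mechanical"
  out
}

#' Construct a pen-stream task recording
#'
#' A `task_recording` bundles the time-ordered digitizer samples of one
#' handwriting task for one participant. Samples carry position (device
#' units), timestamp (ms), pen status (1 = down on the surface, 0 = up,
#' in proximity), tilt angles and pressure (arbitrary units). Pressure
#' must be 0 while the pen is up.
#'
#' @param samples Data frame with integer columns
#'   `x, y, t, status, azimuth, altitude, pressure`.
#' @param task_id Task number 1..10 (determines the category).
#' @param participant_id Opaque participant identifier.
#' @param validate If `TRUE` (default) check field invariants.
#' @return Object of class `task_recording`.
#' @export
task_recording <- function(samples, task_id = 1L, participant_id = "anon",
                           validate = TRUE) {
  if (is.null(samples) || nrow(samples) == 0L) {
    samples <- as.data.frame(matrix(integer(0), ncol = 7,
                                    dimnames = list(NULL, .svc_cols)))
  }
  samples <- as.data.frame(samples)[, .svc_cols, drop = FALSE]
  samples[] <- lapply(samples, as.numeric)   # uniform storage mode
  rownames(samples) <- NULL
  if (validate && nrow(samples) > 0L) {
    if (any(!vapply(samples, is.numeric, logical(1)))) {
      stop("all sample fields must be numeric")
    }
    if (any(is.na(samples))) stop("samples contain missing fields")
    if (any(samples$x < 0) || any(samples$y < 0)) {
      stop("x and y must be non-negative")
    }
    if (any(samples$t < 0)) stop("timestamps must be non-negative")
    if (is.unsorted(samples$t)) stop("timestamps must be non-decreasing")
    if (!all(samples$status %in% c(0L, 1L))) {
      stop("status must be 1 (pen down) or 0 (pen up)")
    }
    if (any(samples$azimuth < 0 | samples$azimuth >= 360)) {
      stop("azimuth must lie in [0, 360)")
    }
    if (any(samples$altitude < 0 | samples$altitude > 90)) {
      stop("altitude must lie in [0, 90]")
    }
    if (any(samples$pressure < 0)) stop("pressure must be non-negative")
  }
  structure(
    list(task_id = as.integer(task_id),
         category = task_category(task_id),
         participant_id = as.character(participant_id),
         samples = samples),
    class = "task_recording"
  )
}

#' @export
print.task_recording <- function(x, ...) {
  cat(sprintf("<task_recording> participant %s, task T%d (%s)\n",
              x$participant_id, x$task_id, x$category))
  n <- nrow(x$samples)
  cat(sprintf("  %d samples", n))
  if (n > 1L) {
    cat(sprintf(", %d ms span, %.0f%% pen-down",
                x$samples$t[n] - x$samples$t[1],
                100 * mean(x$samples$status == 1L)))
  }
  cat("\n")
  invisible(x)
}

#' Read an SVC-dialect pen-stream file
#'
#' The dialect is a plain-text file whose first line is the sample count
#' and whose remaining lines each hold seven whitespace-separated
#' integers: `x y t status azimuth altitude pressure` with status coded
#' 1 = pen down, 0 = pen up. Exact duplicate timestamps are resolved by
#' keeping the first occurrence (later duplicates are dropped and
#' surface as a validation warning).
#'
#' @param path Path to the `.svc` file.
#' @param task_id,participant_id Metadata for the recording; when `NULL`
#'   they are parsed from a `<participant>_T<task>.svc` file name if
#'   possible, else default to task 1 / the base file name.
#' @return A [task_recording()].
#' @export
read_svc <- function(path, task_id = NULL, participant_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file (missing sample-count header): ", path)
  n_declared <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_declared) || n_declared < 0L) {
    stop("line 1: header is not a non-negative integer sample count")
  }
  body <- lines[-1]
  if (length(body) != n_declared) {
    stop(sprintf("header declares %d samples but file has %d data lines",
                 n_declared, length(body)))
  }
  meta <- .parse_svc_name(path)
  if (is.null(task_id)) task_id <- meta$task_id
  if (is.null(participant_id)) participant_id <- meta$participant_id

  if (n_declared == 0L) {
    return(task_recording(NULL, task_id, participant_id))
  }
  fields <- strsplit(trimws(body), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- which(nf != 7L)[1]
    stop(sprintf("line %d: expected 7 fields, found %d", bad + 1L, nf[bad]))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (any(is.na(vals)) || any(vals != floor(vals))) {
    bad <- which(is.na(vals) | vals != floor(vals))[1]
    stop(sprintf("line %d: non-integer field", (bad - 1L) %/% 7L + 2L))
  }
  m <- matrix(vals, ncol = 7, byrow = TRUE,
              dimnames = list(NULL, .svc_cols))
  samples <- as.data.frame(m)
  # keep first occurrence of each timestamp so time stays strictly increasing
  dup <- duplicated(samples$t)
  n_dup <- sum(dup)
  if (n_dup > 0L) samples <- samples[!dup, , drop = FALSE]
  rec <- task_recording(samples, task_id, participant_id)
  attr(rec, "dropped_duplicate_timestamps") <- n_dup
  rec
}

.parse_svc_name <- function(path) {
  base <- sub("\\.svc$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(base, regexec("^(.+)_T([0-9]+)$", base))[[1]]
  if (length(m) == 3L && as.integer(m[3]) >= 1L && as.integer(m[3]) <= 10L) {
    list(participant_id = m[2], task_id = as.integer(m[3]))
  } else {
    list(participant_id = base, task_id = 1L)
  }
}

#' Write a task recording as an SVC-dialect file
#'
#' Integer fields round-trip exactly: `read_svc(write_svc(rec))`
#' reproduces every sample bit for bit.
#'
#' @param rec A [task_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_svc <- function(rec, path) {
  stopifnot(inherits(rec, "task_recording"))
  s <- rec$samples
  header <- format(nrow(s), scientific = FALSE)
  if (nrow(s) == 0L) {
    writeLines(header, path, useBytes = TRUE)
    return(invisible(path))
  }
  body <- do.call(paste, c(lapply(s, function(col) {
    format(col, scientific = FALSE, trim = TRUE)
  }), sep = " "))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Validate a task recording against acquisition assumptions
#'
#' Checks the recording against the nominal 100 Hz acquisition rate
#' (10 ms inter-sample interval) and basic channel coherence. Warnings
#' are coded, not fatal:
#' \describe{
#'   \item{empty_recording}{no samples}
#'   \item{irregular_sampling}{mean inter-sample interval deviates from
#'     10 ms by more than `interval_tol` (fraction, default 0.20)}
#'   \item{duplicate_timestamps}{duplicates were dropped at read time}
#'   \item{pressure_on_pen_up}{pen-up samples carry positive pressure}
#' }
#'
#' @param rec A [task_recording()].
#' @param nominal_interval_ms Nominal sampling interval (default 10 ms).
#' @param interval_tol Relative tolerance on the mean interval.
#' @return List of class `validation_report` with `n_samples`,
#'   `duration_ms`, `mean_interval_ms` and `warnings`.
#' @export
validate_recording <- function(rec, nominal_interval_ms = 10,
                               interval_tol = 0.20) {
  stopifnot(inherits(rec, "task_recording"))
  s <- rec$samples
  n <- nrow(s)
  warnings <- character(0)
  duration <- if (n > 1L) s$t[n] - s$t[1] else 0
  mean_int <- if (n > 1L) duration / (n - 1L) else NA_real_
  if (n == 0L) warnings <- c(warnings, "empty_recording")
  if (n > 1L &&
      abs(mean_int - nominal_interval_ms) > interval_tol * nominal_interval_ms) {
    warnings <- c(warnings, "irregular_sampling")
  }
  n_dup <- attr(rec, "dropped_duplicate_timestamps")
  if (!is.null(n_dup) && n_dup > 0L) {
    warnings <- c(warnings, "duplicate_timestamps")
  }
  if (n > 0L && any(s$status == 0L & s$pressure > 0)) {
    warnings <- c(warnings, "pressure_on_pen_up")
  }
  structure(
    list(n_samples = n, duration_ms = duration,
         mean_interval_ms = mean_int, warnings = warnings),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d samples, %s ms, mean interval %s ms\n",
              x$n_samples, format(x$duration_ms),
              format(round(x$mean_interval_ms, 3))))
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  } else {
    cat("  no warnings\n")
  }
  invisible(x)
}
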