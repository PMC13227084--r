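# Rule-based clinical physical-performance scoring: Short Physical
# Performance Battery (balance, 4-m gait, 5x chair stand) and Timed Up
# and Go bands. Published band endpoints leave micro-gaps (4.65 vs 4.66
# s gait, 11.19 vs 11.20 s and 59 vs 60 s chair); the conventions below
# close them by continuity with the printed endpoints and are the
# package's documented choice.

.check_time <- function(t, what) {
  if (any(!is.na(t) & t < 0)) stop(what, " must be non-negative")
}

#' SPPB balance component (0-4 points)
#'
#' Side-by-side and semi-tandem stands score 1 point for a 10 s hold
#' (0 below 10 s); the tandem stand scores 0 below 3 s, 1 from 3 to
#' under 10 s, and 2 for 10 s or more.
#'
#' @param side_s,semitandem_s,tandem_s Hold times in seconds
#'   (vectorized).
#' @return Integer points 0-4.
#' @export
sppb_balance_score <- function(side_s, semitandem_s, tandem_s) {
  .check_time(c(side_s, semitandem_s, tandem_s), "hold times")
  pts_side <- as.integer(side_s >= 10)
  pts_semi <- as.integer(semitandem_s >= 10)
  pts_tandem <- as.integer(tandem_s >= 3) + as.integer(tandem_s >= 10)
  pts_side + pts_semi + pts_tandem
}

#' SPPB 4-m gait component (0-4 points)
#'
#' 0 if unable; 4 below 3.62 s; 3 for 3.62-4.65 s; 2 above 4.65 up to
#' 6.52 s; 1 above 6.52 s.
#'
#' @param t4m_s 4-m walk time in seconds (vectorized).
#' @param able Logical; `FALSE` scores 0.
#' @return Integer points 0-4.
#' @export
sppb_gait_score <- function(t4m_s, able = TRUE) {
  .check_time(t4m_s, "gait time")
  able <- rep_len(able, length(t4m_s))
  pts <- ifelse(t4m_s < 3.62, 4L,
         ifelse(t4m_s <= 4.65, 3L,
         ifelse(t4m_s <= 6.52, 2L, 1L)))
  as.integer(ifelse(!able | is.na(t4m_s), 0L, pts))
}

#' SPPB chair-stand component (0-4 points)
#'
#' 0 if unable or over 60 s; 4 below 11.20 s; 3 for 11.20-13.69 s; 2
#' above 13.69 up to 16.69 s; 1 above 16.69 up to 60 s.
#'
#' @param t5_s Five-repetition chair-stand time in seconds (vectorized).
#' @param able Logical; `FALSE` scores 0.
#' @return Integer points 0-4.
#' @export
sppb_chair_score <- function(t5_s, able = TRUE) {
  .check_time(t5_s, "chair-stand time")
  able <- rep_len(able, length(t5_s))
  pts <- ifelse(t5_s < 11.20, 4L,
         ifelse(t5_s <= 13.69, 3L,
         ifelse(t5_s <= 16.69, 2L,
         ifelse(t5_s <= 60, 1L, 0L))))
  as.integer(ifelse(!able | is.na(t5_s), 0L, pts))
}

#' SPPB composite score and limitation category
#'
#' Composite 0-12 = balance + gait + chair points; categories: severe
#' (0-3), moderate (4-6), mild (7-9), minimal (10-12) limitations.
#'
#' @param balance_pts,gait_pts,chair_pts Component points (vectorized).
#' @return Tibble of class data with `balance_pts, gait_pts, chair_pts,
#'   composite, category`.
#' @export
sppb_composite <- function(balance_pts, gait_pts, chair_pts) {
  if (any(balance_pts < 0 | balance_pts > 4) ||
      any(gait_pts < 0 | gait_pts > 4) ||
      any(chair_pts < 0 | chair_pts > 4)) {
    stop("component points must lie in 0-4")
  }
  composite <- as.integer(balance_pts + gait_pts + chair_pts)
  category <- cut(composite, breaks = c(-1, 3, 6, 9, 12),
                  labels = c("severe", "moderate", "mild", "minimal"))
  tibble::tibble(balance_pts = as.integer(balance_pts),
                 gait_pts = as.integer(gait_pts),
                 chair_pts = as.integer(chair_pts),
                 composite = composite,
                 category = as.character(category))
}

#' Timed Up and Go band
#'
#' Under 10 s is within normal limits; 10-20 s indicates the onset of
#' functional decline; the `impaired` label for times above 20 s is this
#' package's extension of the published bands.
#'
#' @param t_s TUG time in seconds (vectorized).
#' @return Character: `"normal"`, `"onset_decline"` or `"impaired"`.
#' @export
tug_category <- function(t_s) {
  .check_time(t_s, "TUG time")
  ifelse(t_s < 10, "normal",
  ifelse(t_s <= 20, "onset_decline", "impaired"))
}

#' Score a physical-performance table
#'
#' Adds SPPB component/composite scores and the TUG band to a physical
#' record table (as produced by [generate_physical()] or read from the
#' exported CSV).
#'
#' @param physical Tibble with `balance_side_s, balance_semitandem_s,
#'   balance_tandem_s, gait4m_s, chair5_s, tug_s` and optional
#'   `able_gait`, `able_chair` flags.
#' @return The input with `sppb_balance, sppb_gait, sppb_chair,
#'   sppb_composite, sppb_category, tug_band` appended.
#' @export
score_physical_table <- function(physical) {
  able_gait <- if ("able_gait" %in% names(physical)) physical$able_gait else TRUE
  able_chair <- if ("able_chair" %in% names(physical)) physical$able_chair else TRUE
  bal <- sppb_balance_score(physical$balance_side_s,
                            physical$balance_semitandem_s,
                            physical$balance_tandem_s)
  gait <- sppb_gait_score(physical$gait4m_s, able_gait)
  chair <- sppb_chair_score(physical$chair5_s, able_chair)
  comp <- sppb_composite(bal, gait, chair)
  physical$sppb_balance <- comp$balance_pts
  physical$sppb_gait <- comp$gait_pts
  physical$sppb_chair <- comp$chair_pts
  physical$sppb_composite <- comp$composite
  physical$sppb_category <- comp$category
  physical$tug_band <- tug_category(physical$tug_s)
  physical
}
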