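# Trajectory renderers: construct raw pen-stream recordings whose
# extracted features hit prescribed targets, and synthetic
# intersecting-polygon drawings with known ground truth. Both consume
# the current RNG stream; seed upstream for reproducibility.

#' Render a recording hitting kinematic feature targets
#'
#' Builds a 100 Hz recording whose extracted `time_down` and
#' `time_on_air` land within one sampling interval (10 ms) of the
#' targets and whose mean pressure and mean speed land within 5%.
#' Every inter-sample step has the same path length (a random-walk
#' heading), so per-interval speed is constant up to integer-rounding
#' of device coordinates; pressure is constant over pen-down samples
#' and 0 while up.
#'
#' @param participant_id Identifier stored in the recording.
#' @param task_id Task number 1..10.
#' @param targets List with `time_down` and `time_on_air` (ms),
#'   `mean_pressure` (au), `mean_speed` (mm/s); optional `n_gaps`
#'   (number of pen-up gaps the air time is split across).
#' @param units_per_mm Device resolution (default 200, matching
#'   [kinematics_config()]).
#' @param dt_ms Sampling interval (default 10 ms).
#' @return A [task_recording()].
#' @export
render_task_recording <- function(participant_id, task_id, targets,
                                  units_per_mm = 200, dt_ms = 10) {
  req <- c("time_down", "time_on_air", "mean_pressure", "mean_speed")
  if (!all(req %in% names(targets))) {
    stop("targets must include ", paste(req, collapse = ", "))
  }
  tgt <- lapply(targets[req], as.numeric)
  if (any(vapply(tgt, function(v) is.na(v) || v < 0, logical(1)))) {
    stop("infeasible targets: all targets must be non-negative")
  }
  n_down <- round(tgt$time_down / dt_ms)
  n_up <- round(tgt$time_on_air / dt_ms)
  if (n_down + n_up == 0L) n_down <- 1L   # degenerate: minimal dot

  # keep every pen-up gap under the default 1000 ms air cap
  max_gap_int <- floor(1000 / dt_ms)
  n_gaps <- if (n_up == 0L) 0L else max(
    if (!is.null(targets$n_gaps)) as.integer(targets$n_gaps) else 1L,
    ceiling(n_up / max_gap_int)
  )

  # interval status sequence: down blocks interleaved with up gaps
  if (n_gaps == 0L) {
    st_int <- rep(1L, n_down)
  } else {
    up_sizes <- diff(round(seq(0, n_up, length.out = n_gaps + 1L)))
    down_sizes <- diff(round(seq(0, n_down, length.out = n_gaps + 2L)))
    st_int <- integer(0)
    for (g in seq_len(n_gaps)) {
      st_int <- c(st_int, rep(1L, down_sizes[g]), rep(0L, up_sizes[g]))
    }
    st_int <- c(st_int, rep(1L, down_sizes[n_gaps + 1L]))
  }
  n_int <- length(st_int)
  status <- c(st_int, 1L)               # sample status; final sample down

  step_units <- tgt$mean_speed * (dt_ms / 1000) * units_per_mm
  heading <- cumsum(runif(n_int, -pi / 6, pi / 6)) + runif(1, 0, 2 * pi)
  x <- round(50000 + cumsum(c(0, step_units * cos(heading))))
  y <- round(50000 + cumsum(c(0, step_units * sin(heading))))

  samples <- data.frame(
    x = pmax(x, 0), y = pmax(y, 0),
    t = seq(0, by = dt_ms, length.out = n_int + 1L),
    status = status,
    azimuth = 180L, altitude = 45L,
    pressure = status * round(tgt$mean_pressure)
  )
  task_recording(samples, task_id, participant_id)
}

# vertices of a (possibly radius-jittered) regular polygon, mm
.polygon_vertices <- function(n_sides, center, radius, rotation_deg = 90,
                              jitter_frac = 0) {
  if (n_sides < 3L) stop("side count must be >= 3")
  ang <- (rotation_deg + 360 * (seq_len(n_sides) - 1L) / n_sides) * pi / 180
  r <- radius * (1 + jitter_frac * runif(n_sides, -1, 1))
  cbind(x = center[1] + r * cos(ang), y = center[2] + r * sin(ang))
}

#' Render a two-polygon copy-task drawing with known ground truth
#'
#' Traces each polygon as one closed pen-down stroke of straight
#' segments (sampled at 100 Hz), with a pen-up transit between the two
#' figures. With the defaults (two regular pentagons, 20 mm radius,
#' centers 30 mm apart, no jitter) the figures partially intersect and
#' the drawing passes the pentagon-copy criteria.
#'
#' @param spec List with `sides` (length-2 integer, default `c(5, 5)`),
#'   `centers` (list of two xy pairs, mm), `radii` (length 2, mm),
#'   `rotation_deg` (length 2), `jitter_frac` (radial vertex jitter as a
#'   fraction of the radius, default 0) and `points_per_side`
#'   (default 20).
#' @param participant_id,units_per_mm,dt_ms,pressure Rendering details.
#' @return A [task_recording()] (task 1) with attribute
#'   `"truth_polygons"`: the two generating vertex matrices in the same
#'   mm frame the scorer works in.
#' @export
render_intersecting_pentagons <- function(spec = list(),
                                          participant_id = "anon",
                                          units_per_mm = 200, dt_ms = 10,
                                          pressure = 10000) {
  defaults <- list(sides = c(5L, 5L),
                   centers = list(c(0, 0), c(30, 0)),
                   radii = c(20, 20),
                   rotation_deg = c(90, 90),
                   jitter_frac = 0,
                   points_per_side = 20L)
  for (nm in names(spec)) defaults[[nm]] <- spec[[nm]]
  spec <- defaults
  if (any(spec$sides < 3L)) stop("side count must be >= 3")

  polys <- lapply(1:2, function(k) {
    .polygon_vertices(spec$sides[k], spec$centers[[k]], spec$radii[k],
                      spec$rotation_deg[k], spec$jitter_frac)
  })

  # shift everything into the positive quadrant with a 5 mm margin
  all_xy <- do.call(rbind, polys)
  shift <- pmax(5 - apply(all_xy, 2, min), 5)
  polys <- lapply(polys, function(v) sweep(v, 2, shift, "+"))

  trace_polygon <- function(v, pps) {
    vv <- rbind(v, v[1, , drop = FALSE])
    pts <- NULL
    for (k in seq_len(nrow(vv) - 1L)) {
      tt <- seq(0, 1, length.out = pps + 1L)[-(pps + 1L)]
      pts <- rbind(pts, cbind(vv[k, 1] + tt * (vv[k + 1, 1] - vv[k, 1]),
                              vv[k, 2] + tt * (vv[k + 1, 2] - vv[k, 2])))
    }
    rbind(pts, vv[1, , drop = FALSE])   # close the stroke
  }
  p1 <- trace_polygon(polys[[1]], spec$points_per_side)
  p2 <- trace_polygon(polys[[2]], spec$points_per_side)
  n_transit <- 5L
  tt <- seq(0, 1, length.out = n_transit + 2L)[2:(n_transit + 1L)]
  transit <- cbind(p1[nrow(p1), 1] + tt * (p2[1, 1] - p1[nrow(p1), 1]),
                   p1[nrow(p1), 2] + tt * (p2[1, 2] - p1[nrow(p1), 2]))

  xy_mm <- rbind(p1, transit, p2)
  status <- c(rep(1L, nrow(p1)), rep(0L, n_transit), rep(1L, nrow(p2)))
  samples <- data.frame(
    x = pmax(round(xy_mm[, 1] * units_per_mm), 0),
    y = pmax(round(xy_mm[, 2] * units_per_mm), 0),
    t = seq(0, by = dt_ms, length.out = nrow(xy_mm)),
    status = status,
    azimuth = 180L, altitude = 45L,
    pressure = status * pressure
  )
  rec <- task_recording(samples, task_id = 1L, participant_id)
  attr(rec, "truth_polygons") <- polys
  rec
}
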