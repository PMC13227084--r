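# Automated binary scoring of the intersecting-pentagons copy task:
# a drawing passes (score 1) iff it contains exactly two closed
# polygons, each with five sides, whose interiors partially overlap.
# The source study scored drawings manually; the geometric procedure
# here (farthest-point simplification, closure tolerance, collinearity
# merge, partial-overlap rule) is this package's own operationalization
# of those criteria, calibrated on synthetic fixtures.

#' Scoring configuration for the pentagon-copy task
#'
#' @param units_per_mm Device-to-mm conversion (default 200).
#' @param closure_tol_mm Stroke endpoints within this distance are
#'   considered joined / a path is considered closed (default 3 mm).
#' @param simplify_tol_mm Farthest-point simplification tolerance used
#'   for vertex recovery (default 1 mm).
#' @param collinear_deg Consecutive segments turning by less than this
#'   are merged into one side (default 25 degrees).
#' @param min_overlap_frac Intersection area below this fraction of the
#'   smaller polygon's area does not count as overlap (default 1e-3).
#' @param containment_frac Intersection area above this fraction of the
#'   smaller polygon's area counts as one figure containing the other
#'   (default 0.99).
#' @export
scoring_config <- function(units_per_mm = 200, closure_tol_mm = 3,
                           simplify_tol_mm = 1, collinear_deg = 25,
                           min_overlap_frac = 1e-3,
                           containment_frac = 0.99) {
  structure(list(units_per_mm = units_per_mm,
                 closure_tol_mm = closure_tol_mm,
                 simplify_tol_mm = simplify_tol_mm,
                 collinear_deg = collinear_deg,
                 min_overlap_frac = min_overlap_frac,
                 containment_frac = containment_frac),
            class = "scoring_config")
}

# perpendicular distance from points to the segment (a, b)
.dist_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  tt <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((pts[, 1] - (a[1] + tt * ab[1]))^2 +
       (pts[, 2] - (a[2] + tt * ab[2]))^2)
}

#' Recursive farthest-point polyline simplification
#'
#' Ramer-Douglas-Peucker: keeps the endpoints and recursively retains
#' the point farthest from the current chord whenever that distance
#' exceeds `tolerance`, so every input point lies within `tolerance` of
#' the simplified chain.
#'
#' @param points Two-column matrix (x, y) with at least 2 rows.
#' @param tolerance Positive distance in the same units as `points`.
#' @return Simplified two-column matrix (subset of the input rows).
#' @export
simplify_path <- function(points, tolerance) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  if (!is.numeric(tolerance) || tolerance <= 0) stop("tolerance must be > 0")
  keep <- logical(nrow(points))
  keep[c(1L, nrow(points))] <- TRUE
  stack <- list(c(1L, nrow(points)))
  while (length(stack) > 0L) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- .dist_to_segment(points[mid, , drop = FALSE], points[i, ], points[j, ])
    dmax <- max(d)
    if (dmax > tolerance) {
      # earliest point within numerical tolerance of the maximum: a
      # deterministic tie-break when the chord runs parallel to an edge
      k <- which(d >= dmax - 1e-9 * (1 + dmax))[1]
      split <- mid[k]
      keep[split] <- TRUE
      stack <- c(stack, list(c(i, split)), list(c(split, j)))
    }
  }
  points[keep, , drop = FALSE]
}

# signed shoelace area (positive = counter-clockwise)
.signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Area of a simple polygon (shoelace formula)
#' @param v Two-column vertex matrix (unclosed).
#' @export
polygon_area <- function(v) abs(.signed_area(v))

# merge near-collinear consecutive sides of a closed vertex cycle
.merge_collinear <- function(v, collinear_deg) {
  repeat {
    n <- nrow(v)
    if (n < 3L) return(v)
    prev <- v[c(n, 1:(n - 1L)), , drop = FALSE]
    nxt <- v[c(2:n, 1L), , drop = FALSE]
    a <- v - prev
    b <- nxt - v
    turn <- abs(atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1],
                      a[, 1] * b[, 1] + a[, 2] * b[, 2])) * 180 / pi
    k <- which.min(turn)
    if (turn[k] >= collinear_deg) return(v)
    v <- v[-k, , drop = FALSE]
  }
}

#' Detect closed polygons in a pen-stream drawing
#'
#' Pen-down strokes are chained when one stroke ends within the closure
#' tolerance of where the next begins; a chain whose two free ends meet
#' within the same tolerance is a candidate closed polygon. Each
#' candidate is vertex-simplified ([simplify_path()]) and consecutive
#' near-collinear sides are merged; the closing segment counts as one
#' side.
#'
#' @param rec A [task_recording()].
#' @param cfg A [scoring_config()].
#' @return List of `polygon_shape` objects (fields `vertices` in mm,
#'   `closed`, `n_sides`); empty list for blank recordings.
#' @export
detect_closed_polygons <- function(rec, cfg = scoring_config()) {
  strokes <- segment_strokes(rec)
  down <- Filter(function(s) s$status == "down" && nrow(s$samples) >= 2L,
                 strokes)
  if (length(down) == 0L) return(list())
  paths <- lapply(down, function(s) {
    cbind(s$samples$x, s$samples$y) / cfg$units_per_mm
  })
  # chain strokes whose free ends meet within the closure tolerance
  chains <- list(paths[[1]])
  for (p in paths[-1]) {
    last <- chains[[length(chains)]]
    gap <- sqrt(sum((last[nrow(last), ] - p[1, ])^2))
    if (gap <= cfg$closure_tol_mm) {
      chains[[length(chains)]] <- rbind(last, p)
    } else {
      chains <- c(chains, list(p))
    }
  }
  polys <- list()
  for (ch in chains) {
    closure <- sqrt(sum((ch[1, ] - ch[nrow(ch), ])^2))
    if (closure > cfg$closure_tol_mm) next
    v <- simplify_path(ch, cfg$simplify_tol_mm)
    # drop the duplicated closing point, then merge around the cycle
    if (nrow(v) > 1L &&
        sqrt(sum((v[1, ] - v[nrow(v), ])^2)) <= cfg$closure_tol_mm) {
      v <- v[-nrow(v), , drop = FALSE]
    }
    v <- .merge_collinear(v, cfg$collinear_deg)
    if (nrow(v) < 2L || polygon_area(v) == 0) next
    polys <- c(polys, list(structure(
      list(vertices = v, closed = TRUE, n_sides = nrow(v)),
      class = "polygon_shape"
    )))
  }
  polys
}

#' Intersection area of two convex polygons
#'
#' Sutherland-Hodgman clipping of `a` against `b` followed by the
#' shoelace formula. The clip polygon `b` must be convex (the subject
#' may be mildly non-convex); vertices in any orientation.
#'
#' @param a,b Two-column vertex matrices (mm, unclosed).
#' @return Intersection area (same squared units).
#' @export
polygon_intersection_area <- function(a, b) {
  if (.signed_area(b) < 0) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  out <- a
  nb <- nrow(b)
  for (k in seq_len(nb)) {
    if (nrow(out) == 0L) return(0)
    p1 <- b[k, ]
    p2 <- b[if (k == nb) 1L else k + 1L, ]
    inside <- function(q) {
      (p2[1] - p1[1]) * (q[2] - p1[2]) - (p2[2] - p1[2]) * (q[1] - p1[1]) >= 0
    }
    isect <- function(q1, q2) {
      dc <- p1 - p2
      dp <- q1 - q2
      n1 <- p1[1] * p2[2] - p1[2] * p2[1]
      n2 <- q1[1] * q2[2] - q1[2] * q2[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c(n1 * dp[1] - n2 * dc[1], n1 * dp[2] - n2 * dc[2]) / den
    }
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    n_in <- nrow(inp)
    for (i in seq_len(n_in)) {
      cur <- inp[i, ]
      prv <- inp[if (i == 1L) n_in else i - 1L, ]
      if (inside(cur)) {
        if (!inside(prv)) out <- rbind(out, isect(prv, cur))
        out <- rbind(out, cur)
      } else if (inside(prv)) {
        out <- rbind(out, isect(prv, cur))
      }
    }
  }
  if (nrow(out) < 3L) return(0)
  polygon_area(out)
}

#' Score a pentagon-copy recording
#'
#' Applies the three published pass criteria to the detected polygons:
#' exactly two closed figures, five sides each, and a correctly
#' intersected region — operationalized as the two interiors overlapping
#' with positive area while neither figure entirely contains the other.
#' Figure rotation and tremor are disregarded (scoring is invariant
#' under rigid motion of the whole drawing).
#'
#' @param rec A [task_recording()] of the copy task (task 1).
#' @param cfg A [scoring_config()].
#' @return List of class `pentagon_score`: `score` (0/1),
#'   `n_polygons_found`, `sides_per_polygon`, `intersects_properly` and
#'   per-criterion `diagnostics`.
#' @export
score_pentagon <- function(rec, cfg = scoring_config()) {
  polys <- detect_closed_polygons(rec, cfg)
  n_found <- length(polys)
  sides <- vapply(polys, function(p) p$n_sides, integer(1))
  two_polygons <- n_found == 2L
  five_sides <- two_polygons && all(sides == 5L)
  intersects <- FALSE
  if (two_polygons) {
    a <- polys[[1]]$vertices
    b <- polys[[2]]$vertices
    area_int <- polygon_intersection_area(a, b)
    smaller <- min(polygon_area(a), polygon_area(b))
    intersects <- area_int > cfg$min_overlap_frac * smaller &&
      area_int < cfg$containment_frac * smaller
  }
  structure(list(
    score = as.integer(two_polygons && five_sides && intersects),
    n_polygons_found = n_found,
    sides_per_polygon = sides,
    intersects_properly = intersects,
    diagnostics = list(two_polygons = two_polygons,
                       five_sides_each = five_sides,
                       proper_intersection = intersects)
  ), class = "pentagon_score")
}

#' @export
print.pentagon_score <- function(x, ...) {
  cat(sprintf("<pentagon_score> score = %d (%d polygon(s), sides: %s, proper intersection: %s)\n",
              x$score, x$n_polygons_found,
              paste(x$sides_per_polygon, collapse = ","),
              x$intersects_properly))
  invisible(x)
}

#' Batch-score a directory of pentagon-copy recordings
#'
#' Scores every `*_T1.svc` file in `dir`.
#'
#' @param dir Directory of SVC files.
#' @param cfg A [scoring_config()].
#' @return Tibble with `participant_id`, `score` and diagnostics.
#' @export
score_pentagon_dir <- function(dir, cfg = scoring_config()) {
  files <- list.files(dir, pattern = "_T1\\.svc$", full.names = TRUE)
  rows <- lapply(files, function(f) {
    rec <- read_svc(f)
    sc <- score_pentagon(rec, cfg)
    tibble::tibble(participant_id = rec$participant_id,
                   score = sc$score,
                   n_polygons_found = sc$n_polygons_found,
                   intersects_properly = sc$intersects_properly)
  })
  do.call(rbind, rows)
}
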