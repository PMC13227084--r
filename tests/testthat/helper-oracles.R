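# Independent oracle implementations used to cross-check the package.
# These deliberately use straightforward loops / first-principles
# formulas and share no code with the implementation paths they verify.

# naive per-interval reference for the 8 kinematic features
reference_features <- function(rec, units_per_mm = 200, max_gap_ms = 1000,
                               speed_scope = "all_samples") {
  s <- rec$samples
  n <- nrow(s)
  out <- c(time_on_air = 0, time_down = 0, mean_pressure = 0,
           max_pressure = 0, mean_speed = 0, max_speed = 0,
           mean_acceleration = 0, max_acceleration = 0)
  down_p <- s$pressure[s$status == 1]
  if (length(down_p) > 0) {
    out["mean_pressure"] <- sum(down_p) / length(down_p)
    out["max_pressure"] <- max(down_p)
  }
  if (n < 2) return(out)
  v <- c(); vdt <- c()
  for (i in 1:(n - 1)) {
    dt <- s$t[i + 1] - s$t[i]
    if (s$status[i] == 1) {
      out["time_down"] <- out["time_down"] + dt
    } else {
      out["time_on_air"] <- out["time_on_air"] + min(dt, max_gap_ms)
    }
    in_scope <- dt > 0 && dt <= max_gap_ms &&
      (speed_scope == "all_samples" || s$status[i] == 1)
    if (in_scope) {
      d <- sqrt((s$x[i + 1] - s$x[i])^2 + (s$y[i + 1] - s$y[i])^2) / units_per_mm
      v <- c(v, d / (dt / 1000))
      vdt <- c(vdt, dt)
    }
  }
  if (length(v) > 0) {
    out["mean_speed"] <- sum(v) / length(v)
    out["max_speed"] <- max(v)
  }
  if (length(v) >= 2) {
    a <- c()
    for (k in 2:length(v)) a <- c(a, abs(v[k] - v[k - 1]) / (vdt[k] / 1000))
    out["mean_acceleration"] <- sum(a) / length(a)
    out["max_acceleration"] <- max(a)
  }
  out
}

# brute-force BH step-up adjusted p-values straight from the definition
reference_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in 1:m) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# normal-equations OLS for y ~ 1 + group + age + sex: beta, se of group
reference_ols_group <- function(y, g, age, s) {
  X <- cbind(1, g, age, s)
  XtX_inv <- solve(t(X) %*% X)
  b <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% b
  df <- length(y) - 4
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(XtX_inv))
  list(beta = unname(b[2]), se = unname(se[2]),
       p = unname(2 * pt(-abs(b[2] / se[2]), df)))
}

# grid-sampling classifier for two-polygon overlap ground truth:
# returns list(overlap = interiors share area, nested = one inside other).
# even-odd ray casting, vectorized over a regular point grid.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in 1:n) {
    crosses <- (v[i, 2] > py) != (v[j, 2] > py)
    xint <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) /
      (v[j, 2] - v[i, 2]) + v[i, 1]
    flip <- crosses & px < xint
    flip[is.na(flip)] <- FALSE
    inside <- xor(inside, flip)
    j <- i
  }
  inside
}

reference_overlap <- function(a, b, n_grid = 150) {
  all_v <- rbind(a, b)
  xs <- seq(min(all_v[, 1]), max(all_v[, 1]), length.out = n_grid)
  ys <- seq(min(all_v[, 2]), max(all_v[, 2]), length.out = n_grid)
  g <- expand.grid(x = xs, y = ys)
  ia <- points_in_polygon(g$x, g$y, a)
  ib <- points_in_polygon(g$x, g$y, b)
  n_both <- sum(ia & ib)
  list(overlap = n_both > 0,
       nested = n_both > 0 && n_both >= 0.99 * min(sum(ia), sum(ib)))
}

# random valid recording for property tests
random_recording <- function(n = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  status <- sample(c(0L, 1L), n, replace = TRUE)
  data.frame(
    x = sample(0:60000, n, replace = TRUE),
    y = sample(0:40000, n, replace = TRUE),
    t = cumsum(sample(c(5L, 10L, 10L, 10L, 15L, 200L), n, replace = TRUE)),
    status = status,
    azimuth = sample(0:359, n, replace = TRUE),
    altitude = sample(0:90, n, replace = TRUE),
    pressure = status * sample(0:23000, n, replace = TRUE)
  ) |> task_recording(task_id = sample(1:10, 1))
}
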