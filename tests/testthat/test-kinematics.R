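mk_rec <- function(x, y, t, status, pressure = NULL, task_id = 1L) {
  n <- length(t)
  if (is.null(pressure)) pressure <- status * 1000L
  task_recording(data.frame(x = x, y = y, t = t, status = status,
                            azimuth = 0L, altitude = 0L,
                            pressure = pressure), task_id = task_id)
}

test_that("stroke segmentation returns maximal runs with attributed durations", {
  rec <- mk_rec(1:3, 1:3, c(0, 10, 20), c(1L, 1L, 1L))
  st <- segment_strokes(rec)
  expect_length(st, 1L)
  expect_equal(st[[1]]$status, "down")
  expect_equal(st[[1]]$duration_ms, 20)

  # transition intervals go to the earlier sample's status
  rec <- mk_rec(1:3, 1:3, c(0, 10, 20), c(1L, 0L, 1L))
  st <- segment_strokes(rec)
  expect_equal(vapply(st, `[[`, "", "status"), c("down", "up", "down"))
  expect_equal(vapply(st, `[[`, 0, "duration_ms"), c(10, 10, 0))

  expect_equal(segment_strokes(task_recording(NULL)), list())
})

test_that("uniform motion yields exact times, speeds and zero acceleration", {
  cfg <- kinematics_config(units_per_mm = 1)
  rec <- mk_rec(x = c(0, 2, 4, 6), y = rep(0, 4), t = c(0, 10, 20, 30),
                status = rep(1L, 4), pressure = rep(500L, 4))
  fv <- extract_features(rec, cfg)
  expect_equal(fv[["time_down"]], 30)
  expect_equal(fv[["time_on_air"]], 0)
  expect_equal(fv[["mean_speed"]], 200)
  expect_equal(fv[["max_speed"]], 200)
  expect_equal(fv[["mean_acceleration"]], 0)
  expect_equal(fv[["mean_pressure"]], 500)
  expect_equal(fv[["max_pressure"]], 500)

  # stationary pen: zero speed
  rec <- mk_rec(rep(3, 4), rep(3, 4), c(0, 10, 20, 30), rep(1L, 4))
  fv <- extract_features(rec, cfg)
  expect_equal(fv[["mean_speed"]], 0)
  expect_equal(fv[["max_speed"]], 0)
})

test_that("degenerate recordings flag rather than fail", {
  rec <- mk_rec(1, 1, 0, 1L)
  fv <- extract_features(rec)
  expect_true("too_few_samples" %in% attr(fv, "flags"))
  expect_equal(fv[["mean_speed"]], 0)

  rec <- mk_rec(1:2, 1:2, c(0, 10), c(0L, 0L), pressure = c(0L, 0L))
  fv <- extract_features(rec)
  expect_true("no_down_samples" %in% attr(fv, "flags"))
  expect_equal(fv[["mean_pressure"]], 0)
})

test_that("a 200-sample randomized fixture matches the reference loop", {
  set.seed(314)
  rec <- random_recording(n = 200)
  fv <- extract_features(rec, kinematics_config())
  ref <- reference_features(rec)
  expect_equal(as.numeric(fv), as.numeric(ref[feature_names()]),
               tolerance = 1e-9)
})

test_that("extractor matches the reference loop across random recordings and scopes", {
  set.seed(42)
  for (k in 1:100) {
    rec <- random_recording(n = sample(2:120, 1))
    scope <- sample(c("all_samples", "down_only"), 1)
    cfg <- kinematics_config(speed_scope = scope)
    fv <- extract_features(rec, cfg)
    ref <- reference_features(rec, speed_scope = scope)
    expect_equal(as.numeric(fv), as.numeric(ref[feature_names()]),
                 tolerance = 1e-9)
  }
})

test_that("doubling units_per_mm halves speed/acceleration and fixes time/pressure", {
  set.seed(5)
  rec <- random_recording(n = 150)
  f1 <- extract_features(rec, kinematics_config(units_per_mm = 200))
  f2 <- extract_features(rec, kinematics_config(units_per_mm = 400))
  kin <- c("mean_speed", "max_speed", "mean_acceleration", "max_acceleration")
  other <- setdiff(feature_names(), kin)
  expect_equal(as.numeric(f1[kin]) / 2, as.numeric(f2[kin]))
  expect_equal(f1[other], f2[other])
})

test_that("time down + time on air partitions the span when no gap is capped", {
  set.seed(8)
  for (k in 1:20) {
    n <- sample(2:100, 1)
    status <- sample(c(0L, 1L), n, replace = TRUE)
    rec <- mk_rec(seq_len(n), seq_len(n),
                  cumsum(sample(5:30, n, replace = TRUE)), status)
    fv <- extract_features(rec)
    span <- rec$samples$t[n] - rec$samples$t[1]
    expect_equal(fv[["time_down"]] + fv[["time_on_air"]], span)
  }
})

test_that("re-sorting an already sorted recording changes nothing", {
  set.seed(9)
  rec <- random_recording(n = 80)
  rec2 <- rec
  rec2$samples <- rec2$samples[order(rec2$samples$t), ]
  rownames(rec2$samples) <- NULL
  expect_equal(extract_features(rec2), extract_features(rec))
})

test_that("feature table has the 80-variable schema and propagates missingness", {
  parts <- tibble::tibble(participant_id = c("A", "B"),
                          age = c(65, 70), sex = c("female", "male"),
                          group = c("normal", "altered"))
  set.seed(3)
  recs <- lapply(1:10, function(task) {
    render_task_recording("A", task, list(time_down = 200, time_on_air = 100,
                                          mean_pressure = 900,
                                          mean_speed = 10))
  })
  cohort <- list(participants = parts,
                 recordings = list(A = recs, B = recs[-7]))
  tab <- build_feature_table(cohort)
  expect_equal(dim(tab), c(2L, 84L))
  expect_identical(names(tab)[1:4],
                   c("participant_id", "age", "sex", "group"))
  expect_identical(setdiff(names(tab), c("participant_id", "age", "sex", "group")),
                   handwriting_variable_names())
  t7_cols <- paste0("T7_", feature_names())
  expect_equal(sum(is.na(tab[tab$participant_id == "B", t7_cols])), 8L)
  expect_false(anyNA(tab[tab$participant_id == "A", ]))

  # feature-tier cohorts pass through with the identical schema
  co <- generate_cohort(cohort_config(n_normal = 3, n_altered = 3, seed = 1))
  expect_identical(names(build_feature_table(co)), names(tab))

  cohort$participants$participant_id <- c("A", "A")
  expect_error(build_feature_table(cohort), "duplicate")
})

test_that("unsorted input is a hard error for feature extraction", {
  rec <- mk_rec(1:3, 1:3, c(0, 10, 20), rep(1L, 3))
  rec$samples$t <- c(20, 10, 0)   # bypass constructor check
  expect_error(extract_features(rec), "unsorted")
})
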