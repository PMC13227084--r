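test_that("noise-free degenerate config reproduces the configured mean exactly", {
  hp <- default_handwriting_params()
  hp$mu_normal <- 100; hp$mu_altered <- 100
  hp$sigma_normal <- 0; hp$sigma_altered <- 0
  cfg <- cohort_config(n_normal = 5, n_altered = 5,
                       handwriting_params = hp, seed = 3)
  co <- generate_cohort(cfg)
  vals <- as.matrix(co$feature_table[, handwriting_variable_names()])
  expect_true(all(vals == 100))
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  c1 <- generate_cohort(cohort_config(n_normal = 10, n_altered = 10, seed = 7),
                        tier = "both")
  c2 <- generate_cohort(cohort_config(n_normal = 10, n_altered = 10, seed = 7),
                        tier = "both")
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$feature_table, c2$feature_table)
  expect_identical(c1$physical, c2$physical)
  expect_identical(c1$recordings, c2$recordings)
  c3 <- generate_cohort(cohort_config(n_normal = 10, n_altered = 10, seed = 8))
  expect_false(identical(c1$feature_table, c3$feature_table))
})

test_that("cohort structure honours the configured study conditions", {
  co <- generate_cohort(cohort_config(seed = 5))
  p <- co$participants
  expect_equal(sum(p$group == "normal"), 93L)
  expect_equal(sum(p$group == "altered"), 81L)
  expect_true(all(p$age >= 60))
  expect_true(all(p$sex %in% c("male", "female")))
  # altered group older on average (3.3-year configured gap, sd ~6/sqrt(n))
  expect_gt(mean(p$age[p$group == "altered"]),
            mean(p$age[p$group == "normal"]))
})

test_that("group-wise sample means track the configured values within 3 SE", {
  co <- generate_cohort(cohort_config(seed = 42))
  ft <- co$feature_table
  hp <- default_handwriting_params()
  row <- hp[hp$variable == "T1_time_down", ]
  m_n <- mean(ft$T1_time_down[ft$group == "normal"])
  m_a <- mean(ft$T1_time_down[ft$group == "altered"])
  expect_lt(abs(m_n - row$mu_normal), 3 * row$sigma_normal / sqrt(93))
  expect_lt(abs(m_a - row$mu_altered), 3 * row$sigma_altered / sqrt(81))
})

test_that("rendered recordings hit the kinematic targets within tolerance", {
  set.seed(21)
  cfg <- kinematics_config()
  # forced single-stroke layout: 300 ms down, no air -> 31 samples all down
  r <- render_task_recording("p", 1, list(time_down = 300, time_on_air = 0,
                                          mean_pressure = 4000,
                                          mean_speed = 10))
  expect_equal(nrow(r$samples), 31L)
  expect_true(all(r$samples$status == 1))

  # mean speed target over 1 s
  r <- render_task_recording("p", 4, list(time_down = 1000, time_on_air = 0,
                                          mean_pressure = 4000,
                                          mean_speed = 20))
  fv <- extract_features(r, cfg)
  expect_true(fv[["mean_speed"]] >= 19 && fv[["mean_speed"]] <= 21)

  # air time split across two pen-up gaps
  r <- render_task_recording("p", 8, list(time_down = 800, time_on_air = 500,
                                          mean_pressure = 4000,
                                          mean_speed = 20, n_gaps = 2))
  fv <- extract_features(r, cfg)
  expect_true(fv[["time_on_air"]] >= 490 && fv[["time_on_air"]] <= 510)
  expect_true(all(r$samples$pressure[r$samples$status == 0] == 0))

  # generic targets within documented tolerances
  for (k in 1:10) {
    tgt <- list(time_down = sample(200:4000, 1),
                time_on_air = sample(0:3000, 1),
                mean_pressure = sample(1000:20000, 1),
                mean_speed = runif(1, 5, 80))
    r <- render_task_recording("p", sample(1:10, 1), tgt)
    fv <- extract_features(r, cfg)
    expect_lte(abs(fv[["time_down"]] - tgt$time_down), 10)
    expect_lte(abs(fv[["time_on_air"]] - tgt$time_on_air), 10)
    expect_lte(abs(fv[["mean_pressure"]] - tgt$mean_pressure),
               0.05 * tgt$mean_pressure)
    expect_lte(abs(fv[["mean_speed"]] - tgt$mean_speed),
               0.05 * tgt$mean_speed)
  }
  expect_error(render_task_recording("p", 1, list(time_down = -5,
                                                  time_on_air = 0,
                                                  mean_pressure = 1,
                                                  mean_speed = 1)),
               "infeasible")
})

test_that("rendered two-polygon drawings carry their ground truth", {
  set.seed(2)
  rec <- render_intersecting_pentagons()
  expect_s3_class(rec, "task_recording")
  expect_equal(rec$task_id, 1L)
  truth <- attr(rec, "truth_polygons")
  expect_length(truth, 2L)
  expect_equal(nrow(truth[[1]]), 5L)
  expect_equal(score_pentagon(rec)$score, 1L)

  # square + pentagon violates the five-sides criterion
  rec <- render_intersecting_pentagons(list(sides = c(4L, 5L)))
  expect_equal(score_pentagon(rec)$score, 0L)

  # disjoint figures: exact intersection of the generating vertices is 0
  rec <- render_intersecting_pentagons(list(centers = list(c(0, 0), c(100, 0))))
  truth <- attr(rec, "truth_polygons")
  expect_equal(polygon_intersection_area(truth[[1]], truth[[2]]), 0)
  expect_equal(score_pentagon(rec)$score, 0L)

  expect_error(render_intersecting_pentagons(list(sides = c(2L, 5L))),
               ">= 3")
})

test_that("physical records follow the generative model and stay in range", {
  parts <- tibble::tibble(participant_id = c("A", "B", "C"),
                          age = c(70, 70, 70),
                          sex = c("male", "male", "male"),
                          group = c("normal", "altered", "normal"))
  pp <- default_physical_params()
  pp$sigma <- 0
  pp$mu[pp$variable == "tug_s"] <- 9
  cfg <- cohort_config(physical_params = pp, seed = 1)
  phys <- generate_physical(parts, cfg)
  expect_true(all(phys$tug_s == 9))
  expect_true(all(tug_category(phys$tug_s) == "normal"))

  set.seed(10)
  phys <- generate_physical(generate_cohort(cohort_config(seed = 10))$participants,
                            cohort_config())
  num <- phys[vapply(phys, is.numeric, logical(1))]
  expect_true(all(is.finite(as.matrix(num))))
  expect_true(all(as.matrix(num) >= 0))
  expect_true(all(phys$balance_side_s <= 10))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_normal = 0), "> 0")
  expect_error(cohort_config(age_sd = c(0, 5)), "> 0")
  expect_error(cohort_config(sex_prop_female = 1.2), "\\[0, 1\\]")
  hp <- default_handwriting_params(); hp$sigma_normal[1] <- -1
  expect_error(cohort_config(handwriting_params = hp), ">= 0")
})
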