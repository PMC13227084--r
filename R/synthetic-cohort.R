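# Seeded synthetic cohort generator. Emulates the study conditions the
# analysis pipeline assumes: 93 participants with normal and 81 with
# altered pentagon-copy performance, the altered group older on average,
# 80 handwriting variables with group-specific means/SDs seeded from the
# published summary tables, and physical-performance measures whose
# group differences arise only through the age confound.

#' Default per-variable generating parameters for handwriting outcomes
#'
#' One row per handwriting variable with the group means and SDs
#' (defaults taken from [printed_handwriting_stats()]) and the age/sex
#' slopes (default 0, so configured group means are also the marginal
#' group means).
#'
#' `log_scale` defaults to `TRUE` for variables where a Gaussian noise
#' model with the published SD would put more than 1% of its mass below
#' zero: these are inherently positive, right-skewed measures (short
#' contact times, pressures), and for them the generator draws from a
#' lognormal whose moments are matched to the published group mean and
#' SD instead of clipping a normal at zero.
#'
#' @return Tibble with columns `variable, mu_normal, mu_altered,
#'   sigma_normal, sigma_altered, b_age, b_sex, log_scale`.
#' @export
default_handwriting_params <- function() {
  p <- printed_handwriting_stats()
  tibble::tibble(
    variable = p$variable,
    mu_normal = p$mean_normal,
    mu_altered = p$mean_altered,
    sigma_normal = p$sd_normal,
    sigma_altered = p$sd_altered,
    b_age = 0,
    b_sex = 0,
    log_scale = pmax(pnorm(0, p$mean_normal, p$sd_normal),
                     pnorm(0, p$mean_altered, p$sd_altered)) > 0.01
  )
}

#' Default generating parameters for physical-performance outcomes
#'
#' Plausible community-dwelling older-adult values chosen for the
#' simulator (the source cohort's physical summary table is not
#' reproduced here). The direct group effect is zero for every variable;
#' age slopes are nonzero, so unadjusted group differences arise only
#' through the older age of the altered group and vanish under
#' age/sex adjustment.
#'
#' @return Tibble with columns `variable, mu, sigma, b_age, b_sex,
#'   b_group, upper` (upper = hard cap, e.g. 10 s balance holds).
#' @export
default_physical_params <- function() {
  tibble::tribble(
    ~variable,               ~mu,  ~sigma, ~b_age, ~b_sex, ~b_group, ~upper,
    "grip_kg",                33,     8,   -0.35,   -10,     0,      Inf,
    "arm_curl_reps",          15,     4,   -0.15,    -2,     0,      Inf,
    "midthigh_pull_N",       520,   150,   -6.0,   -120,     0,      Inf,
    "cmj_height_cm",          13,     4,   -0.25,    -3,     0,      Inf,
    "cmj_flight_ms",         325,    50,   -3.0,    -30,     0,      Inf,
    "cmj_power_wkg",          24,     6,   -0.35,    -4,     0,      Inf,
    "walk6_m",               495,    90,   -4.0,    -30,     0,      Inf,
    "vo2peak_ml_kg_min",      19,     5,   -0.20,  -2.5,     0,      Inf,
    "tug_s",                 9.0,   2.5,    0.12,   0.3,     0,      Inf,
    "walk400_s",             325,    60,    3.0,     15,     0,      Inf,
    "gait4m_s",              4.1,   1.0,    0.05,   0.2,     0,      Inf,
    "chair5_s",             12.3,   3.5,    0.15,   0.5,     0,      Inf,
    "balance_side_s",        9.8,   1.0,   -0.05,     0,     0,       10,
    "balance_semitandem_s",  9.4,   1.8,   -0.08,     0,     0,       10,
    "balance_tandem_s",      8.0,   3.0,   -0.15,     0,     0,       10,
    "cop_velocity_mms",       11,     4,    0.15,     0,     0,      Inf,
    "cop_velocity_ap_mms",   7.5,     3,    0.10,     0,     0,      Inf,
    "cop_velocity_ml_mms",   6.5,     3,    0.10,     0,     0,      Inf,
    "cop_freq_ap_hz",       0.50,  0.20,  0.005,     0,     0,      Inf,
    "cop_freq_ml_hz",       0.45,  0.20,  0.005,     0,     0,      Inf,
    "cop_displacement_mm",   5.7,     2,    0.08,     0,     0,      Inf
  )
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions: 93 normal / 81 altered
#' participants, group mean ages 69.6 (SD 5.9) and 72.9 (SD 5.6) years
#' truncated at the 60-year inclusion bound, 108/174 women, and
#' handwriting outcome means/SDs from the published summary tables.
#' Outcomes follow `y = mu_group + b_age * (age - 70) + b_sex * female
#' + e`, `e ~ N(0, sigma_group^2)`, optionally on the log scale, and are
#' clipped at zero (clip counts recorded in the cohort truth).
#'
#' @param n_normal,n_altered Group sizes.
#' @param age_mean,age_sd Length-2 numeric, `c(normal, altered)`.
#' @param age_lower Truncation bound (inclusion criterion, 60 years).
#' @param sex_prop_female Marginal probability of female.
#' @param handwriting_params,physical_params Parameter tibbles; see
#'   [default_handwriting_params()], [default_physical_params()].
#' @param seed Integer seed; every generator consumes this stream.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_normal = 93L, n_altered = 81L,
                          age_mean = c(69.6, 72.9),
                          age_sd = c(5.9, 5.6),
                          age_lower = 60,
                          sex_prop_female = 108 / 174,
                          handwriting_params = default_handwriting_params(),
                          physical_params = default_physical_params(),
                          seed = 1L) {
  if (n_normal <= 0L || n_altered <= 0L) stop("group sizes must be > 0")
  if (any(age_sd <= 0)) stop("age SDs must be > 0")
  if (any(handwriting_params$sigma_normal < 0) ||
      any(handwriting_params$sigma_altered < 0) ||
      any(physical_params$sigma < 0)) {
    stop("outcome SDs must be >= 0")
  }
  if (sex_prop_female < 0 || sex_prop_female > 1) {
    stop("sex_prop_female must be in [0, 1]")
  }
  structure(list(
    n_normal = as.integer(n_normal), n_altered = as.integer(n_altered),
    age_mean = age_mean, age_sd = age_sd, age_lower = age_lower,
    sex_prop_female = sex_prop_female,
    handwriting_params = handwriting_params,
    physical_params = physical_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# inverse-CDF draw from a normal truncated below at `lower`
.rtruncnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- pnorm(lower, mean, sd)
  qnorm(p_lo + runif(n) * (1 - p_lo), mean, sd)
}

.linear_outcome <- function(n, mu, sigma, b_age, b_sex, age, female,
                            log_scale = FALSE, upper = Inf) {
  y <- mu + b_age * (age - 70) + b_sex * female + rnorm(n, 0, sigma)
  if (log_scale) y <- exp(y)
  clipped <- sum(y < 0)
  y <- pmin(pmax(y, 0), upper)
  attr(y, "n_clipped") <- clipped
  y
}

#' Generate a seeded synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param tier `"features"` draws the 80 handwriting variables directly
#'   from the outcome model; `"trajectories"` additionally renders a pen
#'   recording per participant and task whose extracted temporal,
#'   pressure and mean-speed features hit the drawn values;
#'   `"both"` does both.
#' @return List of class `cohort` with `participants` (tibble),
#'   `feature_table`, `recordings` (named by participant, or `NULL`),
#'   `physical` (tibble) and `truth` (generating parameters plus clip
#'   counts) — enough to recompute expected group contrasts analytically.
#' @export
generate_cohort <- function(config = cohort_config(),
                            tier = c("features", "trajectories", "both")) {
  tier <- match.arg(tier)
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  n <- config$n_normal + config$n_altered
  group <- rep(c("normal", "altered"), c(config$n_normal, config$n_altered))
  gi <- as.integer(group == "altered") + 1L   # index into group-wise params
  age <- .rtruncnorm_lower(n, config$age_mean[gi], config$age_sd[gi],
                           config$age_lower)
  sex <- ifelse(runif(n) < config$sex_prop_female, "female", "male")
  participants <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = age, sex = sex, group = group
  )
  female <- as.integer(sex == "female")

  hp <- config$handwriting_params
  feat <- matrix(NA_real_, nrow = n, ncol = nrow(hp),
                 dimnames = list(NULL, hp$variable))
  clip_counts <- setNames(integer(nrow(hp)), hp$variable)
  for (j in seq_len(nrow(hp))) {
    mu <- ifelse(group == "altered", hp$mu_altered[j], hp$mu_normal[j])
    sigma <- ifelse(group == "altered", hp$sigma_altered[j], hp$sigma_normal[j])
    shift <- hp$b_age[j] * (age - 70) + hp$b_sex[j] * female
    if (hp$log_scale[j] && all(mu > 0)) {
      # lognormal with moments matched to the configured mean and SD;
      # covariate shifts act on the log scale
      sdlog <- sqrt(log(1 + (sigma / mu)^2))
      y <- mu * exp(shift - sdlog^2 / 2 + rnorm(n, 0, sdlog))
    } else {
      y <- mu + shift + rnorm(n, 0, sigma)
    }
    clip_counts[j] <- sum(y < 0)
    feat[, j] <- pmax(y, 0)
  }
  feature_table <- tibble::as_tibble(
    cbind(participants, as.data.frame(feat))
  )

  physical <- generate_physical(participants, config)

  recordings <- NULL
  if (tier %in% c("trajectories", "both")) {
    recordings <- setNames(vector("list", n), participants$participant_id)
    for (i in seq_len(n)) {
      recs <- vector("list", 10L)
      for (task in 1:10) {
        tgt <- list(
          time_down = feat[i, sprintf("T%d_time_down", task)],
          time_on_air = feat[i, sprintf("T%d_time_on_air", task)],
          mean_pressure = feat[i, sprintf("T%d_mean_pressure", task)],
          mean_speed = feat[i, sprintf("T%d_mean_speed", task)]
        )
        recs[[task]] <- render_task_recording(
          participants$participant_id[i], task, tgt
        )
      }
      recordings[[i]] <- recs
    }
  }

  structure(list(
    participants = participants,
    feature_table = feature_table,
    recordings = recordings,
    physical = physical,
    truth = list(config = config, clip_counts = clip_counts,
                 group_effects = setNames(hp$mu_altered - hp$mu_normal,
                                          hp$variable))
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("<cohort> %d participants (%d normal / %d altered), %d handwriting variables\n",
              nrow(x$participants), tab[["normal"]], tab[["altered"]],
              sum(grepl("^T[0-9]+_", names(x$feature_table)))))
  if (!is.null(x$recordings)) cat("  trajectory tier: rendered recordings present\n")
  invisible(x)
}

#' Generate physical-performance records for a set of participants
#'
#' Each measure follows the same linear generative form as the
#' handwriting outcomes. Uses the current RNG stream (seed once via
#' [generate_cohort()] or `set.seed()` for reproducibility).
#'
#' @param participants Tibble with `participant_id, age, sex, group`.
#' @param config A [cohort_config()] (its `physical_params` are used).
#' @return Tibble: `participant_id` plus one column per measure and
#'   `able_<component>` flags for gait and chair-stand tests.
#' @export
generate_physical <- function(participants, config = cohort_config()) {
  pp <- config$physical_params
  n <- nrow(participants)
  female <- as.integer(participants$sex == "female")
  altered <- as.integer(participants$group == "altered")
  out <- tibble::tibble(participant_id = participants$participant_id)
  for (j in seq_len(nrow(pp))) {
    y <- pp$mu[j] + pp$b_age[j] * (participants$age - 70) +
      pp$b_sex[j] * female + pp$b_group[j] * altered +
      rnorm(n, 0, pp$sigma[j])
    out[[pp$variable[j]]] <- pmin(pmax(y, 0), pp$upper[j])
  }
  out$able_gait <- TRUE
  out$able_chair <- TRUE
  out
}
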