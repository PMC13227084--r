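# Two-group comparison pipeline: unadjusted tests (Welch t or
# Mann-Whitney, chosen by per-group normality), age- and sex-adjusted
# linear models, optional log transform of nonnormal positive outcomes,
# Benjamini-Hochberg FDR over the variable family, and the category x
# feature significance-count matrix.

#' Analysis configuration
#'
#' @param alpha Significance level for the final p < alpha filter.
#' @param fdr_q FDR target (same scale; BH adjusted p compared to it).
#' @param family Which variables form the multiple-testing family:
#'   the 80 handwriting variables only (default), handwriting plus
#'   physical measures, or BH applied within each task category.
#' @param normality_alpha Shapiro-Wilk level for the per-group normality
#'   check and the transform decision.
#' @param transform Log-transform nonnormal positive outcomes before the
#'   adjusted model (coefficients then reported on the log scale with
#'   the `log_transformed` flag set).
#' @export
analysis_config <- function(alpha = 0.05, fdr_q = 0.05,
                            family = c("handwriting_only",
                                       "handwriting_plus_physical",
                                       "per_category"),
                            normality_alpha = 0.05,
                            transform = TRUE) {
  family <- match.arg(family)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alpha = alpha, fdr_q = fdr_q, family = family,
                 normality_alpha = normality_alpha, transform = transform),
            class = "analysis_config")
}

.as_binary <- function(x, one, what) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop(what, " must be 0/1 or a two-level factor")
    return(as.numeric(x))
  }
  as.numeric(x == one)
}

#' Age- and sex-adjusted group effect (ordinary least squares)
#'
#' Fits `y ~ group + age + sex` on complete cases and returns the group
#' coefficient with its standard error, t-based 95% CI and two-sided
#' p-value (df = n - 4). Group is coded altered = 1 and sex female = 1,
#' so a positive coefficient means a higher outcome in the altered
#' group. A residual variance of (numerically) zero flags the fit as
#' degenerate instead of reporting a spurious p-value.
#'
#' @param y Numeric outcome.
#' @param group Binary vector or factor (`"altered"` = 1).
#' @param age Numeric, years.
#' @param sex Binary vector or factor (`"female"` = 1).
#' @param conf_level CI level (default 0.95).
#' @return List: `beta, se, ci_low, ci_high, p, n_used, degenerate`.
#' @export
fit_adjusted <- function(y, group, age, sex, conf_level = 0.95) {
  g <- .as_binary(group, "altered", "group")
  s <- .as_binary(sex, "female", "sex")
  if (length(unique(c(length(y), length(g), length(age), length(s)))) != 1L) {
    stop("y, group, age, sex must have equal lengths")
  }
  cc <- complete.cases(y, g, age, s)
  y <- y[cc]; g <- g[cc]; age <- age[cc]; s <- s[cc]
  n <- length(y)
  if (n < 5L) stop("need at least 5 complete cases")
  if (length(unique(g)) < 2L) stop("group must have both levels")
  fit <- lm(y ~ g + age + s)
  if (fit$rank < 4L) stop("rank-deficient design")
  sm <- summary(fit)
  beta <- unname(coef(fit)["g"])
  se <- sm$coefficients["g", "Std. Error"]
  df <- fit$df.residual
  degenerate <- sm$sigma < sqrt(.Machine$double.eps) * max(1, abs(beta))
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  p <- if (degenerate) NA_real_ else 2 * pt(-abs(beta / se), df)
  list(beta = beta, se = se,
       ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
       p = p, n_used = n, degenerate = degenerate)
}

#' Unadjusted two-group test
#'
#' Shapiro-Wilk normality is checked in each group at
#' `normality_alpha`; if both groups look normal a Welch two-sample t
#' test is used, otherwise a Mann-Whitney U test (exact enumeration when
#' both groups have at most 8 untied observations, tie-corrected normal
#' approximation otherwise).
#'
#' @param y0,y1 Outcome values in the two groups.
#' @param normality_alpha Shapiro-Wilk level.
#' @param test `"auto"` (default) picks by normality; `"welch_t"` or
#'   `"mann_whitney"` force a choice.
#' @return List: `test` (`"welch_t"` or `"mann_whitney"`), `statistic`,
#'   `p`.
#' @export
unadjusted_test <- function(y0, y1, normality_alpha = 0.05,
                            test = c("auto", "welch_t", "mann_whitney")) {
  test <- match.arg(test)
  y0 <- y0[!is.na(y0)]; y1 <- y1[!is.na(y1)]
  if (length(y0) < 3L || length(y1) < 3L) {
    stop("each group needs at least 3 observations")
  }
  normal <- function(v) {
    if (length(v) > 5000L) v <- v[seq(1L, length(v), length.out = 5000L)]
    if (length(unique(v)) < 3L) return(FALSE)
    shapiro.test(v)$p.value > normality_alpha
  }
  if (test == "welch_t" ||
      (test == "auto" && normal(y0) && normal(y1))) {
    ht <- t.test(y1, y0, var.equal = FALSE)
    return(list(test = "welch_t", statistic = unname(ht$statistic),
                p = ht$p.value))
  }
  ties <- anyDuplicated(c(y0, y1)) > 0L
  exact <- length(y0) <= 8L && length(y1) <= 8L && !ties
  ht <- suppressWarnings(
    wilcox.test(y1, y0, exact = exact, correct = FALSE)
  )
  list(test = "mann_whitney", statistic = unname(ht$statistic),
       p = ht$p.value)
}

#' Pearson chi-square test for a contingency table
#'
#' Classical Pearson statistic (sum of (O-E)^2/E, no continuity
#' correction), df = (rows-1)(cols-1).
#'
#' @param table Matrix of non-negative integer counts.
#' @return List: `statistic, df, p`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column totals must be positive")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Log-transform an outcome when its distribution looks nonnormal
#'
#' Shapiro-Wilk at `normality_alpha` on the (centered) values; if
#' normality is rejected and every value is positive the natural log is
#' returned with the flag set. Nonnormal outcomes containing zeros or
#' negatives are returned untransformed with a warning flag.
#'
#' @param y Numeric outcome.
#' @param normality_alpha Test level.
#' @return List: `values, log_transformed, warning`.
#' @export
maybe_log_transform <- function(y, normality_alpha = 0.05) {
  yy <- y[!is.na(y)]
  nonnormal <- length(yy) >= 3L && length(unique(yy)) >= 3L &&
    shapiro.test(if (length(yy) > 5000L) yy[1:5000] else yy)$p.value <
      normality_alpha
  if (!nonnormal) {
    return(list(values = y, log_transformed = FALSE, warning = FALSE))
  }
  if (all(yy > 0)) {
    list(values = log(y), log_transformed = TRUE, warning = FALSE)
  } else {
    list(values = y, log_transformed = FALSE, warning = TRUE)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: on the sorted vector,
#' `adj_(i) = min(1, min_{j >= i} m p_(j) / j)`, mapped back to the
#' input order.
#'
#' @param p Vector of raw p-values in [0, 1].
#' @return Vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  scaled <- m * p[o] / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(scaled))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Run the full two-group comparison pipeline
#'
#' Per variable: group means/SDs on the original scale, transform
#' decision, unadjusted test (on the original scale), age- and
#' sex-adjusted linear model, then one BH pass over the configured
#' family; finally the category x feature significance-count matrix
#' over the handwriting variables.
#'
#' @param features Feature table (tibble with `participant_id, age, sex,
#'   group` and `T<task>_<feature>` columns).
#' @param physical Optional physical table sharing `participant_id`.
#' @param cfg An [analysis_config()].
#' @return List of class `analysis_result`: `results` (one row per
#'   variable) and `counts` (3 x 8 integer matrix).
#' @export
run_analysis <- function(features, physical = NULL,
                         cfg = analysis_config()) {
  hw_vars <- intersect(handwriting_variable_names(), names(features))
  if (length(hw_vars) == 0L) stop("no handwriting variables in the family")
  if (length(unique(features$group)) < 2L) stop("need both groups")

  dat <- features
  phys_vars <- character(0)
  if (!is.null(physical) && cfg$family == "handwriting_plus_physical") {
    phys_vars <- setdiff(names(physical)[vapply(physical, is.numeric,
                                                logical(1))],
                         "participant_id")
    dat <- merge(features, physical, by = "participant_id", sort = FALSE)
  }
  vars <- c(hw_vars, phys_vars)

  rows <- lapply(vars, function(v) {
    y <- dat[[v]]
    cc <- complete.cases(y, dat$group, dat$age, dat$sex)
    y_cc <- y[cc]
    grp <- dat$group[cc]
    g0 <- y_cc[grp == "normal"]; g1 <- y_cc[grp == "altered"]
    tr <- if (cfg$transform) maybe_log_transform(y_cc, cfg$normality_alpha)
          else list(values = y_cc, log_transformed = FALSE, warning = FALSE)
    un <- unadjusted_test(g0, g1, cfg$normality_alpha)
    ad <- fit_adjusted(tr$values, grp, dat$age[cc], dat$sex[cc])
    tibble::tibble(
      variable = v,
      mean_normal = mean(g0), sd_normal = sd(g0),
      mean_altered = mean(g1), sd_altered = sd(g1),
      beta = ad$beta, se = ad$se,
      ci_low = ad$ci_low, ci_high = ad$ci_high,
      p_raw = ad$p,
      test_unadjusted = un$test, p_unadjusted = un$p,
      log_transformed = tr$log_transformed,
      n_used = ad$n_used
    )
  })
  results <- do.call(rbind, rows)

  results$p_fdr <- NA_real_
  ok <- !is.na(results$p_raw)
  if (cfg$family == "per_category") {
    task <- as.integer(sub("^T([0-9]+)_.*$", "\\1", results$variable))
    cat_of <- ifelse(results$variable %in% hw_vars,
                     task_category(ifelse(is.na(task), 1L, task)), "physical")
    for (cg in unique(cat_of)) {
      sel <- ok & cat_of == cg
      if (any(sel)) results$p_fdr[sel] <- bh_adjust(results$p_raw[sel])
    }
  } else {
    results$p_fdr[ok] <- bh_adjust(results$p_raw[ok])
  }

  counts <- significance_count_matrix(results, alpha = cfg$alpha)
  structure(list(results = results, counts = counts,
                 config = cfg), class = "analysis_result")
}

#' Category x feature significance-count matrix
#'
#' Tallies, per task category and feature, how many task-feature tests
#' have FDR-adjusted p below `alpha`.
#'
#' @param results Tibble with `variable` (handwriting names) and a
#'   p-value column.
#' @param alpha Threshold (default .05).
#' @param p_col Which column to filter on (default `"p_fdr"`).
#' @return 3 x 8 integer matrix (categories x features).
#' @export
significance_count_matrix <- function(results, alpha = 0.05,
                                      p_col = "p_fdr") {
  m <- matrix(0L, nrow = 3, ncol = 8,
              dimnames = list(c("cognitive", "fine_motor", "mechanical"),
                              feature_names()))
  hw <- results[grepl("^T[0-9]+_", results$variable), , drop = FALSE]
  if (nrow(hw) == 0L) return(m)
  task <- as.integer(sub("^T([0-9]+)_.*$", "\\1", hw$variable))
  feature <- sub("^T[0-9]+_", "", hw$variable)
  sig <- !is.na(hw[[p_col]]) & hw[[p_col]] < alpha
  for (i in which(sig)) {
    m[task_category(task[i]), feature[i]] <-
      m[task_category(task[i]), feature[i]] + 1L
  }
  m
}

#' @export
print.analysis_result <- function(x, ...) {
  n_sig <- sum(!is.na(x$results$p_fdr) & x$results$p_fdr < x$config$alpha)
  cat(sprintf("<analysis_result> %d variables, %d significant after FDR (alpha = %.2f)\n",
              nrow(x$results), n_sig, x$config$alpha))
  print(x$counts)
  invisible(x)
}
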