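#' Cohort-level statistics
#'
#' The statistical layer mirrors a paired pre/post surgical design:
#' linear mixed-effects models with fixed effects time, skeletal class and
#' their interaction and a random subject intercept, reported as estimated
#' marginal means (EMMs) with 95% CIs; a paired Wilcoxon signed-rank
#' sensitivity analysis; an OLS model of per-subject metric change on the
#' surgical movement covariates; and two-way intraclass correlation
#' coefficients for method-error (repeatability) analysis.
#'
#' @name facemotion-stats
NULL

metric_columns <- c("magnitude", "shape_change", "shape_change_mm",
                    "symmetry", "time")

covariate_columns <- c(
  "sagittal_maxilla", "vertical_maxilla", "transversal_maxilla",
  "sagittal_mandibula", "vertical_mandibula", "transversal_mandibula",
  "roll_mmc", "pitch_mmc", "yaw_mmc"
)

check_cohort_table <- function(table, metric, expression) {
  need <- c("subject_id", "skeletal_class", "timepoint", "expression",
            metric)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cohort table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- table[table$expression == expression, , drop = FALSE]
  if (!nrow(df))
    stop(sprintf("no rows for expression '%s'", expression), call. = FALSE)
  # complete cases: keep subjects measured at both timepoints
  tp <- table(df$subject_id, df$timepoint)
  complete <- rownames(tp)[rowSums(tp[, c("T0", "T1"), drop = FALSE] >
                                     0L) == 2L]
  df <- df[df$subject_id %in% complete, , drop = FALSE]
  df$subject_id <- factor(df$subject_id)
  df$timepoint <- factor(df$timepoint, levels = c("T0", "T1"))
  df$skeletal_class <- factor(df$skeletal_class, levels = c("II", "III"))
  df
}

#' Fit the time-by-class mixed model and extract estimated marginal means
#'
#' Fits `metric ~ timepoint * skeletal_class + (1 | subject_id)` by REML
#' on the complete-case rows of one expression, and returns EMMs with 95%
#' CIs both pooled over class (the cohort-level table) and per class (the
#' subgroup table), plus the p-value of the time main effect (type-III
#' F-test, Satterthwaite degrees of freedom).
#'
#' A table that is exactly constant in the metric is handled without a
#' model fit: every EMM equals the constant, the time effect is 0 and the
#' p-value is NA (flagged `degenerate`).
#'
#' @param table cohort table: one row per subject x timepoint x expression
#'   with columns `subject_id`, `skeletal_class` (II/III), `timepoint`
#'   (T0/T1), `expression`, and the metric.
#' @param metric name of the metric column (`"magnitude"`, `"symmetry"`,
#'   `"time"`, `"shape_change"`, ...).
#' @param expression `"smile"` or `"lip_purse"`.
#' @return An `emm_result`: list with `pooled` and `by_class` data.frames
#'   (`emmean`, `lower`, `upper`), `p_time`, `n_subjects`, and the fitted
#'   model (`NULL` when degenerate).
#' @export
fit_time_class_model <- function(table, metric, expression) {
  df <- check_cohort_table(table, metric, expression)
  df$.y <- df[[metric]]
  n_per_class <- tapply(df$subject_id, df$skeletal_class,
                        function(s) length(unique(s)))
  if (any(is.na(n_per_class)) || any(n_per_class < 2L))
    stop("need at least 2 complete-case subjects per skeletal class",
         call. = FALSE)

  if (stats::var(df$.y) == 0) {
    cc <- df$.y[1L]
    pooled <- data.frame(timepoint = c("T0", "T1"), emmean = cc,
                         lower = cc, upper = cc)
    by_class <- expand.grid(skeletal_class = c("II", "III"),
                            timepoint = c("T0", "T1"),
                            stringsAsFactors = FALSE)
    by_class$emmean <- cc; by_class$lower <- cc; by_class$upper <- cc
    return(structure(list(metric = metric, expression = expression,
                          pooled = pooled, by_class = by_class,
                          p_time = NA_real_, time_effect = 0,
                          n_subjects = nlevels(df$subject_id),
                          degenerate = TRUE, model = NULL),
                     class = "emm_result"))
  }

  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(.y ~ timepoint * skeletal_class + (1 | subject_id),
                     data = df, REML = TRUE)
    )),
    error = function(e) stop("mixed-model fit failed: ",
                             conditionMessage(e), call. = FALSE)
  )

  emm_pooled <- suppressMessages(
    summary(emmeans::emmeans(fit, ~timepoint), infer = c(TRUE, FALSE)))
  emm_class <- suppressMessages(
    summary(emmeans::emmeans(fit, ~timepoint | skeletal_class),
            infer = c(TRUE, FALSE)))
  an <- suppressMessages(suppressWarnings(stats::anova(fit, type = 3)))
  p_time <- an["timepoint", "Pr(>F)"]

  pooled <- data.frame(timepoint = as.character(emm_pooled$timepoint),
                       emmean = emm_pooled$emmean,
                       lower = emm_pooled$lower.CL,
                       upper = emm_pooled$upper.CL)
  by_class <- data.frame(
    skeletal_class = as.character(emm_class$skeletal_class),
    timepoint = as.character(emm_class$timepoint),
    emmean = emm_class$emmean,
    lower = emm_class$lower.CL,
    upper = emm_class$upper.CL)
  structure(list(metric = metric, expression = expression,
                 pooled = pooled, by_class = by_class, p_time = p_time,
                 time_effect = diff(pooled$emmean),
                 n_subjects = nlevels(df$subject_id),
                 degenerate = FALSE, model = fit),
            class = "emm_result")
}

#' @export
print.emm_result <- function(x, ...) {
  cat(sprintf("<emm_result> %s / %s (n = %d)\n", x$metric, x$expression,
              x$n_subjects))
  print(x$pooled, row.names = FALSE)
  cat(sprintf("  time effect %.4g, p = %.4g\n", x$time_effect, x$p_time))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Sensitivity analysis companion to the mixed model. Zero differences are
#' dropped before ranking (Wilcoxon's original convention); their count is
#' attached as attribute `n_zero`. The p-value is exact for up to 25
#' non-zero untied differences, otherwise a normal approximation with
#' continuity correction is used. If every difference is zero the data
#' carry no signal: p = 1 by convention, flagged via attribute
#' `degenerate`.
#'
#' @param before,after paired measurements (equal length >= 2).
#' @return Two-sided p-value with attributes `n_zero`, `degenerate`, and
#'   `statistic` (the signed-rank V).
#' @export
wilcoxon_paired <- function(before, after) {
  if (length(before) != length(after))
    stop("before/after must have equal length", call. = FALSE)
  if (length(before) < 2L)
    stop("need at least 2 pairs", call. = FALSE)
  d <- after - before
  nz <- d[d != 0]
  n_zero <- sum(d == 0)
  if (!length(nz)) {
    p <- 1
    attr(p, "n_zero") <- n_zero
    attr(p, "degenerate") <- TRUE
    attr(p, "statistic") <- NA_real_
    return(p)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = length(nz) <= 25L,
                       correct = TRUE)
  )
  p <- wt$p.value
  attr(p, "n_zero") <- n_zero
  attr(p, "degenerate") <- FALSE
  attr(p, "statistic") <- unname(wt$statistic)
  p
}

#' Model metric change on the surgical movement covariates
#'
#' Computes each subject's T1 - T0 change in the metric and regresses it
#' (OLS, with intercept) on the nine surgical movement covariates
#' (sagittal/vertical/transversal translation of maxilla and mandibula in
#' mm; roll/pitch/yaw of the maxillomandibular complex in degrees) plus
#' skeletal class and intervention type.
#'
#' @inheritParams fit_time_class_model
#' @return A `surgical_model`: list with `coefficients` (term, estimate,
#'   std_error, t_value, p_value), `n`, and the `lm` fit.
#' @export
fit_surgical_model <- function(table, metric, expression) {
  df <- check_cohort_table(table, metric, expression)
  need <- c(covariate_columns, "intervention")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table is missing covariate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  wide <- merge(
    df[df$timepoint == "T0", c("subject_id", metric)],
    df[df$timepoint == "T1", c("subject_id", metric)],
    by = "subject_id", suffixes = c("_T0", "_T1"))
  wide$.diff <- wide[[paste0(metric, "_T1")]] - wide[[paste0(metric, "_T0")]]
  cov <- unique(df[, c("subject_id", "skeletal_class", "intervention",
                       covariate_columns)])
  if (anyDuplicated(cov$subject_id))
    stop("covariates are not constant within subject", call. = FALSE)
  dat <- merge(wide[, c("subject_id", ".diff")], cov, by = "subject_id")
  dat$intervention <- factor(dat$intervention)

  form <- stats::as.formula(paste(
    ".diff ~", paste(c(covariate_columns, "skeletal_class", "intervention"),
                     collapse = " + ")))
  mm <- stats::model.matrix(form, data = dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("rank-deficient design: collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(form, data = dat)
  cf <- summary(fit)$coefficients
  structure(list(
    metric = metric, expression = expression,
    coefficients = data.frame(term = rownames(cf),
                              estimate = cf[, 1L], std_error = cf[, 2L],
                              t_value = cf[, 3L], p_value = cf[, 4L],
                              row.names = NULL),
    n = nrow(dat), model = fit
  ), class = "surgical_model")
}

#' @export
print.surgical_model <- function(x, ...) {
  cat(sprintf("<surgical_model> change in %s (%s), n = %d\n",
              x$metric, x$expression, x$n))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Two-way intraclass correlation coefficient (single measures)
#'
#' Two-way ANOVA-based ICCs for a complete subjects-by-raters (or
#' repetitions) matrix, single-measure forms: `"agreement"` is the
#' absolute-agreement ICC(A,1), which penalizes systematic offsets between
#' columns; `"consistency"` is ICC(C,1), which does not. Confidence
#' intervals are F-based (McGraw & Wong two-way forms).
#'
#' @param ratings numeric matrix, one row per subject/case, one column per
#'   rater or repetition; no missing cells, at least 5 rows and 2 columns.
#' @param kind `"agreement"` or `"consistency"`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An `icc_result`: list with `estimate`, `lower`, `upper`,
#'   `kind`, `n`, `k`, and the ANOVA mean squares `ms`.
#' @export
icc <- function(ratings, kind = c("agreement", "consistency"),
                conf_level = 0.95) {
  kind <- match.arg(kind)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stop("ratings matrix has missing cells", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 subjects for the ICC", call. = FALSE)
  if (k < 2L) stop("need at least 2 raters/repetitions", call. = FALSE)

  grand <- mean(ratings)
  rm_ <- rowMeans(ratings); cm_ <- colMeans(ratings)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1L)
  msc <- ssc / (k - 1L)
  mse <- sse / ((n - 1L) * (k - 1L))
  alpha <- 1 - conf_level

  if (kind == "consistency") {
    denom <- msr + (k - 1) * mse
    est <- if (denom == 0) 1 else (msr - mse) / denom
    if (mse == 0) {
      lo <- hi <- est
    } else {
      fobs <- msr / mse
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  } else {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    est <- if (denom == 0) 1 else (msr - mse) / denom
    if (mse == 0 && msc == 0) {
      lo <- hi <- est
    } else {
      r <- min(est, 1 - 1e-12)
      a <- (k * r) / (n * (1 - r))
      b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f2 <- stats::qf(1 - alpha / 2, n - 1, v)
      f3 <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f2 * mse) /
        (f2 * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f3 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f3 * msr)
    }
  }
  structure(list(kind = kind, estimate = est,
                 lower = min(lo, est), upper = max(hi, est),
                 n = n, k = k, ms = list(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(%s,1) = %.3f, %d%% CI [%.3f, %.3f] (n=%d, k=%d)\n",
              if (x$kind == "agreement") "A" else "C", x$estimate,
              95L, x$lower, x$upper, x$n, x$k))
  invisible(x)
}
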