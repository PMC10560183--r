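toy_cohort <- function(values, expression = "smile") {
  # values: named list subject -> c(T0, T1); classes alternate II/III
  subj <- names(values)
  cls <- rep(c("II", "III"), length.out = length(subj))
  do.call(rbind, lapply(seq_along(subj), function(i) {
    data.frame(subject_id = subj[i], skeletal_class = cls[i],
               timepoint = c("T0", "T1"), expression = expression,
               magnitude = values[[i]], stringsAsFactors = FALSE)
  }))
}

test_that("EMMs equal cell means on a balanced toy table", {
  tab <- toy_cohort(list(A = c(10, 12), B = c(11, 15),
                         C = c(9, 10), D = c(12, 13)))
  res <- fit_time_class_model(tab, "magnitude", "smile")
  # closed-form oracle: balanced design -> EMMs are arithmetic cell means
  cell <- tapply(tab$magnitude, list(tab$skeletal_class, tab$timepoint),
                 mean)
  expect_equal(res$pooled$emmean[res$pooled$timepoint == "T0"],
               mean(cell[, "T0"]), tolerance = 1e-8)
  expect_equal(res$pooled$emmean[res$pooled$timepoint == "T1"],
               mean(cell[, "T1"]), tolerance = 1e-8)
  by_cls <- res$by_class
  for (cl in c("II", "III")) for (tp in c("T0", "T1"))
    expect_equal(by_cls$emmean[by_cls$skeletal_class == cl &
                                 by_cls$timepoint == tp],
                 cell[cl, tp], tolerance = 1e-8)
  expect_true(all(res$pooled$lower <= res$pooled$emmean + 1e-12 &
                    res$pooled$emmean <= res$pooled$upper + 1e-12))
})

test_that("a constant metric yields constant EMMs and a zero time effect", {
  tab <- toy_cohort(list(A = c(7, 7), B = c(7, 7), C = c(7, 7),
                         D = c(7, 7)))
  res <- fit_time_class_model(tab, "magnitude", "smile")
  expect_true(res$degenerate)
  expect_true(all(res$pooled$emmean == 7))
  expect_identical(res$time_effect, 0)
})

test_that("the mixed model enforces its design preconditions", {
  tab <- toy_cohort(list(A = c(10, 12), B = c(11, 15)))
  tab <- tab[tab$skeletal_class == "II", ]
  expect_error(fit_time_class_model(tab, "magnitude", "smile"),
               "2 complete-case subjects per skeletal class")
  # incomplete subjects are dropped (complete-case analysis)
  tab2 <- toy_cohort(list(A = c(10, 12), B = c(11, 15), C = c(9, 10),
                          D = c(12, 13), E = c(30, 31)))
  tab2 <- tab2[!(tab2$subject_id == "E" & tab2$timepoint == "T1"), ]
  res <- fit_time_class_model(tab2, "magnitude", "smile")
  expect_identical(res$n_subjects, 4L)
})

test_that("paired Wilcoxon matches exhaustive sign-flip enumeration", {
  # 3 pairs, all differences positive: two-sided exact p = 2/8
  expect_equal(as.numeric(wilcoxon_paired(c(1, 2, 3), c(2, 4, 7))), 0.25)
  set.seed(501)
  for (i in 1:15) {
    n <- sample(5:10, 1L)
    before <- rnorm(n); after <- before + rnorm(n, sd = 1.2)
    p <- wilcoxon_paired(before, after)
    expect_equal(as.numeric(p), oracle_signrank_p(after - before),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles zero differences per the dropping convention", {
  p <- wilcoxon_paired(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  expect_identical(attr(p, "n_zero"), 4L)
  # partial zeros are dropped, remaining pairs tested
  p2 <- wilcoxon_paired(c(1, 2, 3, 4, 5), c(1, 2, 5, 7, 9))
  expect_identical(attr(p2, "n_zero"), 2L)
  expect_equal(as.numeric(p2), 0.25)  # 3 positive differences
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")
})

test_that("Wilcoxon p is invariant under rank-preserving transforms", {
  set.seed(502)
  before <- rnorm(12); after <- before + rnorm(12, sd = 1)
  p_ref <- as.numeric(wilcoxon_paired(before, after))
  # any strictly monotone odd transform of the differences keeps the
  # sign/rank structure
  d <- after - before
  for (f in list(function(x) sign(x) * abs(x)^1.5,
                 function(x) x * 3,
                 function(x) sign(x) * log1p(abs(x)))) {
    expect_equal(as.numeric(wilcoxon_paired(before, before + f(d))), p_ref)
  }
})

surgical_table <- function(n = 26L, seed = 1L, effect = NULL,
                           noise_sd = 1) {
  cfg <- default_cohort_config(n_subjects = n, seed = seed)
  tr <- draw_cohort_truth(cfg)
  tr <- tr[tr$expression == "smile", ]
  if (!is.null(effect)) {
    # construct the difference as an exact linear function of a covariate
    d <- effect(tr)
    tr$magnitude[tr$timepoint == "T1"] <-
      tr$magnitude[tr$timepoint == "T0"] + d
  } else if (noise_sd >= 0) {
    tr$magnitude <- rnorm(nrow(tr), 15, noise_sd) +
      ifelse(tr$timepoint == "T1", 0, 0)
  }
  tr
}

test_that("the surgical model recovers an exact linear effect", {
  tab <- surgical_table(effect = function(tr) {
    2 * tr$sagittal_maxilla[tr$timepoint == "T0"]
  })
  # a zero-residual fit makes summary.lm warn; the estimates are the point
  res <- suppressWarnings(fit_surgical_model(tab, "magnitude", "smile"))
  cf <- res$coefficients
  expect_equal(cf$estimate[cf$term == "sagittal_maxilla"], 2,
               tolerance = 1e-8)
  others <- cf$estimate[!cf$term %in% c("sagittal_maxilla")]
  expect_true(all(abs(others) < 1e-7))
})

test_that("rank-deficient surgical designs fail naming the collinear column", {
  tab <- surgical_table()
  tab$vertical_maxilla <- 2 * tab$sagittal_maxilla
  expect_error(fit_surgical_model(tab, "magnitude", "smile"),
               "collinear")
})

test_that("surgical-model p-values are calibrated under the null", {
  set.seed(503)
  hits <- 0L; total <- 0L
  for (r in 1:200) {
    tab <- surgical_table(seed = 600L + r, noise_sd = 3)
    cf <- fit_surgical_model(tab, "magnitude", "smile")$coefficients
    pv <- cf$p_value[cf$term != "(Intercept)"]
    hits <- hits + sum(pv < 0.05)
    total <- total + length(pv)
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)
})

test_that("ICC matches its definitional contrasts", {
  set.seed(504)
  x <- rnorm(8L, 10, 3)
  dup <- cbind(x, x, x)
  expect_equal(icc(dup, "agreement")$estimate, 1, tolerance = 1e-12)
  expect_equal(icc(dup, "consistency")$estimate, 1, tolerance = 1e-12)
  # constant rater offset: consistency stays 1, agreement drops
  off <- cbind(x, x + 4)
  expect_equal(icc(off, "consistency")$estimate, 1, tolerance = 1e-9)
  expect_lt(icc(off, "agreement")$estimate, 1)
  expect_error(icc(cbind(x, c(NA, x[-1L])), "agreement"), "missing")
  expect_error(icc(dup[1:3, ], "agreement"), "at least 5")
})

test_that("ICC equals the two-way ANOVA oracle and orders as expected", {
  set.seed(505)
  for (i in 1:25) {
    n <- sample(5:12, 1L); k <- sample(2:4, 1L)
    m <- matrix(rnorm(n * k, 10, 2), n, k) +
      rnorm(n, sd = 2) +  # subject effect (recycled down columns)
      rep(rnorm(k, sd = runif(1, 0, 1.5)), each = n)  # rater offsets
    a <- icc(m, "agreement"); c_ <- icc(m, "consistency")
    expect_equal(a$estimate, oracle_icc(m, "agreement"), tolerance = 1e-9)
    expect_equal(c_$estimate, oracle_icc(m, "consistency"),
                 tolerance = 1e-9)
    # consistency dominates agreement whenever rater offsets contribute
    # variance beyond residual (MSC >= MSE) and the numerator is
    # non-negative; otherwise the larger denominator can flip the order
    if (a$ms$msc >= a$ms$mse && a$estimate >= 0)
      expect_gte(c_$estimate, a$estimate - 1e-12)
    expect_true(a$lower <= a$estimate && a$estimate <= a$upper)
    expect_true(c_$lower <= c_$estimate && c_$estimate <= c_$upper)
  }
})
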