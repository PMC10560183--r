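# Monte-Carlo recovery study shared by several acceptance checks.
# Computed lazily once per test run and cached.

.replicate_cache <- new.env(parent = emptyenv())

replicate_recovery_study <- function(n_rep = 100L) {
  key <- paste0("study_", n_rep)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  template <- shared_template()
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- default_cohort_config(seed = 20000L + r)
    mc <- facemotion:::measure_cohort(cfg, template = template)
    met <- mc$metrics; tr <- mc$truth
    emm_s <- fit_time_class_model(met, "magnitude", "smile")$pooled
    emm_p <- fit_time_class_model(met, "magnitude", "lip_purse")$pooled
    truth_mean <- function(expr, tp)
      mean(tr$magnitude[tr$expression == expr & tr$timepoint == tp])
    pair_diff <- function(d, expr) {
      w <- merge(d[d$expression == expr & d$timepoint == "T0",
                   c("subject_id", "magnitude")],
                 d[d$expression == expr & d$timepoint == "T1",
                   c("subject_id", "magnitude")],
                 by = "subject_id")
      mean(w$magnitude.y - w$magnitude.x)
    }
    # balanced complete data: pooled EMMs for the remaining metrics equal
    # per-timepoint means, recorded directly
    cell <- function(col, expr, tp)
      mean(met[[col]][met$expression == expr & met$timepoint == tp])
    rows[[r]] <- data.frame(
      emm_smile_T0 = emm_s$emmean[emm_s$timepoint == "T0"],
      emm_smile_T1 = emm_s$emmean[emm_s$timepoint == "T1"],
      emm_purse_T0 = emm_p$emmean[emm_p$timepoint == "T0"],
      emm_purse_T1 = emm_p$emmean[emm_p$timepoint == "T1"],
      truth_smile_T0 = truth_mean("smile", "T0"),
      truth_smile_T1 = truth_mean("smile", "T1"),
      truth_purse_T0 = truth_mean("lip_purse", "T0"),
      truth_purse_T1 = truth_mean("lip_purse", "T1"),
      diff_smile = pair_diff(met, "smile"),
      diff_purse = pair_diff(met, "lip_purse"),
      sym_smile_T0 = cell("symmetry", "smile", "T0"),
      sym_smile_T1 = cell("symmetry", "smile", "T1"),
      sym_purse_T0 = cell("symmetry", "lip_purse", "T0"),
      sym_purse_T1 = cell("symmetry", "lip_purse", "T1"),
      time_smile_T0 = cell("time", "smile", "T0"),
      time_smile_T1 = cell("time", "smile", "T1"),
      time_purse_T0 = cell("time", "lip_purse", "T0"),
      time_purse_T1 = cell("time", "lip_purse", "T1")
    )
  }
  out <- do.call(rbind, rows)
  .replicate_cache[[key]] <- out
  out
}

# pooled calibration targets implied by the default configuration
calibration_targets <- function(cfg = default_cohort_config()) {
  pool <- function(block, tp) mean(block$mu[, tp])
  list(
    magnitude = list(
      smile = c(T0 = pool(cfg$magnitude$smile, "T0"),
                T1 = pool(cfg$magnitude$smile, "T1")),
      lip_purse = c(T0 = pool(cfg$magnitude$lip_purse, "T0"),
                    T1 = pool(cfg$magnitude$lip_purse, "T1"))
    ),
    symmetry = list(
      smile = c(T0 = pool(cfg$asymmetry$smile, "T0"),
                T1 = pool(cfg$asymmetry$smile, "T1")),
      lip_purse = c(T0 = pool(cfg$asymmetry$lip_purse, "T0"),
                    T1 = pool(cfg$asymmetry$lip_purse, "T1"))
    ),
    time = list(
      smile = c(T0 = pool(cfg$time$smile, "T0"),
                T1 = pool(cfg$time$smile, "T1")),
      lip_purse = c(T0 = pool(cfg$time$lip_purse, "T0"),
                    T1 = pool(cfg$time$lip_purse, "T1"))
    )
  )
}
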