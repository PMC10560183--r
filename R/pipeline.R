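#' End-to-end study orchestration
#'
#' [run_study()] drives the whole analysis: generate (or load) corresponded
#' recordings, trim each to its expression clip, compute the four
#' kinematic parameters, then fit the cohort statistics and assemble
#' report tables. Any stage failure on a single recording is caught,
#' logged with its subject/timepoint/expression context, and the run
#' continues — subjects left without a complete T0/T1 pair are excluded
#' from the statistics (complete-case behaviour).
#'
#' @name facemotion-pipeline
NULL

#' Compute metrics for a set of recordings
#'
#' @param sequences list of [mesh_sequence] objects with metadata
#'   (subject, timepoint, expression) set.
#' @param landmarks a [landmark_map] shared by all recordings
#'   (correspondence contract).
#' @param fh_normal Frankfort Horizontal normal used when a sequence does
#'   not record its own.
#' @param trim_args named list of extra arguments passed to [trim_clip()].
#' @param verbose print one log line per clip.
#' @return List with `metrics` (one row per successfully analysed clip)
#'   and `failures` (data.frame of context + error message).
#' @export
analyze_sequences <- function(sequences, landmarks, fh_normal = NULL,
                              trim_args = list(), verbose = FALSE) {
  metrics <- list()
  failures <- list()
  for (key in names(sequences)) {
    s <- sequences[[key]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      clip <- do.call(trim_clip, c(list(s, landmarks, s$expression),
                                   trim_args))
      compute_motion_metrics(clip, landmarks, fh_normal = fh_normal)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- data.frame(
        subject_id = s$subject_id, timepoint = s$timepoint,
        expression = s$expression, error = conditionMessage(res),
        stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("[fail] %s: %s", key, conditionMessage(res)))
    } else {
      metrics[[key]] <- res
      if (verbose)
        message(sprintf("[ok] %s (%.2fs)", key,
                        proc.time()[["elapsed"]] - t0))
    }
  }
  list(
    metrics = if (length(metrics)) do.call(rbind, c(metrics,
                                                    make.row.names = FALSE))
              else NULL,
    failures = if (length(failures)) do.call(rbind, c(failures,
                                                      make.row.names = FALSE))
               else NULL
  )
}

#' Generate and measure one synthetic cohort
#'
#' Streams the cohort recording by recording (generate, trim, measure,
#' discard), so memory stays flat; returns the measured metrics joined
#' with the subject covariates, plus the commanded ground truth.
#'
#' @param config a `cohort_config`.
#' @param template optional prebuilt `face_template` to reuse across calls.
#' @param trim_args extra arguments for [trim_clip()].
#' @return List with `metrics`, `truth`, `template`, `failures`.
#' @export
measure_cohort <- function(config, template = NULL, trim_args = list()) {
  if (is.null(template)) template <- build_face_template()
  truth <- draw_cohort_truth(config)
  rigs <- list(smile = expression_rig(template, "smile"),
               lip_purse = expression_rig(template, "lip_purse"))
  metrics <- vector("list", nrow(truth))
  failures <- list()
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    res <- tryCatch({
      sim <- animate_expression(
        template, rigs[[r$expression]], amplitude = r$magnitude,
        asymmetry = r$asymmetry, time_to_peak = r$time,
        rest_frames = config$rest_frames, hold_frames = config$hold_frames,
        fps = config$fps, noise_sd = config$noise_sd, seed = r$noise_seed,
        subject_id = r$subject_id, timepoint = r$timepoint)
      clip <- do.call(trim_clip,
                      c(list(sim$sequence, template$landmarks,
                             r$expression), trim_args))
      compute_motion_metrics(clip, template$landmarks)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        subject_id = r$subject_id, timepoint = r$timepoint,
        expression = r$expression, error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      metrics[[i]] <- res
    }
  }
  metrics <- do.call(rbind, c(metrics[!vapply(metrics, is.null, TRUE)],
                              make.row.names = FALSE))
  cov_cols <- c("subject_id", "skeletal_class", "intervention",
                covariate_columns, "wits")
  covs <- unique(truth[, cov_cols])
  metrics <- merge(metrics, covs, by = "subject_id", sort = FALSE)
  list(metrics = metrics, truth = truth, template = template,
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}

#' Cohort statistics tables from a metrics table
#'
#' Fits, for every metric x expression: the time-by-class mixed model
#' ([fit_time_class_model()]) and the paired Wilcoxon sensitivity test;
#' and, for magnitude, the surgical-covariate model
#' ([fit_surgical_model()]) when the covariate columns are present.
#'
#' @param table metrics table (one row per subject x timepoint x
#'   expression, plus covariates for the surgical models).
#' @param metrics metric columns to analyse.
#' @return List: `emm` (named list of `emm_result`), `pooled_table` and
#'   `class_table` (stacked report data.frames), `wilcoxon`
#'   (data.frame), `surgical` (named list of `surgical_model`).
#' @export
cohort_stats <- function(table,
                         metrics = c("magnitude", "shape_change",
                                     "symmetry", "time")) {
  emm <- list()
  wil <- list()
  surgical <- list()
  for (expr in intersect(c("smile", "lip_purse"), unique(table$expression))) {
    for (m in metrics) {
      key <- paste(expr, m, sep = ".")
      emm[[key]] <- fit_time_class_model(table, m, expr)
      df <- check_cohort_table(table, m, expr)
      wide <- merge(df[df$timepoint == "T0", c("subject_id", m)],
                    df[df$timepoint == "T1", c("subject_id", m)],
                    by = "subject_id", suffixes = c("_T0", "_T1"))
      p <- wilcoxon_paired(wide[[paste0(m, "_T0")]],
                           wide[[paste0(m, "_T1")]])
      wil[[key]] <- data.frame(
        expression = expr, metric = m, p_wilcoxon = as.numeric(p),
        n_zero_diff = attr(p, "n_zero"), stringsAsFactors = FALSE)
    }
    if (all(c(covariate_columns, "intervention") %in% names(table))) {
      sm <- tryCatch(fit_surgical_model(table, "magnitude", expr),
                     error = function(e) e)
      if (inherits(sm, "error")) {
        warning(sprintf("surgical model (%s) not fitted: %s", expr,
                        conditionMessage(sm)), call. = FALSE)
      } else surgical[[expr]] <- sm
    }
  }
  pooled_table <- do.call(rbind, lapply(emm, function(e) {
    cbind(expression = e$expression, metric = e$metric, e$pooled,
          p_time = e$p_time, row.names = NULL)
  }))
  class_table <- do.call(rbind, lapply(emm, function(e) {
    cbind(expression = e$expression, metric = e$metric, e$by_class,
          row.names = NULL)
  }))
  rownames(pooled_table) <- rownames(class_table) <- NULL
  list(emm = emm, pooled_table = pooled_table, class_table = class_table,
       wilcoxon = do.call(rbind, c(wil, make.row.names = FALSE)),
       surgical = surgical)
}

#' Run a full synthetic study
#'
#' Generates the calibrated cohort, measures every recording with the
#' kinematic pipeline, fits the statistics layer and returns a
#' `study_report`. Fully reproducible: identical `config` (including its
#' seed) gives identical tables.
#'
#' @param config a `cohort_config`; see [default_cohort_config()].
#' @param output_dir if non-NULL, report tables are written there as CSV
#'   plus a plain-text summary ([write_report()]).
#' @param trim_args extra arguments for [trim_clip()].
#' @return A `study_report`: list with `metrics`, `truth`, `stats`
#'   (see [cohort_stats()]), `failures`, `config`, `config_hash`.
#' @export
run_study <- function(config = default_cohort_config(),
                      output_dir = NULL, trim_args = list()) {
  mc <- measure_cohort(config, trim_args = trim_args)
  stats_ <- cohort_stats(mc$metrics)
  report <- structure(list(
    metrics = mc$metrics, truth = mc$truth, stats = stats_,
    failures = mc$failures, config = config,
    config_hash = config_hash(config)
  ), class = "study_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d clips analysed, %d failures (config %s)\n",
              nrow(x$metrics),
              if (is.null(x$failures)) 0L else nrow(x$failures),
              x$config_hash))
  cat("\nEstimated marginal means (pooled over skeletal class):\n")
  print(x$stats$pooled_table, row.names = FALSE, digits = 4)
  invisible(x)
}

# tiny polynomial content hash so reports are traceable to their config
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

#' Write a study report to disk
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(report$truth))
    utils::write.csv(report$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  utils::write.csv(report$stats$pooled_table,
                   file.path(dir, "emm_pooled.csv"), row.names = FALSE)
  utils::write.csv(report$stats$class_table,
                   file.path(dir, "emm_by_class.csv"), row.names = FALSE)
  utils::write.csv(report$stats$wilcoxon,
                   file.path(dir, "wilcoxon.csv"), row.names = FALSE)
  for (expr in names(report$stats$surgical))
    utils::write.csv(report$stats$surgical[[expr]]$coefficients,
                     file.path(dir, sprintf("surgical_%s.csv", expr)),
                     row.names = FALSE)
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    "facemotion study report",
    sprintf("config hash: %s  seed: %d  n: %d",
            report$config_hash, report$config$seed,
            report$config$n_subjects),
    sprintf("clips analysed: %d, failures: %d", nrow(report$metrics),
            if (is.null(report$failures)) 0L else nrow(report$failures)),
    "", "Estimated marginal means, pooled over skeletal class:"), con)
  utils::capture.output(print(report$stats$pooled_table, row.names = FALSE,
                              digits = 4), file = con, append = TRUE)
  writeLines(c("", "Estimated marginal means, per skeletal class:"), con)
  utils::capture.output(print(report$stats$class_table, row.names = FALSE,
                              digits = 4), file = con, append = TRUE)
  writeLines(c("", "Paired Wilcoxon sensitivity analysis:"), con)
  utils::capture.output(print(report$stats$wilcoxon, row.names = FALSE,
                              digits = 4), file = con, append = TRUE)
  for (expr in names(report$stats$surgical)) {
    writeLines(c("", sprintf(
      "Surgical-covariate model (change in %s magnitude):", expr)), con)
    utils::capture.output(print(
      report$stats$surgical[[expr]]$coefficients, row.names = FALSE,
      digits = 3), file = con, append = TRUE)
  }
  if (!is.null(report$failures)) {
    writeLines(c("", "Excluded recordings (complete-case analysis):"), con)
    utils::capture.output(print(report$failures, row.names = FALSE),
                          file = con, append = TRUE)
  }
  invisible(dir)
}

#' Method-error (repeatability) analysis
#'
#' Emulates repeated application of the tracking template to the same
#' recordings: for each of `n_cases` baseline smile recordings, every
#' "repeat" re-perturbs all vertex positions with i.i.d. Gaussian noise of
#' SD `repeat_noise_sd` (the repeat-to-repeat tracking variability) and
#' re-runs the kinematic pipeline. Magnitude and lower-face shape change
#' are collected into cases-by-repeats matrices and their two-way ICCs
#' (agreement and consistency) are returned. With `repeat_noise_sd = 0`
#' the repeats are identical and every ICC is 1.
#'
#' @param n_cases number of recordings re-tracked (default 10).
#' @param n_repeats repeats per case (>= 2).
#' @param repeat_noise_sd SD (mm) of the per-vertex repeat perturbation.
#' @param config cohort configuration supplying the recordings.
#' @param seed seed for the repeat perturbations.
#' @return List: `table` (data.frame metric x kind with estimate and 95%
#'   CI), `icc` (named list of `icc_result`), and the raw `ratings`
#'   matrices.
#' @export
method_error_run <- function(n_cases = 10L, n_repeats = 3L,
                             repeat_noise_sd = 0.15,
                             config = default_cohort_config(),
                             seed = config$seed) {
  if (n_repeats < 2L) stop("n_repeats must be >= 2", call. = FALSE)
  template <- build_face_template()
  rig <- expression_rig(template, "smile")
  truth <- draw_cohort_truth(config)
  truth <- truth[truth$expression == "smile" & truth$timepoint == "T0", ]
  if (nrow(truth) < n_cases)
    stop("config provides fewer subjects than n_cases", call. = FALSE)
  truth <- truth[seq_len(n_cases), ]

  set.seed(seed)
  mag <- matrix(NA_real_, n_cases, n_repeats)
  shp <- matrix(NA_real_, n_cases, n_repeats)
  for (i in seq_len(n_cases)) {
    r <- truth[i, ]
    base_seq <- animate_expression(
      template, rig, amplitude = r$magnitude, asymmetry = r$asymmetry,
      time_to_peak = r$time, rest_frames = config$rest_frames,
      hold_frames = config$hold_frames, fps = config$fps,
      noise_sd = config$noise_sd, seed = r$noise_seed,
      subject_id = r$subject_id, timepoint = "T0")$sequence
    for (j in seq_len(n_repeats)) {
      s <- base_seq
      if (repeat_noise_sd > 0) {
        for (f in seq_along(s$frames)) {
          v <- s$frames[[f]]$vertices
          s$frames[[f]]$vertices <-
            v + matrix(stats::rnorm(length(v), sd = repeat_noise_sd),
                       nrow(v), 3L)
        }
      }
      clip <- trim_clip(s, template$landmarks, "smile")
      met <- compute_motion_metrics(clip, template$landmarks)
      mag[i, j] <- met$magnitude
      shp[i, j] <- met$shape_change
    }
  }
  iccs <- list(
    magnitude.agreement = icc(mag, "agreement"),
    magnitude.consistency = icc(mag, "consistency"),
    shape_change.agreement = icc(shp, "agreement"),
    shape_change.consistency = icc(shp, "consistency")
  )
  table <- do.call(rbind, lapply(names(iccs), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    e <- iccs[[nm]]
    data.frame(metric = parts[1L], kind = parts[2L],
               estimate = e$estimate, lower = e$lower, upper = e$upper,
               stringsAsFactors = FALSE)
  }))
  list(table = table, icc = iccs,
       ratings = list(magnitude = mag, shape_change = shp))
}
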