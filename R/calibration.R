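#' Default cohort configuration (calibration fixture)
#'
#' The generator's default study conditions emulate a 26-patient
#' orthognathic-surgery cohort (13 skeletal class II, 13 class III)
#' recorded at 60 fps before (T0) and four months after (T1) surgery.
#' Per-class metric means encode the cohort summary statistics the
#' generator is designed to reproduce; spreads are back-solved from the
#' corresponding 95% confidence intervals (between-subject SD =
#' half-width x sqrt(n)/1.96) and from the paired test p-values of the
#' pre/post comparison (which pin down the within-subject SD of the
#' change). Where the summary statistics do not identify a component —
#' the between/within split of the time parameter — it is split evenly,
#' a stated assumption. Full derivations are in the methods vignette.
#'
#' Structure of the returned list:
#' \describe{
#'   \item{n_subjects, class_split}{cohort size and class II/III counts.}
#'   \item{magnitude}{per expression: `mu` (class x timepoint mean
#'     matrix, mm), `sd_between`, `sd_within` (mm).}
#'   \item{asymmetry}{per expression: `mu` mean and `sd` of the commanded
#'     asymmetry magnitude (gamma-distributed, random side per subject).}
#'   \item{time}{per expression: `mu` (class x timepoint, s),
#'     `sd_between`, `sd_within` (s).}
#'   \item{covariates}{mean/SD of the nine surgical movements (Table-2
#'     style: translations truncated at 0) and the Wits appraisal per
#'     class; `n_bimax` bimaxillary vs mandible-only interventions.}
#'   \item{noise_sd}{tracking-noise SD, mm per vertex coordinate per
#'     frame.}
#'   \item{fps, rest_frames, hold_frames}{recording geometry.}
#'   \item{seed}{master seed; every random draw derives from it.}
#' }
#'
#' @param n_subjects cohort size (split as evenly as possible between
#'   classes II and III).
#' @param seed master seed.
#' @param noise_sd tracking-noise SD in mm (default 0.15, a mid-range
#'   figure for stereophotogrammetric surface tracking).
#' @return A `cohort_config` list.
#' @export
default_cohort_config <- function(n_subjects = 26L, seed = 1L,
                                  noise_sd = 0.15) {
  cls_mat <- function(II_T0, II_T1, III_T0, III_T1) {
    matrix(c(II_T0, II_T1, III_T0, III_T1), 2L, 2L, byrow = TRUE,
           dimnames = list(c("II", "III"), c("T0", "T1")))
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    class_split = c(II = ceiling(n_subjects / 2), III = floor(n_subjects / 2)),
    magnitude = list(
      smile = list(mu = cls_mat(15.67, 17.67, 14.80, 16.87),
                   sd_between = 5.20, sd_within = 2.12),
      lip_purse = list(mu = cls_mat(8.76, 7.67, 9.92, 8.96),
                       sd_between = 1.95, sd_within = 1.33)
    ),
    asymmetry = list(
      smile = list(mu = cls_mat(0.89, 1.78, 1.09, 1.78), sd = 1.2),
      lip_purse = list(mu = cls_mat(1.22, 1.32, 1.31, 0.80), sd = 1.0)
    ),
    time = list(
      smile = list(mu = cls_mat(0.42, 0.42, 0.39, 0.44),
                   sd_between = 0.078, sd_within = 0.078),
      lip_purse = list(mu = cls_mat(0.38, 0.31, 0.34, 0.32),
                       sd_between = 0.053, sd_within = 0.053)
    ),
    covariates = list(
      sagittal_maxilla = c(2.82, 2.2), vertical_maxilla = c(1.76, 1.3),
      transversal_maxilla = c(0.95, 0.9), sagittal_mandibula = c(4.13, 2.83),
      vertical_mandibula = c(2.42, 1.58),
      transversal_mandibula = c(1.48, 1.27),
      roll_mmc = c(0.62, 0.85), pitch_mmc = c(1.58, 2.48),
      yaw_mmc = c(0.73, 1.04),
      wits = list(II = c(5.2, 1.6), III = c(-9.2, 4.4)),
      n_bimax = 21L
    ),
    noise_sd = noise_sd,
    fps = 60, rest_frames = 10L, hold_frames = 5L,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# normal truncated below at `lower` (rejection-free inverse-CDF draw)
rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(pmax(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

#' Draw the ground-truth table and per-sequence parameters of a cohort
#'
#' Subject-level commanded parameters for every subject x expression x
#' timepoint cell: amplitudes follow a paired design (class/timepoint
#' mean + shared subject intercept + within-subject deviation, truncated
#' at 1 mm); asymmetry magnitudes are gamma draws with a subject-level
#' dominant side; times are analogous paired normals truncated at 4
#' frames. Surgical covariates are subject-level truncated normals. All
#' randomness flows from `config$seed`; each sequence additionally
#' receives its own derived noise seed so any single recording is
#' regenerable in isolation.
#'
#' @param config a `cohort_config` (see [default_cohort_config()]).
#' @return A data.frame (`cohort_truth`) with one row per subject x
#'   expression x timepoint: commanded `magnitude`, `symmetry` (and its
#'   signed `asymmetry`), `time` (frame-quantized), `skeletal_class`,
#'   surgical covariates, `intervention`, and `noise_seed`.
#' @export
draw_cohort_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  if (n < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  cls <- rep(c("II", "III"), times = config$class_split)
  subj <- sprintf("S%02d", seq_len(n))
  cv <- config$covariates
  # keep the bimax : mandible-only ratio of the default cohort at any n,
  # with both intervention types always represented
  n_bimax <- max(1L, min(n - 1L, as.integer(round(n * cv$n_bimax / 26))))
  intervention <- sample(c(rep("bimax", n_bimax),
                           rep("bsso_only", n - n_bimax)))
  covs <- data.frame(subject_id = subj, skeletal_class = cls,
                     intervention = intervention)
  for (nm in covariate_columns)
    covs[[nm]] <- rtruncnorm(n, cv[[nm]][1L], cv[[nm]][2L], lower = 0)
  covs$wits <- ifelse(cls == "II",
                      stats::rnorm(n, cv$wits$II[1L], cv$wits$II[2L]),
                      stats::rnorm(n, cv$wits$III[1L], cv$wits$III[2L]))

  rows <- list()
  for (expr in c("smile", "lip_purse")) {
    mg <- config$magnitude[[expr]]
    tm <- config$time[[expr]]
    asy <- config$asymmetry[[expr]]
    b_mag <- stats::rnorm(n, 0, mg$sd_between)
    b_tim <- stats::rnorm(n, 0, tm$sd_between)
    side <- sample(c(1, -1), n, replace = TRUE)
    for (tp in c("T0", "T1")) {
      amp <- pmax(mg$mu[cls, tp] + b_mag +
                    stats::rnorm(n, 0, mg$sd_within), 1)
      m_as <- asy$mu[cls, tp]
      shape <- (m_as / asy$sd)^2
      asym_mag <- stats::rgamma(n, shape = shape, scale = asy$sd^2 / m_as)
      asym_mag <- pmin(asym_mag, 2 * amp - 1e-9)
      tt <- pmax(tm$mu[cls, tp] + b_tim + stats::rnorm(n, 0, tm$sd_within),
                 4 / config$fps)
      n_ramp <- pmax(2L, as.integer(round(tt * config$fps)))
      rows[[paste(expr, tp)]] <- data.frame(
        subject_id = subj, timepoint = tp,
        expression = expr,
        magnitude = amp, symmetry = asym_mag,
        asymmetry = side * asym_mag,
        time = n_ramp / config$fps,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, rows)
  truth$noise_seed <- sample.int(.Machine$integer.max - 1L, nrow(truth))
  truth <- merge(truth, covs, by = "subject_id", sort = FALSE)
  truth <- truth[order(truth$subject_id, truth$expression,
                       truth$timepoint), ]
  rownames(truth) <- NULL
  class(truth) <- c("cohort_truth", "data.frame")
  truth
}

#' Generate a full synthetic cohort
#'
#' Draws the ground-truth table with [draw_cohort_truth()] and, unless
#' `meshes = FALSE`, animates every recording on the default face
#' template.
#'
#' @param config a `cohort_config`.
#' @param meshes if `FALSE`, return only the ground-truth table (fast
#'   path for purely statistical simulation; the commanded values then
#'   stand in for measured metrics).
#' @param template optional prebuilt `face_template` to reuse.
#' @return List with `truth` (the ground-truth table), `sequences`
#'   (named list of [mesh_sequence], `subject/timepoint/expression`
#'   keys; `NULL` when `meshes = FALSE`), `template`, and `config`.
#' @export
generate_cohort <- function(config = default_cohort_config(),
                            meshes = TRUE, template = NULL) {
  truth <- draw_cohort_truth(config)
  sequences <- NULL
  if (meshes) {
    if (is.null(template)) template <- build_face_template()
    rigs <- list(smile = expression_rig(template, "smile"),
                 lip_purse = expression_rig(template, "lip_purse"))
    sequences <- vector("list", nrow(truth))
    names(sequences) <- with(truth, paste(subject_id, timepoint,
                                          expression, sep = "/"))
    for (i in seq_len(nrow(truth))) {
      r <- truth[i, ]
      sequences[[i]] <- animate_expression(
        template, rigs[[r$expression]], amplitude = r$magnitude,
        asymmetry = r$asymmetry, time_to_peak = r$time,
        rest_frames = config$rest_frames, hold_frames = config$hold_frames,
        fps = config$fps, noise_sd = config$noise_sd,
        seed = r$noise_seed, subject_id = r$subject_id,
        timepoint = r$timepoint
      )$sequence
    }
  }
  list(truth = truth, sequences = sequences, template = template,
       config = config)
}

#' Write a synthetic cohort to disk in the real-data format
#'
#' Exports every sequence as PLY frames plus a shared landmark map and a
#' manifest CSV, so the synthetic fixture pathway is identical to the
#' real-data ingestion pathway ([read_manifest()] +
#' [load_manifest_sequences()]).
#'
#' @param cohort result of [generate_cohort()] (with meshes).
#' @param dir output directory.
#' @param binary write binary little-endian PLY (smaller) instead of
#'   ascii.
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, binary = TRUE) {
  if (is.null(cohort$sequences))
    stop("cohort has no mesh sequences (generated with meshes = FALSE)",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmark_map(cohort$template$landmarks,
                     file.path(dir, "landmarks.txt"))
  rows <- list()
  for (key in names(cohort$sequences)) {
    s <- cohort$sequences[[key]]
    sub <- gsub("/", "_", key)
    paths <- write_mesh_sequence(s, file.path(dir, sub), prefix = "frame",
                                 format = "ply", binary = binary)
    rows[[key]] <- data.frame(
      subject_id = s$subject_id, timepoint = s$timepoint,
      expression = s$expression, fps = s$fps,
      frame = seq_along(paths) - 1L,
      path = file.path(sub, basename(paths)), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mf_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf_path, row.names = FALSE)
  invisible(mf_path)
}
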