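#' Expression clips and displacement kinematics
#'
#' A recording is analysed between two frames: the last frame in rest
#' position (start) and the first frame at the expression's maximum extent
#' (end). All kinematic parameters derive from the per-vertex Euclidean
#' displacement between those two frames — a straight start-vs-end
#' distance, not a cumulative path length.
#'
#' @name facemotion-kinematics
NULL

#' Construct an expression clip
#'
#' @param sequence a [mesh_sequence].
#' @param start_index 0-based index of the last rest frame.
#' @param end_index 0-based index of the first frame at maximum extent.
#' @return An `expression_clip`.
#' @export
expression_clip <- function(sequence, start_index, end_index) {
  start_index <- as.integer(start_index)
  end_index <- as.integer(end_index)
  nf <- length(sequence$frames)
  if (start_index < 0L || end_index >= nf || start_index >= end_index)
    stop(sprintf(
      "invalid clip: need 0 <= start (%d) < end (%d) < %d frames",
      start_index, end_index, nf), call. = FALSE)
  structure(
    list(sequence = sequence, start_index = start_index,
         end_index = end_index),
    class = "expression_clip"
  )
}

#' @export
print.expression_clip <- function(x, ...) {
  cat(sprintf(
    "<expression_clip> frames %d -> %d (%.3f s @ %g fps)\n",
    x$start_index, x$end_index,
    (x$end_index - x$start_index) / x$sequence$fps, x$sequence$fps))
  invisible(x)
}

clip_frame <- function(clip, which = c("start", "end")) {
  which <- match.arg(which)
  i <- if (which == "start") clip$start_index else clip$end_index
  clip$sequence$frames[[i + 1L]]
}

#' Per-vertex Euclidean displacement between start and end frame
#'
#' @param clip an [expression_clip].
#' @return Numeric vector of class `displacement_field`: the 3D Euclidean
#'   distance (mm) travelled by each vertex between the clip's start and
#'   end frame, ordered by vertex index.
#' @export
displacement_field <- function(clip) {
  v0 <- clip_frame(clip, "start")$vertices
  v1 <- clip_frame(clip, "end")$vertices
  d <- sqrt(rowSums((v1 - v0)^2))
  structure(d, class = "displacement_field")
}

field_pair <- function(field, landmarks, expression) {
  sel <- expression_landmarks(landmarks, expression)
  pair <- attr(sel, "pair")
  stats::setNames(unclass(field)[unclass(landmarks)[pair]], pair)
}

#' Magnitude of a facial expression
#'
#' The arithmetic mean of the Euclidean displacements of the two
#' most-moving landmarks: cheilion right/left for a smile, labrale
#' superius/inferius for a lip purse.
#'
#' @param field a [displacement_field].
#' @param landmarks a [landmark_map].
#' @param expression `"smile"` or `"lip_purse"`.
#' @return Magnitude in mm.
#' @export
magnitude <- function(field, landmarks, expression) {
  mean(field_pair(field, landmarks, expression))
}

#' Symmetry of a facial expression
#'
#' The absolute difference between the displacements of the two
#' most-moving landmarks; 0 for a perfectly symmetric movement. Always
#' bounded by twice the magnitude.
#'
#' @inheritParams magnitude
#' @return Asymmetry in mm (0 = symmetric).
#' @export
symmetry <- function(field, landmarks, expression) {
  abs(diff(field_pair(field, landmarks, expression)))[[1L]]
}

#' Time to reach the maximum expression
#'
#' @param clip an [expression_clip].
#' @return `(end_index - start_index) / fps`, in seconds.
#' @export
time_to_peak <- function(clip) {
  (clip$end_index - clip$start_index) / clip$sequence$fps
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Trim a sequence to its expression clip
#'
#' Locates the last rest frame and the first frame at maximum extent from
#' the motion of the two expression landmarks. Let `a(t)` be the mean
#' displacement of the expression landmarks relative to frame 0. The end
#' frame is the first `t` whose raw `a(t)` reaches `peak_fraction` of the
#' (smoothed, hence noise-robust) maximum. The start frame is found in two
#' stages: a coarse motion onset — the first frame before the end whose
#' smoothed landmark speed exceeds `rest_speed_threshold` on two
#' consecutive frames — then refined backwards to the last frame whose
#' displacement is indistinguishable from the rest-phase baseline (within
#' one robust SD of the pre-onset median). On noiseless input this
#' recovers the commanded rest/peak frames exactly; manual `start_index` /
#' `end_index` overrides bypass detection entirely.
#'
#' @param sequence a [mesh_sequence].
#' @param landmarks a [landmark_map] valid for the sequence.
#' @param expression `"smile"` or `"lip_purse"`.
#' @param peak_fraction fraction of the maximum excursion that defines
#'   "maximum extent" (a strict argmax is noise-fragile). Default 0.999.
#' @param rest_speed_threshold landmark speed (mm/frame) below which a
#'   frame counts as resting. Default 0.1.
#' @param smooth_window moving-average window (frames, odd) used for the
#'   noise-robust maximum and the speed signal. Default 5.
#' @param min_motion minimum peak excursion (mm) below which the sequence
#'   is declared expressionless. Default 1.
#' @param start_index,end_index optional manual overrides (0-based).
#' @return An [expression_clip]. The detected excursion curve is attached
#'   as attribute `"excursion"`.
#' @export
trim_clip <- function(sequence, landmarks, expression,
                      peak_fraction = 0.999, rest_speed_threshold = 0.1,
                      smooth_window = 5L, min_motion = 1.0,
                      start_index = NULL, end_index = NULL) {
  validate_landmarks(landmarks, n_vertices(sequence$frames[[1L]]))
  if (!is.null(start_index) && !is.null(end_index))
    return(expression_clip(sequence, start_index, end_index))
  if (peak_fraction <= 0 || peak_fraction > 1)
    stop("peak_fraction must be in (0, 1]", call. = FALSE)
  if (rest_speed_threshold <= 0)
    stop("rest_speed_threshold must be > 0", call. = FALSE)

  sel <- expression_landmarks(landmarks, expression)
  idx <- sel$indices
  ref <- sequence$frames[[1L]]$vertices[idx, , drop = FALSE]
  a <- vapply(sequence$frames, function(fr) {
    mean(sqrt(rowSums((fr$vertices[idx, , drop = FALSE] - ref)^2)))
  }, numeric(1))
  a_s <- moving_average(a, smooth_window)

  peak <- max(a_s)
  if (peak < min_motion)
    stop(sprintf(
      "no expression detected: peak landmark excursion %.3f mm < %.3f mm",
      peak, min_motion), call. = FALSE)

  end <- if (!is.null(end_index)) as.integer(end_index) else {
    which(a >= peak_fraction * peak)[1L] - 1L
  }
  if (is.na(end) || end < 1L) end <- which.max(a) - 1L

  start <- if (!is.null(start_index)) as.integer(start_index) else {
    speed <- abs(diff(a_s))
    sustained <- speed > rest_speed_threshold &
      c(speed[-1L], Inf) > rest_speed_threshold
    onset <- which(sustained[seq_len(max(end, 1L))])[1L] - 1L
    if (is.na(onset)) onset <- 0L
    # fixed-point refinement: the rest baseline is re-estimated from the
    # frames before the current start until stable, so a late onset does
    # not contaminate the baseline with ramp frames
    st <- onset
    for (iter in 1:6) {
      rest_phase <- a[seq_len(st + 1L)]
      baseline <- stats::median(rest_phase)
      band <- max(stats::mad(rest_phase), 1e-9)
      cand <- which(rest_phase <= baseline + band)
      new_st <- if (length(cand)) cand[length(cand)] - 1L else 0L
      if (new_st == st) break
      st <- new_st
    }
    # an already-trimmed recording rises strictly from frame 0: no rest
    # plateau exists and the clip starts at the first frame
    if (st > 0L && all(diff(a[seq_len(st + 1L)]) > 1e-12)) st <- 0L
    st
  }
  start <- min(start, end - 1L)
  clip <- expression_clip(sequence, max(start, 0L), end)
  attr(clip, "excursion") <- a
  clip
}

#' Rigidly stabilize a sequence on the upper face
#'
#' Optional head-motion compensation: every frame is rigidly aligned
#' (rotation + translation, no scaling) to the first frame using the
#' vertices *above* the subnasale plane, which do not deform during lip
#' expressions. Off by default in the pipeline — displacements are defined
#' directly on the recorded geometry, with subjects instructed to hold the
#' head still — but available for recordings with visible head drift.
#'
#' @param sequence a [mesh_sequence].
#' @param landmarks a [landmark_map].
#' @param fh_normal Frankfort Horizontal normal; defaults to the
#'   sequence's recorded `fh_normal`.
#' @return A [mesh_sequence] with stabilized frames.
#' @export
stabilize_sequence <- function(sequence, landmarks, fh_normal = NULL) {
  if (is.null(fh_normal)) fh_normal <- sequence$fh_normal
  if (is.null(fh_normal))
    stop("fh_normal needed (not recorded on the sequence)", call. = FALSE)
  plane <- make_subnasale_plane(sequence$frames[[1L]], landmarks, fh_normal)
  upper <- which(signed_plane_distance(sequence$frames[[1L]]$vertices,
                                       plane) > 1e-9)
  if (length(upper) < 3L)
    stop("too few upper-face vertices to stabilize on", call. = FALSE)
  ref <- sequence$frames[[1L]]$vertices[upper, , drop = FALSE]
  out <- sequence
  for (i in seq_along(sequence$frames)[-1L]) {
    v <- sequence$frames[[i]]$vertices
    fit <- rigid_fit(ref, v[upper, , drop = FALSE])
    out$frames[[i]]$vertices <-
      v %*% fit$rotation + matrix(fit$translation, nrow(v), 3L,
                                  byrow = TRUE)
  }
  out
}

#' Compute all four kinematic parameters for one clip
#'
#' Runs trimming output through the full parameter set: magnitude and
#' symmetry from the expression-landmark displacements, time to peak from
#' the frame indices, and lower-face shape change from Procrustes
#' superimposition of the start- and end-frame lower-face configurations
#' (both the size-normalized Procrustes distance and its raw-mm variant
#' are reported; see [shape_change()]).
#'
#' @param clip an [expression_clip] whose sequence carries `expression`
#'   metadata.
#' @param landmarks a [landmark_map].
#' @param fh_normal Frankfort Horizontal normal; defaults to the
#'   sequence's recorded value.
#' @return A one-row data.frame: subject_id, timepoint, expression,
#'   magnitude, shape_change, shape_change_mm, symmetry, time,
#'   start_index, end_index.
#' @export
compute_motion_metrics <- function(clip, landmarks, fh_normal = NULL) {
  seq_ <- clip$sequence
  expr <- seq_$expression
  if (is.na(expr))
    stop("sequence has no expression label", call. = FALSE)
  if (is.null(fh_normal)) fh_normal <- seq_$fh_normal
  if (is.null(fh_normal))
    stop("fh_normal needed for the lower-face ROI", call. = FALSE)

  field <- displacement_field(clip)
  start_fr <- clip_frame(clip, "start")
  plane <- make_subnasale_plane(start_fr, landmarks, fh_normal)
  roi <- select_lower_face(start_fr, plane)
  cfg0 <- start_fr$vertices[roi$indices, , drop = FALSE]
  cfg1 <- clip_frame(clip, "end")$vertices[roi$indices, , drop = FALSE]

  mag <- magnitude(field, landmarks, expr)
  sym <- symmetry(field, landmarks, expr)
  out <- data.frame(
    subject_id = seq_$subject_id,
    timepoint = seq_$timepoint,
    expression = expr,
    magnitude = mag,
    shape_change = shape_change(cfg0, cfg1),
    shape_change_mm = shape_change(cfg0, cfg1, normalize = FALSE),
    symmetry = sym,
    time = time_to_peak(clip),
    start_index = clip$start_index,
    end_index = clip$end_index,
    stringsAsFactors = FALSE
  )
  stopifnot(out$symmetry <= 2 * out$magnitude + 1e-12)
  out
}
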