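#' Synthetic 4D face-motion generator
#'
#' Generates corresponded face-mesh sequences with fully known ground
#' truth, so every pipeline stage can be validated without patient
#' recordings. The template is a parametric face-like surface on a
#' structured grid; expressions are simple compact-support displacement
#' fields rigged so that the commanded amplitude *is* the ground-truth
#' magnitude (and the commanded asymmetry the ground-truth symmetry)
#' exactly. Realism is explicitly not the contract — ground-truth fidelity
#' is; see the methods vignette.
#'
#' @name facemotion-synthetic
NULL

#' Build the default parametric face template
#'
#' A bilaterally symmetric face-like surface on an `nx` columns by `ny`
#' rows grid (vertex index = row * nx + column, row 0 at the chin), with
#' an ellipsoidal depth profile and a small lateral "cheek lift" so the
#' subnasale vertex is the lowest point of its row. The subnasale row is
#' placed such that the lower-face ROI — every vertex at or below the
#' plane through subnasale with the template's Frankfort Horizontal
#' normal (0,1,0) — contains exactly 559 vertices: 558 strictly below the
#' plane plus subnasale itself on it. This constrains `nx` to divisors of
#' 558 (the default 31 columns puts subnasale at grid row 18); other
#' resolutions raise a construction error.
#'
#' @param grid_resolution integer 2-vector `c(nx, ny)`: columns (odd, a
#'   divisor of 558) and rows. Default `c(31, 30)` = 930 vertices.
#' @param dimensions numeric 3-vector `c(width, height, depth)` of the
#'   face in mm. Default `c(120, 145, 65)`.
#' @return A `face_template`: list with `frame` (a [mesh_frame] with
#'   triangulated faces), `landmarks` (a [landmark_map]), `fh_normal`
#'   (ground truth, `c(0, 1, 0)`), `grid_resolution`, `dimensions`, and
#'   `subnasale_row`.
#' @export
build_face_template <- function(grid_resolution = c(31L, 30L),
                                dimensions = c(120, 145, 65)) {
  nx <- as.integer(grid_resolution[1L]); ny <- as.integer(grid_resolution[2L])
  if (nx * ny < 600L)
    stop("grid too coarse: need at least 600 vertices", call. = FALSE)
  if (nx %% 2L == 0L)
    stop("nx must be odd so a midsagittal vertex column exists",
         call. = FALSE)
  if (558L %% nx != 0L)
    stop(sprintf(
      paste("construction error: %d columns cannot place the 559-vertex",
            "lower-face region (nx must divide 558)"), nx), call. = FALSE)
  sn_row <- 558L %/% nx
  if (sn_row < 6L || sn_row > ny - 3L)
    stop("construction error: subnasale row falls outside the grid",
         call. = FALSE)
  width <- dimensions[1L]; height <- dimensions[2L]; depth <- dimensions[3L]
  row_spacing <- height / (ny - 1L)

  col <- rep(0:(nx - 1L), times = ny)
  row <- rep(0:(ny - 1L), each = nx)
  x <- (col / (nx - 1L) - 0.5) * width
  y_base <- (row - sn_row) * row_spacing
  # lateral lift keeps subnasale the unique lowest vertex of its row
  lift <- 0.4 * row_spacing * (x / (width / 2))^2
  y <- y_base + lift
  z <- depth * sqrt(pmax(0, 1 - (x / (0.55 * width))^2 -
                           (y_base / (0.80 * height))^2))
  vertices <- cbind(x, y, z)

  # grid triangulation (two triangles per cell), 1-based indices
  cell_r <- rep(0:(ny - 2L), each = nx - 1L)
  cell_c <- rep(0:(nx - 2L), times = ny - 1L)
  v00 <- cell_r * nx + cell_c + 1L
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  mid <- (nx - 1L) %/% 2L
  grid_index <- function(r, c) r * nx + c + 1L
  lm <- landmark_map(c(
    subnasale = grid_index(sn_row, mid),
    labrale_superius = grid_index(sn_row - 3L, mid),
    labrale_inferius = grid_index(sn_row - 6L, mid),
    cheilion_right = grid_index(sn_row - 5L, mid - 7L),
    cheilion_left = grid_index(sn_row - 5L, mid + 7L)
  ), n_vertices = nrow(vertices))

  template <- structure(list(
    frame = mesh_frame(vertices, faces),
    landmarks = lm,
    fh_normal = c(0, 1, 0),
    grid_resolution = c(nx, ny),
    dimensions = dimensions,
    subnasale_row = sn_row
  ), class = "face_template")

  plane <- make_subnasale_plane(template$frame, lm, template$fh_normal)
  n_low <- length(select_lower_face(template$frame, plane)$indices)
  if (n_low != 559L)
    stop(sprintf(
      "construction error: lower-face ROI has %d vertices, expected 559",
      n_low), call. = FALSE)
  template
}

#' @export
print.face_template <- function(x, ...) {
  cat(sprintf(
    "<face_template> %d x %d grid (%d vertices), %g x %g x %g mm\n",
    x$grid_resolution[1L], x$grid_resolution[2L],
    nrow(x$frame$vertices), x$dimensions[1L], x$dimensions[2L],
    x$dimensions[3L]))
  invisible(x)
}

# Wendland C2 compactly supported kernel; exactly 0 beyond the support
wendland <- function(d, support) {
  q <- pmin(d / support, 1)
  (1 - q)^4 * (4 * q + 1)
}

#' Build the displacement rig for one expression
#'
#' Smile: each mouth corner is pulled laterally-superiorly by a
#' compact-support radial field centred on its cheilion (support 40 mm,
#' shorter than the inter-cheilion distance, so the two sides are
#' independent and the commanded per-side displacement is exact).
#' Lip purse: each labrale landmark protrudes anteriorly under its own
#' compact-support field (support 14 mm, shorter than the inter-labrale
#' distance), so here too each landmark's displacement equals its
#' commanded value exactly and the landmarks remain the most-moving
#' vertices.
#'
#' At unit amplitude and zero asymmetry the mean displacement of the two
#' expression landmarks is exactly 1 mm, so commanded amplitude equals
#' ground-truth magnitude.
#'
#' @param template a `face_template`.
#' @param expression `"smile"` or `"lip_purse"`.
#' @return An `expression_rig`: closure-based list whose
#'   `peak_field(amplitude, asymmetry)` returns the n x 3 peak
#'   displacement (mm); the first landmark of the pair receives
#'   `amplitude + asymmetry/2`, the second `amplitude - asymmetry/2`.
#' @export
expression_rig <- function(template, expression) {
  v <- template$frame$vertices
  lmk <- unclass(template$landmarks)
  pair <- switch(expression,
    smile = c("cheilion_right", "cheilion_left"),
    lip_purse = c("labrale_superius", "labrale_inferius"),
    stop(sprintf("unknown expression '%s'", expression), call. = FALSE)
  )
  p1 <- v[lmk[[pair[1L]]], ]; p2 <- v[lmk[[pair[2L]]], ]
  d1 <- sqrt(rowSums(sweep(v, 2L, p1)^2))
  d2 <- sqrt(rowSums(sweep(v, 2L, p2)^2))

  if (expression == "smile") {
    support <- 40
    gap <- sqrt(sum((p1 - p2)^2))
    if (gap <= support)
      stop("template too small: cheilion supports overlap", call. = FALSE)
    w1 <- wendland(d1, support); w2 <- wendland(d2, support)
    sgn1 <- sign(p1[1L]); sgn2 <- sign(p2[1L])  # lateral = away from midline
    u1 <- normalize_vector(c(0.72 * sgn1, 0.65, -0.25))
    u2 <- normalize_vector(c(0.72 * sgn2, 0.65, -0.25))
    peak_field <- function(amplitude, asymmetry = 0) {
      s1 <- amplitude + asymmetry / 2
      s2 <- amplitude - asymmetry / 2
      s1 * outer(w1, u1) + s2 * outer(w2, u2)
    }
  } else {
    support <- 14
    gap <- sqrt(sum((p1 - p2)^2))
    if (gap <= support)
      stop("template too small: labrale supports overlap", call. = FALSE)
    w1 <- wendland(d1, support); w2 <- wendland(d2, support)
    u <- c(0, 0, 1)  # anterior protrusion
    peak_field <- function(amplitude, asymmetry = 0) {
      ((amplitude + asymmetry / 2) * w1 +
         (amplitude - asymmetry / 2) * w2) %o% u
    }
  }
  structure(list(expression = expression, pair = pair,
                 support = support, peak_field = peak_field),
            class = "expression_rig")
}

smoothstep <- function(s) 3 * s^2 - 2 * s^3

#' Animate an expression on the face template
#'
#' Produces a corresponded sequence: `rest_frames` static frames, a
#' smoothstep ramp from rest to peak over `time_to_peak` (quantized to
#' whole frames), then `hold_frames` at the peak. Optional tracking noise
#' is i.i.d. isotropic Gaussian per vertex per frame. The returned ground
#' truth records what the pipeline should recover: magnitude = commanded
#' amplitude, symmetry = |asymmetry|, time = the frame-quantized
#' time-to-peak, plus the true start/end frame indices.
#'
#' @param template a `face_template`.
#' @param expression `"smile"` or `"lip_purse"` (or a prebuilt
#'   [expression_rig]).
#' @param amplitude commanded magnitude (mm, > 0).
#' @param asymmetry commanded signed asymmetry (mm); the first landmark of
#'   the rig pair gets `+asymmetry/2`, the other `-asymmetry/2`.
#'   `|asymmetry|` must not exceed `2 * amplitude`.
#' @param time_to_peak commanded rise time (s).
#' @param rest_frames number of static frames before motion onset.
#' @param hold_frames number of frames held at the peak.
#' @param fps frame rate (Hz).
#' @param noise_sd tracking-noise SD (mm) per vertex coordinate per frame.
#' @param seed optional integer seed for the noise.
#' @param subject_id,timepoint metadata stamped on the sequence.
#' @return List with `sequence` (a [mesh_sequence] carrying the
#'   template's `fh_normal`) and `ground_truth` (list: magnitude,
#'   symmetry, time, start_index, end_index).
#' @export
animate_expression <- function(template, expression, amplitude,
                               asymmetry = 0, time_to_peak = 0.4,
                               rest_frames = 10L, hold_frames = 5L,
                               fps = 60, noise_sd = 0, seed = NULL,
                               subject_id = NA_character_,
                               timepoint = NA_character_) {
  rig <- if (inherits(expression, "expression_rig")) expression
         else expression_rig(template, expression)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (abs(asymmetry) > 2 * amplitude)
    stop("|asymmetry| > 2*amplitude would force negative landmark motion",
         call. = FALSE)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  n_ramp <- max(2L, as.integer(round(time_to_peak * fps)))
  if (!is.null(seed)) set.seed(seed)

  peak <- rig$peak_field(amplitude, asymmetry)
  base <- template$frame$vertices
  nv <- nrow(base)
  profile <- c(rep(0, rest_frames), smoothstep((0:n_ramp) / n_ramp),
               rep(1, hold_frames))
  frames <- lapply(seq_along(profile), function(i) {
    v <- base + profile[i] * peak
    if (noise_sd > 0)
      v <- v + matrix(stats::rnorm(nv * 3L, sd = noise_sd), nv, 3L)
    mesh_frame(v, template$frame$faces, index = i - 1L)
  })
  seq_ <- mesh_sequence(frames, fps = fps, subject_id = subject_id,
                        timepoint = timepoint,
                        expression = rig$expression,
                        fh_normal = template$fh_normal)
  list(
    sequence = seq_,
    ground_truth = list(
      magnitude = amplitude, symmetry = abs(asymmetry),
      time = n_ramp / fps,
      start_index = rest_frames, end_index = rest_frames + n_ramp
    )
  )
}
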