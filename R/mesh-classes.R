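#' @title Core mesh containers
#'
#' @description
#' `facemotion` represents a 4D recording as a [mesh_sequence]: an ordered
#' list of [mesh_frame]s sharing one vertex numbering (vertex-wise
#' correspondence), captured at a fixed frame rate. All coordinates are in
#' millimetres. Inside R, vertices are addressed 1-based (the native R
#' convention); on-disk interchange files (landmark maps, ROI exports) use
#' 0-based indices, converted at read/write time.
#'
#' @name facemotion-classes
NULL

#' Required anatomical landmark names
#'
#' The five landmarks every landmark map must define: subnasale anchors the
#' lower-face cutting plane; the two cheilia (mouth corners) are the
#' most-moving landmarks of a maximum smile; labrale superius/inferius
#' (midline vermilion points) are the most-moving landmarks of a lip purse.
#'
#' @export
REQUIRED_LANDMARKS <- c(
  "subnasale", "cheilion_right", "cheilion_left",
  "labrale_superius", "labrale_inferius"
)

#' Construct a single mesh frame
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces optional integer matrix of triangle vertex indices (1-based),
#'   one row per triangle. Geometry-only operations ignore it.
#' @param index 0-based frame number within its sequence.
#' @return An object of class `mesh_frame`.
#' @export
mesh_frame <- function(vertices, faces = NULL, index = 0L) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (nrow(vertices) < 1L)
    stop("a mesh frame needs at least one vertex", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must all be finite", call. = FALSE)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L)
      stop("faces must be an m x 3 matrix of triangles", call. = FALSE)
    storage.mode(faces) <- "integer"
    if (nrow(faces) > 0L &&
        (min(faces) < 1L || max(faces) > nrow(vertices)))
      stop("face indices out of vertex range", call. = FALSE)
  }
  structure(
    list(vertices = vertices, faces = faces, index = as.integer(index)),
    class = "mesh_frame"
  )
}

#' @export
print.mesh_frame <- function(x, ...) {
  cat(sprintf(
    "<mesh_frame> %d vertices, %s faces (frame %d)\n",
    nrow(x$vertices),
    if (is.null(x$faces)) "no" else format(nrow(x$faces)),
    x$index
  ))
  invisible(x)
}

n_vertices <- function(frame) nrow(frame$vertices)

#' Construct a corresponded mesh sequence
#'
#' Frames must all share the same vertex count; vertex `i` refers to the
#' same surface point in every frame (the correspondence contract that all
#' displacement-based metrics rely on).
#'
#' @param frames list of [mesh_frame]s in temporal order (at least two).
#' @param fps frame rate in Hz (> 0).
#' @param subject_id,timepoint,expression optional recording metadata;
#'   `timepoint` must be `"T0"` or `"T1"`, `expression` `"smile"` or
#'   `"lip_purse"` when given.
#' @param fh_normal optional unit vector giving the orientation (normal) of
#'   the Frankfort Horizontal plane in mesh coordinates, used to place the
#'   lower-face cutting plane. Supplied as capture metadata; the synthetic
#'   generator records its ground-truth value here.
#' @return An object of class `mesh_sequence`.
#' @export
mesh_sequence <- function(frames, fps, subject_id = NA_character_,
                          timepoint = NA_character_,
                          expression = NA_character_,
                          fh_normal = NULL) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("a mesh sequence needs at least two frames", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "mesh_frame")))
    stop("all frames must be mesh_frame objects", call. = FALSE)
  nv <- vapply(frames, n_vertices, integer(1))
  if (length(unique(nv)) != 1L) {
    bad <- which(nv != nv[1L])[1L]
    stop(sprintf(
      "correspondence error: frame %d has %d vertices, frame 0 has %d",
      bad - 1L, nv[bad], nv[1L]
    ), call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  if (!is.na(timepoint) && !timepoint %in% c("T0", "T1"))
    stop("timepoint must be 'T0' or 'T1'", call. = FALSE)
  if (!is.na(expression) && !expression %in% c("smile", "lip_purse"))
    stop("expression must be 'smile' or 'lip_purse'", call. = FALSE)
  if (!is.null(fh_normal)) fh_normal <- normalize_vector(fh_normal)
  for (i in seq_along(frames)) frames[[i]]$index <- i - 1L
  structure(
    list(
      frames = frames, fps = as.numeric(fps),
      subject_id = subject_id, timepoint = timepoint,
      expression = expression, fh_normal = fh_normal
    ),
    class = "mesh_sequence"
  )
}

#' @export
print.mesh_sequence <- function(x, ...) {
  cat(sprintf(
    "<mesh_sequence> %d frames x %d vertices @ %g fps (%.2f s)\n",
    length(x$frames), n_vertices(x$frames[[1L]]), x$fps,
    (length(x$frames) - 1L) / x$fps
  ))
  meta <- c(subject = x$subject_id, timepoint = x$timepoint,
            expression = x$expression)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.mesh_sequence <- function(x) length(x$frames)

#' Construct a landmark map
#'
#' @param indices named integer vector mapping landmark names to 1-based
#'   vertex indices. All of [REQUIRED_LANDMARKS] must be present; additional
#'   names (e.g. head-orientation landmarks) are allowed.
#' @param n_vertices optional vertex count to validate index range against.
#' @return An object of class `landmark_map` (a named integer vector).
#' @export
landmark_map <- function(indices, n_vertices = NULL) {
  indices <- vapply(indices, as.integer, integer(1))
  missing_lm <- setdiff(REQUIRED_LANDMARKS, names(indices))
  if (length(missing_lm))
    stop("landmark map is missing required landmark(s): ",
         paste(missing_lm, collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(indices)))
    stop("duplicate landmark names in map", call. = FALSE)
  if (any(indices < 1L))
    stop("landmark indices must be >= 1 (1-based in memory)", call. = FALSE)
  lm <- structure(indices, class = "landmark_map")
  if (!is.null(n_vertices)) validate_landmarks(lm, n_vertices)
  lm
}

#' Validate a landmark map against a vertex count
#'
#' @param landmarks a [landmark_map].
#' @param n_vertices vertex count of the mesh the map refers to.
#' @return `landmarks`, invisibly; errors if any index is out of range.
#' @export
validate_landmarks <- function(landmarks, n_vertices) {
  bad <- landmarks > n_vertices
  if (any(bad))
    stop(sprintf(
      "landmark index out of range for a %d-vertex mesh: %s",
      n_vertices,
      paste(sprintf("%s=%d", names(landmarks)[bad],
                    landmarks[bad] - 1L), collapse = ", ")
    ), call. = FALSE)
  invisible(landmarks)
}

#' @export
print.landmark_map <- function(x, ...) {
  cat("<landmark_map>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s -> vertex %d\n", nm, unclass(x)[[nm]] - 1L))
  invisible(x)
}

normalize_vector <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3L || !all(is.finite(v)))
    stop("expected a finite 3-vector", call. = FALSE)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector cannot be normalized", call. = FALSE)
  v / n
}
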