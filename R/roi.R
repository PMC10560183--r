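#' Regions of interest on the corresponded face mesh
#'
#' Two ROIs drive the kinematic parameters: (1) the *lower face*, all
#' vertices at or below a plane through subnasale oriented parallel to
#' Frankfort Horizontal, used for the Procrustes shape-change parameter;
#' (2) the *expression landmarks*, the two most-moving landmarks of each
#' expression (cheilion right/left for a maximum smile, labrale
#' superius/inferius for a lip purse), used for magnitude and symmetry.
#' Because frames are corresponded, an ROI computed on the clip's start
#' frame transfers to every other frame by vertex index.
#'
#' @name facemotion-roi
NULL

#' Construct the subnasale cutting plane
#'
#' Builds the plane through the subnasale vertex of `frame`, oriented
#' parallel to Frankfort Horizontal. FH itself is not reconstructible from
#' the lip landmarks, so its normal is supplied as capture metadata
#' (`fh_normal`, pointing toward the upper face); the synthetic generator
#' records the ground-truth normal on its sequences.
#'
#' @param frame a [mesh_frame].
#' @param landmarks a [landmark_map] valid for `frame`.
#' @param fh_normal non-zero 3-vector normal of Frankfort Horizontal,
#'   pointing superiorly; normalized internally.
#' @return A `cut_plane` object: list with unit `normal` and `point` (the
#'   subnasale position, mm).
#' @export
make_subnasale_plane <- function(frame, landmarks, fh_normal) {
  validate_landmarks(landmarks, n_vertices(frame))
  normal <- normalize_vector(fh_normal)
  point <- frame$vertices[landmarks[["subnasale"]], ]
  structure(list(point = point, normal = normal), class = "cut_plane")
}

#' Select the lower-face region of interest
#'
#' Returns the indices of all vertices with signed distance to the plane
#' `<= 0` (below subnasale when the normal points superiorly). Vertices
#' within `1e-9` mm of the plane count as below — a deterministic
#' tie-break for on-plane vertices such as subnasale itself.
#'
#' @param frame a [mesh_frame].
#' @param plane a `cut_plane` from [make_subnasale_plane()].
#' @return An `roi_selection`: list with sorted unique 1-based `indices`
#'   and `label = "lower_face"`.
#' @export
select_lower_face <- function(frame, plane) {
  if (!inherits(plane, "cut_plane"))
    stop("plane must be a cut_plane", call. = FALSE)
  d <- signed_plane_distance(frame$vertices, plane)
  idx <- which(d <= 1e-9)
  if (!length(idx))
    stop("lower-face ROI is empty: cutting plane lies below the whole mesh",
         call. = FALSE)
  roi_selection(idx, "lower_face", n_vertices(frame))
}

signed_plane_distance <- function(vertices, plane) {
  as.numeric(sweep(vertices, 2L, plane$point) %*% plane$normal)
}

#' Select the expression-specific most-moving landmarks
#'
#' @param landmarks a [landmark_map].
#' @param expression `"smile"` (cheilion right + left) or `"lip_purse"`
#'   (labrale superius + inferius).
#' @return An `roi_selection` with `label = "expression_landmarks"`; the
#'   `pair` attribute names the two landmarks in (right/superior,
#'   left/inferior) order.
#' @export
expression_landmarks <- function(landmarks, expression) {
  pair <- switch(expression,
    smile = c("cheilion_right", "cheilion_left"),
    lip_purse = c("labrale_superius", "labrale_inferius"),
    stop(sprintf("unknown expression '%s' (use 'smile' or 'lip_purse')",
                 expression), call. = FALSE)
  )
  idx <- unclass(landmarks)[pair]
  sel <- roi_selection(idx, "expression_landmarks")
  attr(sel, "pair") <- pair
  sel
}

roi_selection <- function(indices, label, n_vertices = NULL) {
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices))
    stop("ROI selection must be non-empty", call. = FALSE)
  if (!is.null(n_vertices) && (min(indices) < 1L || max(indices) > n_vertices))
    stop("ROI indices out of vertex range", call. = FALSE)
  structure(list(indices = indices, label = label), class = "roi_selection")
}

#' @export
print.roi_selection <- function(x, ...) {
  cat(sprintf("<roi_selection> '%s': %d vertices\n", x$label,
              length(x$indices)))
  invisible(x)
}

#' Export / import an ROI as a plain index list
#'
#' One 0-based vertex index per line (interchange convention), `#` comments
#' allowed; the label is stored as a comment on the first line.
#'
#' @param roi an `roi_selection`.
#' @param path file path.
#' @return `path` (write) or an `roi_selection` (read).
#' @export
write_roi <- function(roi, path) {
  writeLines(c(sprintf("# label: %s", roi$label),
               as.character(roi$indices - 1L)), path)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  label <- "lower_face"
  m <- grep("^#\\s*label:", lines, value = TRUE)
  if (length(m)) label <- trimws(sub("^#\\s*label:", "", m[1L]))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  roi_selection(as.integer(lines) + 1L, label)
}
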