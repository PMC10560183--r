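#' Ordinary Procrustes superimposition and the shape-change parameter
#'
#' The shape-change parameter quantifies how much the lower face deforms
#' during an expression, independent of head position and size: the start-
#' and end-frame lower-face configurations are superimposed by
#' translating, scaling and rotating, and the residual root-sum-of-squares
#' of landmark positions is the Procrustes distance. Reflections are never
#' allowed — a face cannot mirror between frames.
#'
#' @name facemotion-procrustes
NULL

centroid_size <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  sqrt(sum(Xc^2))
}

# rotation (det +1) minimizing ||X - Y R||_F for centred row-point matrices
optimal_rotation <- function(Yc, Xc) {
  s <- svd(crossprod(Yc, Xc))  # t(Yc) %*% Xc
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) stop("degenerate configuration: rank < 2", call. = FALSE)
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, traced = sum(s$d * c(1, 1, d)))
}

# rigid (rotation + translation, unit scale) fit of Y onto X
rigid_fit <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  rot <- optimal_rotation(Yc, Xc)
  list(rotation = rot$R, translation = cx - as.numeric(cy %*% rot$R))
}

check_configuration <- function(X, name) {
  X <- as.matrix(X)
  if (ncol(X) != 3L)
    stop(sprintf("%s must be an n x 3 configuration", name), call. = FALSE)
  if (nrow(X) < 3L)
    stop(sprintf("%s needs at least 3 landmarks", name), call. = FALSE)
  if (!all(is.finite(X)))
    stop(sprintf("%s has non-finite coordinates", name), call. = FALSE)
  if (centroid_size(X) < .Machine$double.eps^0.5)
    stop(sprintf("degenerate configuration: %s has zero centroid size",
                 name), call. = FALSE)
  sv <- svd(sweep(X, 2L, colMeans(X)), nu = 0, nv = 0)$d
  if (sv[2L] < 1e-9 * sv[1L])
    stop(sprintf("degenerate configuration: %s has rank < 2", name),
         call. = FALSE)
  X
}

#' Ordinary Procrustes superimposition of one configuration onto another
#'
#' Finds the similarity transform (translation, scale, proper rotation) of
#' `Y` minimizing the sum of squared distances to `X`. `X` is the
#' reference and is left untouched; in the pipeline the end frame is
#' mapped onto the start frame, so change is expressed in the rest pose.
#'
#' @param X reference configuration: n x 3 matrix of landmark positions
#'   (mm), n >= 3 non-collinear points.
#' @param Y configuration to superimpose; same landmark count and order.
#' @return A `superimposition` object: `aligned` (transformed `Y`),
#'   `scale`, `rotation` (3 x 3, det +1), `translation` (so that
#'   `aligned = scale * Y %*% rotation + translation`), and `residual`,
#'   the root-sum-of-squared distances between `X` and `aligned` (mm).
#' @export
superimpose <- function(X, Y) {
  X <- check_configuration(X, "X")
  Y <- check_configuration(Y, "Y")
  if (nrow(X) != nrow(Y))
    stop("configurations must have equal landmark counts", call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  rot <- optimal_rotation(Yc, Xc)
  if (rot$traced <= 0)
    stop("degenerate configuration: no positive-scale fit", call. = FALSE)
  s <- rot$traced / sum(Yc^2)
  aligned <- s * Yc %*% rot$R + matrix(cx, nrow(X), 3L, byrow = TRUE)
  structure(
    list(
      aligned = aligned,
      scale = s,
      rotation = rot$R,
      translation = cx - s * as.numeric(cy %*% rot$R),
      residual = sqrt(sum((X - aligned)^2))
    ),
    class = "superimposition"
  )
}

#' @export
print.superimposition <- function(x, ...) {
  cat(sprintf("<superimposition> scale %.6g, residual %.6g mm\n",
              x$scale, x$residual))
  invisible(x)
}

#' Procrustes shape change between two configurations
#'
#' With `normalize = TRUE` (the default and the value reported as the
#' `shape_change` parameter), both configurations are first centred and
#' scaled to unit centroid size, then optimally rotated; the returned
#' value is the classical Procrustes distance
#' `sqrt(sum((X1 - Y1 R)^2))` on the unit-size shapes, zero iff the two
#' configurations differ only by a similarity transform. With
#' `normalize = FALSE`, the raw residual in mm after full similarity
#' superimposition ([superimpose()]) is returned (`shape_change_mm` in
#' pipeline output). Both variants are exported to CSV because the
#' size-normalized form matches the order of magnitude conventionally
#' reported for dense lower-face configurations, while the raw form keeps
#' physical units; see the methods vignette.
#'
#' @param start_cfg,end_cfg n x 3 landmark configurations (mm), matched
#'   row order, n >= 3.
#' @param normalize scale both configurations to unit centroid size before
#'   comparison (default `TRUE`).
#' @return Non-negative shape change; 0 iff the configurations are
#'   similarity-equivalent.
#' @export
shape_change <- function(start_cfg, end_cfg, normalize = TRUE) {
  X <- check_configuration(start_cfg, "start_cfg")
  Y <- check_configuration(end_cfg, "end_cfg")
  if (nrow(X) != nrow(Y))
    stop("configurations must have equal landmark counts", call. = FALSE)
  if (normalize) {
    Xc <- sweep(X, 2L, colMeans(X)) / centroid_size(X)
    Yc <- sweep(Y, 2L, colMeans(Y)) / centroid_size(Y)
    rot <- optimal_rotation(Yc, Xc)
    sqrt(max(0, sum((Xc - Yc %*% rot$R)^2)))
  } else {
    superimpose(X, Y)$residual
  }
}
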