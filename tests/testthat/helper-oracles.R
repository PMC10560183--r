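# Independent oracles used to validate the analytic implementations.

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

euler_rotation <- function(ang) {
  cz <- cos(ang[1L]); sz <- sin(ang[1L])
  cy <- cos(ang[2L]); sy <- sin(ang[2L])
  cx <- cos(ang[3L]); sx <- sin(ang[3L])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3L, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3L, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3L, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Numeric-optimization ordinary-Procrustes oracle: searches the similarity
# transform (3 Euler angles, log scale, translation) minimizing
# ||X - (s * Y R + t)||_F^2, multi-start BFGS. Returns the best residual
# root-sum-of-squares. Independent of the SVD-based implementation.
oracle_procrustes_residual <- function(X, Y, n_starts = 12L,
                                       fix_scale = FALSE) {
  objective <- function(par) {
    R <- euler_rotation(par[1:3])
    s <- if (fix_scale) 1 else exp(par[4L])
    t <- par[5:7]
    sum((X - (s * Y %*% R + matrix(t, nrow(X), 3L, byrow = TRUE)))^2)
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    ang <- runif(3, -pi, pi)
    s0 <- if (fix_scale) 1 else runif(1, 0.3, 3)
    t0 <- colMeans(X) - s0 * as.numeric(colMeans(Y) %*% euler_rotation(ang))
    start <- c(ang, log(s0), t0)
    f1 <- tryCatch(
      stats::optim(start, objective, method = "Nelder-Mead",
                   control = list(maxit = 2000)),
      error = function(e) NULL)
    if (is.null(f1)) next
    f2 <- tryCatch(
      stats::optim(f1$par, objective, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-15)),
      error = function(e) f1)
    if (f2$value < best) best <- f2$value
  }
  sqrt(max(best, 0))
}

# Exhaustive signed-rank enumeration: two-sided p over all 2^n sign
# assignments of the ranked absolute differences (no ties, no zeros).
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12L, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# Two-way ANOVA ICC oracle via aov(): mean squares from the fitted table.
oracle_icc <- function(ratings, kind) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1L]][, "Mean Sq"]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  if (kind == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
}

# Small random mesh sequence fixture (not face-like; IO/geometry tests).
random_sequence <- function(n_frames = 3L, n_vertices = 12L, fps = 60,
                            with_faces = TRUE) {
  faces <- if (with_faces)
    cbind(1:(n_vertices - 2L), 2:(n_vertices - 1L), 3:n_vertices)
  frames <- lapply(seq_len(n_frames), function(i)
    mesh_frame(matrix(rnorm(n_vertices * 3L, sd = 10), n_vertices, 3L),
               faces = faces, index = i - 1L))
  mesh_sequence(frames, fps = fps)
}

toy_landmarks <- function(n_vertices = 12L) {
  landmark_map(c(subnasale = 1L, cheilion_right = 2L, cheilion_left = 3L,
                 labrale_superius = 4L, labrale_inferius = 5L),
               n_vertices = n_vertices)
}

# shared default template (built once per test run)
shared_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- build_face_template()
    tpl
  }
})
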