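make_clip <- function(v0, v1, fps = 60) {
  expression_clip(mesh_sequence(list(mesh_frame(v0), mesh_frame(v1)),
                                fps = fps), 0L, 1L)
}

test_that("displacement field is the per-vertex start-to-end distance", {
  v0 <- matrix(0, 4L, 3L)
  v1 <- rbind(c(3, 4, 0), c(0, 0, 0), c(1, 0, 0), c(0, 0, 2))
  d <- displacement_field(make_clip(v0, v1))
  expect_equal(as.numeric(d), c(5, 0, 1, 2))
  # identical frames -> all zeros
  expect_equal(as.numeric(displacement_field(make_clip(v1, v1))),
               rep(0, 4L))
  # brute-force oracle on a random clip
  set.seed(301)
  a <- matrix(rnorm(30), 10L, 3L); b <- matrix(rnorm(30), 10L, 3L)
  d2 <- as.numeric(displacement_field(make_clip(a, b)))
  oracle <- vapply(1:10, function(i) sqrt(sum((b[i, ] - a[i, ])^2)),
                   numeric(1))
  expect_equal(d2, oracle, tolerance = 1e-12)
})

test_that("displacement field is invariant under common rigid motion", {
  set.seed(302)
  a <- matrix(rnorm(30), 10L, 3L); b <- matrix(rnorm(30), 10L, 3L)
  ref <- as.numeric(displacement_field(make_clip(a, b)))
  for (i in 1:10) {
    R <- random_rotation(); t <- rnorm(3, sd = 20)
    tr <- function(x) x %*% R + matrix(t, 10L, 3L, byrow = TRUE)
    got <- as.numeric(displacement_field(make_clip(tr(a), tr(b))))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("magnitude and symmetry follow the two-landmark definitions", {
  lm <- toy_landmarks()
  field <- structure(c(0, 10, 12, 3, 7, rep(0, 7)),
                     class = "displacement_field")
  expect_equal(magnitude(field, lm, "smile"), 11)
  expect_equal(symmetry(field, lm, "smile"), 2)
  expect_equal(magnitude(field, lm, "lip_purse"), 5)
  expect_equal(symmetry(field, lm, "lip_purse"), 4)
  expect_error(magnitude(field, lm, "frown"), "unknown expression")

  zero <- structure(rep(0, 12L), class = "displacement_field")
  expect_equal(magnitude(zero, lm, "smile"), 0)
  expect_equal(symmetry(zero, lm, "smile"), 0)

  # order independence: swapping left/right leaves both unchanged
  swapped <- landmark_map(c(subnasale = 1L, cheilion_right = 3L,
                            cheilion_left = 2L, labrale_superius = 5L,
                            labrale_inferius = 4L))
  expect_equal(magnitude(field, swapped, "smile"),
               magnitude(field, lm, "smile"))
  expect_equal(symmetry(field, swapped, "smile"),
               symmetry(field, lm, "smile"))
})

test_that("symmetry never exceeds twice the magnitude", {
  lm <- toy_landmarks()
  set.seed(303)
  for (i in 1:1000) {
    f <- structure(abs(rnorm(12L, sd = 5)), class = "displacement_field")
    expect_lte(symmetry(f, lm, "smile"), 2 * magnitude(f, lm, "smile"))
  }
})

test_that("time to peak is the trimmed frame span over fps", {
  s <- random_sequence(n_frames = 30L, n_vertices = 5L, fps = 60)
  expect_equal(time_to_peak(expression_clip(s, 0L, 25L)), 25 / 60)
  expect_equal(time_to_peak(expression_clip(s, 5L, 6L)), 1 / 60)
  s30 <- random_sequence(n_frames = 30L, n_vertices = 5L, fps = 30)
  expect_equal(time_to_peak(expression_clip(s30, 0L, 24L)), 0.8)
  # frame quantization: time * fps is always an integer
  expect_equal((time_to_peak(expression_clip(s, 3L, 17L)) * 60) %% 1, 0)
})

test_that("clip invariants reject inverted or out-of-range frame indices", {
  s <- random_sequence(n_frames = 10L, n_vertices = 5L)
  expect_error(expression_clip(s, 5L, 5L), "invalid clip")
  expect_error(expression_clip(s, -1L, 5L), "invalid clip")
  expect_error(expression_clip(s, 0L, 10L), "invalid clip")
})

test_that("trim_clip recovers the commanded rest and peak frames", {
  tpl <- shared_template()
  sim <- animate_expression(tpl, "smile", amplitude = 16,
                            time_to_peak = 25 / 60, rest_frames = 10L,
                            noise_sd = 0)
  clip <- trim_clip(sim$sequence, tpl$landmarks, "smile")
  expect_lte(abs(clip$start_index - 10L), 1L)
  expect_lte(abs(clip$end_index - 35L), 1L)

  # already-trimmed sequence (motion from frame 0) -> start 0
  sim0 <- animate_expression(tpl, "smile", amplitude = 16,
                             time_to_peak = 25 / 60, rest_frames = 0L,
                             noise_sd = 0)
  clip0 <- trim_clip(sim0$sequence, tpl$landmarks, "smile")
  expect_identical(clip0$start_index, 0L)

  # static sequence -> "no expression detected"
  static <- mesh_sequence(replicate(12L, tpl$frame, simplify = FALSE),
                          fps = 60)
  expect_error(trim_clip(static, tpl$landmarks, "smile"),
               "no expression detected")

  # manual override bypasses detection
  manual <- trim_clip(sim$sequence, tpl$landmarks, "smile",
                      start_index = 3L, end_index = 20L)
  expect_identical(c(manual$start_index, manual$end_index), c(3L, 20L))
})

test_that("pipeline metrics equal the manual composition of module calls", {
  tpl <- shared_template()
  sim <- animate_expression(tpl, "lip_purse", amplitude = 9, asymmetry = 1,
                            time_to_peak = 0.35, noise_sd = 0.1, seed = 42L,
                            subject_id = "S01", timepoint = "T0")
  clip <- trim_clip(sim$sequence, tpl$landmarks, "lip_purse")
  met <- compute_motion_metrics(clip, tpl$landmarks)

  field <- displacement_field(clip)
  expect_equal(met$magnitude, magnitude(field, tpl$landmarks, "lip_purse"))
  expect_equal(met$symmetry, symmetry(field, tpl$landmarks, "lip_purse"))
  expect_equal(met$time, time_to_peak(clip))
  start_fr <- sim$sequence$frames[[clip$start_index + 1L]]
  end_fr <- sim$sequence$frames[[clip$end_index + 1L]]
  pl <- make_subnasale_plane(start_fr, tpl$landmarks, tpl$fh_normal)
  roi <- select_lower_face(start_fr, pl)
  expect_equal(met$shape_change,
               shape_change(start_fr$vertices[roi$indices, ],
                            end_fr$vertices[roi$indices, ]))
})

test_that("upper-face stabilization removes a common rigid head drift", {
  tpl <- shared_template()
  sim <- animate_expression(tpl, "smile", amplitude = 12,
                            time_to_peak = 0.4, noise_sd = 0)
  drifted <- sim$sequence
  ang <- 0.02
  R <- euler_rotation(c(ang, -ang, ang / 2))
  for (i in seq_along(drifted$frames)[-1L]) {
    v <- drifted$frames[[i]]$vertices
    drifted$frames[[i]]$vertices <-
      v %*% R + matrix(c(1.5, -1, 0.5), nrow(v), 3L, byrow = TRUE)
  }
  stab <- stabilize_sequence(drifted, tpl$landmarks)
  clip <- trim_clip(stab, tpl$landmarks, "smile")
  field <- displacement_field(clip)
  expect_equal(magnitude(field, tpl$landmarks, "smile"), 12,
               tolerance = 0.05)
})
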