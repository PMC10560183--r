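test_that("the default template is deterministic and bilaterally symmetric", {
  t1 <- build_face_template()
  t2 <- build_face_template()
  expect_identical(t1$frame$vertices, t2$frame$vertices)
  expect_identical(t1$landmarks, t2$landmarks)
  # mirror about the midsagittal (x = 0) plane maps the vertex set to itself
  v <- t1$frame$vertices
  mirrored <- v %*% diag(c(-1, 1, 1))
  ord <- function(m) m[order(round(m[, 1L], 6), round(m[, 2L], 6),
                             round(m[, 3L], 6)), ]
  expect_equal(ord(mirrored), ord(v), tolerance = 1e-9)
  # cheilion landmarks are mirror images
  lmk <- unclass(t1$landmarks)
  expect_equal(v[lmk[["cheilion_right"]], ] * c(-1, 1, 1),
               v[lmk[["cheilion_left"]], ], tolerance = 1e-9)
})

test_that("template construction rejects incompatible resolutions", {
  expect_error(build_face_template(grid_resolution = c(10L, 10L)),
               "at least 600")
  expect_error(build_face_template(grid_resolution = c(30L, 30L)), "odd")
  expect_error(build_face_template(grid_resolution = c(33L, 30L)),
               "559")
  # another divisor of 558 also satisfies the lower-face constraint
  t93 <- build_face_template(grid_resolution = c(93L, 12L))
  pl <- make_subnasale_plane(t93$frame, t93$landmarks, t93$fh_normal)
  expect_length(select_lower_face(t93$frame, pl)$indices, 559L)
})

test_that("rigs command exact landmark displacements at unit amplitude", {
  tpl <- shared_template()
  for (expr in c("smile", "lip_purse")) {
    rig <- expression_rig(tpl, expr)
    lmk <- unclass(tpl$landmarks)[rig$pair]
    field <- rig$peak_field(1, 0)
    d <- sqrt(rowSums(field^2))
    expect_equal(mean(d[unlist(lmk)]), 1, tolerance = 1e-12)
    expect_equal(unname(d[lmk[[1L]]]), unname(d[lmk[[2L]]]),
                 tolerance = 1e-12)
    # the commanded pair moves at least as much as any other vertex
    expect_gte(min(d[unlist(lmk)]), max(d) - 1e-9)
    # asymmetric command splits exactly
    field2 <- rig$peak_field(10, 3)
    d2 <- sqrt(rowSums(field2^2))
    expect_equal(unname(d2[lmk[[1L]]]), 11.5, tolerance = 1e-9)
    expect_equal(unname(d2[lmk[[2L]]]), 8.5, tolerance = 1e-9)
  }
})

test_that("zero-noise animation recovers all commanded parameters exactly", {
  tpl <- shared_template()
  sim <- animate_expression(tpl, "smile", amplitude = 16, asymmetry = 0,
                            time_to_peak = 0.4, noise_sd = 0)
  clip <- trim_clip(sim$sequence, tpl$landmarks, "smile")
  field <- displacement_field(clip)
  expect_equal(magnitude(field, tpl$landmarks, "smile"), 16,
               tolerance = 1e-6)
  expect_equal(symmetry(field, tpl$landmarks, "smile"), 0,
               tolerance = 1e-6)

  sim2 <- animate_expression(tpl, "smile", amplitude = 16, asymmetry = 2,
                             time_to_peak = 0.4, noise_sd = 0)
  clip2 <- trim_clip(sim2$sequence, tpl$landmarks, "smile")
  expect_equal(symmetry(displacement_field(clip2), tpl$landmarks, "smile"),
               2, tolerance = 1e-6)
  expect_equal(time_to_peak(clip2), 0.4, tolerance = 1 / 60 + 1e-9)

  expect_error(animate_expression(tpl, "smile", amplitude = 5,
                                  asymmetry = 11), "asymmetry")
  expect_error(animate_expression(tpl, "smile", amplitude = -1), "amplitude")
})

test_that("tracking noise leaves magnitude nearly unbiased", {
  tpl <- shared_template()
  rig <- expression_rig(tpl, "smile")
  errs <- vapply(1:20, function(i) {
    sim <- animate_expression(tpl, rig, amplitude = 15, asymmetry = 0,
                              time_to_peak = 0.4, noise_sd = 0.2,
                              seed = 7000L + i)
    clip <- trim_clip(sim$sequence, tpl$landmarks, "smile")
    magnitude(displacement_field(clip), tpl$landmarks, "smile") - 15
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("cohort ground truth is reproducible and structurally valid", {
  cfg <- default_cohort_config(seed = 11L)
  t1 <- draw_cohort_truth(cfg)
  t2 <- draw_cohort_truth(cfg)
  expect_identical(t1, t2)

  # every subject appears at both timepoints for both expressions
  counts <- table(t1$subject_id, t1$timepoint, t1$expression)
  expect_true(all(counts == 1L))
  # covariates constant within subject
  cov_cols <- c(facemotion:::covariate_columns, "intervention",
                "skeletal_class")
  per_subj <- tapply(seq_len(nrow(t1)), t1$subject_id, function(i) {
    nrow(unique(t1[i, cov_cols]))
  })
  expect_true(all(per_subj == 1L))
  expect_true(all(t1$magnitude > 0))
  expect_true(all(t1$symmetry >= 0))
  expect_true(all(t1$symmetry <= 2 * t1$magnitude))
  expect_true(all(t1$time > 0))
  frames <- t1$time * cfg$fps
  expect_true(all(abs(frames - round(frames)) < 1e-9))
  expect_setequal(unique(t1$skeletal_class), c("II", "III"))

  # degenerate config: no between/within spread -> identical subjects
  cfg0 <- default_cohort_config(seed = 3L)
  for (e in c("smile", "lip_purse")) {
    cfg0$magnitude[[e]]$sd_between <- 0
    cfg0$magnitude[[e]]$sd_within <- 0
    cfg0$magnitude[[e]]$mu[, ] <- 12
  }
  t0 <- draw_cohort_truth(cfg0)
  expect_true(all(t0$magnitude == 12))
})

test_that("single recordings are regenerable in isolation from their seed", {
  cfg <- default_cohort_config(n_subjects = 4L, seed = 21L)
  cohort <- generate_cohort(cfg, template = shared_template())
  r <- cohort$truth[5L, ]
  again <- animate_expression(
    shared_template(),
    expression_rig(shared_template(), r$expression),
    amplitude = r$magnitude, asymmetry = r$asymmetry,
    time_to_peak = r$time, rest_frames = cfg$rest_frames,
    hold_frames = cfg$hold_frames, fps = cfg$fps,
    noise_sd = cfg$noise_sd, seed = r$noise_seed,
    subject_id = r$subject_id, timepoint = r$timepoint)$sequence
  key <- paste(r$subject_id, r$timepoint, r$expression, sep = "/")
  orig <- cohort$sequences[[key]]
  expect_identical(orig$frames[[10L]]$vertices, again$frames[[10L]]$vertices)
})
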