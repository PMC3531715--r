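test_that("position smoothing passes slow motion and rejects jitter", {
  fs <- 120
  t <- seq(0, 5, by = 1 / fs)
  df <- data.frame(hip_x = rep(0.3, length(t)), hip_y = rep(-1, length(t)))
  out <- smooth_positions(df, fs)
  expect_equal(out$hip_x, df$hip_x, tolerance = 1e-4)

  slow <- data.frame(hip_x = sin(2 * pi * 1 * t), hip_y = rep(0, length(t)))
  y <- smooth_positions(slow, fs)$hip_x
  mid <- seq(fs, length(t) - fs)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.02)

  fast <- data.frame(hip_x = sin(2 * pi * 30 * t), hip_y = rep(0, length(t)))
  y2 <- smooth_positions(fast, fs)$hip_x
  expect_lt(max(abs(y2[mid])), 0.01)
  expect_error(smooth_positions(df, fs, cutoff = 100), "fs/2")
})

test_that("angular position follows the stated convention", {
  below <- matrix(c(0, -1), 1)
  expect_equal(angular_position(below)$theta, 0)
  above <- matrix(c(0, 1), 1)
  expect_equal(angular_position(above)$theta, 180)
  side <- matrix(c(1, 0), 1)
  expect_equal(angular_position(side, direction = 1)$theta, 90)
  other <- matrix(c(-1, 0), 1)
  expect_equal(angular_position(other, direction = 1)$theta, 270)
  expect_error(angular_position(matrix(c(0, 0), 1)), "coincides")
})

test_that("joint angles are interior angles in degrees", {
  mk <- function(sh, el, hp, kn) {
    data.frame(shoulder_x = sh[1], shoulder_y = sh[2],
               elbow_x = el[1], elbow_y = el[2],
               hip_x = hp[1], hip_y = hp[2],
               knee_x = kn[1], knee_y = kn[2])
  }
  # colinear chain: both angles 180
  straight <- mk(c(0, 0), c(0, 1), c(0, -1), c(0, -2))
  ja <- joint_angles(straight)
  expect_equal(ja$shoulder, 180)
  expect_equal(ja$hip, 180)
  # perpendicular arm
  bent <- mk(c(0, 0), c(1, 0), c(0, -1), c(0, -2))
  expect_equal(joint_angles(bent)$shoulder, 90)
  # constructed 150-degree hip flexion
  a <- 150 * pi / 180
  flexed <- mk(c(0, 0), c(0, 1), c(0, -1),
               c(sin(pi - a), -1 - cos(pi - a)))
  expect_equal(joint_angles(flexed)$hip, 150, tolerance = 1e-6)
  degenerate <- mk(c(0, 0), c(0, 0), c(0, -1), c(0, -2))
  expect_error(joint_angles(degenerate), "degenerate")
})

test_that("angular velocity matches uniform rotation and an analytic derivative", {
  fs <- 100
  t <- seq(0, 1.5, by = 1 / fs)
  theta_unif <- 240 * t
  expect_equal(angular_velocity(theta_unif, fs), rep(240, length(t)),
               tolerance = 1e-9)
  expect_equal(angular_velocity(rep(45, 10), fs), rep(0, 10))
  theta_sin <- 30 * sin(2 * pi * 0.5 * t)
  w <- angular_velocity(theta_sin, fs)
  w_true <- 30 * 2 * pi * 0.5 * cos(2 * pi * 0.5 * t)
  mid <- 2:(length(t) - 1)
  expect_equal(w[mid], w_true[mid], tolerance = 5e-3 * max(abs(w_true)))
})

test_that("whole-body CG is the mass-weighted mean of segment CGs", {
  model <- body_model(body_mass = 60, segments = data.frame(
    name = c("a", "b"), from = c("wrist", "elbow"), to = c("elbow", "hip"),
    mass_fraction = c(0.25, 0.75), cg_fraction = c(0.5, 0.4),
    gyration_fraction = c(0.3, 0.3), length = c(1, 2)))
  mk <- data.frame(wrist_x = 0, wrist_y = 0, elbow_x = 0, elbow_y = -1,
                   hip_x = 2, hip_y = -1)
  bc <- body_cg(mk, model, fs = 100)
  cg_a <- c(0, -0.5)
  cg_b <- c(0.8, -1)
  expect_equal(as.vector(bc$cg), 0.25 * cg_a + 0.75 * cg_b, tolerance = 1e-12)
  # symmetric static pose about the bar vertical has CG x = 0
  st <- static_markers()
  bc2 <- body_cg(st, body_model(), fs = 100)
  expect_equal(max(abs(bc2$cg[, 1])), 0, tolerance = 1e-12)
})

test_that("moment of inertia reproduces the point-mass formula and the parallel-axis identity", {
  # single segment: body CG = segment CG so d = 0 and I_G = M (l r)^2
  mdl <- one_segment_model(M = 70, length = 1, gyration_fraction = 0.3)
  mk <- data.frame(wrist_x = 0, wrist_y = 0, hip_x = 0, hip_y = -1)
  expect_equal(moment_of_inertia(mk, mdl, 100), 70 * 0.09, tolerance = 1e-12)
  mdl0 <- one_segment_model(M = 70, length = 1, gyration_fraction = 0)
  expect_equal(moment_of_inertia(mk, mdl0, 100), 0)

  # five-segment pose: parallel-axis identity I_bar = I_G + M |cg|^2
  cfg <- swing_sim_config(length_modulation = 0.4, n_cycles = 1)
  markers <- simulate_giant_swing(cfg)
  model <- cfg$model
  f <- 25  # one arbitrary frame
  row <- markers[f, , drop = FALSE]
  IG <- moment_of_inertia(row, model, cfg$frame_rate)
  bc <- body_cg(row, model, cfg$frame_rate)
  I_bar <- 0
  for (i in seq_len(nrow(model$segments))) {
    s <- bc$segments[[model$segments$name[i]]]
    mi <- model$M * model$segments$mass_fraction[i]
    I_bar <- I_bar + mi * (s$length * model$segments$gyration_fraction[i])^2 +
      mi * sum(s$cg[1, ]^2)
  }
  expect_equal(IG, I_bar - model$M * sum(bc$cg[1, ]^2), tolerance = 1e-9)
  # the CG minimises the second moment: any other reference gives more
  expect_lt(IG, I_bar)
})

test_that("total energy of a static pose is purely potential and mass-normalised", {
  st <- static_markers()
  model <- body_model()
  E <- total_energy(st, model, fs = 100)
  bc <- body_cg(st, model, fs = 100)
  expect_equal(E, rep(model$g * as.numeric(bc$cg[1, 2]), nrow(st)),
               tolerance = 1e-9)
  # doubling body mass leaves the mass-normalised energy unchanged
  model2 <- body_model(body_mass = 2 * model$M)
  expect_equal(total_energy(st, model2, fs = 100), E, tolerance = 1e-9)
})

test_that("energy bookkeeping is invariant to horizontal shifts and linear in vertical shifts", {
  cfg <- swing_sim_config(n_cycles = 1)
  markers <- simulate_giant_swing(cfg)
  model <- cfg$model
  E0 <- total_energy(markers, model, cfg$frame_rate)
  shifted <- markers
  for (cl in grep("_x$", names(markers), value = TRUE))
    shifted[[cl]] <- shifted[[cl]] + 3.7
  expect_equal(total_energy(shifted, model, cfg$frame_rate), E0,
               tolerance = 1e-9)
  lifted <- markers
  for (cl in grep("_y$", names(markers), value = TRUE))
    lifted[[cl]] <- lifted[[cl]] + 2
  expect_equal(total_energy(lifted, model, cfg$frame_rate), E0 + model$g * 2,
               tolerance = 1e-9)
})

test_that("the simulated swing covers full rotations and conserves energy when rigid", {
  cfg <- swing_sim_config(friction = 0, length_modulation = 0, n_cycles = 2)
  markers <- simulate_giant_swing(cfg)
  kin <- swing_kinematics(markers, cfg$model, cfg$frame_rate)
  total_rot <- kin$theta_unwrapped[length(kin$theta_unwrapped)] -
    kin$theta_unwrapped[1]
  expect_gte(total_rot, 2 * 360 - 1)
  expect_true(all(kin$theta >= 0 & kin$theta < 360))
  n <- length(kin$E_Tot)
  e <- kin$E_Tot[3:(n - 2)]  # interior frames (central differences)
  expect_lt((max(e) - min(e)) / abs(mean(e)), 0.005)
  expect_true(all(kin$I_G > 0))
})

test_that("length modulation shrinks the moment of inertia during the ascent", {
  cfg <- swing_sim_config(length_modulation = 0.5, n_cycles = 2)
  markers <- simulate_giant_swing(cfg)
  kin <- swing_kinematics(markers, cfg$model, cfg$frame_rate)
  phase <- kin$theta
  ascent <- phase > 20 & phase < 160
  descent <- phase > 200 & phase < 340
  expect_lt(mean(kin$I_G[ascent]), mean(kin$I_G[descent]))
})

test_that("simulator configuration is validated", {
  expect_error(swing_sim_config(friction = -1), "non-negative")
  expect_error(swing_sim_config(length_modulation = 2), "0, 1")
  expect_error(swing_sim_config(frame_rate = 0), "positive")
})

test_that("angle re-indexing preserves cyclic continuity", {
  cfg <- swing_sim_config(n_cycles = 2)
  markers <- simulate_giant_swing(cfg)
  kin <- swing_kinematics(markers, cfg$model, cfg$frame_rate)
  prof <- profile_by_angle(kin$theta_unwrapped, kin$E_Tot, n_points = 100)
  expect_length(prof$mean, 100L)
  expect_equal(nrow(prof$cycles), 2L)
  # energy is conserved, so the angular profile is flat end to end
  expect_lt(abs(prof$mean[1] - prof$mean[100]) / abs(mean(prof$mean)), 0.01)
})
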