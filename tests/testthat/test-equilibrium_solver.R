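test_that("residual wrench reflects unopposed loads and slack ligaments", {
  model <- knee_model(slack_ligament_config())
  # separated pose, no loads at all -> zero wrench
  loads0 <- point_loads(model, fy = 0)
  r0 <- residual_wrench(joint_pose(ty = 4), loads0, model)
  expect_equal(r0, rep(0, 5), tolerance = 1e-12)
  # pure superior load W with the femur separated -> (0, -W, 0, 0, 0)
  W <- 400
  r <- residual_wrench(joint_pose(ty = 4), point_loads(model, fy = -W), model)
  expect_equal(r, c(0, -W, 0, 0, 0), tolerance = 1e-9)
})

test_that("symmetric vertical load solves to a symmetric pose", {
  model <- knee_model(slack_ligament_config())
  loads <- point_loads(model, fy = -600)
  # on the symmetric manifold the lateral force and frontal/transverse
  # moments vanish identically, so the vertical 1-DOF balance is a full
  # equilibrium
  lo <- -3; hi <- 1
  f <- function(ty) residual_wrench(joint_pose(ty = ty), loads, model)[2]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) * f(lo) <= 0) hi <- mid else lo <- mid
  }
  r <- residual_wrench(joint_pose(ty = (lo + hi) / 2), loads, model)
  expect_lt(abs(r[2]), 1e-6 * 600)
  expect_equal(r[c(1, 3, 4, 5)], rep(0, 4), tolerance = 1e-9)
  # the full 5-DOF solve stays symmetric to within the contact-cell scale
  sol <- solve_pose(joint_pose(), loads, model, dt = 6e-3,
                    control = list(bracket_ty = TRUE))
  expect_true(sol$converged)
  expect_lt(abs(sol$pose$tz), 0.3)
  expect_lt(abs(sol$pose$abduction_deg), 0.1)
  expect_lt(sol$scaled_norm, 1e-8)
  # lateral perturbation shifts the pose and the load split laterally
  sol2 <- solve_pose(sol$pose, point_loads(model, fy = -600, madd = -4000),
                     model, dt = 6e-3)
  expect_gt(sol2$pose$abduction_deg, 1e-3)
  cells <- model$geometry$cells
  lat0 <- sum(sol$detail$f_cell[cells$compartment == "lateral"])
  lat2 <- sum(sol2$detail$f_cell[cells$compartment == "lateral"])
  expect_gt(lat2, lat0)
})

test_that("sphere-on-foundation contact follows the Winkler scaling", {
  # drained elastic foundation: doubling the load gives ~sqrt(2) penetration
  cfg <- slack_ligament_config()
  cfg$material <- utils::modifyList(cfg$material,
                                    list(E_0 = 0, E_eps = 0, M_k = 0, chi = 1))
  cfg$geometry <- utils::modifyList(cfg$geometry,
                                    list(hoop_stiffness = 0, horn_stiffness = 0,
                                         cell_mm = 1.5))
  model <- knee_model(cfg)
  dt_drained <- 3e4          # long step: consolidation complete
  s1 <- solve_pose(joint_pose(), point_loads(model, fy = -150), model,
                   dt = dt_drained, control = list(bracket_ty = TRUE))
  s2 <- solve_pose(s1$pose, point_loads(model, fy = -300), model,
                   dt = dt_drained)
  p1 <- max(s1$detail$pen); p2 <- max(s2$detail$pen)
  expect_equal(p2 / p1, sqrt(2), tolerance = 0.06)
})

test_that("warm starting does not move the converged pose", {
  model <- knee_model(coarse_config())
  trial <- synth_gait(seed = 1)
  loads <- frame_loads(trial, model, 30)
  a <- solve_pose(joint_pose(flexion_deg = trial$flexion_deg[30]), loads,
                  model, dt = 6e-3, control = list(bracket_ty = TRUE))
  b <- solve_pose(joint_pose(flexion_deg = trial$flexion_deg[30],
                             ty = a$pose$ty - 0.3, tx = a$pose$tx + 0.5,
                             abduction_deg = a$pose$abduction_deg + 0.5),
                  loads, model, dt = 6e-3)
  expect_lt(abs(a$pose$ty - b$pose$ty), 1e-5)
  expect_lt(abs(a$pose$tx - b$pose$tx), 1e-4)
  expect_lt(abs(a$pose$abduction_deg - b$pose$abduction_deg), 1e-4)
})

test_that("a short stance run conserves load and tracks the double bump", {
  model <- knee_model(coarse_config())
  trial <- synth_gait(list(noise_sd = 0), seed = 3)
  frames <- seq(1, 101, by = 4)
  sol <- run_stance(trial, model, frames = frames)
  f <- sol$frames
  # vertical conservation at every frame
  resid <- abs(f$applied_fy_n + f$lig_fy_n + f$contact_fy_n) /
    pmax(abs(f$applied_fy_n), 1)
  expect_lt(max(resid), 1e-6)
  # JCF follows the double-bump loading
  locmax <- which(diff(sign(diff(f$jcf_bw))) == -2) + 1
  expect_gte(length(locmax), 2)
  # per-cell force sum equals the reported JCF
  expect_equal(f$jcf_n, f$jcf_medial_n + f$jcf_lateral_n, tolerance = 1e-9)
  # determinism of the full pipeline
  sol2 <- run_stance(trial, model, frames = frames)
  expect_identical(sol$frames, sol2$frames)
  # summary and accessors are consistent
  s <- summary(sol)
  expect_equal(s$peak_jcf_bw, max(f$jcf_bw))
  jcf <- joint_contact_force(sol, frame = frames[10])
  expect_equal(jcf$jcf_n, f$jcf_n[10])
})

test_that("a zero-load trial leaves only pre-strain-induced contact", {
  model <- knee_model(coarse_config())
  trial <- synth_gait(list(noise_sd = 0, peak_load_bw = 0,
                           extension_demand_nm = 0, flexion_demand_nm = 0,
                           adduction_peak_nm = 0, rotation_peak_nm = 0,
                           peak_flexion_deg = 3, base_flexion_deg = 3),
                      seed = 1)
  trial$muscle_drive[] <- NA_real_   # unbounded -> floor activation only
  sol <- run_stance(trial, model, frames = c(1, 25, 50))
  f <- sol$frames
  # near-constant, ligament-borne contact force
  expect_lt(diff(range(f$jcf_n)) / max(f$jcf_n), 0.25)
  expect_gt(min(f$jcf_n), 0)
})
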