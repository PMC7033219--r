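test_that("element force law has slack, toe and linear branches", {
  expect_equal(element_force(-0.02, 1, 0.03), 0)
  expect_equal(element_force(0.05, 1, 0.03), 0.25 * 0.0025 / 0.03)
  expect_equal(element_force(0.10, 1, 0.03), 0.07)
  # C0/C1 continuity at the toe/linear junction
  epsl <- 0.03; K <- 7.3
  expect_equal(element_force(2 * epsl, K, epsl), K * epsl, tolerance = 1e-14)
  d <- 1e-7
  slope_toe <- (element_force(2 * epsl, K, epsl) -
                  element_force(2 * epsl - d, K, epsl)) / d
  slope_lin <- (element_force(2 * epsl + d, K, epsl) -
                  element_force(2 * epsl, K, epsl)) / d
  expect_equal(slope_toe, K, tolerance = 1e-5)
  expect_equal(slope_lin, K, tolerance = 1e-5)
  # monotone non-decreasing and tension-only
  eps <- seq(-0.1, 0.3, by = 1e-3)
  f <- element_force(eps, 2.5, 0.03)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0))
  # linear scaling with bundle stiffness at fixed strain
  expect_equal(element_force(0.08, 4, 0.03), 2 * element_force(0.08, 2, 0.03))
})

test_that("pre-strain sets slack lengths so reference strain equals eps_r", {
  b <- ligament_bundle("ACL", K_l = 10, eps_r = 0.08, n_elements = 1,
                       femur_center = c(0, 30, 0), tibia_center = c(0, 0, 0),
                       footprint_radius = 1e-9)
  b <- apply_prestrain(b, joint_pose(), ref0 = c(0, 0, 0))
  expect_equal(b$L0, 30 / 1.08, tolerance = 1e-10)  # 27.7778 mm
  b2 <- ligament_bundle("PCL", 18, -0.135, 1, c(0, 30, 0), c(0, 0, 0), 1e-9)
  b2 <- apply_prestrain(b2, joint_pose(), c(0, 0, 0))
  expect_equal(b2$L0, 30 / 0.865, tolerance = 1e-4)  # 34.6821 mm
  st <- kneestance:::bundle_state(b2, joint_pose(), c(0, 0, 0))
  expect_lt(st$eps, 0)                               # slack at reference
  expect_error(ligament_bundle("X", 1, -1.2, 1, c(0, 1, 0), c(0, 0, 0)),
               "non-positive")
})

test_that("default bundles have the standard counts, stiffness and state", {
  geom <- generate_geometry()
  bundles <- build_default_ligaments(geom)
  expect_equal(sum(vapply(bundles, function(b) b$n_elements, 0)), 195)
  expect_equal(vapply(bundles, function(b) b$n_elements, 0),
               c(ACL = 60, PCL = 100, LCL = 15, MCL = 20))
  for (b in bundles)
    expect_equal(b$k_elem * b$n_elements, b$K_l, tolerance = 1e-12)
  expect_equal(bundles$ACL$K_l, 10)
  # reference pose: ACL and MCL taut, PCL and LCL slack
  for (nm in c("ACL", "MCL")) {
    st <- kneestance:::bundle_state(bundles[[nm]], geom$ref_pose, geom$ref0)
    expect_true(all(st$eps > 0), info = nm)
  }
  for (nm in c("PCL", "LCL")) {
    st <- kneestance:::bundle_state(bundles[[nm]], geom$ref_pose, geom$ref0)
    expect_true(all(st$eps < 0), info = nm)
  }
})

test_that("reference strain equals the pre-strain over the whole offset grid", {
  geom <- generate_geometry()
  ref <- c(ACL = 8, PCL = -13.5, LCL = -7.33, MCL = 3.66)
  for (lig in names(ref)) for (off in c(-10, -5, 0, 5, 10)) {
    offs <- c(ACL = 0, PCL = 0, LCL = 0, MCL = 0); offs[lig] <- off
    bundles <- build_default_ligaments(geom, offsets_pct = offs)
    st <- kneestance:::bundle_state(bundles[[lig]], geom$ref_pose, geom$ref0)
    expect_equal(st$eps, rep((ref[[lig]] + off) / 100, bundles[[lig]]$n_elements),
                 tolerance = 1e-12)
  }
})

test_that("bundle wrench sums element tensions about the reference point", {
  # all slack -> zero wrench
  b <- ligament_bundle("X", 5, -0.5, 10, c(0, 20, 0), c(0, 0, 0), 2)
  b <- apply_prestrain(b, joint_pose(), c(0, 0, 0))
  w <- bundle_wrench(list(b), joint_pose(), c(0, 0, 0))
  expect_equal(w$force, c(0, 0, 0))
  expect_equal(w$moment, c(0, 0, 0))

  # single taut element along -y with a lever arm: force and r x F
  b1 <- ligament_bundle("Y", 1, 0.1, 1, c(10, 25, 5), c(10, 0, 5), 1e-9)
  b1 <- apply_prestrain(b1, joint_pose(), c(0, 0, 0))
  w1 <- bundle_wrench(list(b1), joint_pose(), c(0, 0, 0))
  f_exp <- element_force(0.1, 1, 0.03) * 1000
  expect_equal(w1$force, c(0, -f_exp, 0), tolerance = 1e-9)
  expect_equal(w1$moment, kneestance:::cross3(c(10, 25, 5), c(0, -f_exp, 0)),
               tolerance = 1e-9)

  # raising eps_r never lowers any element tension at a fixed pose
  pose <- joint_pose(flexion_deg = 10, ty = -1)
  geom <- generate_geometry()
  t_prev <- -Inf
  for (off in c(-5, 0, 5, 10)) {
    bb <- build_default_ligaments(geom, offsets_pct = c(ACL = off))
    st <- kneestance:::bundle_state(bb$ACL, pose, geom$ref0)
    expect_gte(sum(st$f_kN), t_prev - 1e-12)
    t_prev <- sum(st$f_kN)
  }

  # sagittal mirror flips the z-component of the bundle force
  bm <- ligament_bundle("Z", 2, 0.05, 8, c(3, 20, 6), c(1, 0, -4), 2)
  bm <- apply_prestrain(bm, joint_pose(), c(0, 0, 0))
  bf <- ligament_bundle("Z", 2, 0.05, 8, c(3, 20, -6), c(1, 0, 4), 2)
  bf <- apply_prestrain(bf, joint_pose(), c(0, 0, 0))
  wm <- bundle_wrench(list(bm), joint_pose(), c(0, 0, 0))
  wf <- bundle_wrench(list(bf), joint_pose(), c(0, 0, 0))
  expect_equal(wf$force[3], -wm$force[3], tolerance = 1e-9)
  expect_equal(wf$force[1:2], wm$force[1:2], tolerance = 1e-9)
})
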