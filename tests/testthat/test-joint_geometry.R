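test_that("geometry generation is deterministic with the documented grid", {
  g <- generate_geometry(list(plateau_x = 30, plateau_z = 60, cell_mm = 1,
                              condyle_offset_z = 18, az = 10))
  expect_equal(nrow(g$cells), 1800)
  g1 <- generate_geometry(seed = 1)
  g2 <- generate_geometry(seed = 99)
  expect_identical(g1, g2)            # zero randomization amplitude
  g3 <- generate_geometry(list(thickness_jitter = 0.3), seed = 5)
  g4 <- generate_geometry(list(thickness_jitter = 0.3), seed = 5)
  expect_identical(g3, g4)
  expect_false(identical(g3$cells$thickness, g1$cells$thickness))
  # symmetric parameter set -> mirror-symmetric cells
  key <- function(g) {
    k <- g$cells[order(g$cells$x, g$cells$z), c("x", "y_surf")]
    rownames(k) <- NULL
    k
  }
  gm <- mirror_geometry(g1)
  expect_equal(key(gm), key(g1))
  expect_error(generate_geometry(list(condyle_offset_z = 60)), "geometry")
})

test_that("contact map matches sphere-on-plane geometry", {
  # lifted femur: no contact anywhere
  g <- generate_geometry()
  cm <- contact_gaps(g, joint_pose(ty = 5))
  expect_true(all(cm$penetration == 0))

  # spherical condyles on a nearly flat plateau: patch radius ~ sqrt(2 R d)
  gs <- generate_geometry(list(ax = 24, ay = 24, az = 12, cell_mm = 1,
                               dish_radius_mm = 1e9))
  d <- 0.4
  cms <- contact_gaps(gs, joint_pose(ty = -d))
  med <- cms[cms$compartment == "medial" & cms$penetration > 0, ]
  r_patch <- max(sqrt(med$x^2 + (med$z + gs$params$condyle_offset_z)^2))
  r_exp <- sqrt(2 * 24 * d)
  expect_lt(abs(r_patch - r_exp), 1.5)   # within ~one cell

  # translation consistency on the flat plateau: lifting by delta reduces
  # every positive penetration by exactly delta
  cms2 <- contact_gaps(gs, joint_pose(ty = -d + 0.1))
  sel <- cms2$penetration > 0
  expect_equal(cms2$penetration[sel], pmax(cms$penetration[sel] - 0.1, 0),
               tolerance = 1e-9)

  # an adduction tilt (medial side down) loads medial, unloads lateral
  cm0 <- contact_gaps(g, joint_pose(ty = -0.3))
  cmm <- contact_gaps(g, joint_pose(ty = -0.3, abduction_deg = -1))
  expect_gt(sum(cmm$penetration[cmm$compartment == "medial"]),
            sum(cm0$penetration[cm0$compartment == "medial"]))
  expect_lt(sum(cmm$penetration[cmm$compartment == "lateral"]),
            sum(cm0$penetration[cm0$compartment == "lateral"]))
  # a pure medial translation digs both condyles into their compartment
  # walls by the same amount (dished compartments, rigid femur)
  cmt <- contact_gaps(g, joint_pose(ty = -0.3, tz = -3))
  expect_equal(sum(cmt$penetration[cmt$compartment == "medial"]),
               sum(cmt$penetration[cmt$compartment == "lateral"]),
               tolerance = 1e-9)
  expect_gt(sum(cmt$penetration), sum(cm0$penetration))
})

test_that("contact areas sum cell areas with the pathway filter", {
  g <- generate_geometry()
  empty <- contact_area(contact_gaps(g, joint_pose(ty = 5)))
  expect_equal(empty$total, 0)
  expect_true(is.na(empty$ratio))
  expect_false(empty$ratio_defined)

  # hand-built map: 37 medial + 25 lateral contacting 1-mm2 cells
  map <- data.frame(x = 0, z = 0, area = 1,
                    penetration = c(rep(1, 37), rep(1, 25), 0),
                    compartment = c(rep("medial", 37), rep("lateral", 25), "medial"),
                    pathway = "cartilage-cartilage")
  a <- contact_area(map)
  expect_equal(a$medial, 37)
  expect_equal(a$lateral, 25)
  expect_equal(a$ratio, 1.48)

  # meniscus-covered cells are excluded by the cartilage-cartilage filter
  map$pathway[1:10] <- "cartilage-meniscus"
  acc <- contact_area(map, pathway = "cartilage-cartilage")
  expect_equal(acc$medial, 27)
})

test_that("meniscus load share degenerates and scales with hoop stiffness", {
  g0 <- generate_geometry(list(hoop_stiffness = 0, horn_stiffness = 0))
  m0 <- meniscus_load_share(g0)
  expect_equal(m0$medial$k_found, 0)
  expect_equal(m0$lateral$k_found, 0)
  g1 <- generate_geometry(list(hoop_stiffness = 150))
  g2 <- generate_geometry(list(hoop_stiffness = 300))
  m1 <- meniscus_load_share(g1); m2 <- meniscus_load_share(g2)
  expect_gt(m2$medial$k_found, m1$medial$k_found)
  # symmetric geometry: equal shares
  expect_equal(m1$medial$k_found, m1$lateral$k_found)
})
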