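# Parametric tibiofemoral geometry: two femoral condyle ellipsoids over a
# rectangular grid of tibial plateau cells (each cell backed by a cartilage
# column), shallow dished compartments, annular meniscus rings with hoop and
# horn-spring load sharing, and ligament attachment sites. Coordinates are a
# right-handed tibia-fixed frame of a right knee: x anterior, y superior,
# z lateral. The full-extension reference pose has the condyles just
# touching the compartment centers.

#' Joint pose (femur relative to tibia)
#'
#' Flexion is the prescribed primary degree of freedom; the remaining five
#' (two rotations, three translations) are solved from equilibrium.
#'
#' @param flexion_deg Knee flexion (deg).
#' @param abduction_deg Ab/adduction (deg, positive tips the lateral side
#'   down).
#' @param internal_deg Internal/external rotation (deg).
#' @param tx,ty,tz Anterior, superior and lateral translations (mm) of the
#'   femoral reference point from its full-extension position.
#' @return Object of class \code{joint_pose}.
#' @export
joint_pose <- function(flexion_deg = 0, abduction_deg = 0, internal_deg = 0,
                       tx = 0, ty = 0, tz = 0) {
  vals <- c(flexion_deg, abduction_deg, internal_deg, tx, ty, tz)
  if (any(!is.finite(vals))) stop_knee("pose must be finite")
  if (abs(abduction_deg) >= 90 || abs(internal_deg) >= 90)
    stop_knee("rotations must be within (-90, 90) deg")
  structure(list(flexion_deg = flexion_deg, abduction_deg = abduction_deg,
                 internal_deg = internal_deg, tx = tx, ty = ty, tz = tz),
            class = "joint_pose")
}

#' Generate a parametric knee geometry
#'
#' Builds the condyle-on-plateau stand-in for segmented imaging geometry:
#' condyle ellipsoid semi-axes and spacing, a plateau cell grid with
#' combined cartilage thickness, dished compartment surfaces, meniscus
#' rings and ligament attachment footprints. With zero randomization
#' amplitude the output is independent of the seed.
#'
#' @param params Named list overriding any of: \code{plateau_x} (AP extent
#'   mm, 45), \code{plateau_z} (ML extent mm, 80), \code{cell_mm} (grid
#'   pitch, 2), \code{condyle_offset_z} (22), \code{ax,ay,az} (condyle
#'   semi-axes mm, 28/24/18), \code{thickness_mm} (combined cartilage, 6),
#'   \code{dish_radius_mm} (80), \code{meniscus_r_in} (7),
#'   \code{meniscus_r_out} (14), \code{meniscus_wedge_tan} (0.5),
#'   \code{hoop_stiffness} (150 N/mm), \code{horn_stiffness} (200 N/mm per
#'   horn), \code{thickness_jitter} (randomization amplitude mm, 0).
#' @param seed Integer seed (only used when \code{thickness_jitter > 0}).
#' @return Object of class \code{knee_geometry}.
#' @export
generate_geometry <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    plateau_x = 45, plateau_z = 80, cell_mm = 2,
    condyle_offset_z = 22, ax = 28, ay = 24, az = 18,
    thickness_mm = 6, dish_radius_mm = 80,
    meniscus_r_in = 7, meniscus_r_out = 14, meniscus_wedge_tan = 0.5,
    hoop_stiffness = 150, horn_stiffness = 200,
    thickness_jitter = 0), params)
  if (p$cell_mm <= 0 || p$plateau_x <= 0 || p$plateau_z <= 0 ||
      p$ax <= 0 || p$ay <= 0 || p$az <= 0 || p$thickness_mm <= 0)
    stop_knee("geometry dimensions must be > 0")
  if (p$condyle_offset_z + p$az > p$plateau_z / 2 + p$cell_mm)
    stop_knee("geometry error: condyles extend beyond the plateau")
  # symmetric cell-center grid regardless of pitch/extent divisibility
  nx <- max(1, round(p$plateau_x / p$cell_mm))
  nz <- max(1, round(p$plateau_z / p$cell_mm))
  xs <- (seq_len(nx) - (nx + 1) / 2) * p$cell_mm
  zs <- (seq_len(nz) - (nz + 1) / 2) * p$cell_mm
  grid <- expand.grid(x = xs, z = zs)
  compartment <- ifelse(grid$z < 0, "medial", "lateral")
  zc <- ifelse(grid$z < 0, -p$condyle_offset_z, p$condyle_offset_z)
  kappa <- 1 / (2 * p$dish_radius_mm)
  y_surf <- kappa * (grid$x^2 + (grid$z - zc)^2)
  r_comp <- sqrt(grid$x^2 + (grid$z - zc)^2)
  meniscus <- r_comp >= p$meniscus_r_in & r_comp <= p$meniscus_r_out
  h <- rep(p$thickness_mm, nrow(grid))
  if (p$thickness_jitter > 0)
    h <- with_seed(seed, pmax(h + stats::rnorm(length(h), 0, p$thickness_jitter),
                              0.2 * p$thickness_mm))
  ref0 <- c(0, p$ay, 0)
  attachments <- list(
    ACL = list(femur = c(-6, -10, 7),  tibia = c(12, 0, 2),    footprint_radius = 4.5),
    PCL = list(femur = c(-4, -10, -5), tibia = c(-14, -4, 0),  footprint_radius = 5.7),
    LCL = list(femur = c(-2, -12, 38), tibia = c(0, -30, 40),  footprint_radius = 3),
    MCL = list(femur = c(0, -14, -36), tibia = c(1, -50, -37), footprint_radius = 3.5))
  horns <- list(
    medial = list(
      horn_spring(c(p$meniscus_r_out, 0, -p$condyle_offset_z + 2), c(p$meniscus_r_out + 4, -2, -p$condyle_offset_z + 4), p$horn_stiffness),
      horn_spring(c(-p$meniscus_r_out, 0, -p$condyle_offset_z + 2), c(-p$meniscus_r_out - 4, -2, -p$condyle_offset_z + 4), p$horn_stiffness)),
    lateral = list(
      horn_spring(c(p$meniscus_r_out, 0, p$condyle_offset_z - 2), c(p$meniscus_r_out + 4, -2, p$condyle_offset_z - 4), p$horn_stiffness),
      horn_spring(c(-p$meniscus_r_out, 0, p$condyle_offset_z - 2), c(-p$meniscus_r_out - 4, -2, p$condyle_offset_z - 4), p$horn_stiffness)))
  # outward surface normal of the dished plateau at each cell (used when
  # surface_normals is on; otherwise contact acts along the cell vertical)
  if (isTRUE(p$surface_normals %||% TRUE)) {
    gx <- 2 * kappa * grid$x
    gz <- 2 * kappa * (grid$z - zc)
    nn <- sqrt(1 + gx^2 + gz^2)
    nrm <- cbind(-gx / nn, 1 / nn, -gz / nn)
  } else {
    nrm <- cbind(0 * grid$x, 1 + 0 * grid$x, 0 * grid$x)
  }
  structure(list(
    params = p,
    cells = data.frame(x = grid$x, z = grid$z, area = p$cell_mm^2,
                       thickness = h, compartment = compartment,
                       meniscus = meniscus, y_surf = y_surf,
                       nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                       stringsAsFactors = FALSE),
    condyle_centers = rbind(medial = c(0, 0, -p$condyle_offset_z),
                            lateral = c(0, 0, p$condyle_offset_z)),
    semi_axes = c(p$ax, p$ay, p$az),
    ligament_attachments = attachments,
    horns = horns,
    ref0 = ref0,
    ref_pose = joint_pose(),
    total_area = sum(p$cell_mm^2 * rep(1, nrow(grid)))), class = "knee_geometry")
}

#' @export
print.knee_geometry <- function(x, ...) {
  cat(sprintf("<knee_geometry: %d cells (%.0f mm^2), condyle semi-axes %.0f/%.0f/%.0f mm>\n",
              nrow(x$cells), x$total_area, x$semi_axes[1], x$semi_axes[2],
              x$semi_axes[3]))
  invisible(x)
}

# Height of the lower surface of both condyle ellipsoids above each cell
# center (tibia frame), Inf where the vertical line misses the condyles.
condyle_lower_surface <- function(geom, pose) {
  R <- pose_rotation(pose)
  D <- diag(1 / geom$semi_axes^2)
  A <- R %*% D %*% t(R)
  rp <- ref_point_position(pose, geom$ref0)
  x <- geom$cells$x
  z <- geom$cells$z
  yf <- rep(Inf, length(x))
  for (ci in 1:2) {
    cen <- as.numeric(R %*% geom$condyle_centers[ci, ]) + rp
    dx <- x - cen[1]
    dz <- z - cen[3]
    Cq <- A[1, 1] * dx^2 + A[3, 3] * dz^2 + 2 * A[1, 3] * dx * dz - 1
    bq <- A[1, 2] * dx + A[2, 3] * dz
    disc <- bq^2 - A[2, 2] * Cq
    ok <- disc >= 0
    dy <- (-bq[ok] - sqrt(disc[ok])) / A[2, 2]
    yf[ok] <- pmin(yf[ok], cen[2] + dy)
  }
  yf
}

#' Contact penetration map
#'
#' Per-cell penetration of the femoral condyle surfaces into the (dished)
#' tibial plateau surface along the cell vertical, with cells under the
#' meniscus ring flagged as the cartilage-meniscus pathway.
#'
#' @param geom A \code{\link{generate_geometry}} result.
#' @param pose Current \code{\link{joint_pose}}.
#' @return Object of class \code{contact_map}: data.frame with columns
#'   \code{penetration} (mm, >= 0), \code{compartment}, \code{pathway} and
#'   the cell geometry.
#' @export
contact_gaps <- function(geom, pose) {
  yf <- condyle_lower_surface(geom, pose)
  pen <- pmax(0, geom$cells$y_surf - yf)
  pen[!is.finite(yf)] <- 0
  out <- data.frame(x = geom$cells$x, z = geom$cells$z,
                    area = geom$cells$area,
                    penetration = pen,
                    compartment = geom$cells$compartment,
                    pathway = ifelse(geom$cells$meniscus,
                                     "cartilage-meniscus", "cartilage-cartilage"),
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_map", "data.frame")
  out
}

#' Contact area per compartment
#'
#' Sums cell areas with positive penetration, optionally filtered to one
#' contact pathway (the cartilage-to-cartilage filter matches how contact
#' area is usually reported, excluding meniscus-covered cells).
#'
#' @param map A \code{\link{contact_gaps}} result.
#' @param pathway NULL (all), "cartilage-cartilage" or
#'   "cartilage-meniscus".
#' @return List with \code{medial}, \code{lateral} (mm^2), \code{total} and
#'   \code{ratio} (medial / lateral; NA with a \code{ratio_defined} flag
#'   when the lateral area is zero).
#' @export
contact_area <- function(map, pathway = NULL) {
  sel <- map$penetration > 0
  if (!is.null(pathway)) sel <- sel & map$pathway == pathway
  med <- sum(map$area[sel & map$compartment == "medial"])
  lat <- sum(map$area[sel & map$compartment == "lateral"])
  list(medial = med, lateral = lat, total = med + lat,
       ratio = if (lat > 0) med / lat else NA_real_,
       ratio_defined = lat > 0)
}

#' Meniscus load sharing
#'
#' Reduces each meniscus ring to an annular elastic foundation: vertical
#' squeeze of the wedge extrudes the ring radially; hoop tension and the
#' horn springs resist the extrusion, and the resulting vertical support is
#' spread over the covered cells as an added foundation stiffness. With
#' both hoop and horn stiffness zero the meniscus transmits no load.
#'
#' @param geom A \code{\link{generate_geometry}} result.
#' @return List per compartment with \code{k_found} (MPa/mm added
#'   foundation stiffness on covered cells), \code{covered_area} (mm^2) and
#'   \code{radial_stiffness} (N/mm).
#' @export
meniscus_load_share <- function(geom) {
  p <- geom$params
  out <- list()
  for (comp in c("medial", "lateral")) {
    cov <- geom$cells$meniscus & geom$cells$compartment == comp
    A <- sum(geom$cells$area[cov])
    k_horn <- sum(vapply(geom$horns[[comp]], function(h) h$stiffness, 0))
    k_rad <- p$hoop_stiffness + k_horn
    k_found <- if (A > 0) k_rad / (p$meniscus_wedge_tan^2 * A) else 0
    out[[comp]] <- list(k_found = k_found, covered_area = A,
                        radial_stiffness = k_rad)
  }
  out
}

#' Mirror a geometry in the sagittal plane
#'
#' Flips the medial-lateral axis (z to -z) of every cell, condyle,
#' attachment and horn spring, and swaps the compartment labels. Mirroring
#' geometry, loads and pre-strains swaps the medial and lateral outputs of
#' a stance solution exactly.
#'
#' @param geom A \code{\link{generate_geometry}} result.
#' @return The mirrored \code{knee_geometry}.
#' @export
mirror_geometry <- function(geom) {
  g <- geom
  g$cells$z <- -g$cells$z
  g$cells$nz <- -g$cells$nz
  g$cells$compartment <- ifelse(geom$cells$compartment == "medial",
                                "lateral", "medial")
  g$condyle_centers[, 3] <- -g$condyle_centers[, 3]
  rownames(g$condyle_centers) <- c("lateral", "medial")[match(rownames(geom$condyle_centers), c("medial", "lateral"))]
  for (nm in names(g$ligament_attachments)) {
    g$ligament_attachments[[nm]]$femur[3] <- -g$ligament_attachments[[nm]]$femur[3]
    g$ligament_attachments[[nm]]$tibia[3] <- -g$ligament_attachments[[nm]]$tibia[3]
  }
  mirror_horn <- function(h) {
    h$attach_meniscus[3] <- -h$attach_meniscus[3]
    h$attach_tibia[3] <- -h$attach_tibia[3]
    h
  }
  g$horns <- list(medial = lapply(geom$horns$lateral, mirror_horn),
                  lateral = lapply(geom$horns$medial, mirror_horn))
  g
}
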