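# Nonlinear ligament bundles. Each of the four main knee ligaments (ACL,
# PCL, LCL, MCL) is a bundle of parallel spring elements with a tension-only
# piecewise force-strain law: slack below zero strain, a quadratic toe up to
# strain 2*eps_l, and a linear region beyond. Pre-strain at the fully
# extended reference pose sets every element's slack length.

#' Tension in one ligament spring element
#'
#' Piecewise slack/toe/linear force-strain law for a nonlinear ligament
#' spring element: zero below zero strain, quadratic toe
#' \eqn{f = k \epsilon^2 / (4 \epsilon_l)} for \eqn{0 \le \epsilon \le 2\epsilon_l},
#' and linear \eqn{f = k(\epsilon - \epsilon_l)} beyond. The law is C1
#' continuous at the toe/linear junction.
#'
#' @param eps Current element strain (dimensionless, vectorized).
#' @param k Element stiffness in kN (force per unit strain in the linear
#'   region).
#' @param eps_l End of the toe region as a strain (default 0.03).
#' @return Element tension in kN, always >= 0.
#' @examples
#' element_force(0.05, k = 1, eps_l = 0.03)
#' @export
element_force <- function(eps, k, eps_l = 0.03) {
  if (any(eps_l <= 0)) stop_knee("eps_l must be > 0")
  f <- ifelse(eps < 0, 0,
       ifelse(eps <= 2 * eps_l, 0.25 * k * eps^2 / eps_l,
              k * (eps - eps_l)))
  pmax(f, 0)
}

#' Construct a ligament bundle
#'
#' A bundle is a named set of parallel spring elements sharing a total
#' stiffness \code{K_l} (split equally across elements), a toe-region bound
#' and a reference pre-strain. Attachment footprints are discs around the
#' femoral and tibial attachment centers; elements are paired points laid
#' out deterministically (sunflower pattern) over the two footprints.
#'
#' @param name One of "ACL", "PCL", "LCL", "MCL" (free-form allowed).
#' @param K_l Total bundle stiffness in kN.
#' @param eps_r Pre-strain (fraction, e.g. 0.08) at the full-extension
#'   reference pose.
#' @param n_elements Number of spring elements.
#' @param femur_center Attachment center in the femur frame (mm, relative to
#'   the femoral reference point).
#' @param tibia_center Attachment center in the tibia frame (mm).
#' @param footprint_radius Radius (mm) of the attachment footprint disc.
#' @param eps_l Toe-region end strain.
#' @return Object of class \code{ligament_bundle}. Slack lengths are unset
#'   until \code{\link{apply_prestrain}} is called.
#' @export
ligament_bundle <- function(name, K_l, eps_r, n_elements,
                            femur_center, tibia_center,
                            footprint_radius = 4, eps_l = 0.03) {
  if (K_l <= 0) stop_knee("K_l must be > 0 (%s)", name)
  if (n_elements < 1) stop_knee("n_elements must be >= 1 (%s)", name)
  if (eps_l <= 0) stop_knee("eps_l must be > 0 (%s)", name)
  if (1 + eps_r <= 0) stop_knee("pre-strain %.3f implies non-positive length", eps_r)
  # Deterministic, roughly uniform layout over the footprint disc, built
  # from mirrored sunflower pairs so the element set is symmetric in the
  # first in-plane direction (keeps whole-joint sagittal mirroring exact).
  # The same in-disc offsets are used at both ends so elements stay
  # near-parallel.
  npair <- n_elements %/% 2
  odd <- n_elements %% 2 == 1
  if (npair > 0) {
    j <- seq_len(npair)
    r <- footprint_radius * sqrt((j - 0.5) / npair)
    th <- j * pi * (3 - sqrt(5))
    u <- c(if (odd) 0, rbind(r * cos(th), -r * cos(th)))
    v <- c(if (odd) 0, rbind(r * sin(th), r * sin(th)))
  } else {
    u <- 0; v <- 0
  }
  # Footprint plane: perpendicular to the bundle line at each end.
  axis <- tibia_center - femur_center
  axis <- axis / sqrt(sum(axis^2))
  seed_vec <- if (abs(axis[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- cross3(axis, seed_vec); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(axis, e1)
  off <- outer(u, e1) + outer(v, e2)
  structure(list(
    name = name, K_l = K_l, eps_r = eps_r, eps_l = eps_l,
    n_elements = n_elements, k_elem = K_l / n_elements,
    femur_attach = sweep(off, 2, femur_center, "+"),
    tibia_attach = sweep(off, 2, tibia_center, "+"),
    L0 = NULL), class = "ligament_bundle")
}

#' Set element slack lengths from the reference pre-strain
#'
#' At the full-extension reference pose, each element's slack length is set
#' to \code{L_ref / (1 + eps_r)} where \code{L_ref} is the attachment
#' distance at that pose, so the element strain at full extension equals the
#' bundle pre-strain exactly.
#'
#' @param bundle A \code{\link{ligament_bundle}}.
#' @param ref_pose Reference pose (full extension); see
#'   \code{\link{joint_pose}}.
#' @param ref0 Femoral reference point position (mm, tibia frame) at the
#'   reference pose.
#' @return The bundle with \code{L0} filled in.
#' @export
apply_prestrain <- function(bundle, ref_pose = joint_pose(), ref0 = c(0, 0, 0)) {
  if (1 + bundle$eps_r <= 0) stop_knee("1 + eps_r must be positive")
  fa <- femur_to_tibia(bundle$femur_attach, ref_pose, ref0)
  d <- fa - bundle$tibia_attach
  L_ref <- sqrt(rowSums(d^2))
  bundle$L0 <- L_ref / (1 + bundle$eps_r)
  bundle
}

# Element strains and tensions (kN) at a pose. Internal.
bundle_state <- function(bundle, pose, ref0) {
  if (is.null(bundle$L0)) stop_knee("bundle %s has no slack lengths; call apply_prestrain()", bundle$name)
  fa <- femur_to_tibia(bundle$femur_attach, pose, ref0)
  d <- bundle$tibia_attach - fa           # femur attachment -> tibia attachment
  L <- sqrt(rowSums(d^2))
  eps <- L / bundle$L0 - 1
  f_kN <- element_force(eps, bundle$k_elem, bundle$eps_l)
  list(fa = fa, dir = d / L, L = L, eps = eps, f_kN = f_kN)
}

#' Net ligament wrench on the femur
#'
#' Sums element tensions over all bundles: each taut element pulls its
#' femoral attachment toward its tibial attachment. Forces are in N and
#' moments in N.mm about the femoral reference point. Meniscal horn springs
#' act within the meniscus ring balance, not in this wrench.
#'
#' @param bundles List of pre-strained \code{ligament_bundle} objects.
#' @param pose Current \code{\link{joint_pose}}.
#' @param ref0 Femoral reference point position at the reference pose (mm).
#' @return List with \code{force} (N, 3-vector), \code{moment} (N.mm,
#'   3-vector about the femoral reference point) and per-bundle total
#'   tensions \code{tension_n} (N).
#' @export
bundle_wrench <- function(bundles, pose, ref0 = c(0, 0, 0)) {
  Ftot <- c(0, 0, 0)
  Mtot <- c(0, 0, 0)
  tension <- numeric(length(bundles))
  names(tension) <- vapply(bundles, function(b) b$name, "")
  rp <- ref_point_position(pose, ref0)
  for (j in seq_along(bundles)) {
    st <- bundle_state(bundles[[j]], pose, ref0)
    Fel <- st$dir * (st$f_kN * 1000)           # N, rows are elements
    r <- sweep(st$fa, 2, rp)                   # lever arms about ref point
    Ftot <- Ftot + colSums(Fel)
    Mtot <- Mtot + colSums(cross3_rows(r, Fel))
    tension[j] <- sum(st$f_kN) * 1000
  }
  list(force = Ftot, moment = Mtot, tension_n = tension)
}

#' Build the default ligament set for a knee geometry
#'
#' Creates the four bundles with their standard element counts (ACL 60,
#' PCL 100, LCL 15, MCL 20; about 1 mm2 of insertion area per element),
#' total stiffnesses and reference pre-strains (ACL 10 kN / 8%,
#' PCL 18 kN / -13.5%, LCL 6 kN / -7.33%, MCL 8.25 kN / 3.66%), applies the
#' requested pre-strain offsets, and sets slack lengths at the geometry's
#' full-extension reference pose.
#'
#' @param geometry A \code{\link{generate_geometry}} result supplying
#'   attachment sites and the reference pose.
#' @param params Optional list overriding per-ligament \code{K_l} (kN),
#'   \code{prestrain_pct} (percent) and \code{n_elements}.
#' @param offsets_pct Named numeric vector of percentage-point shifts added
#'   to the reference pre-strains, e.g. \code{c(ACL = 5)}.
#' @return List of four pre-strained \code{ligament_bundle} objects.
#' @export
build_default_ligaments <- function(geometry, params = NULL,
                                    offsets_pct = c(ACL = 0, PCL = 0, LCL = 0, MCL = 0)) {
  defaults <- list(
    ACL = list(K_l = 10,   prestrain_pct = 8,     n_elements = 60),
    PCL = list(K_l = 18,   prestrain_pct = -13.5, n_elements = 100),
    LCL = list(K_l = 6,    prestrain_pct = -7.33, n_elements = 15),
    MCL = list(K_l = 8.25, prestrain_pct = 3.66,  n_elements = 20))
  att <- geometry$ligament_attachments
  bundles <- vector("list", 4)
  names(bundles) <- names(defaults)
  for (nm in names(defaults)) {
    p <- defaults[[nm]]
    if (!is.null(params[[nm]])) p <- utils::modifyList(p, params[[nm]])
    off <- if (nm %in% names(offsets_pct)) offsets_pct[[nm]] else 0
    eps_r <- (p$prestrain_pct + off) / 100
    fr <- att[[nm]]$footprint_radius %||% 4
    n_req <- p$n_elements
    # about 1 mm2 per element: footprint must hold the requested count
    if (pi * fr^2 < n_req * 0.5)
      stop_knee("footprint of %s too small for %d elements", nm, n_req)
    b <- ligament_bundle(nm, p$K_l, eps_r, n_req,
                         femur_center = att[[nm]]$femur,
                         tibia_center = att[[nm]]$tibia,
                         footprint_radius = fr)
    bundles[[nm]] <- apply_prestrain(b, geometry$ref_pose, geometry$ref0)
  }
  bundles
}

#' Linear meniscal horn spring
#'
#' @param attach_meniscus Meniscus end attachment point (mm, tibia frame).
#' @param attach_tibia Tibial attachment point (mm).
#' @param stiffness Linear stiffness in N/mm.
#' @return Object of class \code{horn_spring}.
#' @export
horn_spring <- function(attach_meniscus, attach_tibia, stiffness = 200) {
  if (stiffness < 0) stop_knee("horn stiffness must be >= 0")
  structure(list(attach_meniscus = attach_meniscus,
                 attach_tibia = attach_tibia,
                 stiffness = stiffness,
                 rest_length = sqrt(sum((attach_meniscus - attach_tibia)^2))),
            class = "horn_spring")
}

#' @export
print.ligament_bundle <- function(x, ...) {
  cat(sprintf("<ligament_bundle %s: K_l=%.2f kN, pre-strain=%.2f%%, %d elements%s>\n",
              x$name, x$K_l, 100 * x$eps_r, x$n_elements,
              if (is.null(x$L0)) ", slack lengths unset" else ""))
  invisible(x)
}
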