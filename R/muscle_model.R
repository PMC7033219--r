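# Hill-type muscle forces and per-frame EMG-bounded static optimization.
#
# Muscles are quasi-static rigid-tendon Hill actuators: force
# F = f_max (a fl(l) fv(v) + fp(l)) with fv = 1 by default. At each stance
# frame the activation vector minimizes sum(a^2) subject to the muscle-
# generated flexion-extension moment matching the external demand, with each
# activation boxed in [0.02, 1], narrowed to +/- one EMG band around the
# measured envelope for muscles with recorded EMG. The knee's frontal and
# transverse moments are applied to the joint externally and never assigned
# to muscles.

#' Active force-length scaling
#'
#' Gaussian curve equal to 1 at optimal fiber length, \eqn{e^{-1}} one
#' width away from it and vanishing far from the optimum.
#'
#' @param l_norm Normalized fiber length (> 0, vectorized).
#' @param width Gaussian width (dimensionless, default 0.4).
#' @return Scale factor in [0, 1].
#' @export
active_force_length <- function(l_norm, width = 0.4) {
  if (any(l_norm <= 0)) stop_knee("l_norm must be > 0")
  exp(-((l_norm - 1) / width)^2)
}

#' Passive force-length scaling
#'
#' Exponential-toe passive curve: zero at or below the slack length
#' (l_norm = 1), rising exponentially beyond.
#'
#' @param l_norm Normalized fiber length (vectorized).
#' @param k_pe Exponential shape factor.
#' @param eps_max Passive strain at which the curve reaches 1.
#' @return Dimensionless passive force scale (>= 0).
#' @export
passive_force_length <- function(l_norm, k_pe = 4, eps_max = 0.6) {
  s <- (expm1(k_pe * (l_norm - 1) / eps_max)) / expm1(k_pe)
  ifelse(l_norm <= 1, 0, s)
}

#' Hill muscle force
#'
#' \eqn{F = f_{max}(a\, fl(l)\, fv(v) + fp(l))} with the quasi-static
#' default \eqn{fv \equiv 1}.
#'
#' @param f_max Maximum isometric force (N).
#' @param a Activation in [0, 1].
#' @param l_norm Normalized fiber length.
#' @param v_norm Normalized shortening velocity (ignored unless
#'   \code{use_fv}).
#' @param use_fv If TRUE apply a simple force-velocity multiplier.
#' @param width,k_pe,eps_max Curve shape parameters, see
#'   \code{\link{active_force_length}} and
#'   \code{\link{passive_force_length}}.
#' @return Muscle force in N (>= 0).
#' @export
hill_force <- function(f_max, a, l_norm = 1, v_norm = 0, use_fv = FALSE,
                       width = 0.4, k_pe = 4, eps_max = 0.6) {
  if (any(a < 0 | a > 1)) stop_knee("activation must be in [0, 1]")
  fv <- if (use_fv) pmax(0, (1 - v_norm) / (1 + v_norm / 0.25)) else 1
  pmax(f_max * (a * active_force_length(l_norm, width) * fv +
                  passive_force_length(l_norm, k_pe, eps_max)), 0)
}

#' Default knee-crossing muscle set
#'
#' Seven muscle-tendon units spanning the knee with literature-typical
#' maximum isometric forces, signed flexion moment arms (m; extensors
#' negative by the package's moment convention), femoral application points
#' (mm, femur frame relative to the femoral reference point) and distal
#' free-end points (mm, tibia frame). The \code{measured} flag marks muscles
#' with an EMG envelope in a typical gait protocol.
#'
#' @return data.frame with one row per muscle.
#' @export
default_muscles <- function() {
  data.frame(
    name = c("vaslat", "vasmed", "rectfem", "bflh", "semiten",
             "gasmed", "gaslat"),
    f_max = c(1870, 1295, 780, 720, 410, 1115, 490),
    r_m = c(-0.042, -0.042, -0.042, 0.032, 0.032, 0.025, 0.025),
    measured = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    ax = c(42, 42, 42, -32, -32, -25, -25),
    ay = c(6, 6, 6, 4, 4, 2, 2),
    az = c(10, -10, 0, 20, -20, -22, 22),
    fx = c(44, 44, 44, -33, -33, -26, -26),
    fy = c(-60, -60, -60, -70, -70, -80, -80),
    fz = c(10, -10, 0, 24, -26, -24, 22),
    stringsAsFactors = FALSE)
}

# Moment generated per unit activation and the activation clipped to bounds
# for a given multiplier: a_i(lambda) = clip(lambda c_i / 2, lo_i, hi_i).
activation_profile <- function(lambda, cvec, lo, hi) clamp(lambda * cvec / 2, lo, hi)

#' EMG-bounded static optimization of muscle activations
#'
#' Minimizes \eqn{\sum a_i^2} subject to the muscle flexion-extension moment
#' \eqn{\sum r_i F_i(a_i)} matching the external moment, with activations
#' boxed in [floor, 1], narrowed to the measured EMG envelope +/- the band
#' for measured muscles. The box-constrained quadratic program is solved
#' exactly by bisection on the Lagrange multiplier of the moment constraint
#' (the clipped stationarity map is monotone). If the bounds make the
#' moment unattainable, moment matching becomes a quadratic penalty and the
#' solution is flagged \code{infeasible-relaxed}.
#'
#' @param M_ext External flexion-extension moment to balance (N m).
#' @param muscles data.frame as \code{\link{default_muscles}} (needs
#'   \code{f_max}, \code{r_m}, \code{measured}).
#' @param emg Optional named numeric vector of EMG envelope values in
#'   [0, 1] for measured muscles (NA = unbounded).
#' @param band Half-width of the activation window around each measured
#'   envelope (default 0.1).
#' @param floor Activation lower bound treated as zero excitation
#'   (default 0.02).
#' @param l_norm Normalized fiber lengths (recycled).
#' @param penalty_weight Weight of the quadratic moment penalty in the
#'   relaxed problem.
#' @return List with \code{a} (named activations), \code{moment} (achieved,
#'   N m), \code{objective} (sum of squared activations) and \code{status}
#'   ("ok" or "infeasible-relaxed").
#' @export
solve_activations_emg <- function(M_ext, muscles, emg = NULL, band = 0.1,
                                  floor = 0.02, l_norm = 1,
                                  penalty_weight = 1e3) {
  if (nrow(muscles) == 0) stop_knee("empty muscle set")
  n <- nrow(muscles)
  l_norm <- rep(l_norm, length.out = n)
  fl <- active_force_length(l_norm)
  fp <- passive_force_length(l_norm)
  cvec <- muscles$r_m * muscles$f_max * fl        # N m per unit activation
  M_passive <- sum(muscles$r_m * muscles$f_max * fp)
  M_target <- M_ext - M_passive
  lo <- rep(floor, n)
  hi <- rep(1, n)
  if (!is.null(emg)) {
    idx <- match(muscles$name, names(emg))
    e <- ifelse(is.na(idx), NA_real_, emg[idx])
    use <- muscles$measured & !is.na(e)
    lo[use] <- pmax(floor, e[use] - band)
    hi[use] <- pmin(1, e[use] + band)
    bad <- use & lo > hi
    lo[bad] <- hi[bad] <- clamp(e[bad], floor, 1)
  }
  g <- function(lam) sum(cvec * activation_profile(lam, cvec, lo, hi))
  gmin <- sum(cvec * ifelse(cvec > 0, lo, hi))
  gmax <- sum(cvec * ifelse(cvec > 0, hi, lo))
  feasible <- (M_target >= gmin - 1e-12) && (M_target <= gmax + 1e-12) &&
    any(cvec != 0)
  if (all(cvec == 0)) feasible <- abs(M_target) < 1e-9
  if (feasible) {
    # bracket then bisect on the multiplier
    lamL <- -1; lamU <- 1
    for (i in 1:200) { if (g(lamL) <= M_target) break; lamL <- lamL * 2 }
    for (i in 1:200) { if (g(lamU) >= M_target) break; lamU <- lamU * 2 }
    for (i in 1:200) {
      lam <- 0.5 * (lamL + lamU)
      if (g(lam) < M_target) lamL <- lam else lamU <- lam
    }
    lam <- 0.5 * (lamL + lamU)
    a <- activation_profile(lam, cvec, lo, hi)
    status <- "ok"
  } else {
    # penalty form: root of lam + 2 w (g(lam) - M) = 0, monotone in lam
    w <- penalty_weight
    hfun <- function(lam) lam + 2 * w * (g(lam) - M_target)
    lamL <- -1; lamU <- 1
    for (i in 1:300) { if (hfun(lamL) <= 0) break; lamL <- lamL * 2 }
    for (i in 1:300) { if (hfun(lamU) >= 0) break; lamU <- lamU * 2 }
    for (i in 1:300) {
      lam <- 0.5 * (lamL + lamU)
      if (hfun(lam) < 0) lamL <- lam else lamU <- lam
    }
    a <- activation_profile(0.5 * (lamL + lamU), cvec, lo, hi)
    status <- "infeasible-relaxed"
  }
  names(a) <- muscles$name
  list(a = a, moment = sum(cvec * a) + M_passive, objective = sum(a^2),
       status = status)
}

#' Muscle force vectors at a pose
#'
#' Converts activations (or directly supplied force magnitudes) into 3-D
#' force vectors on the femur. Each muscle's femoral application point moves
#' with the femur; its free end is fixed in the tibia frame, and the force
#' acts along the current application-to-free-end line.
#'
#' @param muscles data.frame as \code{\link{default_muscles}}.
#' @param activations Named activation vector (used with \code{forces}
#'   NULL).
#' @param forces Optional named vector of force magnitudes (N), bypassing
#'   the Hill evaluation.
#' @param pose Current \code{\link{joint_pose}}.
#' @param ref0 Femoral reference point position at the reference pose (mm).
#' @param l_norm Normalized fiber lengths (recycled).
#' @return List with \code{force} (n x 3, N, tibia frame), \code{point}
#'   (n x 3 application points, mm) and \code{magnitude} (N).
#' @export
muscle_force_vectors <- function(muscles, activations = NULL, forces = NULL,
                                 pose = joint_pose(), ref0 = c(0, 0, 0),
                                 l_norm = 1) {
  n <- nrow(muscles)
  if (is.null(forces)) {
    a <- activations[muscles$name]
    if (any(is.na(a))) stop_knee("missing activation for some muscles")
    l_norm <- rep(l_norm, length.out = n)
    mag <- hill_force(muscles$f_max, as.numeric(a), l_norm)
  } else {
    mag <- as.numeric(forces[muscles$name])
    if (any(is.na(mag))) stop_knee("missing force for some muscles")
  }
  app_f <- cbind(muscles$ax, muscles$ay, muscles$az)
  app_t <- femur_to_tibia(app_f, pose, ref0)
  free_t <- cbind(muscles$fx, muscles$fy, muscles$fz)
  d <- free_t - app_t
  L <- sqrt(rowSums(d^2))
  if (any(L < 1e-9)) stop_knee("zero-length muscle path at current pose")
  dir <- d / L
  list(force = dir * mag, point = app_t, magnitude = mag,
       name = muscles$name)
}
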