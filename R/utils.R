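# Internal geometry/numerics helpers. Working units throughout the package:
# lengths mm, forces N, moments N.mm, stresses MPa, ligament stiffness kN,
# time s, angles deg (converted to rad at the trig call sites).

deg2rad <- function(x) x * pi / 180

rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Femur-to-tibia rotation, Cardan sequence flexion (about -z), then
# abduction (about rotated x), then internal rotation (about rotated y).
pose_rotation <- function(pose) {
  rot_z(-pose$flexion_deg) %*% rot_x(pose$abduction_deg) %*%
    rot_y(pose$internal_deg)
}

# Points given in the femur frame (n x 3, relative to the femoral reference
# point) mapped into the tibia frame for a pose.
femur_to_tibia <- function(P, pose, ref0) {
  P <- matrix(P, ncol = 3)
  R <- pose_rotation(pose)
  out <- P %*% t(R)
  out[, 1] <- out[, 1] + ref0[1] + pose$tx
  out[, 2] <- out[, 2] + ref0[2] + pose$ty
  out[, 3] <- out[, 3] + ref0[3] + pose$tz
  out
}

ref_point_position <- function(pose, ref0) {
  c(ref0[1] + pose$tx, ref0[2] + pose$ty, ref0[3] + pose$tz)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# Normalized trapezoid weights so sum(w * v) approximates mean(v) over a
# uniform grid of n nodes.
trapz_weights <- function(n) {
  w <- rep(1, n)
  w[1] <- 0.5
  w[n] <- 0.5
  w / (n - 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_knee <- function(fmt, ..., class = "kneestance_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

# Run an expression with a locally seeded RNG, restoring the caller's RNG
# state so package functions do not perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
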