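# Quasi-static 5-DOF femur equilibrium through the stance phase.
#
# Flexion is position-driven per frame; the remaining two rotations and
# three translations are solved so that muscle force vectors, the residual
# force, the external frontal/transverse moments, ligament tensions and
# poroelastic contact tractions balance on the femur. Contact columns are
# advanced with the frame time step inside the residual evaluation, so the
# converged pose and the reported tractions are mutually consistent and
# vertical load is conserved to solver precision.

#' Assemble a knee model
#'
#' Builds the geometry, pre-strained ligament bundles, meniscus load
#' sharing, tissue material and muscle set from a configuration list (see
#' \code{\link{default_config}}).
#'
#' @param config Configuration list; missing entries take defaults.
#' @param prestrain_offsets_pct Named percentage-point offsets added to the
#'   reference ligament pre-strains, e.g. \code{c(ACL = 5)}.
#' @return Object of class \code{knee_model}.
#' @export
knee_model <- function(config = default_config(),
                       prestrain_offsets_pct = c(ACL = 0, PCL = 0, LCL = 0, MCL = 0)) {
  config <- utils::modifyList(default_config(), config)
  geom <- generate_geometry(config$geometry, seed = config$seed %||% 1)
  bundles <- build_default_ligaments(geom, params = config$ligaments,
                                     offsets_pct = prestrain_offsets_pct)
  mat <- do.call(frpe_material, config$material[setdiff(names(config$material),
                                                        c("n_nodes", "chi"))])
  men <- meniscus_load_share(geom)
  muscles <- config$muscles$table %||% default_muscles()
  structure(list(config = config, geometry = geom, bundles = bundles,
                 material = mat, meniscus = men, muscles = muscles,
                 offsets = prestrain_offsets_pct,
                 n_nodes = config$material$n_nodes %||% 8,
                 chi = config$material$chi %||% 0.9,
                 ref0 = geom$ref0), class = "knee_model")
}

#' @export
print.knee_model <- function(x, ...) {
  off <- paste(sprintf("%s%+g", names(x$offsets), x$offsets), collapse = " ")
  cat(sprintf(paste0("<knee_model: %d plateau cells, %d ligament elements, ",
                     "%d muscles, pre-strain offsets [%s] pct>\n"),
              nrow(x$geometry$cells),
              sum(vapply(x$bundles, function(b) b$n_elements, 0)),
              nrow(x$muscles), off))
  invisible(x)
}

new_model_columns <- function(model) {
  new_column_batch(model$material, model$geometry$cells$thickness,
                   model$n_nodes, model$chi,
                   area = model$geometry$cells$area)
}

# Per-cell penetration for a pose (fast path of contact_gaps), capped below
# the column thickness so the tissue response stays defined during solver
# excursions.
cell_penetration <- function(model, pose) {
  yf <- condyle_lower_surface(model$geometry, pose)
  pen <- pmax(0, model$geometry$cells$y_surf - yf)
  pen[!is.finite(yf)] <- 0
  pmin(pen, 0.9 * model$geometry$cells$thickness)
}

men_k_found <- function(model) {
  cells <- model$geometry$cells
  k <- numeric(nrow(cells))
  for (comp in c("medial", "lateral")) {
    sel <- cells$meniscus & cells$compartment == comp
    k[sel] <- model$meniscus[[comp]]$k_found
  }
  k
}

# Full wrench evaluation at a trial pose. Does not mutate column state.
eval_wrench <- function(pose, loads, model, columns, dt) {
  ref0 <- model$ref0
  rp <- ref_point_position(pose, ref0)
  # muscles
  mv <- muscle_force_vectors(model$muscles, forces = loads$muscle_forces_n,
                             pose = pose, ref0 = ref0)
  Fm <- colSums(mv$force)
  Mm <- colSums(cross3_rows(sweep(mv$point, 2, rp), mv$force))
  # ligaments
  lw <- bundle_wrench(model$bundles, pose, ref0)
  # contact
  pen <- cell_penetration(model, pose)
  cells <- model$geometry$cells
  kmen <- loads$k_men
  idx <- which(pen > 0)
  t_cc <- numeric(length(pen))
  if (length(idx) > 0) {
    st <- step_columns(columns, dt, mode = "disp", delta = pen[idx], idx = idx)
    t_cc[idx] <- pmax(st$sigma, 0)
  } else st <- NULL
  t_men <- kmen * pen
  f_mag <- (t_cc + t_men) * cells$area           # N along the cell normal
  Fcell <- cbind(f_mag * cells$nx, f_mag * cells$ny, f_mag * cells$nz)
  Fc <- colSums(Fcell)
  rcell <- cbind(cells$x - rp[1], cells$y_surf - rp[2], cells$z - rp[3])
  Mc <- colSums(cross3_rows(rcell, Fcell))
  f_cell <- f_mag * cells$ny                     # vertical component, N
  # external
  Fe <- loads$residual_force_n
  Me <- c(-loads$adduction_moment_nmm, loads$rotation_moment_nmm, 0)
  Ftot <- Fm + lw$force + Fc + Fe
  Mtot <- Mm + lw$moment + Mc + Me
  list(residual = c(Ftot, Mtot[1], Mtot[2]),
       force_muscle = Fm, force_ligament = lw$force, force_contact = Fc,
       force_external = Fe, moment = Mtot,
       ligament_tension_n = lw$tension_n,
       pen = pen, idx = idx, column_step = st,
       t_cc = t_cc, t_men = t_men, f_cell = f_cell)
}

#' Net out-of-balance wrench on the femur
#'
#' The five components the equilibrium solver drives to zero: net force
#' (N, 3) and the net abduction and internal-rotation moments (N mm). The
#' flexion moment is the reaction of the prescribed degree of freedom and
#' is excluded.
#'
#' @param pose Trial \code{\link{joint_pose}}.
#' @param loads Frame load set as built by \code{\link{frame_loads}}.
#' @param model A \code{\link{knee_model}}.
#' @param columns Column state (internal; defaults to a pristine state).
#' @param dt Frame time step (s).
#' @return Numeric length-5 residual.
#' @export
residual_wrench <- function(pose, loads, model, columns = NULL, dt = 6e-3) {
  if (is.null(columns)) columns <- new_model_columns(model)
  eval_wrench(pose, loads, model, columns, dt)$residual
}

#' Build the load set for one frame of a gait trial
#'
#' Solves the EMG-bounded activation problem (envelope mode) or takes the
#' supplied force magnitudes (force mode), and converts external moments to
#' N mm.
#'
#' @param trial A \code{\link{gait_trial}}.
#' @param model A \code{\link{knee_model}}.
#' @param i Frame index.
#' @return List with muscle force magnitudes, activation solution, residual
#'   force and external moments.
#' @export
frame_loads <- function(trial, model, i) {
  mus <- model$muscles
  if (trial$drive_mode == "envelope") {
    env <- trial$muscle_drive[i, ]
    sol <- solve_activations_emg(trial$flexion_moment_nm[i], mus,
                                 emg = env[!is.na(env)],
                                 band = model$config$muscles$band %||% 0.1,
                                 floor = model$config$muscles$floor %||% 0.02)
    mags <- sol$a * mus$f_max
    names(mags) <- mus$name
  } else {
    mags <- trial$muscle_drive[i, ]
    sol <- NULL
  }
  list(muscle_forces_n = mags, activation = sol,
       residual_force_n = trial$residual_force[i, ],
       adduction_moment_nmm = trial$adduction_moment_nm[i] * 1000,
       rotation_moment_nmm = trial$rotation_moment_nm[i] * 1000,
       k_men = men_k_found(model))
}

pose_from_q <- function(q, flexion_deg) {
  joint_pose(flexion_deg = flexion_deg, abduction_deg = q[4],
             internal_deg = q[5], tx = q[1], ty = q[2], tz = q[3])
}

#' Solve the 5-DOF equilibrium pose for one frame
#'
#' Levenberg-Marquardt least squares on the scaled residual wrench followed
#' by damped Newton polishing, so the converged residual is far below the
#' applied load (vertical conservation to better than 1e-6 relative).
#'
#' @param init Initial \code{\link{joint_pose}} (its flexion is kept).
#' @param loads Frame loads from \code{\link{frame_loads}}.
#' @param model A \code{\link{knee_model}}.
#' @param columns Column state carried across frames.
#' @param dt Frame time step (s).
#' @param control List: \code{maxit} (LM iterations, 200), \code{tol_rel}
#'   (target scaled residual, 1e-9), \code{bracket_ty} (bisect the vertical
#'   translation first; default TRUE for a cold start).
#' @return List with \code{pose}, \code{residual}, \code{scaled_norm},
#'   \code{converged} and \code{detail} (the final wrench evaluation).
#' @export
solve_pose <- function(init, loads, model, columns = NULL, dt = 6e-3,
                       control = list()) {
  if (is.null(columns)) columns <- new_model_columns(model)
  ctl <- utils::modifyList(list(maxit = 200, tol_rel = 1e-9,
                                bracket_ty = FALSE), control)
  flex <- init$flexion_deg
  Fs <- max(100, abs(loads$residual_force_n[2]) + sum(loads$muscle_forces_n))
  scale <- c(Fs, Fs, Fs, Fs * 10, Fs * 10)
  q <- c(init$tx, init$ty, init$tz, init$abduction_deg, init$internal_deg)
  rfun <- function(q) {
    eval_wrench(pose_from_q(q, flex), loads, model, columns, dt)$residual / scale
  }
  if (isTRUE(ctl$bracket_ty)) {
    # cold start: bisection on the superior translation for vertical balance
    lo <- -4; hi <- 2
    flo <- rfun(c(q[1], lo, q[3], q[4], q[5]))[2]
    fhi <- rfun(c(q[1], hi, q[3], q[4], q[5]))[2]
    if (flo * fhi < 0) {
      for (it in 1:30) {
        mid <- 0.5 * (lo + hi)
        fm <- rfun(c(q[1], mid, q[3], q[4], q[5]))[2]
        if (fm * flo <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
      }
      q[2] <- 0.5 * (lo + hi)
    }
  }
  fit <- minpack.lm::nls.lm(par = q, fn = rfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = ctl$maxit, ftol = 1e-15,
                              ptol = 1e-13, gtol = 0))
  q <- fit$par
  r <- rfun(q)
  # damped Newton polish with a central-difference Jacobian
  hstep <- c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4)
  for (newton in 1:15) {
    if (max(abs(r)) < ctl$tol_rel) break
    J <- matrix(0, 5, 5)
    for (j in 1:5) {
      qp <- q; qm <- q
      qp[j] <- q[j] + hstep[j]; qm[j] <- q[j] - hstep[j]
      J[, j] <- (rfun(qp) - rfun(qm)) / (2 * hstep[j])
    }
    dq <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dq)) break
    lam <- 1
    improved <- FALSE
    for (half in 1:8) {
      qn <- q + lam * dq
      rn <- rfun(qn)
      if (max(abs(rn)) < max(abs(r))) {
        q <- qn; r <- rn; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  detail <- eval_wrench(pose_from_q(q, flex), loads, model, columns, dt)
  list(pose = pose_from_q(q, flex), residual = detail$residual,
       scaled_norm = max(abs(detail$residual / scale)),
       converged = max(abs(detail$residual / scale)) < 1e-3,
       detail = detail, scale = scale)
}

# Commit the column states at a solved pose: contacting cells advance
# displacement-driven (suction-free), previously loaded cells that lost
# contact recover under zero load.
commit_frame <- function(columns, model, pose, dt) {
  pen <- cell_penetration(model, pose)
  idx <- which(pen > 0)
  if (length(idx) > 0) {
    st <- step_columns(columns, dt, mode = "disp", delta = pen[idx], idx = idx)
    suck <- st$sigma < 0
    if (any(suck)) {
      ids <- idx[suck]
      st0 <- step_columns(columns, dt, mode = "load",
                          sigma_t = rep(0, length(ids)), idx = ids)
      keep <- !suck
      st$idx <- st$idx[keep]
      st$sigma <- st$sigma[keep]
      st$p <- st$p[, keep, drop = FALSE]
      st$eps <- st$eps[, keep, drop = FALSE]
      st$el <- st$el[keep]
      columns <- commit_columns(columns, st0)
    }
    if (length(st$idx) > 0) columns <- commit_columns(columns, st)
  }
  loaded <- which(colSums(abs(columns$p)) + abs(columns$el) +
                    colSums(abs(columns$eps)) > 1e-14)
  rest <- setdiff(loaded, idx)
  if (length(rest) > 0) {
    st0 <- step_columns(columns, dt, mode = "load",
                        sigma_t = rep(0, length(rest)), idx = rest)
    columns <- commit_columns(columns, st0)
  }
  columns
}

frame_metrics <- function(model, pose, detail, columns, dt, bw) {
  cells <- model$geometry$cells
  pen <- detail$pen
  f_cell <- detail$f_cell
  med <- cells$compartment == "medial"
  in_contact <- pen > 0
  cc <- cells$meniscus == FALSE
  jcf_med <- sum(f_cell[med])
  jcf_lat <- sum(f_cell[!med])
  jcf <- jcf_med + jcf_lat
  area_cc_med <- sum(cells$area[in_contact & cc & med])
  area_cc_lat <- sum(cells$area[in_contact & cc & !med])
  area_tot <- sum(cells$area[in_contact])
  st <- detail$column_step
  tiss <- list(medial = c(fibril = NA, stress = NA, pressure = NA),
               lateral = c(fibril = NA, stress = NA, pressure = NA))
  if (!is.null(st)) {
    for (comp in c("medial", "lateral")) {
      sel <- which(cc[st$idx] & (cells$compartment[st$idx] == comp) &
                     detail$t_cc[st$idx] > 0)
      if (length(sel) > 0)
        tiss[[comp]] <- c(fibril = mean(st$eps_f[sel]),
                          stress = mean(st$sigma1[sel]),
                          pressure = mean(st$p_mean[sel]))
    }
  }
  data.frame(
    abduction_deg = pose$abduction_deg, internal_deg = pose$internal_deg,
    tx_mm = pose$tx, ty_mm = pose$ty, tz_mm = pose$tz,
    flexion_deg = pose$flexion_deg,
    jcf_n = jcf, jcf_bw = jcf / bw,
    jcf_medial_n = jcf_med, jcf_lateral_n = jcf_lat,
    jcf_ml_ratio = if (jcf_lat > 0) jcf_med / jcf_lat else NA_real_,
    contact_area_cc_medial_mm2 = area_cc_med,
    contact_area_cc_lateral_mm2 = area_cc_lat,
    contact_area_cc_mm2 = area_cc_med + area_cc_lat,
    contact_area_total_mm2 = area_tot,
    area_ml_ratio = if (area_cc_lat > 0) area_cc_med / area_cc_lat else NA_real_,
    fibril_strain_medial = tiss$medial["fibril"],
    fibril_strain_lateral = tiss$lateral["fibril"],
    max_stress_medial_mpa = tiss$medial["stress"],
    max_stress_lateral_mpa = tiss$lateral["stress"],
    fluid_pressure_medial_mpa = tiss$medial["pressure"],
    fluid_pressure_lateral_mpa = tiss$lateral["pressure"],
    lig_fy_n = detail$force_ligament[2],
    muscle_fy_n = detail$force_muscle[2],
    applied_fy_n = detail$force_muscle[2] + detail$force_external[2],
    contact_fy_n = detail$force_contact[2],
    row.names = NULL)
}

#' Run the full stance-phase simulation
#'
#' Solves the quasi-static equilibrium frame by frame with warm-started
#' poses, carrying the poroelastic column state (consolidation memory)
#' across frames, and collects joint contact force, contact area, tissue
#' response and ligament tension metrics per frame.
#'
#' @param trial A \code{\link{gait_trial}}.
#' @param model A \code{\link{knee_model}}.
#' @param frames Optional integer subset of frames (default all).
#' @param store_maps If TRUE keep each frame's per-cell traction vector.
#' @param quiet Suppress the per-frame progress line.
#' @return Object of class \code{stance_solution}: per-frame metrics in
#'   \code{$frames}, per-bundle ligament tensions in \code{$ligaments},
#'   activations in \code{$activations}, solver diagnostics, and the model
#'   configuration.
#' @export
run_stance <- function(trial, model, frames = NULL, store_maps = FALSE,
                       quiet = TRUE) {
  n <- length(trial$stance_pct)
  if (is.null(frames)) frames <- seq_len(n)
  dur <- model$config$solver$stance_duration_s %||% 0.6
  dt <- dur * diff(range(trial$stance_pct)) / 100 / (n - 1)
  columns <- new_model_columns(model)
  res <- vector("list", length(frames))
  lig <- matrix(NA_real_, length(frames), length(model$bundles),
                dimnames = list(NULL, names(model$bundles)))
  act <- matrix(NA_real_, length(frames), nrow(model$muscles),
                dimnames = list(NULL, model$muscles$name))
  act_status <- character(length(frames))
  maps <- if (store_maps) vector("list", length(frames)) else NULL
  pose <- joint_pose(flexion_deg = trial$flexion_deg[frames[1]])
  for (k in seq_along(frames)) {
    i <- frames[k]
    loads <- frame_loads(trial, model, i)
    pose$flexion_deg <- trial$flexion_deg[i]
    sol <- solve_pose(pose, loads, model, columns, dt,
                      control = list(bracket_ty = (k == 1)))
    if (!sol$converged)
      stop_knee("frame %d did not converge (scaled residual %.3e)",
                i, sol$scaled_norm)
    pose <- sol$pose
    res[[k]] <- cbind(frame = i, stance_pct = trial$stance_pct[i],
                      frame_metrics(model, pose, sol$detail, columns, dt,
                                    trial$bodyweight_n),
                      residual_scaled = sol$scaled_norm)
    lig[k, ] <- sol$detail$ligament_tension_n
    if (!is.null(loads$activation)) {
      act[k, ] <- loads$activation$a
      act_status[k] <- loads$activation$status
    }
    if (store_maps) maps[[k]] <- list(idx = sol$detail$idx,
                                      t_cc = sol$detail$t_cc[sol$detail$idx],
                                      pen = sol$detail$pen[sol$detail$idx])
    columns <- commit_frame(columns, model, pose, dt)
    if (!quiet)
      message(sprintf("frame %3d (%5.1f%%): JCF %.2f BW, residual %.1e",
                      i, trial$stance_pct[i], res[[k]]$jcf_bw, sol$scaled_norm))
  }
  structure(list(frames = do.call(rbind, res), ligaments = lig,
                 activations = act, activation_status = act_status,
                 maps = maps, bodyweight_n = trial$bodyweight_n,
                 offsets = model$offsets, dt = dt,
                 config = model$config), class = "stance_solution")
}

#' Joint contact force of a solved frame
#'
#' @param sol A \code{\link{run_stance}} solution.
#' @param frame Frame index into the solution (default: all frames).
#' @return data.frame with the total JCF (N and bodyweights) and the
#'   medial:lateral split and ratio (NA when the lateral share is zero).
#' @export
joint_contact_force <- function(sol, frame = NULL) {
  f <- sol$frames
  if (!is.null(frame)) f <- f[f$frame %in% frame, , drop = FALSE]
  f[, c("frame", "stance_pct", "jcf_n", "jcf_bw", "jcf_medial_n",
        "jcf_lateral_n", "jcf_ml_ratio")]
}

#' @export
print.stance_solution <- function(x, ...) {
  f <- x$frames
  cat(sprintf(paste0("<stance_solution: %d frames, peak JCF %.2f BW at %.0f%% ",
                     "stance, peak contact area %.0f mm^2>\n"),
              nrow(f), max(f$jcf_bw), f$stance_pct[which.max(f$jcf_bw)],
              max(f$contact_area_total_mm2)))
  invisible(x)
}

#' @export
summary.stance_solution <- function(object, ...) {
  f <- object$frames
  pk <- which.max(f$jcf_bw)
  out <- list(
    n_frames = nrow(f),
    peak_jcf_bw = f$jcf_bw[pk],
    peak_jcf_stance_pct = f$stance_pct[pk],
    ml_ratio_at_peak = f$jcf_ml_ratio[pk],
    peak_contact_area_mm2 = max(f$contact_area_total_mm2),
    peak_fibril_strain = suppressWarnings(max(c(f$fibril_strain_medial,
                                                f$fibril_strain_lateral), na.rm = TRUE)),
    peak_max_stress_mpa = suppressWarnings(max(c(f$max_stress_medial_mpa,
                                                 f$max_stress_lateral_mpa), na.rm = TRUE)),
    peak_fluid_pressure_mpa = suppressWarnings(max(c(f$fluid_pressure_medial_mpa,
                                                     f$fluid_pressure_lateral_mpa), na.rm = TRUE)),
    max_ligament_tension_n = apply(object$ligaments, 2, max),
    worst_residual = max(f$residual_scaled))
  class(out) <- "summary.stance_solution"
  out
}

#' @export
print.summary.stance_solution <- function(x, ...) {
  cat(sprintf("Stance solution over %d frames\n", x$n_frames))
  cat(sprintf("  peak JCF:            %.2f BW at %.0f%% stance (M:L ratio %.2f)\n",
              x$peak_jcf_bw, x$peak_jcf_stance_pct, x$ml_ratio_at_peak))
  cat(sprintf("  peak contact area:   %.0f mm^2\n", x$peak_contact_area_mm2))
  cat(sprintf("  peak fibril strain:  %.2f %%\n", 100 * x$peak_fibril_strain))
  cat(sprintf("  peak max stress:     %.2f MPa\n", x$peak_max_stress_mpa))
  cat(sprintf("  peak fluid pressure: %.2f MPa\n", x$peak_fluid_pressure_mpa))
  cat("  peak ligament tensions (N):\n")
  for (nm in names(x$max_ligament_tension_n))
    cat(sprintf("    %s: %.0f\n", nm, x$max_ligament_tension_n[nm]))
  invisible(x)
}

#' @export
as.data.frame.stance_solution <- function(x, ...) {
  cbind(x$frames, as.data.frame(x$ligaments))
}

#' @export
plot.stance_solution <- function(x, which = c("jcf", "area", "tissue"), ...) {
  which <- match.arg(which)
  f <- x$frames
  if (which == "jcf") {
    graphics::plot(f$stance_pct, f$jcf_bw, type = "l", lwd = 2,
                   xlab = "stance (%)", ylab = "JCF (BW)", ...)
    graphics::lines(f$stance_pct, f$jcf_medial_n / x$bodyweight_n, lty = 2)
    graphics::lines(f$stance_pct, f$jcf_lateral_n / x$bodyweight_n, lty = 3)
    graphics::legend("topright", c("total", "medial", "lateral"),
                     lty = 1:3, bty = "n")
  } else if (which == "area") {
    graphics::plot(f$stance_pct, f$contact_area_total_mm2, type = "l", lwd = 2,
                   xlab = "stance (%)", ylab = "contact area (mm^2)", ...)
    graphics::lines(f$stance_pct, f$contact_area_cc_mm2, lty = 2)
    graphics::legend("topright", c("total", "cartilage-cartilage"),
                     lty = 1:2, bty = "n")
  } else {
    graphics::plot(f$stance_pct, 100 * f$fibril_strain_medial, type = "l",
                   lwd = 2, xlab = "stance (%)",
                   ylab = "mean fibril strain in contact (%)", ...)
    graphics::lines(f$stance_pct, 100 * f$fibril_strain_lateral, lty = 2)
    graphics::legend("topright", c("medial", "lateral"), lty = 1:2, bty = "n")
  }
  invisible(x)
}
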