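# Shared fixtures, built in code.

# Coarse, fast model configuration for solver-level tests.
coarse_config <- function(...) {
  cfg <- default_config()
  cfg$geometry$cell_mm <- 3
  utils::modifyList(cfg, list(...))
}

# A model whose ligaments are all far slack, so contact and external loads
# are the only players.
slack_ligament_config <- function(cfg = coarse_config()) {
  for (nm in names(cfg$ligaments)) cfg$ligaments[[nm]]$prestrain_pct <- -60
  cfg
}

# Zero-muscle-force loads with a single external force at the femoral
# reference point.
point_loads <- function(model, fy = -500, fx = 0, fz = 0,
                        madd = 0, mrot = 0) {
  mags <- rep(0, nrow(model$muscles))
  names(mags) <- model$muscles$name
  list(muscle_forces_n = mags, activation = NULL,
       residual_force_n = c(fx, fy, fz),
       adduction_moment_nmm = madd, rotation_moment_nmm = mrot,
       k_men = kneestance:::men_k_found(model))
}

# Brute-force activation grid search (independent oracle for the bounded
# static optimization): exhaustive enumeration minimizing sum(a^2) among
# grid points whose moment error is within what the grid can represent
# (half a step of the largest moment arm). Because the moment constraint is
# only representable to that resolution, the grid optimum can detour from
# the continuous optimum by slightly more than one grid step.
grid_search_activations <- function(M_ext, muscles, lo, hi, step = 0.01) {
  grids <- lapply(seq_len(nrow(muscles)), function(i) seq(lo[i], hi[i], by = step))
  combos <- as.matrix(expand.grid(grids))
  cvec <- muscles$r_m * muscles$f_max
  mom <- combos %*% cvec
  ok <- abs(mom - M_ext) <= max(abs(cvec)) * step / 2 + 1e-9
  if (!any(ok)) return(list(a = NULL, objective = Inf))
  obj <- rowSums(combos^2)
  best <- which(ok)[which.min(obj[ok])]
  list(a = unname(combos[best, ]), objective = obj[best])
}

# Mirror a gait trial in the sagittal plane: z force components and the
# transverse/frontal moments flip sign.
mirror_trial <- function(trial) {
  tr <- trial
  tr$residual_force[, 3] <- -tr$residual_force[, 3]
  tr$adduction_moment_nm <- -tr$adduction_moment_nm
  tr$rotation_moment_nm <- -tr$rotation_moment_nm
  tr$muscles$az <- -tr$muscles$az
  tr$muscles$fz <- -tr$muscles$fz
  tr
}

# Mirror a model: geometry flipped, muscle z-coordinates flipped; ligament
# parameters stay attached to their (mirrored) anatomical sites.
mirror_model <- function(model) {
  cfg <- model$config
  m2 <- knee_model(cfg, prestrain_offsets_pct = model$offsets)
  m2$geometry <- mirror_geometry(model$geometry)
  m2$bundles <- build_default_ligaments(m2$geometry, params = cfg$ligaments,
                                        offsets_pct = model$offsets)
  m2$meniscus <- meniscus_load_share(m2$geometry)
  mus <- m2$muscles
  mus$az <- -mus$az
  mus$fz <- -mus$fz
  m2$muscles <- mus
  m2
}
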