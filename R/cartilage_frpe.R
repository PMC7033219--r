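# Fibril-reinforced poroelastic (FRPE) tissue columns.
#
# Each contact cell of the tibial plateau carries a 1-D biphasic column:
# a linear non-fibrillar matrix, a Darcy pore fluid with void-ratio
# dependent permeability, and a tension-only collagen fibril network that
# engages through lateral expansion of the column. The axial consolidation
# PDE  d(eps_v)/dt = -d/dz( k dp/dz )  is advanced implicitly; the articular
# surface is drained (p = 0) and the bone interface impermeable. Lateral
# stretch is solved from in-plane equilibrium of matrix stress, fibril
# tension, pore pressure and a confinement restraint chi, so the undrained
# column is compliant through lateral bulging (fluid load support) while the
# drained column relaxes to the elastic matrix response. With viscosity
# eta > 0 the fibril adds a rate-stiffening dashpot (FRPVE); eta = 0 is the
# purely elastic fibril network.

#' FRPE/FRPVE material parameter set
#'
#' Default values are literature-typical for articular cartilage at desk
#' scale, not subject-specific measurements.
#'
#' @param E_m Non-fibrillar matrix Young's modulus (MPa).
#' @param nu_m Matrix Poisson ratio (0 <= nu < 0.5).
#' @param E_0 Initial fibril network modulus (MPa).
#' @param E_eps Strain-dependent fibril modulus coefficient (MPa).
#' @param eta Fibril dashpot viscosity (MPa s); 0 gives the purely elastic
#'   FRPE fibril.
#' @param k_0 Initial permeability in m^4/(N s).
#' @param M_k Permeability-void-ratio exponent.
#' @param e_0 Initial void ratio.
#' @return Object of class \code{frpe_material}.
#' @export
frpe_material <- function(E_m = 0.5, nu_m = 0.15, E_0 = 2, E_eps = 500,
                          eta = 0, k_0 = 2e-15, M_k = 5, e_0 = 4) {
  if (E_m <= 0) stop_knee("E_m must be > 0")
  if (nu_m < 0 || nu_m >= 0.5) stop_knee("nu_m must be in [0, 0.5)")
  if (E_0 < 0 || E_eps < 0) stop_knee("fibril moduli must be >= 0")
  if (k_0 <= 0) stop_knee("k_0 must be > 0")
  if (e_0 <= 0) stop_knee("e_0 must be > 0")
  lam <- E_m * nu_m / ((1 + nu_m) * (1 - 2 * nu_m))
  mu <- E_m / (2 * (1 + nu_m))
  structure(list(E_m = E_m, nu_m = nu_m, E_0 = E_0, E_eps = E_eps,
                 eta = eta, k_0 = k_0, M_k = M_k, e_0 = e_0,
                 lambda = lam, mu = mu, M_conf = lam + 2 * mu,
                 k_0_mm = k_0 * 1e12),   # mm^4/(N s)
            class = "frpe_material")
}

#' Void-ratio dependent permeability
#'
#' \eqn{k = k_0 ((1+e)/(1+e_0))^{M_k}}; equals \code{k_0} at the initial
#' void ratio and decreases under compaction for \code{M_k > 0}.
#'
#' @param e Current void ratio (> 0, vectorized).
#' @param mat A \code{\link{frpe_material}}.
#' @return Permeability in m^4/(N s).
#' @export
permeability <- function(e, mat) {
  if (any(e <= 0)) stop_knee("void ratio must be > 0")
  mat$k_0 * ((1 + e) / (1 + mat$e_0))^mat$M_k
}

#' Tension-only fibril stress
#'
#' Elastic branch \eqn{\sigma_f = (E_0 + E_\epsilon \epsilon_f)\epsilon_f}
#' for tensile fibril strain, zero in compression. With \code{eta > 0} a
#' dashpot term \code{eta * (eps_f - eps_f_old)/dt} adds rate stiffening.
#'
#' @param eps_f Fibril strain (tensile positive, vectorized).
#' @param mat A \code{\link{frpe_material}}.
#' @param eps_f_old Fibril strain at the previous time step (for the
#'   viscous term; defaults to \code{eps_f}, i.e. no rate contribution).
#' @param dt Time step (s); required > 0 when \code{eta > 0}.
#' @return Fibril stress in MPa, always >= 0.
#' @export
fibril_stress <- function(eps_f, mat, eps_f_old = eps_f, dt = 1) {
  if (mat$eta > 0 && dt <= 0) stop_knee("dt must be > 0 when eta > 0")
  s <- (mat$E_0 + mat$E_eps * eps_f) * eps_f +
    if (mat$eta > 0) mat$eta * (eps_f - eps_f_old) / dt else 0
  ifelse(eps_f <= 0, 0, pmax(s, 0))
}

#' Terzaghi degree-of-consolidation series solution
#'
#' Analytic oracle for the one-dimensional consolidation solver:
#' \eqn{U(T_v) = 1 - \sum_m (2/M^2) e^{-M^2 T_v}}, \eqn{M = \pi(2m+1)/2},
#' truncated at relative 1e-10.
#'
#' @param Tv Dimensionless time factor \eqn{c_v t / H^2} (vectorized, >= 0).
#' @return Degree of consolidation in [0, 1].
#' @export
terzaghi_oracle <- function(Tv) {
  if (any(Tv < 0)) stop_knee("Tv must be >= 0")
  vapply(Tv, function(tv) {
    if (tv == 0) return(0)
    s <- 0
    for (m in 0:2000) {
      M <- pi * (2 * m + 1) / 2
      term <- (2 / M^2) * exp(-M^2 * tv)
      s <- s + term
      if (term < 1e-10 * max(s, 1e-300)) break
    }
    min(max(1 - s, 0), 1)
  }, 0)
}

# ---------------------------------------------------------------------------
# Batch column state: n_nodes x m matrices, vectorized over columns.

new_column_batch <- function(mat, h, n_nodes, chi, area = rep(1, length(h))) {
  m <- length(h)
  if (any(h <= 0)) stop_knee("column thickness must be > 0")
  if (n_nodes < 2) stop_knee("n_nodes must be >= 2")
  if (any(chi < 0 | chi > 1)) stop_knee("chi must be in [0, 1]")
  list(mat = mat, h = h, n_nodes = n_nodes,
       chi = rep(chi, length.out = m), area = area, m = m,
       p = matrix(0, n_nodes, m),        # pore pressure, MPa
       eps = matrix(0, n_nodes, m),      # axial strain, compression positive
       el = numeric(m),                  # lateral (in-plane) strain
       sigma = numeric(m))               # total axial traction, MPa
}

# Solve tridiagonal systems for every column at once (Thomas algorithm with
# vector sweeps over columns). a: sub-diagonal, b: diagonal, c: super-
# diagonal, each n x m; rhs a list of n x m right-hand sides.
tridiag_batch <- function(a, b, c, rhs) {
  n <- nrow(b)
  cp <- matrix(0, n, ncol(b))
  sols <- lapply(rhs, function(d) d)
  dp <- sols
  cp[1, ] <- c[1, ] / b[1, ]
  for (k in seq_along(rhs)) dp[[k]][1, ] <- rhs[[k]][1, ] / b[1, ]
  for (i in 2:n) {
    denom <- b[i, ] - a[i, ] * cp[i - 1, ]
    if (i < n) cp[i, ] <- c[i, ] / denom
    for (k in seq_along(rhs))
      dp[[k]][i, ] <- (rhs[[k]][i, ] - a[i, ] * dp[[k]][i - 1, ]) / denom
  }
  for (k in seq_along(rhs)) {
    x <- dp[[k]]
    for (i in (n - 1):1) x[i, ] <- dp[[k]][i, ] - cp[i, ] * x[i + 1, ]
    sols[[k]] <- x
  }
  sols
}

# One implicit consolidation step for a batch of columns.
# mode "disp": delta (mm) prescribed, total traction solved.
# mode "load": total traction sigma_t (MPa) prescribed, settlement solved.
#
# For a fixed secant modulus and (time-lagged) permeability field the
# discrete system is linear, so the mean pore pressure is affine in the
# lateral strain; the in-plane equilibrium then reduces to one scalar
# monotone equation per column, solved exactly by a vectorized Newton. An
# outer loop refines the secant modulus. Does not mutate `batch`; returns
# the would-be new state plus responses.
step_columns <- function(batch, dt, mode = c("disp", "load"),
                         delta = NULL, sigma_t = NULL, idx = NULL) {
  mode <- match.arg(mode)
  if (dt <= 0) stop_knee("dt must be > 0")
  mat <- batch$mat
  if (is.null(idx)) idx <- seq_len(batch$m)
  m <- length(idx)
  n <- batch$n_nodes
  h <- batch$h[idx]
  chi <- batch$chi[idx]
  dz <- h / (n - 1)
  w <- trapz_weights(n)
  eps_old <- batch$eps[, idx, drop = FALSE]
  el_old <- batch$el[idx]
  if (mode == "disp") {
    if (any(delta >= h)) stop_knee("compression must be smaller than column thickness")
    eps_a <- delta / h
  } else {
    eps_a <- colSums(w * eps_old)
  }
  el <- el_old
  lam <- mat$lambda; mu <- mat$mu
  kconf <- ifelse(chi >= 1, Inf, chi / (1 - chi) * mat$M_conf)
  confined <- !is.finite(kconf)
  kc <- ifelse(confined, 0, kconf)
  visc <- if (mat$eta > 0) mat$eta / dt else 0
  mfloor <- 0.05 * (lam + 2 * mu)
  # permeability lagged at the committed state (explicit in time)
  ev <- sweep(eps_old, 2, 2 * el_old)   # volumetric strain
  evc <- pmin(ev, mat$e_0 / (1 + mat$e_0) * 0.999)
  e_node <- mat$e_0 - (1 + mat$e_0) * evc
  k_node <- mat$k_0_mm * ((1 + e_node) / (1 + mat$e_0))^mat$M_k
  kmid <- 0.5 * (k_node[-1, , drop = FALSE] + k_node[-n, , drop = FALSE])
  r_base <- eps_old - matrix(2 * el_old, n, m, byrow = TRUE)
  r_base[1, ] <- 0
  ones <- matrix(1, n, m); ones[1, ] <- 0
  sig <- numeric(m)
  converged <- FALSE
  Mhat_prev <- rep(NA_real_, m)
  for (outer in 1:50) {
    # secant axial modulus with a smooth floor (no branch switching)
    sa_eff <- (lam + 2 * mu) * eps_a - 2 * lam * el
    Mraw <- ifelse(abs(eps_a) > 1e-9, sa_eff / eps_a, lam + 2 * mu)
    dM <- Mraw - mfloor
    Mhat <- mfloor + 0.5 * (dM + sqrt(dM^2 + (0.2 * mfloor)^2))
    # tridiagonal operator (row 1: drained surface, p = 0)
    a <- b <- cc <- matrix(0, n, m)
    b[1, ] <- 1
    for (i in 2:n) {
      klo <- kmid[i - 1, ]
      if (i < n) {
        khi <- kmid[i, ]
        a[i, ] <- dt * klo / dz^2
        cc[i, ] <- dt * khi / dz^2
        b[i, ] <- -1 / Mhat - dt * (klo + khi) / dz^2
      } else {
        a[i, ] <- 2 * dt * klo / dz^2
        b[i, ] <- -1 / Mhat - 2 * dt * klo / dz^2
      }
    }
    mv <- matrix(1 / Mhat, n, m, byrow = TRUE)
    mv[1, ] <- 0
    sol <- tridiag_batch(a, b, cc, list(r_base, ones, mv))
    u0 <- sol[[1]]; ue <- sol[[2]]; v <- sol[[3]]
    Su0 <- colSums(w * u0); Sue <- colSums(w * ue); Sv <- colSums(w * v)
    S1v <- colSums(w * (1 + v))
    if (mode == "disp") {
      # sigma(el) = s0 + s1 el; pbar(el) = A + B el
      s0 <- (Mhat * eps_a + Su0) / S1v
      s1 <- 2 * Sue / S1v
      A <- Su0 - s0 * Sv
      B <- 2 * Sue - s1 * Sv
      dea <- rep(0, m)                   # d eps_a / d el
    } else {
      s0 <- sigma_t; s1 <- rep(0, m)
      A <- Su0 - sigma_t * Sv
      B <- 2 * Sue
      dea <- -B / Mhat                   # eps_a = (sigma - pbar)/Mhat
    }
    # scalar in-plane equilibrium per column, monotone in el
    for (nit in 1:100) {
      if (mode == "load") eps_a <- (s0 - (A + B * el)) / Mhat
      sf <- ifelse(el > 0,
                   pmax((mat$E_0 + mat$E_eps * el) * el + visc * (el - el_old), 0), 0)
      G <- lam * (-eps_a + 2 * el) + 2 * mu * el + sf + kc * el - (A + B * el)
      dsf <- ifelse(el > 0 & sf > 0, mat$E_0 + 2 * mat$E_eps * el + visc, 0)
      dG <- 2 * lam + 2 * mu + dsf + kc - B - lam * dea
      el_new <- clamp(el - G / dG, -0.45, 0.9)
      el_new[confined] <- 0
      if (max(abs(el_new - el)) < 1e-14) { el <- el_new; break }
      el <- el_new
    }
    sig <- s0 + s1 * el
    if (mode == "load") eps_a <- (s0 - (A + B * el)) / Mhat
    dMh <- if (all(is.na(Mhat_prev))) Inf else
      max(abs(Mhat - Mhat_prev) / pmax(abs(Mhat), 1e-12))
    Mhat_prev <- Mhat
    if (dMh < 1e-11) { converged <- TRUE; break }
  }
  if (!converged)
    stop_knee("column step failed to converge (d_Mhat=%.3e)", dMh)
  p <- u0 + sweep(ue, 2, 2 * el, "*") - sweep(v, 2, sig, "*")
  eps <- sweep(sweep(-p, 2, sig, "+"), 2, Mhat, "/")
  eps_f <- pmax(el, 0)
  sf <- ifelse(el > 0, pmax((mat$E_0 + mat$E_eps * el) * el +
                              visc * (el - el_old), 0), 0)
  # in-plane effective stress (tensile positive) incl. fibril tension
  s_lat <- lam * (-eps_a + 2 * el) + 2 * mu * el + sf
  list(idx = idx, sigma = sig, p = p, eps = eps, el = el,
       p_surf = p[min(2, n), ], p_mean = colSums(w * p),
       eps_a = eps_a, eps_f = eps_f, sigma1 = s_lat,
       settlement = eps_a * h)
}

commit_columns <- function(batch, st) {
  batch$p[, st$idx] <- st$p
  batch$eps[, st$idx] <- st$eps
  batch$el[st$idx] <- st$el
  batch$sigma[st$idx] <- st$sigma
  batch
}

# ---------------------------------------------------------------------------
# Single-column user API.

#' Create a fibril-reinforced poroelastic tissue column
#'
#' @param mat A \code{\link{frpe_material}}.
#' @param h Column thickness (mm).
#' @param n_nodes Axial discretization (>= 2).
#' @param chi Lateral restraint in [0, 1]; 1 is fully confined (no lateral
#'   stretch, hence no fibril engagement), 0 laterally free.
#' @param area Plan area (mm^2), used only for force bookkeeping.
#' @return Object of class \code{tissue_column} holding the discretized
#'   pore-pressure and strain state.
#' @export
tissue_column <- function(mat, h = 6, n_nodes = 20, chi = 0.9, area = 1) {
  b <- new_column_batch(mat, h, n_nodes, chi, area)
  structure(b, class = "tissue_column")
}

#' Advance a tissue column one implicit consolidation step
#'
#' Prescribes the axial compression of the column surface and advances the
#' pore-pressure field by one backward-Euler step of the consolidation
#' equation. Total surface traction is the sum of the effective (matrix +
#' lateral-coupling) stress and the pore pressure at every node (mixture
#' consistency); fibril strain is the tensile part of the lateral stretch.
#'
#' @param col A \code{\link{tissue_column}}.
#' @param compression Axial compression of the surface (mm, < thickness).
#' @param dt Time step (s, > 0).
#' @return List with \code{column} (updated state) and \code{response}:
#'   \code{traction} (total axial stress, MPa, compression positive),
#'   \code{fluid_pressure} (pore pressure at the first subsurface node,
#'   MPa), \code{fluid_pressure_mean}, \code{fibril_strain},
#'   \code{max_principal_stress} (in-plane effective stress incl. fibril
#'   tension, MPa) and \code{settlement} (mm).
#' @export
column_step <- function(col, compression, dt) {
  st <- step_columns(col, dt, mode = "disp", delta = compression)
  col2 <- commit_columns(col, st)
  class(col2) <- class(col)
  list(column = col2,
       response = list(traction = st$sigma,
                       fluid_pressure = st$p_surf,
                       fluid_pressure_mean = st$p_mean,
                       fibril_strain = st$eps_f,
                       max_principal_stress = st$sigma1,
                       settlement = st$settlement))
}

#' Advance a tissue column under prescribed load (creep)
#'
#' Load-driven counterpart of \code{\link{column_step}}: the total axial
#' traction is prescribed and the settlement solved, as in a consolidation
#' (creep) test. Used for validation against the Terzaghi series solution.
#'
#' @inheritParams column_step
#' @param load Total axial traction (MPa, compression positive).
#' @return As \code{\link{column_step}}.
#' @export
column_creep_step <- function(col, load, dt) {
  st <- step_columns(col, dt, mode = "load", sigma_t = load)
  col2 <- commit_columns(col, st)
  class(col2) <- class(col)
  list(column = col2,
       response = list(traction = st$sigma,
                       fluid_pressure = st$p_surf,
                       fluid_pressure_mean = st$p_mean,
                       fibril_strain = st$eps_f,
                       max_principal_stress = st$sigma1,
                       settlement = st$settlement))
}

#' @export
print.tissue_column <- function(x, ...) {
  cat(sprintf("<tissue_column: h=%.2f mm, %d nodes, chi=%.2f, E_m=%.2f MPa>\n",
              x$h[1], x$n_nodes, x$chi[1], x$mat$E_m))
  invisible(x)
}
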