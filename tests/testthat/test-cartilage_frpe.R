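test_that("permeability follows the void-ratio power law", {
  mat <- frpe_material(k_0 = 2e-15, M_k = 5, e_0 = 4)
  expect_equal(permeability(4, mat), 2e-15)
  mat0 <- frpe_material(M_k = 0)
  expect_equal(permeability(2, mat0), permeability(6, mat0))
  expect_lt(permeability(3, mat), mat$k_0)   # compaction reduces k
  expect_error(permeability(-1, mat), "void ratio")
})

test_that("fibril stress is tension-only with the stated elastic branch", {
  mat <- frpe_material(E_0 = 2, E_eps = 100, eta = 0)
  expect_equal(fibril_stress(-0.01, mat), 0)
  expect_equal(fibril_stress(0.05, mat), 0.35)
  # eta = 0 FRPVE reduces exactly to the elastic FRPE branch
  matv <- frpe_material(E_0 = 2, E_eps = 100, eta = 0.5)
  expect_equal(fibril_stress(0.05, matv, eps_f_old = 0.05, dt = 0.01),
               fibril_stress(0.05, mat))
  # rate stiffening: fast ramp to the same strain gives larger stress
  fast <- fibril_stress(0.05, matv, eps_f_old = 0.04, dt = 1e-3)
  slow <- fibril_stress(0.05, matv, eps_f_old = 0.04, dt = 1)
  expect_gt(fast, slow)
  expect_gt(fast, fibril_stress(0.05, mat))
})

test_that("Terzaghi oracle series has the known values", {
  expect_equal(terzaghi_oracle(0), 0)
  expect_equal(terzaghi_oracle(50), 1, tolerance = 1e-12)
  expect_equal(terzaghi_oracle(0.5), 0.7639, tolerance = 1e-4)
  expect_true(all(diff(terzaghi_oracle(seq(0, 2, 0.05))) >= 0))
})

test_that("trivial column limits hold", {
  mat <- frpe_material()
  col <- tissue_column(mat, h = 6, n_nodes = 10, chi = 0.9)
  st <- column_step(col, 0, 0.01)
  expect_equal(st$response$traction, 0, tolerance = 1e-12)
  expect_equal(st$response$fluid_pressure, 0, tolerance = 1e-12)
  expect_equal(st$response$fibril_strain, 0, tolerance = 1e-12)
  # fully confined: no lateral stretch, no fibril strain at any compression
  colc <- tissue_column(mat, h = 6, n_nodes = 10, chi = 1)
  stc <- column_step(colc, 0.5, 0.01)
  expect_equal(stc$response$fibril_strain, 0)
  expect_error(column_step(colc, 7, 0.01), "thickness")
  expect_error(column_step(colc, 0.1, 0), "dt")
})

test_that("undrained step pressurizes the fluid to the applied stress", {
  mat <- frpe_material(E_0 = 0, E_eps = 0, M_k = 0)
  col <- tissue_column(mat, h = 6, n_nodes = 20, chi = 1)
  st <- column_creep_step(col, 0.2, 1e-9)
  expect_equal(st$response$fluid_pressure, 0.2, tolerance = 1e-6)
  # instantaneous settlement is a small fraction of the drained settlement
  # (only the drained surface node responds immediately)
  expect_lt(st$response$settlement, 0.1 * 6 * 0.2 / mat$M_conf)
})

test_that("mixture consistency: traction = effective stress + pore pressure", {
  mat <- frpe_material()
  col <- tissue_column(mat, h = 6, n_nodes = 12, chi = 0.9)
  out <- column_step(col, 0.4, 0.006)
  col2 <- out$column
  sig <- col2$sigma[1]
  # recover the secant modulus from the first subsurface node, then check
  # every node satisfies sigma_total = Mhat * eps + p
  Mhat <- (sig - col2$p[2, 1]) / col2$eps[2, 1]
  resid <- sig - (Mhat * col2$eps[, 1] + col2$p[, 1])
  expect_lt(max(abs(resid)) / sig, 1e-9)
})

test_that("held compression relaxes monotonically to the drained solution", {
  mat <- frpe_material(E_0 = 0, E_eps = 0, M_k = 0)
  col <- tissue_column(mat, h = 6, n_nodes = 40, chi = 1)
  M <- mat$M_conf
  tr <- c()
  dt <- 36 / (M * mat$k_0_mm) / 50       # 1/50 of the consolidation time
  for (i in 1:400) {
    st <- column_step(col, 0.6, dt)
    col <- st$column
    tr <- c(tr, st$response$traction)
  }
  expect_true(all(diff(tr) <= 1e-9))
  expect_equal(tr[length(tr)], M * 0.1, tolerance = 0.01)  # drained elastic
  expect_lt(abs(st$response$fluid_pressure), 1e-3 * tr[1])
})

test_that("consolidation matches the Terzaghi series within 0.5 percent", {
  mat <- frpe_material(E_0 = 0, E_eps = 0, M_k = 0)
  col <- tissue_column(mat, h = 6, n_nodes = 50, chi = 1)
  M <- mat$M_conf; cv <- M * mat$k_0_mm; h <- 6
  Tvs <- c(0.1, 0.2, 0.5, 1.0)
  tend <- Tvs * h^2 / cv
  times <- sort(unique(c(10^seq(log10(min(tend) * 1e-4), log10(max(tend)),
                                length.out = 900), tend)))
  s <- numeric(length(times)); tprev <- 0
  for (i in seq_along(times)) {
    st <- column_creep_step(col, 0.1, times[i] - tprev)
    col <- st$column
    s[i] <- st$response$settlement
    tprev <- times[i]
  }
  U <- s[match(tend, times)] / (h * 0.1 / M)
  expect_equal(U, terzaghi_oracle(Tvs), tolerance = 5e-3)
})
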