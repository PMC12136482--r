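# Single-cell model: reversal potentials, currents, RHS, integration.

test_that("Nernst potential matches closed forms", {
  expect_equal(nernst_potential(5, 5), 0)
  expect_equal(nernst_potential(exp(1) * 3, 3), 26.64)
  # direct evaluation, cross-checked against independent evaluation of
  # 26.64 * log(4/140)
  expect_equal(nernst_potential(4, 140), 26.64 * log(4 / 140))
  expect_lt(nernst_potential(4, 140), -94)
  expect_gt(nernst_potential(4, 140), -95)
  expect_error(nernst_potential(0, 1), "positive")
  expect_error(nernst_potential(4, -2), "positive")
})

test_that("ionic currents vanish at the reversal potential and match an
           independent re-implementation", {
  p <- cell_params(K_bath = 9.5)
  # put V exactly at E_K: driving force zero regardless of gating
  EK <- nernst_potential(p$K0_o, p$K0_i, p$C_nernst)
  st <- cell_state(V = EK, n = 0.3)
  cur <- ionic_currents(st, p)
  expect_equal(unname(cur["i_K"]), 0)

  # straight-line oracle: re-evaluate every printed formula independently
  oracle <- function(st, p) {
    Ki <- p$K0_i + st["dKi"]; Nai <- p$Na0_i - st["dKi"]
    Ko <- p$K0_o - p$beta_vol * st["dKi"] + st["Kg"]
    Nao <- p$Na0_o + p$beta_vol * st["dKi"]
    EK <- p$C_nernst * log(Ko / Ki)
    ENa <- p$C_nernst * log(Nao / Nai)
    ECl <- p$C_nernst * log(p$Cl0_i / p$Cl0_o)
    minf <- 1 / (1 + exp(-(p$v_m + st["V"]) / p$s_m))
    h <- 1.1 - 1 / (1 + exp(3.2 - 8 * st["n"]))
    c(iK = unname((p$g0_K * st["n"] + p$gl_K) * (st["V"] - EK)),
      iNa = unname((p$g0_Na * minf * h + p$gl_Na) * (st["V"] - ENa)),
      iCl = unname(p$g0_Cl * (st["V"] - ECl)),
      ipump = unname(p$rho / ((1 + exp(10.5 - 0.5 * Nai)) * (1 + exp(5.5 - Ko)))))
  }
  for (st in list(cell_state(-65, 0.1, 0.5, 0.2),
                  cell_state(-30, 0.45, -3, 4),
                  cell_state(10, 0.8, -6, 8))) {
    cur <- ionic_currents(st, p)
    ref <- oracle(unclass(st), p)
    expect_equal(unname(cur[c("i_K", "i_Na", "i_Cl", "i_pump")]),
                 unname(ref), tolerance = 1e-12)
  }
})

test_that("pump current approaches its analytic floor for depleted Na_i and K_o", {
  p <- cell_params()
  # drive Na_i near zero via dKi, and pull K_o near zero with Kg
  dKi <- p$Na0_i - 1e-6
  Kg <- -(p$K0_o - p$beta_vol * dKi) + 1e-6
  st <- cell_state(V = -65, n = 0.1, dKi = dKi, Kg = Kg)
  cur <- ionic_currents(st, p)
  floor_val <- p$rho / ((1 + exp(10.5)) * (1 + exp(5.5)))
  expect_equal(unname(cur["i_pump"]), floor_val, tolerance = 1e-3)
  expect_lt(floor_val / p$rho, 3e-7)
})

test_that("cell state with NaN is rejected with a diagnostic", {
  p <- cell_params()
  expect_error(ionic_currents(cell_state(NaN, 0.1), p), "NaN")
})

test_that("slow derivatives vanish under flux balance and bath equality", {
  p0 <- cell_params()
  p <- cell_params(K_bath = p0$K0_o)  # bath equals baseline ECS potassium
  st <- cell_state(V = -70, n = .2, dKi = 0, Kg = 0)
  r <- cell_rhs(st, p)
  expect_equal(unname(r["Kg"]), 0)  # K_o == K_bath
  # flux balance: choose n so that i_K equals f_pump * i_pump
  cur <- ionic_currents(st, p)
  expect_equal(unname(r["dKi"]),
               -p$gamma_ion * unname(cur["i_K"] - p$f_pump * cur["i_pump"]))
})

test_that("RHS matches the numerical derivative of an integrated trajectory", {
  p <- cell_params(K_bath = 9.5)
  tr <- simulate_cell(p, T = 200, dt = 0.025)
  # central difference at an interior sample vs analytic RHS
  i <- 4001  # t = 100 ms
  st <- cell_state(tr$V_mV[i], tr$n[i], tr$dKi_mM[i], tr$Kg_mM[i])
  r <- cell_rhs(st, p)
  dVdt_num <- (tr$V_mV[i + 1] - tr$V_mV[i - 1]) / (2 * 0.025)
  expect_equal(unname(r["V"]), dVdt_num, tolerance = 0.05)
  dKgdt_num <- (tr$Kg_mM[i + 1] - tr$Kg_mM[i - 1]) / (2 * 0.025)
  expect_equal(unname(r["Kg"]), dKgdt_num, tolerance = 1e-4)
})

test_that("simulate_cell is deterministic, has the right length, and
           conserves the bookkeeping identities", {
  p <- cell_params(K_bath = 9.5)
  a <- simulate_cell(p, T = 500, dt = 0.025)
  b <- simulate_cell(p, T = 500, dt = 0.025)
  expect_identical(a, b)
  expect_equal(nrow(a), 500 / 0.025 + 1)
  # conservation by construction at arbitrary sample points
  for (i in c(1, 5000, nrow(a))) {
    st <- cell_state(a$V_mV[i], a$n[i], a$dKi_mM[i], a$Kg_mM[i])
    cur <- ionic_currents(st, p)
    expect_equal(unname(cur["Na_i"]) + a$dKi_mM[i], p$Na0_i)
    expect_equal(unname(cur["K_i"]) - a$dKi_mM[i], p$K0_i)
  }
})

test_that("eps = 0 and gamma = 0 freeze the slow subsystem exactly", {
  p <- cell_params(K_bath = 17, epsilon = 0, gamma_ion = 0)
  tr <- simulate_cell(p, T = 1000, dt = 0.025,
                      init = cell_state(-60, 0.2, dKi = 0.2, Kg = -0.1))
  expect_true(all(tr$dKi_mM == 0.2))
  expect_true(all(tr$Kg_mM == -0.1))
})

test_that("halving the step changes V(1 s) by less than tolerance", {
  p <- cell_params(K_bath = 4)
  v1 <- tail(simulate_cell(p, T = 1000, dt = 0.05)$V_mV, 1)
  v2 <- tail(simulate_cell(p, T = 1000, dt = 0.025)$V_mV, 1)
  expect_lt(abs(v1 - v2), 0.5)
})

test_that("divergent integration fails naming the offending time", {
  # absurd drive forces divergence
  p <- cell_params(K_bath = 9.5)
  expect_error(
    simulate_cell(p, T = 100, dt = 0.025, i_syn = function(t) 1e7),
    "t = ")
})
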