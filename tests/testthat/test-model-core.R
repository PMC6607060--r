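test_that("gating steady states obey midpoint, limit and slope identities", {
  p <- nominal_parameters()
  for (g in gate_table()$gate) {
    E <- p[[apuq:::.gate_half[[g]]]]
    expect_equal(gate_steady_state(E, g, p), 0.5)
    lim <- gate_steady_state(1e4, g, p)
    if (g %in% c("m", "r", "d", "xr", "xs")) {
      expect_equal(lim, 1)
      grid <- gate_steady_state(seq(-120, 60, by = 5), g, p)
      expect_true(all(diff(grid) > 0))
    } else {
      expect_equal(lim, 0)
      grid <- gate_steady_state(seq(-120, 60, by = 5), g, p)
      expect_true(all(diff(grid) < 0))
    }
    vals <- gate_steady_state(c(-200, -50, 100), g, p)
    expect_true(all(vals >= 0 & vals <= 1))
  }
  expect_error(gate_steady_state(-85, "q"), "unknown gate")
})

test_that("gating steady states match the hand-computed sigmoid oracle", {
  p <- nominal_parameters()
  expect_equal(gate_steady_state(-85, "m", p),
               oracle_act_inf(-85, -52.244, 6.5472))
  expect_equal(gate_steady_state(-85, "h", p),
               oracle_inact_inf(-85, -78.7, 5.93))
  expect_equal(gate_steady_state(-85, "m", p), 0.00666, tolerance = 1e-2)
  expect_equal(gate_steady_state(-85, "h", p), 0.743, tolerance = 1e-3)
})

test_that("tau_h satisfies its closed-form identities", {
  p <- nominal_parameters()
  expect_equal(tau_h(p[["Eh"]], p), p[["tau_h0"]])
  expect_equal(tau_h(p[["Eh"]] + p[["kh"]], p),
               2 * p[["tau_h0"]] * exp(p[["delta_h"]]) / (1 + exp(1)))
  expect_lt(tau_h(-500, p), 1e-10)       # V -> -Inf limit with delta_h > 0
  expect_true(all(tau_h(seq(-150, 80, by = 1), p) > 0))
})

test_that("parameterization has 36 parameters and 7 state variables", {
  expect_length(param_names(), 36)
  expect_length(param_names(include_fixed = FALSE), 33)
  expect_length(initial_conditions(), 7)
  expect_length(ap_rhs(0, initial_conditions()), 7)
  expect_length(nominal_parameters(), 37)  # 36 + Cm
  # defaults are the nominal table values, bit-for-bit
  p <- nominal_parameters()
  expect_identical(p[["gNa"]], 12)
  expect_identical(p[["Em"]], -52.244)
  expect_identical(p[["delta_h"]], 0.799163)
  expect_identical(p[["tau_h0"]], 6.80738)
  expect_identical(p[["Ed"]], 0.7)
  expect_identical(p[["tau_xs"]], 628)
  expect_identical(p[["EK"]], -85)
  expect_identical(p[["Cm"]], 1)
})

test_that("parameter invariants are enforced", {
  expect_error(nominal_parameters(gNa = -1), "strictly positive")
  expect_error(nominal_parameters(km = 0), "strictly positive")
  expect_error(nominal_parameters(bogus = 1), "unknown parameter")
  expect_silent(validate_parameters(nominal_parameters(Em = -60)))
})

test_that("ionic currents match an independent hand evaluation", {
  p <- nominal_parameters()
  y0 <- initial_conditions(p)
  got <- ionic_currents(y0, p)
  want <- oracle_currents(y0, p)
  expect_equal(unlist(got[1, ]), want, tolerance = 1e-12)
  # zero driving force at V = EK for the potassium currents
  yk <- y0
  yk[["V"]] <- p[["EK"]]
  ck <- ionic_currents(yk, p)
  expect_equal(ck$IK1, 0)
  expect_equal(ck$Ito, 0)
  expect_equal(ck$IKr, 0)
  expect_equal(ck$IKs, 0)
  # closed m gate kills INa regardless of voltage
  ym <- y0
  ym[["V"]] <- 20
  ym[["m"]] <- 0
  expect_equal(ionic_currents(ym, p)$INa, 0)
})

test_that("the RHS is consistent with currents and the gating ODE", {
  p <- nominal_parameters()
  y0 <- initial_conditions(p)
  d0 <- ap_rhs(0, y0, p)
  # gates start at steady state: all gate derivatives exactly 0
  expect_equal(unname(d0[2:7]), rep(0, 6))
  # dV/dt = -sum(Iion)/Cm with no stimulus, vs the hand-evaluated currents
  expect_equal(d0[["V"]], -sum(oracle_currents(y0, p)) / p[["Cm"]],
               tolerance = 1e-12)
  # capacitor equation under a constant stimulus
  d5 <- ap_rhs(0, y0, p, stim = function(t) 5)
  expect_equal(d5[["V"]] - d0[["V"]], 5 / p[["Cm"]])
  expect_error(ap_rhs(0, replace(y0, 1, NaN), p), "non-finite")
})

test_that("initial conditions are the resting steady state at EK", {
  p <- nominal_parameters()
  y0 <- initial_conditions(p)
  expect_equal(y0[["V"]], -85)
  expect_equal(y0[["m"]], 0.00666, tolerance = 1e-2)
  expect_equal(y0[["h"]], 0.743, tolerance = 1e-3)
  p2 <- nominal_parameters(Em = -45, kh = 7)
  expect_equal(unname(ap_rhs(0, initial_conditions(p2), p2)[2:7]),
               rep(0, 6))
})

test_that("gate trajectories stay in [0,1] under perturbed parameters", {
  spec <- uncertainty_spec(0.05)
  samples <- sample_parameters(spec, 5, seed = 42)
  for (i in seq_len(5)) {
    tr <- simulate_ap(unlist(samples[i, ]), duration = 300,
                      with_states = TRUE)
    gates <- as.matrix(tr[, c("m", "h", "s", "f", "xr", "xs")])
    expect_true(all(gates >= 0 & gates <= 1))
  }
})

test_that("voltage is frozen when all conductances vanish", {
  eps <- 1e-12
  p <- nominal_parameters(gNa = eps, gK1 = eps, gto = eps, gCaL = eps,
                          gKr = eps, gKs = eps)
  tr <- simulate_ap(p, amplitude = 0, duration = 200)
  expect_lt(max(abs(tr$V + 85)), 1e-6)
})
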