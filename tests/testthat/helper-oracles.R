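# Independent oracles used across the test files. These deliberately
# re-derive quantities from first principles (explicit formulas, brute
# force enumeration) rather than calling the package's own code paths.

# sigmoid steady states written out directly from the gating equations
oracle_act_inf <- function(V, E, k) 1 / (1 + exp(-(V - E) / k))
oracle_inact_inf <- function(V, E, k) 1 / (1 + exp((V - E) / k))

# hand evaluation of the six current equations at a given state
oracle_currents <- function(state, p) {
  V <- state[["V"]]
  c(
    INa = p[["gNa"]] * state[["m"]]^3 * state[["h"]]^2 * (V - p[["ENa"]]),
    IK1 = p[["gK1"]] * oracle_inact_inf(V, p[["Ez"]], p[["kz"]]) *
      (V - p[["EK"]]),
    Ito = p[["gto"]] * oracle_act_inf(V, p[["Er"]], p[["kr"]]) *
      state[["s"]] * (V - p[["EK"]]),
    ICaL = p[["gCaL"]] * oracle_act_inf(V, p[["Ed"]], p[["kd"]]) *
      state[["f"]] * (V - p[["ECa"]]),
    IKr = p[["gKr"]] * state[["xr"]] *
      oracle_inact_inf(V, p[["Ey"]], p[["ky"]]) * (V - p[["EK"]]),
    IKs = p[["gKs"]] * state[["xs"]] * (V - p[["EK"]])
  )
}

# brute-force two-sample KS statistic: sup |ECDF_a - ECDF_b| evaluated at
# every pooled data point
oracle_ks_d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# piecewise-linear synthetic voltage trace on a uniform grid, with the
# attributes extract_qois()/classify_behavior() expect
synthetic_trace <- function(knots_t, knots_v, dt = 0.05, t_end = 1000,
                            onset = 0) {
  t <- seq(0, t_end, by = dt)
  V <- approx(knots_t, knots_v, xout = t, rule = 2)$y
  structure(tibble::tibble(time = t, V = V,
                           dVdt = c(diff(V) / dt, 0)),
            stim_onset = onset,
            class = c("ap_trace", class(tibble::tibble())))
}
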