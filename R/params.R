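# Model parameterization: 36 parameters (33 kinetic/conductance + 3 Nernst
# potentials) plus the fixed membrane capacitance Cm.

# canonical parameter order; sample matrices and the C++ kernels rely on it
.param_order <- c(
  "gNa", "Em", "km", "tau_m", "Eh", "kh", "delta_h", "tau_h0",
  "gK1", "Ez", "kz",
  "gto", "Er", "kr", "Es", "ks", "tau_s",
  "gCaL", "Ed", "kd", "Ef", "kf", "tau_f",
  "gKr", "Exr", "kxr", "tau_xr", "Ey", "ky",
  "gKs", "Exs", "kxs", "tau_xs",
  "ENa", "EK", "ECa"
)

.nominal <- c(
  gNa = 12, Em = -52.244, km = 6.5472, tau_m = 0.12,
  Eh = -78.7, kh = 5.93, delta_h = 0.799163, tau_h0 = 6.80738,
  gK1 = 0.73893, Ez = -91.9655, kz = 12.4997,
  gto = 0.1688, Er = 14.3116, kr = 11.462,
  Es = -47.9286, ks = 4.9314, tau_s = 9.90669,
  gCaL = 0.11503, Ed = 0.7, kd = 4.3, Ef = -15.7, kf = 4.6, tau_f = 30,
  gKr = 0.056, Exr = -26.6, kxr = 6.5, tau_xr = 334, Ey = -49.6, ky = 23.5,
  gKs = 0.0080, Exs = 24.6, kxs = 12.1, tau_xs = 628,
  ENa = 65, EK = -85, ECa = 50, Cm = 1
)

.positive_params <- c(
  "gNa", "gK1", "gto", "gCaL", "gKr", "gKs",
  "km", "kh", "kz", "kr", "ks", "kd", "kf", "kxr", "ky", "kxs",
  "tau_m", "tau_s", "tau_f", "tau_xr", "tau_xs", "tau_h0", "delta_h"
)

.voltage_params <- c("Em", "Eh", "Ez", "Er", "Es", "Ed", "Ef",
                     "Exr", "Ey", "Exs")

.fixed_params <- c("ENa", "EK", "ECa")

#' Nominal model parameters
#'
#' Returns the full parameterization of the cell model: six maximal
#' conductances (mS/uF), ten half-(in)activation voltages (mV), ten sigmoid
#' slope factors (mV), five constant time constants plus the tau_h scale
#' tau_h0 (ms) and asymmetry factor delta_h (dimensionless), the three
#' Nernst potentials ENa/EK/ECa (mV, environmental, never sampled), and the
#' specific membrane capacitance Cm (uF/cm^2, fixed at 1).
#'
#' The nominal half-activation voltage of the L-type calcium current, `Ed`,
#' is +0.7 mV as printed in the source parameter table; it can be
#' overridden if the sign-flipped value is preferred.
#'
#' @param ... named overrides, e.g. `nominal_parameters(gNa = 6)`.
#' @return A named numeric vector of length 37 with class
#'   `"apuq_parameters"`.
#' @examples
#' p <- nominal_parameters()
#' p[["gNa"]]
#' halved <- nominal_parameters(gNa = 6)
#' @export
nominal_parameters <- function(...) {
  p <- .nominal
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      abort("parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    p[names(ov)] <- unlist(ov)
  }
  validate_parameters(p)
  structure(p, class = "apuq_parameters")
}

#' Parameter names in canonical order
#'
#' @param include_fixed keep the fixed Nernst potentials `ENa`, `EK`, `ECa`
#'   (36 names)? With `FALSE`, only the 33 perturbable parameters are
#'   returned. `Cm` is never included.
#' @return character vector.
#' @export
param_names <- function(include_fixed = TRUE) {
  if (include_fixed) .param_order else setdiff(.param_order, .fixed_params)
}

#' Check parameter invariants
#'
#' Conductances, slope factors, time constants and `delta_h` must be
#' strictly positive; all values finite.
#'
#' @param params named numeric vector as from [nominal_parameters()].
#' @return `params`, invisibly; errors on violation.
#' @export
validate_parameters <- function(params) {
  miss <- setdiff(c(.param_order, "Cm"), names(params))
  if (length(miss))
    abort(paste0("missing parameter(s): ", paste(miss, collapse = ", ")))
  if (any(!is.finite(params)))
    abort("parameters must be finite")
  pos <- params[c(.positive_params, "Cm")]
  if (any(pos <= 0))
    abort(paste0("parameter(s) must be strictly positive: ",
                 paste(names(pos)[pos <= 0], collapse = ", ")))
  invisible(params)
}

# full 37-vector in C++ layout from any named input (vector or 1-row data
# frame); missing entries filled from nominal
as_param_vector <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1)
    params <- unlist(params[intersect(names(params), names(.nominal))])
  }
  p <- .nominal
  p[names(params)] <- as.numeric(params)
  p[c(.param_order, "Cm")]
}

#' Gating variable catalogue
#'
#' The ten gates of the model: activation gates m, r, d, xr, xs and
#' inactivation gates h, z, s, f, y. Gates z, r, d and y reach their
#' steady states instantaneously and are never integrated; m, h, s, f, xr
#' and xs are state variables. Only h has a voltage-dependent (h-shaped)
#' time constant.
#'
#' @return tibble with columns `gate`, `kind`, `dynamic`, `tau_kind`.
#' @export
gate_table <- function() {
  tibble::tibble(
    gate = c("m", "h", "z", "r", "s", "d", "f", "xr", "y", "xs"),
    kind = c("activation", "inactivation", "inactivation", "activation",
             "inactivation", "activation", "inactivation", "activation",
             "inactivation", "activation"),
    dynamic = c("state-variable", "state-variable", "instantaneous",
                "instantaneous", "state-variable", "instantaneous",
                "state-variable", "state-variable", "instantaneous",
                "state-variable"),
    tau_kind = c("constant", "h-shaped", "none", "none", "constant",
                 "none", "constant", "none", "none", "constant")
  )
}

.gate_half <- c(m = "Em", h = "Eh", z = "Ez", r = "Er", s = "Es",
                d = "Ed", f = "Ef", xr = "Exr", y = "Ey", xs = "Exs")
.gate_slope <- c(m = "km", h = "kh", z = "kz", r = "kr", s = "ks",
                 d = "kd", f = "kf", xr = "kxr", y = "ky", xs = "kxs")
.activation_gates <- c("m", "r", "d", "xr", "xs")
.state_gates <- c("m", "h", "s", "f", "xr", "xs")

#' Sigmoid gating steady state
#'
#' `Yinf(V) = 1 / (1 + exp(-(V - E_Y)/k_Y))` for activation gates and
#' `1 / (1 + exp(+(V - E_Y)/k_Y))` for inactivation gates.
#'
#' @param V membrane voltage, mV (vectorized).
#' @param gate one of m, h, z, r, s, d, f, xr, y, xs.
#' @param params parameter vector.
#' @return steady-state occupancy in (0, 1).
#' @examples
#' gate_steady_state(-85, "m")
#' @export
gate_steady_state <- function(V, gate, params = nominal_parameters()) {
  if (length(gate) != 1 || !gate %in% names(.gate_half))
    abort(paste0("unknown gate: ", paste(gate, collapse = ", ")))
  p <- as_param_vector(params)
  E <- p[[.gate_half[[gate]]]]
  k <- p[[.gate_slope[[gate]]]]
  s <- if (gate %in% .activation_gates) -1 else 1
  1 / (1 + exp(s * (V - E) / k))
}

#' Voltage-dependent time constant of the h gate
#'
#' `tau_h(V) = 2 tau_h0 exp(delta_h (V - Eh)/kh) / (1 + exp((V - Eh)/kh))`,
#' equal to `tau_h0` at `V = Eh`.
#'
#' @inheritParams gate_steady_state
#' @return time constant, ms (strictly positive).
#' @export
tau_h <- function(V, params = nominal_parameters()) {
  p <- as_param_vector(params)
  u <- (V - p[["Eh"]]) / p[["kh"]]
  2 * p[["tau_h0"]] * exp(p[["delta_h"]] * u) / (1 + exp(u))
}

#' Gating time constant
#'
#' Constant for m, s, f, xr, xs; h-shaped voltage dependence for h; zero
#' for the instantaneous gates z, r, d, y.
#'
#' @inheritParams gate_steady_state
#' @return time constant, ms.
#' @export
gate_time_constant <- function(V, gate, params = nominal_parameters()) {
  if (length(gate) != 1 || !gate %in% names(.gate_half))
    abort(paste0("unknown gate: ", gate))
  p <- as_param_vector(params)
  switch(gate,
    h = tau_h(V, p),
    m = rep(p[["tau_m"]], length(V)),
    s = rep(p[["tau_s"]], length(V)),
    f = rep(p[["tau_f"]], length(V)),
    xr = rep(p[["tau_xr"]], length(V)),
    xs = rep(p[["tau_xs"]], length(V)),
    rep(0, length(V))
  )
}

.state_names <- c("V", "m", "h", "s", "f", "xr", "xs")

as_state_matrix <- function(state) {
  if (is.data.frame(state)) state <- as.matrix(state[, .state_names])
  if (is.null(dim(state))) {
    if (length(state) != 7) abort("state must have 7 entries (V, m, h, s, f, xr, xs)")
    state <- matrix(state, nrow = 1, dimnames = list(NULL, .state_names))
  }
  if (ncol(state) != 7) abort("state must have 7 columns")
  state
}

#' Ionic currents
#'
#' Evaluates the six ionic currents from a model state. The instantaneous
#' gates (z, r, d, y) are evaluated at the supplied voltage; they are not
#' part of the state.
#'
#' @param state named numeric vector `(V, m, h, s, f, xr, xs)`, or a matrix
#'   / data frame with those seven columns (one row per state).
#' @param params parameter vector.
#' @return tibble with columns `INa`, `IK1`, `Ito`, `ICaL`, `IKr`, `IKs`
#'   (uA/cm^2), one row per state.
#' @export
ionic_currents <- function(state, params = nominal_parameters()) {
  p <- as_param_vector(params)
  m <- cpp_currents(p, as_state_matrix(state))
  colnames(m) <- c("INa", "IK1", "Ito", "ICaL", "IKr", "IKs")
  tibble::as_tibble(m)
}

#' Model right-hand side
#'
#' `dV/dt = (Istim - sum(Iion)) / Cm`; each state gate relaxes to its
#' steady state, `dY/dt = (Yinf(V) - Y) / tau_Y(V)`.
#'
#' @param t time, ms (passed to `stim`).
#' @param state named numeric vector `(V, m, h, s, f, xr, xs)`.
#' @param params parameter vector.
#' @param stim stimulus function of time returning uA/cm^2; positive
#'   depolarizes. Defaults to no stimulus.
#' @return named numeric vector of the seven time derivatives.
#' @export
ap_rhs <- function(t, state, params = nominal_parameters(),
                   stim = function(t) 0) {
  if (any(!is.finite(state))) abort("non-finite state")
  p <- as_param_vector(params)
  d <- cpp_derivs(p, as_state_matrix(state), as.numeric(stim(t)))
  setNames(as.numeric(d[1, ]), .state_names)
}

#' Resting initial conditions
#'
#' `V = EK`; every state gate starts at its steady state evaluated at `EK`,
#' so all gate derivatives are exactly zero at t = 0.
#'
#' @param params parameter vector.
#' @return named numeric state vector of length 7.
#' @export
initial_conditions <- function(params = nominal_parameters()) {
  p <- as_param_vector(params)
  V0 <- p[["EK"]]
  y <- c(V0, vapply(.state_gates,
                    function(g) gate_steady_state(V0, g, p), numeric(1)))
  setNames(y, .state_names)
}

#' @export
print.apuq_parameters <- function(x, ...) {
  cat("<apuq_parameters> 36 model parameters + Cm\n")
  print(unclass(x), ...)
  invisible(x)
}
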