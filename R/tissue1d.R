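# 1D monodomain strand: chi (Cm dV/dt + Iion) = d/dx (sigma dV/dx),
# solved by operator splitting (Rush-Larsen / forward-Euler reaction,
# backward-Euler diffusion on a second-order centered stencil) with
# no-flux boundaries.

#' Strand configuration
#'
#' @param length strand length, cm (default 1).
#' @param chi surface-area-to-volume ratio, 1/cm (default 1400).
#' @param sigma bulk conductivity, mS/cm (default 1.4).
#' @param dx node spacing, cm (default 0.005; must be <= 0.01).
#' @param dt PDE time step, ms (default 0.01).
#' @param stim_width stimulated span at the x = 0 end, cm (default 0.05).
#' @param stim_amplitude stimulus current, uA/cm^2; the default `NULL`
#'   uses 2x the single-cell threshold of the parameter set.
#' @param stim_duration stimulus duration, ms (default 1).
#' @return list of class `"strand_config"`.
#' @export
strand_config <- function(length = 1, chi = 1400, sigma = 1.4,
                          dx = 0.005, dt = 0.01, stim_width = 0.05,
                          stim_amplitude = NULL, stim_duration = 1) {
  if (dx > 0.01) abort("dx must be <= 0.01 cm")
  if (chi <= 0 || sigma <= 0) abort("chi and sigma must be positive")
  structure(list(length = length, chi = chi, sigma = sigma, dx = dx,
                 dt = dt, stim_width = stim_width,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration),
            class = "strand_config")
}

#' Solve the monodomain strand
#'
#' Propagates a stimulated wave along a uniform 1D strand of the cell
#' model and records per-node activation times (first upward crossing of
#' -70 mV, linearly interpolated in time) plus the full voltage trace at
#' a probe location. A wave that never reaches the probe is flagged in
#' the result, not raised as an error.
#'
#' @param params parameter vector.
#' @param config a [strand_config()].
#' @param duration simulation time, ms.
#' @param probe_x probe location, cm (default 0.75).
#' @param dt_out probe trace output step, ms.
#' @return object of class `"strand_solution"`: list with `activation`
#'   (tibble `x`, `activation_time`), `probe` (tibble `time`, `V`, `dVdt`
#'   by central differences), `probe_x`, `propagation_failed`, `config`.
#' @export
solve_strand <- function(params = nominal_parameters(),
                         config = strand_config(), duration = 40,
                         probe_x = 0.75, dt_out = 0.1) {
  p <- as_param_vector(params)
  validate_parameters(p)
  amp <- config$stim_amplitude
  if (is.null(amp)) amp <- 2 * find_threshold(p)
  n_nodes <- round(config$length / config$dx) + 1
  n_stim <- max(2L, round(config$stim_width / config$dx))
  probe_node <- round(probe_x / config$dx)
  if (probe_node >= n_nodes) abort("probe_x outside the strand")
  y0 <- initial_conditions(p)
  res <- cpp_strand(p, as.numeric(y0), n_nodes, config$dx, config$dt,
                    duration, config$chi, config$sigma, n_stim, amp,
                    config$stim_duration, probe_node, dt_out)
  act <- tibble::tibble(x = res$x, activation_time = res$activation_time)
  vp <- res$v_probe
  tp <- res$t
  dvdt <- c(NA_real_, (vp[-1] - vp[-length(vp)]) / diff(tp))
  probe <- structure(
    tibble::tibble(time = tp, V = vp, dVdt = dvdt),
    stim_onset = 0,
    class = c("ap_trace", class(tibble::tibble())))
  structure(list(
    activation = act,
    probe = probe,
    probe_x = probe_node * config$dx,
    propagation_failed = is.na(res$activation_time[probe_node + 1]),
    stim_amplitude = amp,
    config = config,
    duration = duration
  ), class = "strand_solution")
}

#' Conduction velocity from activation times
#'
#' `CV = (x2 - x1) / (t(x2) - t(x1))`, converted to cm/s. Both points
#' should lie outside the stimulated region.
#'
#' @param sol a [solve_strand()] result.
#' @param x1,x2 measurement points, cm (defaults 0.25 and 0.75).
#' @return conduction velocity, cm/s.
#' @export
conduction_velocity <- function(sol, x1 = 0.25, x2 = 0.75) {
  act <- sol$activation
  t1 <- act$activation_time[which.min(abs(act$x - x1))]
  t2 <- act$activation_time[which.min(abs(act$x - x2))]
  if (is.na(t1) || is.na(t2))
    abort("measurement point not activated; wave did not propagate")
  (x2 - x1) / (t2 - t1) * 1000
}

#' AP quantities of interest at a strand location
#'
#' Delegates to [extract_qois()] on the probe-node voltage trace (the
#' threshold field is left undefined: it is a single-cell protocol
#' quantity). `dVdt` at the probe is a central finite difference of the
#' recorded trace, which includes the electrotonic (diffusive) current.
#'
#' @param sol a [solve_strand()] result.
#' @param x location, cm; must equal the probe location of the solve.
#' @return one-row QOI tibble as from [extract_qois()].
#' @export
strand_qois <- function(sol, x = 0.75) {
  if (abs(x - sol$probe_x) > 1e-9)
    abort(paste0("trace recorded at x = ", sol$probe_x,
                 "; re-solve with probe_x = ", x))
  extract_qois(sol$probe)
}
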