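# Stimulus protocols and time integration of the 7-ODE cell model.

#' Stimulus protocol description
#'
#' @param onset time of the (first) pulse, ms.
#' @param duration pulse width, ms (default 0.5).
#' @param amplitude pulse height, uA/cm^2 (>= 0).
#' @param period pacing period (basic cycle length), ms; `NULL` for a
#'   single pulse.
#' @param n_beats number of pulses when pacing.
#' @return list with class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(onset = 0, duration = 0.5, amplitude,
                              period = NULL, n_beats = NULL) {
  if (duration <= 0) abort("stimulus duration must be > 0")
  if (amplitude < 0) abort("stimulus amplitude must be >= 0")
  if (!is.null(period) && period <= duration)
    abort("pacing period must exceed stimulus duration")
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 period = period, n_beats = n_beats),
            class = "stimulus_protocol")
}

pulse_matrix <- function(stim) {
  if (is.null(stim$period)) {
    matrix(c(stim$onset, stim$duration, stim$amplitude), nrow = 1)
  } else {
    on <- stim$onset + (seq_len(stim$n_beats) - 1) * stim$period
    cbind(on, stim$duration, stim$amplitude)
  }
}

default_solver <- function() {
  list(rtol = 1e-6, atol = 1e-8, max_step = 1)
}

new_ap_trace <- function(df, stim, params, threshold = NA_real_,
                         solver = default_solver()) {
  structure(tibble::as_tibble(df),
            stim_onset = stim$onset, stim_duration = stim$duration,
            stim_amplitude = stim$amplitude, threshold = threshold,
            params = as_param_vector(params), solver = solver,
            class = c("ap_trace", class(tibble::tibble())))
}

#' Simulate a single action potential
#'
#' Integrates the seven-ODE cell model with an adaptive Dormand-Prince 5(4)
#' solver (integration restarted at stimulus on/off boundaries, so the
#' square pulse never crosses a step). The solution is reported on a
#' uniform output grid; `dVdt` is the model right-hand side evaluated at
#' the grid points, not a finite difference.
#'
#' @param params parameter vector (named; missing entries filled from
#'   nominal).
#' @param amplitude stimulus amplitude, uA/cm^2. The default `NULL`
#'   computes the parameter-set-specific threshold by bisection and
#'   stimulates at `threshold_factor` times it.
#' @param threshold_factor multiple of threshold used when
#'   `amplitude = NULL` (default 1.1).
#' @param duration simulation horizon, ms (default 1000).
#' @param dt_out output grid step, ms (default 0.05).
#' @param stim stimulus protocol; default a single 0.5 ms pulse at t = 0.
#' @param init initial state; default [initial_conditions()].
#' @param with_currents append the six ionic current columns.
#' @param with_states append the six gate state columns.
#' @param rtol,atol,max_step solver controls.
#' @return An `ap_trace` tibble with columns `time`, `V`, `dVdt` (and
#'   optionally currents/states), carrying the stimulus metadata, the
#'   threshold (when computed) and the parameters as attributes.
#' @examples
#' tr <- simulate_ap(nominal_parameters(), duration = 400)
#' max(tr$V)
#' @export
simulate_ap <- function(params = nominal_parameters(), amplitude = NULL,
                        threshold_factor = 1.1, duration = 1000,
                        dt_out = 0.05, stim = NULL, init = NULL,
                        with_currents = FALSE, with_states = FALSE,
                        rtol = 1e-6, atol = 1e-8, max_step = 1) {
  p <- as_param_vector(params)
  validate_parameters(p)
  thr <- NA_real_
  if (is.null(stim)) {
    if (is.null(amplitude)) {
      thr <- find_threshold(p, rtol = rtol, atol = atol, max_step = max_step)
      amplitude <- threshold_factor * thr
    }
    stim <- stimulus_protocol(onset = 0, duration = 0.5,
                              amplitude = amplitude)
  }
  if (duration < stim$onset + stim$duration)
    abort("duration must cover the stimulus")
  y0 <- if (is.null(init)) initial_conditions(p) else init
  res <- tryCatch(
    cpp_simulate(p, as.numeric(y0), pulse_matrix(stim), duration, dt_out,
                 rtol, atol, max_step, with_states, with_currents),
    error = function(e) {
      abort(paste0("AP simulation failed (", conditionMessage(e),
                   ") for parameter set with gNa=", signif(p[["gNa"]], 6),
                   ", Eh=", signif(p[["Eh"]], 6)))
    })
  df <- tibble::tibble(time = res$t, V = res$V, dVdt = res$dVdt)
  if (with_currents) {
    cur <- res$currents
    colnames(cur) <- c("INa", "IK1", "Ito", "ICaL", "IKr", "IKs")
    df <- dplyr::bind_cols(df, tibble::as_tibble(cur))
  }
  if (with_states) {
    st <- res$states
    colnames(st) <- .state_names
    df <- dplyr::bind_cols(df, tibble::as_tibble(st[, -1, drop = FALSE]))
  }
  tr <- new_ap_trace(df, stim, p, threshold = thr,
                     solver = list(rtol = rtol, atol = atol,
                                   max_step = max_step))
  attr(tr, "final_state") <- setNames(as.numeric(res$final_state),
                                      .state_names)
  tr
}

#' Threshold stimulus by bisection
#'
#' The minimum amplitude of a 0.5 ms square pulse that elicits
#' depolarization, defined as V exceeding `v_criterion` (0 mV) within
#' `window` (50 ms) of stimulus onset. Bisection on
#' `[0, search_hi]` to relative tolerance `rel_tol`; the returned
#' amplitude depolarizes while `amplitude / (1 + rel_tol)` does not.
#'
#' @param params parameter vector.
#' @param search_hi upper bracket, uA/cm^2 (default 200).
#' @param rel_tol relative bisection tolerance (default 0.005).
#' @param stim_duration pulse width, ms.
#' @param window depolarization detection window after onset, ms.
#' @param v_criterion voltage defining depolarization, mV.
#' @param init initial state; default resting conditions.
#' @param rtol,atol,max_step solver controls.
#' @return threshold amplitude, uA/cm^2.
#' @export
find_threshold <- function(params = nominal_parameters(), search_hi = 200,
                           rel_tol = 0.005, stim_duration = 0.5,
                           window = 50, v_criterion = 0, init = NULL,
                           rtol = 1e-6, atol = 1e-8, max_step = 1) {
  p <- as_param_vector(params)
  y0 <- if (is.null(init)) initial_conditions(p) else init
  thr <- cpp_find_threshold(p, as.numeric(y0), 0, search_hi, rel_tol,
                            stim_duration, window + stim_duration,
                            v_criterion, rtol, atol, max_step)
  if (is.na(thr))
    abort(paste0("threshold bracket failure: no depolarization up to ",
                 search_hi, " uA/cm^2 for parameter set with gNa=",
                 signif(p[["gNa"]], 6), ", Eh=", signif(p[["Eh"]], 6)))
  thr
}

#' Pace the cell model at a fixed cycle length
#'
#' Repeated 0.5 ms stimuli at `amplitude` (default 1.1x the parameter
#' set's threshold), with the state carried continuously between beats.
#'
#' @param params parameter vector.
#' @param bcl basic cycle length, ms (>= 100).
#' @param n_beats number of beats.
#' @param amplitude stimulus amplitude; default 1.1x threshold.
#' @param keep `"all"` returns one `ap_trace` per beat (times aligned to
#'   each stimulus); `"last"` integrates beats 1..n-1 without storing
#'   output and returns only the final beat's trace.
#' @inheritParams simulate_ap
#' @return list of `ap_trace` (`keep = "all"`) or a single `ap_trace`
#'   (`keep = "last"`); each trace's `final_state` attribute is the state
#'   at the end of its beat.
#' @export
pace <- function(params = nominal_parameters(), bcl = 1000, n_beats = 10,
                 amplitude = NULL, keep = c("all", "last"), dt_out = 0.05,
                 init = NULL, with_currents = FALSE, with_states = FALSE,
                 rtol = 1e-6, atol = 1e-8, max_step = 1) {
  keep <- match.arg(keep)
  p <- as_param_vector(params)
  if (bcl < 100) abort("bcl must be >= 100 ms")
  if (is.null(amplitude))
    amplitude <- 1.1 * find_threshold(p, rtol = rtol, atol = atol,
                                      max_step = max_step)
  y <- if (is.null(init)) initial_conditions(p) else init
  stim <- stimulus_protocol(onset = 0, duration = 0.5,
                            amplitude = amplitude)
  if (keep == "last") {
    res <- cpp_pace_last(p, as.numeric(y), bcl, n_beats, amplitude, 0.5,
                         dt_out, rtol, atol, max_step, with_states,
                         with_currents)
    df <- tibble::tibble(time = res$t, V = res$V, dVdt = res$dVdt)
    if (with_currents) {
      cur <- res$currents
      colnames(cur) <- c("INa", "IK1", "Ito", "ICaL", "IKr", "IKs")
      df <- dplyr::bind_cols(df, tibble::as_tibble(cur))
    }
    if (with_states) {
      st <- res$states
      colnames(st) <- .state_names
      df <- dplyr::bind_cols(df, tibble::as_tibble(st[, -1, drop = FALSE]))
    }
    tr <- new_ap_trace(df, stim, p)
    attr(tr, "final_state") <- setNames(as.numeric(res$final_state),
                                        .state_names)
    return(tr)
  }
  beats <- vector("list", n_beats)
  for (b in seq_len(n_beats)) {
    tr <- simulate_ap(p, amplitude = amplitude, duration = bcl,
                      dt_out = dt_out, stim = stim, init = y,
                      with_currents = with_currents,
                      with_states = with_states,
                      rtol = rtol, atol = atol, max_step = max_step)
    y <- attr(tr, "final_state")
    beats[[b]] <- tr
  }
  beats
}

#' Dynamic APD restitution protocol
#'
#' Paces at each basic cycle length in turn (state carried across cycle
#' lengths) and reports the final beat's APD95 -- the time from activation
#' (first upward crossing of -70 mV) to 95% repolarization of that beat's
#' amplitude -- together with the diastolic interval `DI = BCL - APD95`.
#' Beats that lose 1:1 capture are flagged, not dropped.
#'
#' @param params parameter vector.
#' @param bcl_list decreasing cycle lengths, ms.
#' @param beats_per_bcl beats at each cycle length (>= 20 recommended).
#' @param amplitude stimulus amplitude; default 1.1x threshold.
#' @inheritParams simulate_ap
#' @return tibble with columns `bcl`, `apd95`, `di`, `captured`, of class
#'   `"ap_restitution"`.
#' @export
dynamic_restitution <- function(params = nominal_parameters(),
                                bcl_list = c(1000, 800, 600, 500, 400, 300),
                                beats_per_bcl = 20, amplitude = NULL,
                                dt_out = 0.05, rtol = 1e-6, atol = 1e-8,
                                max_step = 1) {
  p <- as_param_vector(params)
  if (is.unsorted(rev(bcl_list)))
    abort("bcl_list must be decreasing")
  if (is.null(amplitude))
    amplitude <- 1.1 * find_threshold(p, rtol = rtol, atol = atol,
                                      max_step = max_step)
  y <- initial_conditions(p)
  rows <- vector("list", length(bcl_list))
  for (i in seq_along(bcl_list)) {
    bcl <- bcl_list[i]
    res <- cpp_pace_last(p, as.numeric(y), bcl, beats_per_bcl, amplitude,
                         0.5, dt_out, rtol, atol, max_step, FALSE, FALSE)
    y <- setNames(as.numeric(res$final_state), .state_names)
    apd95 <- apd_at_fraction(res$t, res$V, onset = 0, fraction = 0.95)
    captured <- is.finite(apd95) && apd95 < bcl && max(res$V) > 0
    rows[[i]] <- tibble::tibble(
      bcl = bcl,
      apd95 = if (captured) apd95 else NA_real_,
      di = if (captured) bcl - apd95 else NA_real_,
      captured = captured
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ap_restitution", class(out))
  out
}

# APD to a repolarization fraction of the beat's amplitude (APD95 etc.)
apd_at_fraction <- function(t, V, onset = 0, fraction = 0.95) {
  rest <- V[which.min(abs(t - onset))]
  pk <- max(V)
  if (pk < 0) return(NA_real_)
  vcut <- pk - fraction * (pk - rest)
  t_act <- interp_crossing(t, V, -70, "up", after = onset)
  if (is.na(t_act)) return(NA_real_)
  t_rep <- interp_crossing(t, V, vcut, "down", after = t[which.max(V)])
  if (is.na(t_rep)) return(NA_real_)
  t_rep - t_act
}

# linearly interpolated first threshold crossing after a given time
interp_crossing <- function(t, V, level, direction = c("up", "down"),
                            after = -Inf) {
  direction <- match.arg(direction)
  n <- length(V)
  if (direction == "up")
    idx <- which(V[-n] < level & V[-1] >= level)
  else
    idx <- which(V[-n] >= level & V[-1] < level)
  idx <- idx[t[idx] >= after]
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  t[i] + (level - V[i]) / (V[i + 1] - V[i]) * (t[i + 1] - t[i])
}
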