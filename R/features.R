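# Scalar quantities of interest (QOIs) extracted from an AP trace, and the
# four-way behavior taxonomy with oscillatory sub-types.

# Local extrema of V with a prominence filter. Raw extrema come from sign
# changes of the discrete differences; adjacent extremum pairs closer in
# voltage than `prominence` are then merged away (smallest pair first),
# which suppresses solver wiggle and the kink at stimulus offset without
# smoothing the trace itself. Returns alternating extrema, interior only.
find_extrema <- function(t, V, prominence = 0.5) {
  d <- diff(V)
  s <- sign(d)
  # carry the previous sign over exact zeros so flats do not spawn extrema
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  chg <- which(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0) + 1
  if (!length(chg)) {
    return(tibble::tibble(idx = integer(), time = numeric(),
                          value = numeric(), type = character()))
  }
  idx <- chg
  type <- ifelse(s[chg - 1] > 0, "max", "min")
  # merge shallow features: walk the alternating sequence (with the trace
  # endpoints as barriers) and drop the least prominent feature until every
  # adjacent voltage gap is at least `prominence`. An interior pair is
  # removed together (keeps alternation); an extremum adjacent to an
  # endpoint is removed alone.
  repeat {
    if (!length(idx)) break
    vals <- c(V[1], V[idx], V[length(V)])
    gaps <- abs(diff(vals))
    k <- which.min(gaps)
    if (gaps[k] >= prominence) break
    if (k == 1) {
      drop <- 1L
    } else if (k == length(gaps)) {
      drop <- length(idx)
    } else {
      drop <- c(k - 1L, k)
    }
    idx <- idx[-drop]
    type <- type[-drop]
  }
  tibble::tibble(idx = idx, time = t[idx], value = V[idx], type = type)
}

trace_onset <- function(trace) {
  on <- attr(trace, "stim_onset")
  if (is.null(on)) 0 else on
}

#' Extract scalar QOIs from an AP trace
#'
#' Computes the upstroke metrics (maximum upstroke velocity, its time
#' relative to stimulus onset, and the action potential amplitude APA),
#' the action potential duration (APD: time from activation, the first
#' upward crossing of -70 mV, to the subsequent downward crossing, both
#' linearly interpolated), and the notch voltages (the local minimum after
#' the initial spike and the following local maximum, when the trace has
#' spike-and-dome morphology). Each potentially undefined quantity carries
#' an explicit `*_defined` flag; undefined values are `NA`, never zero.
#'
#' The upstroke window runs from stimulus onset to the first
#' prominence-filtered local maximum of V; `dVdt` is the model RHS on the
#' output grid and the argmax time is refined by local parabolic
#' interpolation. The resting potential used for APA is V at stimulus
#' onset.
#'
#' @param trace an `ap_trace` from [simulate_ap()] (or any tibble with
#'   `time`, `V` and optionally `dVdt` columns plus stimulus attributes).
#' @param prominence extremum prominence filter, mV.
#' @return one-row tibble: `threshold`, `max_upstroke_velocity`,
#'   `time_of_max_upstroke_velocity`, `apa`, `apd`, `notch_min`,
#'   `notch_max`, plus logical `upstroke_defined`, `apd_defined`,
#'   `notch_defined`.
#' @export
extract_qois <- function(trace, prominence = 0.5) {
  t <- trace$time
  V <- trace$V
  dv <- if ("dVdt" %in% names(trace)) trace$dVdt else
    c(diff(V) / diff(t), NA_real_)
  onset <- trace_onset(trace)
  thr <- attr(trace, "threshold")
  if (is.null(thr)) thr <- NA_real_
  post <- which(t >= onset)
  win <- post[t[post] <= onset + 50]
  depolarized <- length(win) > 0 && any(V[win] > 0)
  ex <- find_extrema(t[post], V[post], prominence)
  mxv <- tmx <- apa <- NA_real_
  upstroke_defined <- FALSE
  first_max <- which(ex$type == "max")[1]
  if (depolarized && !is.na(first_max)) {
    ipk <- post[ex$idx[first_max]]
    iw <- post[post <= ipk]
    im <- iw[which.max(dv[iw])]
    mxv <- dv[im]
    tmx <- refine_argmax(t, dv, im) - onset
    apa <- V[ipk] - V[post[1]]
    upstroke_defined <- TRUE
  }
  t_act <- interp_crossing(t, V, -70, "up", after = onset)
  apd <- NA_real_
  if (!is.na(t_act)) {
    t_rep <- interp_crossing(t, V, -70, "down", after = t_act)
    if (!is.na(t_rep)) apd <- t_rep - t_act
  }
  notch_min <- notch_max <- NA_real_
  notch_defined <- FALSE
  if (!is.na(first_max) && nrow(ex) >= first_max + 2 &&
      ex$type[first_max + 1] == "min" && ex$type[first_max + 2] == "max") {
    notch_min <- ex$value[first_max + 1]
    notch_max <- ex$value[first_max + 2]
    notch_defined <- TRUE
  }
  tibble::tibble(
    threshold = thr,
    max_upstroke_velocity = mxv,
    time_of_max_upstroke_velocity = tmx,
    apa = apa,
    apd = apd,
    notch_min = notch_min,
    notch_max = notch_max,
    upstroke_defined = upstroke_defined,
    apd_defined = !is.na(apd),
    notch_defined = notch_defined
  )
}

# parabolic refinement of a grid argmax
refine_argmax <- function(t, y, i) {
  if (i <= 1 || i >= length(y)) return(t[i])
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (den >= 0) return(t[i])
  t[i] + 0.5 * (y[i - 1] - y[i + 1]) / den * (t[i + 1] - t[i])
}

#' Classify AP behavior
#'
#' Four-way taxonomy based on the prominence-filtered interior local
#' extrema of the post-stimulus voltage trace over a 1000 ms horizon:
#'
#' * Behavior 1 -- dome without spike: a single local maximum occurring
#'   later than 10 ms after stimulus onset, no local minimum.
#' * Behavior 2 -- spike without dome: a single local maximum within
#'   10 ms, no local minimum (monotone decay after the peak).
#' * Behavior 3 -- oscillatory dynamics: more than one local minimum; also
#'   traces with exactly two local maxima and one local minimum whose
#'   first maximum occurs later than 10 ms (voltage keeps rising after the
#'   upstroke before oscillating).
#' * Behavior 4 -- normal: anything else, including the physiological
#'   spike-notch-dome shape (two maxima, one minimum, early first peak).
#'
#' Behavior 3 is refined by the voltage at t = 1000 ms after onset:
#' 3A below -75 mV (back at rest: early afterdepolarizations), 3B above
#' -25 mV (repolarization failure), 3C in between (low-voltage
#' oscillations).
#'
#' @param trace an `ap_trace` covering at least 1000 ms after stimulus
#'   onset.
#' @param prominence extremum prominence filter, mV.
#' @param horizon classification horizon, ms.
#' @return one-row tibble with integer `major`, character `sub`
#'   (`"none"`, `"3A"`, `"3B"`, `"3C"`) and `label` (`"1"`, `"2"`,
#'   `"3A"`, `"3B"`, `"3C"`, `"4"`).
#' @export
classify_behavior <- function(trace, prominence = 0.5, horizon = 1000) {
  t <- trace$time
  V <- trace$V
  onset <- trace_onset(trace)
  if (max(t) < onset + horizon - 1e-9)
    abort("trace must extend to at least the classification horizon")
  keep <- which(t >= onset & t <= onset + horizon)
  ex <- find_extrema(t[keep], V[keep], prominence)
  n_max <- sum(ex$type == "max")
  n_min <- sum(ex$type == "min")
  t_first_max <- if (n_max > 0) ex$time[ex$type == "max"][1] - onset else NA
  major <- if (n_max == 1 && n_min == 0) {
    if (t_first_max > 10) 1L else 2L
  } else if (n_min >= 2 ||
             (n_max == 2 && n_min == 1 && !is.na(t_first_max) &&
              t_first_max > 10)) {
    3L
  } else 4L
  sub <- "none"
  if (major == 3L)
    sub <- classify_oscillatory_subtype(trace, horizon = horizon)
  tibble::tibble(major = major, sub = sub,
                 label = if (major == 3L) sub else as.character(major))
}

#' Oscillatory sub-type from end-of-horizon voltage
#'
#' Partition of Behavior-3 traces by V at 1000 ms after stimulus onset:
#' `< -75 mV` is 3A (AP returned to rest), `> -25 mV` is 3B
#' (repolarization failure), otherwise 3C (low-voltage oscillations).
#'
#' @inheritParams classify_behavior
#' @return `"3A"`, `"3B"` or `"3C"`.
#' @export
classify_oscillatory_subtype <- function(trace, horizon = 1000) {
  onset <- trace_onset(trace)
  v_end <- trace$V[which.min(abs(trace$time - (onset + horizon)))]
  if (v_end < -75) "3A" else if (v_end > -25) "3B" else "3C"
}
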