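# Hyper-parameter-controlled input distributions, Monte Carlo sampling and
# uncertainty propagation.

#' Build the parameter uncertainty specification
#'
#' One scalar hyper-parameter, `sigma_hat`, scales every parameter's
#' uncertainty. Half-(in)activation voltages (the ten `E_Y`) are normal
#' with mean at the nominal value and standard deviation
#' `sigma_hat * reference_range` (reference range 100 mV, so voltages of
#' different magnitude get comparable variability). Conductances, slope
#' factors, time constants and `delta_h` -- all necessarily positive --
#' are lognormal with underlying mean `log(p_nom) - sigma_hat^2/2` and
#' standard deviation `sigma_hat`, so their analytic mean is exactly the
#' nominal value and their standard deviation is approximately
#' `sigma_hat * p_nom`. The Nernst potentials and Cm are environmental and
#' always fixed. `sigma_hat = 0` degenerates every distribution to a
#' point mass at the nominal value.
#'
#' @param sigma_hat dimensionless hyper-parameter (0.01 for "1%"); >= 0.
#' @param reference_range reference voltage range, mV (default 100).
#' @param nominal nominal parameter vector.
#' @param fix_at_nominal names of additional parameters to hold fixed at
#'   nominal (e.g. `c("Eh","delta_h","Er","Ed","Ef")` for the influential-
#'   parameter rescue experiment).
#' @return tibble with one row per parameter (`parameter`, `nominal`,
#'   `family`, `mean`, `sd`, `meanlog`, `sdlog`) of class
#'   `"uncertainty_spec"`; `sigma_hat`, `reference_range` and the full
#'   nominal vector are attached as attributes.
#' @examples
#' spec <- uncertainty_spec(0.05)
#' param_interval(spec, "gNa")   # equal-tailed 95% interval
#' @export
uncertainty_spec <- function(sigma_hat, reference_range = 100,
                             nominal = nominal_parameters(),
                             fix_at_nominal = character()) {
  if (sigma_hat < 0) abort("sigma_hat must be >= 0")
  p <- as_param_vector(nominal)
  bad <- setdiff(fix_at_nominal, .param_order)
  if (length(bad))
    abort(paste0("unknown parameter(s) in fix_at_nominal: ",
                 paste(bad, collapse = ", ")))
  fam <- ifelse(.param_order %in% .fixed_params, "fixed",
         ifelse(.param_order %in% .voltage_params, "normal", "lognormal"))
  fam[.param_order %in% fix_at_nominal] <- "fixed"
  nom <- p[.param_order]
  spec <- tibble::tibble(
    parameter = .param_order,
    nominal = unname(nom),
    family = fam,
    mean = ifelse(fam == "normal", unname(nom), NA_real_),
    sd = ifelse(fam == "normal", sigma_hat * reference_range, NA_real_),
    meanlog = ifelse(fam == "lognormal",
                     suppressWarnings(log(unname(nom))) - sigma_hat^2 / 2,
                     NA_real_),
    sdlog = ifelse(fam == "lognormal", sigma_hat, NA_real_)
  )
  structure(spec, sigma_hat = sigma_hat,
            reference_range = reference_range, nominal = p,
            class = c("uncertainty_spec", class(spec)))
}

#' Per-parameter quantile function
#'
#' @param spec an [uncertainty_spec()].
#' @param parameter parameter name.
#' @param prob probabilities.
#' @return quantiles of that parameter's marginal distribution.
#' @export
param_quantile <- function(spec, parameter, prob) {
  row <- spec[spec$parameter == parameter, ]
  if (nrow(row) != 1) abort(paste0("unknown parameter: ", parameter))
  switch(row$family,
    fixed = rep(row$nominal, length(prob)),
    normal = qnorm(prob, row$mean, row$sd),
    lognormal = qlnorm(prob, row$meanlog, row$sdlog))
}

#' Equal-tailed interval of a parameter's marginal
#'
#' @inheritParams param_quantile
#' @param level coverage (default 0.95).
#' @return length-2 numeric vector (lower, upper).
#' @export
param_interval <- function(spec, parameter, level = 0.95) {
  a <- (1 - level) / 2
  param_quantile(spec, parameter, c(a, 1 - a))
}

#' Draw a Monte Carlo sample matrix
#'
#' Independent draws per parameter. The random stream is consumed one
#' parameter at a time in the canonical column order, so the draws for a
#' given `(n, seed)` do not depend on which QOIs are analyzed later.
#' Fixed-family parameters are constant across rows.
#'
#' @param spec an [uncertainty_spec()].
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @return tibble with `n` rows and 36 parameter columns, carrying
#'   `sigma_hat`, `seed` and `scheme = "simple-mc"` attributes.
#' @export
sample_parameters <- function(spec, n, seed = 1) {
  if (n < 1) abort("n must be >= 1")
  set.seed(seed)
  cols <- lapply(seq_len(nrow(spec)), function(i) {
    switch(spec$family[i],
      fixed = rep(spec$nominal[i], n),
      normal = rnorm(n, spec$mean[i], spec$sd[i]),
      lognormal = rlnorm(n, spec$meanlog[i], spec$sdlog[i]))
  })
  names(cols) <- spec$parameter
  out <- tibble::as_tibble(cols)
  structure(out, sigma_hat = attr(spec, "sigma_hat"), seed = seed,
            scheme = "simple-mc")
}

# simulate one sampled parameter row and extract QOIs + behavior label;
# returns a one-row tibble. Failures are recorded in `status`.
simulate_sample_row <- function(row, duration = 1000, dt_out = 0.05,
                                threshold_factor = 1.1, search_hi = 200,
                                rtol = 1e-6, atol = 1e-8, max_step = 1) {
  empty <- tibble::tibble(
    threshold = NA_real_, max_upstroke_velocity = NA_real_,
    time_of_max_upstroke_velocity = NA_real_, apa = NA_real_,
    apd = NA_real_, notch_min = NA_real_, notch_max = NA_real_,
    upstroke_defined = FALSE, apd_defined = FALSE, notch_defined = FALSE,
    behavior = NA_character_, v_end = NA_real_)
  p <- as_param_vector(row)
  y0 <- initial_conditions(p)
  thr <- tryCatch(
    cpp_find_threshold(p, as.numeric(y0), 0, search_hi, 0.005, 0.5, 50.5,
                       0, rtol, atol, max_step),
    error = function(e) NA_real_)
  if (is.na(thr)) {
    empty$behavior <- NA_character_
    return(dplyr::mutate(empty, status = "threshold_failure"))
  }
  tr <- tryCatch(
    simulate_ap(p, amplitude = threshold_factor * thr, duration = duration,
                dt_out = dt_out, rtol = rtol, atol = atol,
                max_step = max_step),
    error = function(e) NULL)
  if (is.null(tr)) {
    empty$threshold <- thr
    return(dplyr::mutate(empty, status = "solver_failure"))
  }
  q <- extract_qois(tr)
  q$threshold <- thr
  cls <- if (duration >= 1000) classify_behavior(tr)$label else NA_character_
  q$behavior <- cls
  q$v_end <- tr$V[nrow(tr)]
  dplyr::mutate(q, status = "ok")
}

#' Monte Carlo uncertainty propagation
#'
#' Samples `n` parameter sets, finds each set's threshold stimulus by
#' bisection, simulates a 1000 ms AP at 1.1x threshold from resting
#' initial conditions, extracts all scalar QOIs and classifies the
#' behavior. Individual solver or threshold failures are recorded per row
#' and excluded from summaries -- the batch never aborts.
#'
#' @param spec an [uncertainty_spec()] (or a pre-drawn sample tibble from
#'   [sample_parameters()]).
#' @param n number of Monte Carlo samples (ignored when `spec` is a
#'   sample matrix).
#' @param seed RNG seed.
#' @param duration simulation horizon, ms.
#' @param dt_out output grid, ms.
#' @param threshold_factor stimulus amplitude in units of threshold.
#' @return object of class `"ap_propagation"`: a list with `qois` (tibble:
#'   parameter columns, QOI columns, `behavior`, `status`), `sigma_hat`,
#'   `seed`, `n`. Summarize with [tidy()] (per-QOI mean/sd/CoV and the
#'   N-vs-N/2 convergence flag) and [glance()].
#' @examples
#' \donttest{
#' pr <- propagate(uncertainty_spec(0.01), n = 50, seed = 1)
#' tidy(pr)
#' }
#' @export
propagate <- function(spec, n = 1000, seed = 1, duration = 1000,
                      dt_out = 0.05, threshold_factor = 1.1) {
  if (inherits(spec, "uncertainty_spec")) {
    samples <- sample_parameters(spec, n, seed)
    sigma_hat <- attr(spec, "sigma_hat")
  } else {
    samples <- spec
    n <- nrow(samples)
    sigma_hat <- attr(samples, "sigma_hat")
  }
  mat <- as.matrix(samples[, .param_order])
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- simulate_sample_row(mat[i, ], duration = duration,
                                    dt_out = dt_out,
                                    threshold_factor = threshold_factor)
  }
  qois <- dplyr::bind_cols(samples, dplyr::bind_rows(res))
  structure(list(qois = qois, sigma_hat = sigma_hat, seed = seed, n = n),
            class = "ap_propagation")
}

.qoi_names <- c("threshold", "max_upstroke_velocity",
                "time_of_max_upstroke_velocity", "apa", "apd",
                "notch_min", "notch_max")

# the N-vs-N/2 convergence rule: mean stable to 3 significant figures and
# sd stable to 2 when re-estimated from the first half of the sample
mc_converged <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) return(NA)
  half <- x[seq_len(floor(length(x) / 2))]
  isTRUE(signif(mean(x), 3) == signif(mean(half), 3)) &&
    isTRUE(signif(sd(x), 2) == signif(sd(half), 2))
}

#' @describeIn propagate per-QOI summary: mean, sd, coefficient of
#'   variation (percent), defined fraction, convergence flag.
#' @param x an `ap_propagation`.
#' @param ... unused.
#' @export
tidy.ap_propagation <- function(x, ...) {
  q <- x$qois
  ok <- q$status == "ok"
  purrr::map_dfr(.qoi_names, function(nm) {
    v <- q[[nm]][ok]
    v <- v[is.finite(v)]
    tibble::tibble(
      qoi = nm,
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else NA_real_,
      cov_pct = if (length(v) > 1 && mean(v) != 0)
        100 * sd(v) / abs(mean(v)) else NA_real_,
      n_defined = length(v),
      frac_defined = length(v) / nrow(q),
      converged = mc_converged(v)
    )
  })
}

#' @describeIn propagate one-row overview: n, failures, behavior counts.
#' @export
glance.ap_propagation <- function(x, ...) {
  q <- x$qois
  tibble::tibble(
    n = x$n,
    sigma_hat = x$sigma_hat,
    seed = x$seed,
    n_ok = sum(q$status == "ok"),
    n_failed = sum(q$status != "ok"),
    frac_normal = mean(q$behavior == "4", na.rm = TRUE),
    frac_non_normal = mean(q$behavior != "4", na.rm = TRUE)
  )
}

#' Behavior probabilities under parameter uncertainty
#'
#' Fraction of sampled APs in each behavior class, with binomial standard
#' errors. Accepts an existing propagation (reusing its simulations) or an
#' [uncertainty_spec()] (runs one).
#'
#' @param x `ap_propagation` or `uncertainty_spec`.
#' @param n,seed used when `x` is a spec.
#' @return tibble with `label`, `count`, `fraction`, `se`; the major
#'   labels 1/2/3/4 partition the classified samples (fractions sum to 1)
#'   and rows 3A/3B/3C break down Behavior 3.
#' @export
behavior_probabilities <- function(x, n = 1000, seed = 1) {
  if (inherits(x, "uncertainty_spec")) x <- propagate(x, n, seed)
  lab <- x$qois$behavior
  lab <- lab[!is.na(lab)]
  m <- length(lab)
  major <- substr(lab, 1, 1)
  labels <- c("1", "2", "3", "4", "3A", "3B", "3C")
  counts <- c(vapply(c("1", "2", "3", "4"),
                     function(l) sum(major == l), integer(1)),
              vapply(c("3A", "3B", "3C"),
                     function(l) sum(lab == l), integer(1)))
  frac <- counts / m
  tibble::tibble(label = labels, count = counts, fraction = frac,
                 se = sqrt(frac * (1 - frac) / m))
}

#' Fixed-bin QOI histogram
#'
#' Histogram over `center * (1 +/- 0.4)` with a fixed number of bins, so
#' the spread of different QOIs can be compared on a common relative axis.
#'
#' @param x `ap_propagation`.
#' @param qoi QOI column name.
#' @param bins bin count (default 50).
#' @param center axis center; default the QOI mean.
#' @return tibble with `bin_mid`, `count`.
#' @export
qoi_histogram <- function(x, qoi, bins = 50, center = NULL) {
  v <- x$qois[[qoi]]
  v <- v[is.finite(v)]
  if (is.null(center)) center <- mean(v)
  breaks <- seq(center - 0.4 * abs(center), center + 0.4 * abs(center),
                length.out = bins + 1)
  v <- v[v >= breaks[1] & v <= breaks[bins + 1]]
  h <- hist(v, breaks = breaks, plot = FALSE)
  tibble::tibble(bin_mid = h$mids, count = h$counts)
}
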