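# Variance-based global sensitivity analysis: Saltelli design with
# first-order (Saltelli 2010) and total (Jansen) Sobol estimators plus
# bootstrap errors, and Morris elementary-effects screening.

#' Saltelli sampling design for Sobol indices
#'
#' Builds the radial A/B/AB_i design supporting joint estimation of
#' first-order and total indices for every parameter in `parameters`:
#' two independent base matrices A and B of `base_n` rows each, plus one
#' matrix AB_i per parameter (A with column i replaced from B). Total
#' model evaluations: `base_n * (k + 2)`. Uniform variates are mapped
#' through each parameter's marginal quantile function, so all rows
#' satisfy the positivity invariants.
#'
#' @param spec an [uncertainty_spec()].
#' @param base_n base sample size (a power of 2 recommended).
#' @param seed RNG seed.
#' @param parameters parameters to analyze; default all non-fixed ones.
#' @return tibble of class `"saltelli_design"` with the 36 parameter
#'   columns plus `.matrix` (`"A"`, `"B"` or `"AB_<param>"`) and `.base`
#'   (base-sample index); analyzed parameter names in the
#'   `"parameters"` attribute.
#' @export
saltelli_design <- function(spec, base_n = 256, seed = 1,
                            parameters = NULL) {
  if (is.null(parameters))
    parameters <- spec$parameter[spec$family != "fixed"]
  if (!length(parameters)) abort("empty parameter subset")
  bad <- setdiff(parameters, spec$parameter)
  if (length(bad))
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  k <- length(parameters)
  set.seed(seed)
  U_A <- matrix(runif(base_n * k), base_n, k, dimnames = list(NULL, parameters))
  U_B <- matrix(runif(base_n * k), base_n, k, dimnames = list(NULL, parameters))
  to_rows <- function(U, tag) {
    full <- matrix(rep(attr(spec, "nominal")[.param_order], each = base_n),
                   base_n, 36, dimnames = list(NULL, .param_order))
    for (p in parameters) full[, p] <- param_quantile(spec, p, U[, p])
    out <- tibble::as_tibble(as.data.frame(full))
    out$.matrix <- tag
    out$.base <- seq_len(base_n)
    out
  }
  blocks <- list(to_rows(U_A, "A"), to_rows(U_B, "B"))
  for (p in parameters) {
    U <- U_A
    U[, p] <- U_B[, p]
    blocks[[length(blocks) + 1]] <- to_rows(U, paste0("AB_", p))
  }
  out <- dplyr::bind_rows(blocks)
  structure(out, parameters = parameters, base_n = base_n, seed = seed,
            sigma_hat = attr(spec, "sigma_hat"),
            class = c("saltelli_design", class(out)))
}

#' Sobol first-order and total indices from an evaluated design
#'
#' First-order indices use the Saltelli (2010) estimator
#' `S1_i = mean(f(B) * (f(AB_i) - f(A))) / V`; total indices use Jansen's
#' estimator `ST_i = mean((f(A) - f(AB_i))^2) / (2 V)`. Errors are
#' half-widths of central bootstrap intervals over base-sample indices.
#'
#' @param design a [saltelli_design()].
#' @param y numeric QOI values, one per design row (same order).
#' @param n_boot bootstrap resamples (default 100).
#' @param conf bootstrap interval coverage (default 0.95).
#' @param seed bootstrap RNG seed.
#' @return tibble of class `"sobol_result"`: `parameter`, `S1`, `S1_err`,
#'   `ST`, `ST_err`, with the output variance and design metadata as
#'   attributes.
#' @export
sobol_indices <- function(design, y, n_boot = 100, conf = 0.95, seed = 1) {
  params <- attr(design, "parameters")
  n <- attr(design, "base_n")
  if (length(y) != nrow(design))
    abort("y must have one value per design row")
  n_undef <- sum(!is.finite(y))
  if (n_undef > 0.01 * length(y))
    abort(paste0(n_undef, " undefined QOI values (> 1% of the design); ",
                 "variance decomposition over a censored sample is ",
                 "meaningless -- use a lower sigma_hat or a more robust QOI"))
  if (n_undef > 0) {
    warn(paste0(n_undef, " undefined QOI value(s) imputed with the mean"))
    y[!is.finite(y)] <- mean(y[is.finite(y)])
  }
  fA <- y[design$.matrix == "A"][order(design$.base[design$.matrix == "A"])]
  fB <- y[design$.matrix == "B"][order(design$.base[design$.matrix == "B"])]
  fAB <- sapply(params, function(p) {
    sel <- design$.matrix == paste0("AB_", p)
    y[sel][order(design$.base[sel])]
  })
  est <- function(idx) {
    # center the outputs: the S1 estimator is exact in expectation either
    # way, but centering removes the mean-level noise amplification
    ctr <- mean(c(fA[idx], fB[idx]))
    gA <- fA[idx] - ctr
    gB <- fB[idx] - ctr
    gAB <- fAB[idx, , drop = FALSE] - ctr
    V <- var(c(gA, gB))
    if (V == 0) return(cbind(S1 = rep(0, length(params)),
                             ST = rep(0, length(params))))
    S1 <- colMeans(gB * (gAB - gA)) / V
    ST <- colMeans((gA - gAB)^2) / (2 * V)
    cbind(S1 = S1, ST = ST)
  }
  point <- est(seq_len(n))
  V <- var(c(fA, fB))
  if (V == 0) warn("QOI has zero variance; all indices are 0")
  set.seed(seed)
  boots <- array(NA_real_, c(length(params), 2, n_boot))
  for (b in seq_len(n_boot))
    boots[, , b] <- est(sample.int(n, n, replace = TRUE))
  a <- (1 - conf) / 2
  hw <- function(j) apply(boots[, j, , drop = FALSE], 1, function(v)
    diff(quantile(v, c(a, 1 - a), na.rm = TRUE)) / 2)
  out <- tibble::tibble(
    parameter = params,
    S1 = unname(point[, "S1"]), S1_err = unname(hw(1)),
    ST = unname(point[, "ST"]), ST_err = unname(hw(2))
  )
  structure(out, base_n = n, variance = V, n_undefined = n_undef,
            class = c("sobol_result", class(out)))
}

#' Morris elementary-effects screening
#'
#' Randomized one-at-a-time trajectories on a `levels`-level grid in the
#' unit cube, mapped through the marginal quantile functions (the extreme
#' 1% tails are truncated so lattice points stay finite). Reports the mean
#' absolute elementary effect `mu_star` and the standard deviation of the
#' effects per parameter; parameters with
#' `mu_star < cutoff * max(mu_star)` are screened out as non-influential.
#' Trajectories along which the QOI is undefined are discarded (counted in
#' the `n_discarded` attribute).
#'
#' @param spec an [uncertainty_spec()].
#' @param f evaluator: function taking a tibble of parameter rows and
#'   returning one numeric QOI value per row (see [qoi_evaluator()]).
#' @param trajectories number of trajectories (default 50).
#' @param levels grid levels p (default 4); step is `p / (2 (p - 1))`.
#' @param seed RNG seed.
#' @param parameters parameters to screen; default all non-fixed.
#' @param cutoff relative mu_star cutoff for the screening verdict.
#' @return tibble of class `"morris_result"`: `parameter`, `mu_star`,
#'   `sigma`, `verdict` (`"influential"` / `"excluded"`).
#' @export
morris_screen <- function(spec, f, trajectories = 50, levels = 4,
                          seed = 1, parameters = NULL, cutoff = 0.01) {
  if (is.null(parameters))
    parameters <- spec$parameter[spec$family != "fixed"]
  k <- length(parameters)
  if (!k) abort("empty parameter subset")
  delta <- levels / (2 * (levels - 1))
  grid <- seq(0, 1 - delta, length.out = levels / 2)
  set.seed(seed)
  nominal <- attr(spec, "nominal")[.param_order]
  ee <- matrix(NA_real_, trajectories, k, dimnames = list(NULL, parameters))
  n_discarded <- 0
  for (tr in seq_len(trajectories)) {
    base <- sample(grid, k, replace = TRUE)
    dir <- ifelse(base + delta <= 1, delta, -delta)
    ord <- sample.int(k)
    pts <- matrix(base, k + 1, k, byrow = TRUE,
                  dimnames = list(NULL, parameters))
    for (j in seq_len(k))
      pts[(j + 1):(k + 1), ord[j]] <- base[ord[j]] + dir[ord[j]]
    # map unit-cube points through quantiles (1% tail truncation)
    full <- matrix(rep(nominal, each = k + 1), k + 1, 36,
                   dimnames = list(NULL, .param_order))
    for (p in parameters)
      full[, p] <- param_quantile(spec, p, 0.01 + 0.98 * pts[, p])
    yv <- f(tibble::as_tibble(as.data.frame(full)))
    if (any(!is.finite(yv))) {
      n_discarded <- n_discarded + 1
      next
    }
    for (j in seq_len(k))
      ee[tr, ord[j]] <- (yv[j + 1] - yv[j]) / dir[ord[j]]
  }
  keep <- stats::complete.cases(ee)
  if (!any(keep)) abort("all Morris trajectories discarded")
  mu_star <- colMeans(abs(ee[keep, , drop = FALSE]))
  sig <- apply(ee[keep, , drop = FALSE], 2, sd)
  out <- tibble::tibble(
    parameter = parameters,
    mu_star = unname(mu_star),
    sigma = unname(sig),
    verdict = ifelse(mu_star < cutoff * max(mu_star), "excluded",
                     "influential")
  ) %>% dplyr::arrange(desc(.data$mu_star))
  structure(out, trajectories = sum(keep), levels = levels,
            n_discarded = n_discarded,
            class = c("morris_result", class(out)))
}

#' QOI evaluator for sensitivity analyses
#'
#' Returns a function mapping a tibble of parameter rows to a numeric
#' vector of one QOI value per row, simulating each row at 1.1x its
#' threshold. Upstroke QOIs only need a short horizon; APD and behavior
#' need the full 1000 ms.
#'
#' @param qoi one of `"threshold"`, `"max_upstroke_velocity"`,
#'   `"time_of_max_upstroke_velocity"`, `"apa"`, `"apd"`.
#' @param duration simulation horizon, ms; default 80 for upstroke QOIs
#'   and 1000 otherwise.
#' @param dt_out output grid, ms.
#' @return function usable as the `f` argument of [morris_screen()] or
#'   applied to [saltelli_design()] rows for [sobol_indices()].
#' @export
qoi_evaluator <- function(qoi = "apd", duration = NULL, dt_out = 0.05) {
  upstroke <- qoi %in% c("threshold", "max_upstroke_velocity",
                         "time_of_max_upstroke_velocity", "apa")
  if (is.null(duration)) duration <- if (upstroke) 80 else 1000
  function(rows) {
    mat <- as.matrix(rows[, .param_order])
    vapply(seq_len(nrow(mat)), function(i) {
      p <- as_param_vector(mat[i, ])
      y0 <- initial_conditions(p)
      thr <- tryCatch(
        cpp_find_threshold(p, as.numeric(y0), 0, 200, 0.005, 0.5, 50.5,
                           0, 1e-6, 1e-8, 1),
        error = function(e) NA_real_)
      if (is.na(thr)) return(NA_real_)
      if (qoi == "threshold") return(thr)
      tr <- tryCatch(
        simulate_ap(p, amplitude = 1.1 * thr, duration = duration,
                    dt_out = dt_out),
        error = function(e) NULL)
      if (is.null(tr)) return(NA_real_)
      q <- extract_qois(tr)
      q[[qoi]]
    }, numeric(1))
  }
}

#' @export
glance.sobol_result <- function(x, ...) {
  tibble::tibble(base_n = attr(x, "base_n"),
                 n_parameters = nrow(x),
                 total_evaluations = attr(x, "base_n") * (nrow(x) + 2),
                 variance = attr(x, "variance"),
                 n_undefined = attr(x, "n_undefined"))
}

#' @export
tidy.sobol_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
tidy.morris_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.morris_result <- function(x, ...) {
  tibble::tibble(trajectories = attr(x, "trajectories"),
                 levels = attr(x, "levels"),
                 n_discarded = attr(x, "n_discarded"),
                 n_excluded = sum(x$verdict == "excluded"))
}
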