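# Monte Carlo filtering (regionalized sensitivity analysis): compare the
# conditional parameter distributions of samples that did / did not show a
# behavior with the two-sample Kolmogorov-Smirnov statistic.

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sample p-value.
#'
#' @param a,b non-empty numeric vectors.
#' @return one-row tibble with `d_stat` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble::tibble(d_stat = unname(kt$statistic),
                 p_value = unname(kt$p.value))
}

behavior_matches <- function(labels, behavior) {
  behavior <- as.character(behavior)
  if (behavior %in% c("1", "2", "3", "4")) {
    substr(as.character(labels), 1, 1) == behavior
  } else if (behavior %in% c("3A", "3B", "3C")) {
    as.character(labels) == behavior
  } else {
    abort(paste0("unknown behavior: ", behavior))
  }
}

#' Monte Carlo filtering of a sampled ensemble
#'
#' Splits the sampled parameter sets into those whose AP showed
#' `behavior` and those whose did not ("behavior k vs all others"), and
#' for each parameter compares the two conditional CDFs with the
#' two-sample KS test. Parameters with `D_stat > 0.2` are categorized as
#' highly influential; those with `p < alpha` but `D_stat <= 0.2` as
#' influential; the rest as not influential.
#'
#' For the oscillatory sub-behaviors the split can alternatively be
#' restricted to Behavior-3 samples only (`within = "behavior3"`).
#'
#' @param samples tibble of sampled parameters (e.g.
#'   [sample_parameters()] output or the `qois` table of a propagation);
#'   only non-constant parameter columns are analyzed.
#' @param labels behavior labels, one per row (as from
#'   [classify_behavior()]; `NA` rows are dropped).
#' @param behavior target behavior: `"1"`, `"2"`, `"3"`, `"4"`, `"3A"`,
#'   `"3B"` or `"3C"`.
#' @param alpha significance level for the influential category.
#' @param d_highly `D_stat` cutoff for the highly influential category.
#' @param within `"all"` (default) conditions within the full sample;
#'   `"behavior3"` restricts to Behavior-3 rows (sub-behaviors only).
#' @param min_split minimum rows per split set.
#' @return tibble of class `"mcf_result"`: `parameter`, `d_stat`,
#'   `p_value`, `category`, sorted by decreasing `d_stat`; split sizes in
#'   attributes `n_in` / `n_out`.
#' @export
mc_filter <- function(samples, labels, behavior, alpha = 0.01,
                      d_highly = 0.2, within = c("all", "behavior3"),
                      min_split = 10) {
  within <- match.arg(within)
  params <- intersect(param_names(), names(samples))
  keep <- !is.na(labels)
  if (within == "behavior3") {
    if (!behavior %in% c("3A", "3B", "3C"))
      abort("within = \"behavior3\" applies to sub-behaviors only")
    keep <- keep & behavior_matches(labels, "3")
  }
  df <- samples[keep, params, drop = FALSE]
  lab <- labels[keep]
  varying <- params[vapply(df, function(v) length(unique(v)) > 1,
                           logical(1))]
  inset <- behavior_matches(lab, behavior)
  if (sum(inset) < min_split || sum(!inset) < min_split)
    abort(paste0("split sets too small (", sum(inset), " / ", sum(!inset),
                 "); increase M or sigma_hat"))
  out <- purrr::map_dfr(varying, function(p) {
    ks <- ks_two_sample(df[[p]][inset], df[[p]][!inset])
    dplyr::mutate(ks, parameter = p, .before = 1)
  })
  out <- out %>%
    dplyr::mutate(category = dplyr::case_when(
      .data$d_stat > d_highly ~ "highly-influential",
      .data$p_value < alpha ~ "influential",
      TRUE ~ "not-influential")) %>%
    dplyr::arrange(desc(.data$d_stat))
  structure(out, behavior = as.character(behavior),
            n_in = sum(inset), n_out = sum(!inset), within = within,
            class = c("mcf_result", class(out)))
}

#' Behavior-conditioned pairwise parameter correlations
#'
#' Pearson correlations between parameters over the subset of samples
#' whose AP showed `behavior` (default the normal class), with `delta_h`
#' entering on the log scale.
#'
#' @param samples tibble of sampled parameters.
#' @param labels behavior labels, one per row.
#' @param parameters parameters to correlate (default the five
#'   highly influential ones: Eh, delta_h, Er, Ed, Ef).
#' @param behavior conditioning behavior (default `"4"`, normal APs).
#' @param log_params parameters entered as logs (default `"delta_h"`).
#' @param min_rows minimum conditioned subset size.
#' @return tibble with `param1`, `param2`, `correlation`, `n`; log-scale
#'   parameters are labelled `log(<name>)`.
#' @export
conditional_correlations <- function(samples, labels,
                                     parameters = c("Eh", "delta_h", "Er",
                                                    "Ed", "Ef"),
                                     behavior = "4",
                                     log_params = "delta_h",
                                     min_rows = 100) {
  keep <- !is.na(labels) & behavior_matches(labels, behavior)
  if (sum(keep) < min_rows)
    abort(paste0("conditioned subset too small (", sum(keep), " rows)"))
  df <- samples[keep, parameters, drop = FALSE]
  nm <- parameters
  for (p in intersect(log_params, parameters)) {
    df[[p]] <- log(df[[p]])
    nm[nm == p] <- paste0("log(", p, ")")
  }
  names(df) <- nm
  cm <- cor(as.matrix(df))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  tibble::tibble(
    param1 = nm[pairs[, 1]],
    param2 = nm[pairs[, 2]],
    correlation = cm[pairs],
    n = sum(keep)
  )
}

#' @export
tidy.mcf_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mcf_result <- function(x, ...) {
  tibble::tibble(behavior = attr(x, "behavior"),
                 n_in = attr(x, "n_in"), n_out = attr(x, "n_out"),
                 within = attr(x, "within"),
                 n_highly = sum(x$category == "highly-influential"),
                 n_influential = sum(x$category == "influential"))
}

#' Conditional CDF pairs for plotting
#'
#' Empirical CDFs of each parameter conditioned on whether the behavior
#' occurred, for CDF-overlay plots of the filtering result.
#'
#' @inheritParams mc_filter
#' @param parameters parameters to export.
#' @return long tibble: `parameter`, `occurred`, `value`, `cdf`.
#' @export
filter_cdf_pairs <- function(samples, labels, behavior,
                             parameters = c("Eh", "delta_h", "Er", "Ed",
                                            "Ef")) {
  keep <- !is.na(labels)
  df <- samples[keep, parameters, drop = FALSE]
  inset <- behavior_matches(labels[keep], behavior)
  purrr::map_dfr(parameters, function(p) {
    purrr::map_dfr(c(TRUE, FALSE), function(g) {
      v <- sort(df[[p]][inset == g])
      tibble::tibble(parameter = p, occurred = g, value = v,
                     cdf = seq_along(v) / length(v))
    })
  })
}
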