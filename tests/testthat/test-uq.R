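test_that("distribution construction matches the analytic forms", {
  spec <- uncertainty_spec(0.05)
  # lognormal parameters have analytic mean exactly at nominal
  ln <- spec[spec$family == "lognormal", ]
  expect_equal(exp(ln$meanlog + ln$sdlog^2 / 2), ln$nominal)
  # voltage parameters are normal with sd = sigma_hat * R
  nm <- spec[spec$family == "normal", ]
  expect_true(all(nm$sd == 0.05 * 100))
  expect_identical(sort(nm$parameter),
                   sort(c("Em", "Eh", "Ez", "Er", "Es", "Ed", "Ef",
                          "Exr", "Ey", "Exs")))
  # Nernst potentials are never sampled
  expect_identical(spec$family[spec$parameter %in% c("ENa", "EK", "ECa")],
                   rep("fixed", 3))
  expect_error(uncertainty_spec(-0.01), "sigma_hat")
})

test_that("the gNa 95% interval at sigma_hat = 5% is [10.9, 13.2]", {
  spec <- uncertainty_spec(0.05)
  ci <- param_interval(spec, "gNa")
  expect_equal(signif(ci[1], 3), 10.9)
  expect_equal(signif(ci[2], 3), 13.2)
})

test_that("sigma_hat = 0 degenerates every distribution to the nominal", {
  spec <- uncertainty_spec(0)
  for (p in c("gNa", "Em", "delta_h", "tau_xr"))
    expect_equal(param_quantile(spec, p, c(0.01, 0.5, 0.99)),
                 rep(spec$nominal[spec$parameter == p], 3))
  s <- sample_parameters(spec, 5, seed = 1)
  expect_equal(unname(vapply(s, function(x) length(unique(x)),
                             integer(1))),
               rep(1L, 36))
})

test_that("sampling matches the analytic moments and is reproducible", {
  spec <- uncertainty_spec(0.05)
  s <- sample_parameters(spec, 1e5, seed = 2)
  expect_equal(mean(s$gNa), 12, tolerance = 0.005)   # law of large numbers
  expect_equal(sd(s$gNa) / 12, 0.05, tolerance = 0.05)
  spec1 <- uncertainty_spec(0.01)
  s1 <- sample_parameters(spec1, 1e5, seed = 2)
  expect_equal(sd(s1$Em), 1, tolerance = 0.02)       # sigma_hat * R = 1 mV
  expect_true(all(s$ENa == 65) && all(s$EK == -85))
  expect_true(all(as.matrix(s[, apuq:::.positive_params]) > 0))
  expect_identical(s, sample_parameters(spec, 1e5, seed = 2))
  expect_false(identical(s$gNa, sample_parameters(spec, 1e5, seed = 3)$gNa))
})

test_that("lognormal relative variance approaches sigma_hat^2", {
  for (sig in c(0.01, 0.05)) {
    s <- sample_parameters(uncertainty_spec(sig), 2e5, seed = 4)
    expect_equal(var(s$gCaL) / 0.11503^2, sig^2, tolerance = 0.05)
  }
})

test_that("fix_at_nominal holds the requested parameters constant", {
  spec <- uncertainty_spec(0.05,
                           fix_at_nominal = c("Eh", "delta_h", "Er",
                                              "Ed", "Ef"))
  s <- sample_parameters(spec, 50, seed = 5)
  expect_true(all(s$Eh == -78.7) && all(s$delta_h == 0.799163))
  expect_true(all(s$Ed == 0.7))
  expect_gt(length(unique(s$gNa)), 1)
  expect_error(uncertainty_spec(0.05, fix_at_nominal = "nope"), "unknown")
})

test_that("propagation summaries behave at the degenerate point", {
  pr <- propagate(uncertainty_spec(0), n = 4, seed = 1)
  td <- tidy(pr)
  expect_true(all(td$cov_pct[td$n_defined > 0] == 0))
  expect_true(all(pr$qois$status == "ok"))
  expect_true(all(pr$qois$behavior == "4"))
})

test_that("propagation records failures without aborting the batch", {
  spec <- uncertainty_spec(0.05)
  samples <- sample_parameters(spec, 4, seed = 6)
  samples$gNa[2] <- 1e-4   # unexcitable cell: threshold bracket fails
  samples$gK1[2] <- 500    # huge resting leak clamps V below 0
  pr <- propagate(samples)
  expect_identical(pr$qois$status[2], "threshold_failure")
  expect_identical(sum(pr$qois$status == "ok"), 3L)
})

test_that("the N-vs-N/2 convergence rule detects stability", {
  expect_true(apuq:::mc_converged(rep(c(1, 1.0000001), 500)))
  set.seed(7)
  expect_false(apuq:::mc_converged(rnorm(20)))
})

test_that("behavior probabilities sum to one over the major classes", {
  pr <- propagate(uncertainty_spec(0.05), n = 60, seed = 8)
  bp <- behavior_probabilities(pr)
  expect_equal(sum(bp$fraction[bp$label %in% c("1", "2", "3", "4")]), 1)
  expect_equal(sum(bp$fraction[bp$label %in% c("3A", "3B", "3C")]),
               unname(bp$fraction[bp$label == "3"]))
  expect_true(all(bp$se >= 0))
})
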