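test_that("the KS statistic matches brute-force ECDF enumeration", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$d_stat, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$d_stat, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1, 2, 3))$d_stat, 1 / 3)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$d_stat, 0.5)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$d_stat, oracle_ks_d(a, b))
  }
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})

test_that("mc_filter categorizes parameters by D and p", {
  set.seed(12)
  n <- 400
  samples <- tibble::tibble(
    Eh = rnorm(n, -78.7, 5),
    Ed = rnorm(n, 0.7, 5),
    gNa = rlnorm(n, log(12), 0.05)
  )
  # behavior driven entirely by Eh
  labels <- ifelse(samples$Eh > -78.7, "1", "4")
  flt <- mc_filter(samples, labels, behavior = "1")
  expect_identical(flt$category[flt$parameter == "Eh"],
                   "highly-influential")
  expect_gt(flt$d_stat[flt$parameter == "Eh"], 0.5)
  expect_identical(flt$category[flt$parameter == "gNa"],
                   "not-influential")
  # categories are a pure function of (D, p)
  expect_true(all(
    (flt$d_stat > 0.2) == (flt$category == "highly-influential")))
  expect_true(all(
    (flt$d_stat <= 0.2 & flt$p_value < 0.01) ==
      (flt$category == "influential")))
})

test_that("permuted labels drive D toward zero", {
  set.seed(13)
  n <- 2000
  samples <- tibble::tibble(Eh = rnorm(n), Ed = rnorm(n))
  labels <- sample(rep(c("1", "4"), each = n / 2))
  flt <- mc_filter(samples, labels, behavior = "1")
  expect_true(all(flt$d_stat < 0.1))
  expect_true(all(flt$p_value > 0.001))
})

test_that("disjoint conditional supports give D = 1", {
  samples <- tibble::tibble(Eh = c(1:20, 101:120), Ed = rnorm(40))
  labels <- c(rep("2", 20), rep("4", 20))
  flt <- mc_filter(samples, labels, behavior = "2")
  expect_equal(flt$d_stat[flt$parameter == "Eh"], 1)
})

test_that("undersized splits are an error", {
  samples <- tibble::tibble(Eh = rnorm(30))
  labels <- c(rep("1", 3), rep("4", 27))
  expect_error(mc_filter(samples, labels, behavior = "1"), "too small")
})

test_that("sub-behavior filtering can condition within Behavior 3", {
  set.seed(14)
  n <- 300
  samples <- tibble::tibble(Em = rnorm(n), Ez = rnorm(n))
  labels <- sample(c("3A", "3B", "4"), n, replace = TRUE)
  all_mode <- mc_filter(samples, labels, behavior = "3A")
  sub_mode <- mc_filter(samples, labels, behavior = "3A",
                        within = "behavior3")
  expect_identical(attr(all_mode, "n_in") , sum(labels == "3A"))
  expect_identical(attr(all_mode, "n_out"), sum(labels != "3A"))
  expect_identical(attr(sub_mode, "n_out"), sum(labels == "3B"))
  expect_error(mc_filter(samples, labels, behavior = "1",
                         within = "behavior3"), "sub-behaviors")
})

test_that("unconditioned independent draws are uncorrelated", {
  spec <- uncertainty_spec(0.05)
  s <- sample_parameters(spec, 5000, seed = 15)
  cc <- conditional_correlations(s, rep("4", nrow(s)))
  expect_true(all(abs(cc$correlation) < 0.05))
  expect_true("log(delta_h)" %in% c(cc$param1, cc$param2))
  expect_error(conditional_correlations(s[1:50, ], rep("4", 50)),
               "too small")
})
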