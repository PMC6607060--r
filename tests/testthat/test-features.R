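test_that("APD is definitional on a synthetic trapezoid", {
  tr <- synthetic_trace(
    knots_t = c(0, 0.9, 1, 2, 200, 201, 202, 1000),
    knots_v = c(-85, -85, -70, 20, 20, -70, -85, -85))
  q <- extract_qois(tr)
  expect_equal(q$apd, 200)
  expect_true(q$apd_defined)
  expect_equal(q$apa, 105)   # plateau peak minus resting potential
})

test_that("a trace that never repolarizes has its APD flagged undefined", {
  tr <- synthetic_trace(
    knots_t = c(0, 1, 2, 1000),
    knots_v = c(-85, -70, 10, 5))
  q <- extract_qois(tr)
  expect_false(q$apd_defined)
  expect_true(is.na(q$apd))
  expect_true(q$upstroke_defined)
})

test_that("a subthreshold response leaves the upstroke undefined, not zero", {
  tr <- synthetic_trace(
    knots_t = c(0, 1, 3, 10, 1000),
    knots_v = c(-85, -80, -78, -85, -85))
  q <- extract_qois(tr)
  expect_false(q$upstroke_defined)
  expect_true(is.na(q$apa))
  expect_true(is.na(q$max_upstroke_velocity))
})

test_that("the nominal AP has a notch with notch_min < notch_max", {
  q <- extract_qois(simulate_ap(duration = 1000))
  expect_true(q$notch_defined)
  expect_lt(q$notch_min, q$notch_max)
  expect_true(q$upstroke_defined && q$apd_defined)
  expect_gt(q$apa, 0)
  expect_gt(q$apd, 0)
})

test_that("APD at -70 mV and APD95 agree within 15% at nominal parameters", {
  tr <- simulate_ap(duration = 1000)
  apd70 <- extract_qois(tr)$apd
  apd95 <- apuq:::apd_at_fraction(tr$time, tr$V, onset = 0,
                                  fraction = 0.95)
  expect_lt(abs(apd70 - apd95) / apd95, 0.15)
})

test_that("behavior classification follows the extremum taxonomy", {
  # single early maximum, monotone decay: spike without dome
  b2 <- synthetic_trace(c(0, 1, 5, 300, 1000), c(-85, -70, 25, -85, -85))
  expect_identical(classify_behavior(b2)$label, "2")
  # single late maximum: dome without spike
  b1 <- synthetic_trace(c(0, 1, 80, 300, 1000), c(-85, -70, 30, -85, -85))
  expect_identical(classify_behavior(b1)$label, "1")
  # two interior minima: oscillatory
  b3 <- synthetic_trace(
    c(0, 1, 5, 50, 120, 200, 280, 400, 1000),
    c(-85, -70, 25, -20, 10, -30, 5, -85, -85))
  expect_identical(substr(classify_behavior(b3)$label, 1, 1), "3")
  # two maxima + one minimum with a LATE first maximum is oscillatory too
  b3b <- synthetic_trace(
    c(0, 1, 40, 150, 400, 600, 1000),
    c(-85, -70, 25, 0, 20, -85, -85))
  expect_identical(substr(classify_behavior(b3b)$label, 1, 1), "3")
  # the same shape with an EARLY first maximum is the normal morphology
  b4 <- synthetic_trace(
    c(0, 1, 3, 10, 85, 330, 340, 1000),
    c(-85, -70, 29, 11, 34, -70, -85, -85))
  expect_identical(classify_behavior(b4)$label, "4")
  expect_identical(classify_behavior(b4)$sub, "none")
  # nominal parameters give the normal morphology
  expect_identical(classify_behavior(simulate_ap(duration = 1000))$label,
                   "4")
  short <- synthetic_trace(c(0, 500), c(-85, -85), t_end = 500)
  expect_error(classify_behavior(short), "horizon")
})

test_that("oscillatory sub-types partition by the end-of-horizon voltage", {
  osc <- function(v_end) synthetic_trace(
    c(0, 1, 5, 50, 120, 200, 280, 999, 1000),
    c(-85, -70, 25, -20, 10, -30, 5, v_end, v_end))
  expect_identical(classify_behavior(osc(-85))$sub, "3A")
  expect_identical(classify_behavior(osc(-10))$sub, "3B")
  expect_identical(classify_behavior(osc(-50))$sub, "3C")
})

test_that("classification is total over a perturbed ensemble", {
  spec <- uncertainty_spec(0.05)
  pr <- propagate(spec, n = 30, seed = 99)
  lab <- pr$qois$behavior[pr$qois$status == "ok"]
  expect_true(all(lab %in% c("1", "2", "3A", "3B", "3C", "4")))
})

test_that("the prominence filter suppresses sub-0.1 mV noise", {
  tr <- simulate_ap(duration = 1000)
  set.seed(1)
  noisy <- tr
  noisy$V <- tr$V + rnorm(nrow(tr), 0, 0.03)
  expect_identical(classify_behavior(noisy)$label,
                   classify_behavior(tr)$label)
  expect_equal(extract_qois(noisy)$apd, extract_qois(tr)$apd,
               tolerance = 0.01)
})
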