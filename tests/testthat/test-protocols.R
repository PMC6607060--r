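test_that("the resting state is (approximately) stationary", {
  tr <- simulate_ap(amplitude = 0, duration = 1000)
  expect_lt(max(abs(tr$V - (-85))), 1)
})

test_that("threshold bisection brackets the depolarization boundary", {
  thr <- find_threshold()
  above <- simulate_ap(amplitude = 1.1 * thr, duration = 60)
  expect_gt(max(above$V), 0)
  below <- simulate_ap(amplitude = 0.9 * thr, duration = 60)
  expect_lt(max(below$V), 0)
  expect_error(find_threshold(search_hi = 1e-3), "bracket failure")
})

test_that("threshold is monotone non-increasing in gNa", {
  thr <- vapply(c(0.5, 1, 2) * 12,
                function(g) find_threshold(nominal_parameters(gNa = g)),
                numeric(1))
  expect_true(all(diff(thr) <= 0))
})

test_that("simulation is deterministic and grid-independent", {
  a <- simulate_ap(amplitude = 50, duration = 400)
  b <- simulate_ap(amplitude = 50, duration = 400)
  expect_identical(a$V, b$V)
  coarse <- simulate_ap(amplitude = 50, duration = 400, dt_out = 0.1)
  expect_lt(abs(extract_qois(a)$apd - extract_qois(coarse)$apd), 0.2)
})

test_that("tightening solver tolerances leaves the QOIs unchanged", {
  base <- extract_qois(simulate_ap(amplitude = 50, duration = 500))
  tight <- extract_qois(simulate_ap(amplitude = 50, duration = 500,
                                    rtol = 1e-7, atol = 1e-9))
  expect_lt(abs(base$apd - tight$apd), 0.1)
  for (q in c("max_upstroke_velocity", "apa", "notch_min", "notch_max"))
    expect_lt(abs(base[[q]] - tight[[q]]) / abs(tight[[q]]), 0.005)
})

test_that("a single paced beat reproduces simulate_ap exactly", {
  one <- pace(n_beats = 1, bcl = 1000, amplitude = 47)[[1]]
  direct <- simulate_ap(amplitude = 47, duration = 1000)
  expect_identical(one$V, direct$V)
})

test_that("1 Hz pacing approaches a limit cycle and differs from beat 1", {
  beats <- pace(n_beats = 11, bcl = 1000, amplitude = 47)
  apd10 <- extract_qois(beats[[10]])$apd
  apd11 <- extract_qois(beats[[11]])$apd
  expect_lt(abs(apd11 - apd10) / apd10, 0.01)
  apd1 <- extract_qois(beats[[1]])$apd
  expect_gt(abs(apd1 - apd11), 1)  # paced AP differs from first beat
  # keep = "last" matches the stored-beats path
  last <- pace(n_beats = 11, bcl = 1000, amplitude = 47, keep = "last")
  expect_equal(last$V, beats[[11]]$V, tolerance = 1e-10)
})

test_that("dynamic restitution is monotone with DI + APD95 = BCL", {
  res <- dynamic_restitution(bcl_list = c(1000, 800, 600, 400),
                             beats_per_bcl = 20)
  expect_true(all(res$captured))
  expect_true(all(diff(res$apd95) < 0))  # APD shortens as BCL decreases
  expect_equal(res$di + res$apd95, res$bcl)
  expect_error(dynamic_restitution(bcl_list = c(400, 1000)), "decreasing")
})

test_that("stimulus protocol invariants are enforced", {
  expect_error(stimulus_protocol(duration = 0, amplitude = 1), "duration")
  expect_error(stimulus_protocol(amplitude = -1), "amplitude")
  expect_error(stimulus_protocol(amplitude = 1, period = 0.1), "period")
  expect_error(pace(bcl = 50), "bcl")
})
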