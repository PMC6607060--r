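test_that("the Saltelli design has the right arithmetic and support", {
  spec <- uncertainty_spec(0.05)
  des <- saltelli_design(spec, base_n = 64, seed = 1,
                         parameters = c("gNa", "Em", "kh"))
  expect_identical(nrow(des), 64L * (3L + 2L))
  expect_identical(sort(unique(des$.matrix)),
                   sort(c("A", "B", "AB_gNa", "AB_Em", "AB_kh")))
  expect_true(all(des$gNa > 0) && all(des$kh > 0))
  # non-analyzed parameters sit at nominal
  expect_true(all(des$gKr == 0.056))
  expect_identical(des, saltelli_design(spec, base_n = 64, seed = 1,
                                        parameters = c("gNa", "Em", "kh")))
  expect_error(saltelli_design(spec, parameters = character()), "empty")
})

test_that("Sobol estimates match the analytic linear decomposition", {
  # q = 1*Em + 2*Eh; both inputs share the same variance, so
  # S1 = (0.2, 0.8) and ST = S1 (no interactions)
  spec <- uncertainty_spec(0.01)
  des <- saltelli_design(spec, base_n = 1024, seed = 2,
                         parameters = c("Em", "Eh"))
  s <- sobol_indices(des, des$Em + 2 * des$Eh)
  expect_equal(s$S1[s$parameter == "Em"], 0.2, tolerance = 0.08)
  expect_equal(s$S1[s$parameter == "Eh"], 0.8, tolerance = 0.08)
  expect_equal(s$ST, s$S1, tolerance = 0.1)
  expect_true(all(s$S1_err > 0) && all(s$ST_err > 0))
})

test_that("Sobol estimates converge at the Monte Carlo rate", {
  spec <- uncertainty_spec(0.01)
  err <- vapply(c(256, 1024), function(n) {
    des <- saltelli_design(spec, base_n = n, seed = 3,
                           parameters = c("Em", "Eh", "Ez"))
    s <- sobol_indices(des, des$Em + 2 * des$Eh + 0.5 * des$Ez)
    truth <- c(Em = 1, Eh = 4, Ez = 0.25) / 5.25
    max(abs(s$S1 - truth[s$parameter]))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("a pure interaction shows zero S1 but full ST", {
  spec <- uncertainty_spec(0.01)
  des <- saltelli_design(spec, base_n = 2048, seed = 4,
                         parameters = c("Em", "Eh"))
  q <- (des$Em + 52.244) * (des$Eh + 78.7)  # zero-mean product
  s <- sobol_indices(des, q)
  expect_equal(s$S1, c(0, 0), tolerance = 0.1)
  expect_equal(s$ST, c(1, 1), tolerance = 0.1)
})

test_that("constant output yields zero indices with a variance warning", {
  spec <- uncertainty_spec(0.01)
  des <- saltelli_design(spec, base_n = 32, seed = 5,
                         parameters = c("Em", "Eh"))
  expect_warning(s <- sobol_indices(des, rep(3, nrow(des))),
                 "zero variance")
  expect_true(all(s$S1 == 0) && all(s$ST == 0))
})

test_that("excess undefined QOI rows abort the Sobol computation", {
  spec <- uncertainty_spec(0.01)
  des <- saltelli_design(spec, base_n = 64, seed = 6,
                         parameters = c("Em", "Eh"))
  y <- des$Em
  y[1:10] <- NA
  expect_error(sobol_indices(des, y), "undefined")
})

test_that("Morris screening separates influential from inert parameters", {
  spec <- uncertainty_spec(0.05)
  f <- function(rows) rows$gNa^2          # gNa active, Em inert
  m <- morris_screen(spec, f, trajectories = 30, seed = 7,
                     parameters = c("gNa", "Em"))
  expect_equal(m$mu_star[m$parameter == "Em"], 0)
  expect_gt(m$mu_star[m$parameter == "gNa"], 0)
  expect_gt(m$sigma[m$parameter == "gNa"], 0)   # nonlinearity
  expect_identical(m$verdict[m$parameter == "Em"], "excluded")
  expect_identical(m$verdict[m$parameter == "gNa"], "influential")
  # a linear response has constant elementary effects
  # a response linear in the (normal) parameter has elementary effects of
  # constant magnitude on the symmetric 4-level lattice
  ml <- morris_screen(spec, function(rows) 3 * rows$Em, trajectories = 20,
                      seed = 8, parameters = c("Em", "Eh"))
  expect_equal(ml$sigma[ml$parameter == "Em"], 0, tolerance = 1e-8)
  expect_gt(ml$mu_star[ml$parameter == "Em"], 0)
  # determinism
  m2 <- morris_screen(spec, f, trajectories = 30, seed = 7,
                      parameters = c("gNa", "Em"))
  expect_identical(m, m2)
})

test_that("Morris elementary effects match brute-force enumeration", {
  spec <- uncertainty_spec(0.05)
  # record evaluation points, then recompute effects by hand
  pts <- list()
  f <- function(rows) {
    pts[[length(pts) + 1]] <<- rows
    rows$gNa^2
  }
  m <- morris_screen(spec, f, trajectories = 5, seed = 9,
                     parameters = c("gNa", "Em"))
  ee <- unlist(lapply(pts, function(rows) {
    y <- rows$gNa^2
    d <- which(diff(rows$gNa) != 0)
    # unit-cube step is p/(2(p-1)) = 2/3 for 4 levels
    abs(y[d + 1] - y[d]) / (2 / 3)
  }))
  expect_equal(m$mu_star[m$parameter == "gNa"], mean(ee))
})
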