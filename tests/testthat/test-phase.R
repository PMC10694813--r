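test_that("the packaged melting-point table yields the known eutectic minima", {
  systems <- read_melting_table(extdata("simulated_melting_points.csv"))
  expect_named(systems, c("POP/POST", "POP/STOST", "POST/STOST"))

  e1 <- find_minimum(systems[["POP/POST"]])
  expect_equal(e1$temperature, 18.8)
  expect_equal(e1$fraction, 0.5)

  e2 <- find_minimum(systems[["POP/STOST"]])
  expect_equal(e2$temperature, 15.6)
  expect_equal(e2$fraction, 0.8)

  # every system has an interior minimum strictly below both pure TAGs:
  # the nonlinear/eutectic signature
  for (s in names(systems)) {
    d <- systems[[s]]
    e <- find_minimum(d)
    pures <- d$melting_point[d$fraction %in% c(0, 1)]
    expect_true(all(e$temperature < pures))
    expect_true(all(e$temperature <= d$melting_point))
  }
})

test_that("find_minimum breaks ties toward 0.5 and honors the endpoint flag", {
  d <- phase_diagram(c(0, 0.2, 0.5, 0.8, 1), c(10, 20, 20, 20, 12))
  res <- find_minimum(d)                      # interior ties at 20
  expect_equal(res$fraction, 0.5)
  expect_equal(sort(res$tied_fractions), c(0.2, 0.5, 0.8))
  withend <- find_minimum(d, include_endpoints = TRUE)
  expect_equal(withend$temperature, 10)
  expect_equal(withend$fraction, 0)

  # strictly monotone diagram: interior minimum at the extreme interior point
  mono <- phase_diagram(seq(0, 1, 0.1), seq(40, 20, length.out = 11))
  expect_equal(find_minimum(mono)$fraction, 0.9)
  expect_error(find_minimum(phase_diagram(c(0, 1), c(1, 2))),
               class = "tagmelt_invalid_argument")
})

test_that("the ideal-solubility branch matches a bisection oracle and its endpoint identity", {
  p <- hildebrand_params(T_m = c(310, 305), dH_f = c(1e5, 9e4))
  expect_identical(hildebrand_temperature(p, 1, 1), 310)
  expect_identical(hildebrand_temperature(p, 2, 1), 305)

  bisect <- function(T_m, dH_f, x, R = 8.314462618) {
    # f is decreasing in T: f(T_m) = log(x) <= 0 and f -> +Inf as T -> 0
    f <- function(T) log(x) - (dH_f / R) * (1 / T_m - 1 / T)
    lo <- 1; hi <- T_m
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (x in c(0.05, 0.25, 0.5, 0.9, 0.99)) {
    expect_equal(hildebrand_temperature(p, 1, x), bisect(310, 1e5, x),
                 tolerance = 1e-6 / 310)
    expect_equal(hildebrand_temperature(p, 2, x), bisect(305, 9e4, x),
                 tolerance = 1e-6 / 305)
  }
  expect_error(hildebrand_temperature(p, 1, 0), class = "tagmelt_invalid_argument")
  expect_error(hildebrand_temperature(p, 1, -0.2), class = "tagmelt_invalid_argument")
})

test_that("the branch temperature rises with mole fraction and enthalpy", {
  p <- hildebrand_params(T_m = c(310, 305), dH_f = c(1e5, 9e4))
  xs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(hildebrand_temperature(p, 1, xs)) > 0))
  hs <- seq(5e4, 2e5, by = 1e4)
  at_half <- vapply(hs, function(h) {
    hildebrand_temperature(hildebrand_params(c(310, 305), c(h, 9e4)), 1, 0.5)
  }, numeric(1))
  expect_true(all(diff(at_half) > 0))
})

test_that("the liquidus is the upper envelope of the two branches with the crossing as eutectic", {
  p <- hildebrand_params(T_m = c(306.65, 312.05), dH_f = c(92e3, 104e3))
  grid <- seq(0.02, 0.98, by = 0.02)
  liq <- hildebrand_liquidus(p, grid, pair = "A/B")
  expect_equal(liq$melting_point[liq$fraction == 0], 312.05 - 273.15)
  expect_equal(liq$melting_point[liq$fraction == 1], 306.65 - 273.15)

  TA <- hildebrand_temperature(p, 1, grid) - 273.15
  TB <- hildebrand_temperature(p, 2, 1 - grid) - 273.15
  interior <- liq$melting_point[liq$fraction %in% grid]
  expect_true(all(interior >= TA - 1e-9))
  expect_true(all(interior >= TB - 1e-9))

  # model eutectic equals the dense-grid argmin of the max-branch curve
  eu <- attr(liq, "eutectic")
  dense <- seq(1e-4, 1 - 1e-4, length.out = 20001)
  env <- pmax(hildebrand_temperature(p, 1, dense),
              hildebrand_temperature(p, 2, 1 - dense))
  expect_equal(eu$fraction, dense[which.min(env)], tolerance = 1e-3)
  # symmetric components give a symmetric liquidus with the eutectic at 0.5
  sym <- hildebrand_params(T_m = c(310, 310), dH_f = c(1e5, 1e5))
  liq_sym <- hildebrand_liquidus(sym, grid)
  expect_equal(attr(liq_sym, "eutectic")$fraction, 0.5, tolerance = 1e-9)
  expect_equal(liq_sym$melting_point, rev(liq_sym$melting_point))
})

test_that("the synthetic Hildebrand fixture parses and predicts sub-pure liquidus points", {
  tab <- read.csv(extdata("hildebrand_params_synthetic.csv"), comment.char = "#")
  expect_equal(tab$species, c("POP", "POST", "STOST"))
  p <- hildebrand_params(T_m = tab$T_m_C[c(1, 3)] + 273.15,
                         dH_f = tab$dH_f_J_mol[c(1, 3)])
  liq <- hildebrand_liquidus(p, seq(0.1, 0.9, 0.1), pair = "POP/STOST")
  eu <- attr(liq, "eutectic")
  expect_lt(eu$temperature_C, 33.5)
  expect_gt(eu$fraction, 0)
  expect_lt(eu$fraction, 1)
})
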