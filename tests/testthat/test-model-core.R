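test_that("the assembled RHS is S v with compartment division", {
  m <- compile_model(parse_sbml(toy_sbml(1)))
  f <- assemble_rhs(m)
  expect_equal(f(0, c(A = 2, B = 0), c(k = 1)), c(A = -2, B = 2))

  # closed two-reaction cycle conserves total mass: elementwise sum of f = 0
  r1 <- instantiate_law("mass_action_irr_uni", species = c(s1 = "X"),
                        params = c(k = 0.9), id = "f")
  r1$products <- c(Y = 1)
  r2 <- instantiate_law("mass_action_irr_uni", species = c(s1 = "Y"),
                        params = c(k = 0.4), id = "b")
  r2$products <- c(X = 1)
  cyc <- kinetic_model(list(r1, r2), initial = c(X = 1, Y = 1))
  g <- assemble_rhs(cyc)
  for (x in c(0.2, 1, 3)) expect_equal(sum(g(0, c(X = x, Y = 2 - x))), 0)
})

test_that("RHS matches an independent dense S.v evaluation at random states", {
  fx <- fixture_model("enzyme")
  m <- fx$model
  f <- assemble_rhs(m)
  set.seed(21)
  for (i in 1:50) {
    y <- stats::setNames(stats::runif(3, 0.01, 3), m$species)
    # independent oracle: evaluate each reaction's rate via evaluate_rate and
    # assemble S %*% v by hand
    v <- vapply(m$spec$reactions, function(rx)
      evaluate_rate(rx, y, m$theta_ref), 0)
    expect_equal(unname(f(0, y)), as.numeric(m$S %*% v), tolerance = 1e-12)
  }
})

test_that("simulation reproduces closed forms and conservation laws", {
  fx <- fixture_model("decay")
  tr <- simulate_model(fx$model, times = c(0, 1))
  expect_true(tr$success)
  expect_equal(unname(tr$values["A", 2]), 2 * exp(-0.5), tolerance = 1e-6)

  # A <-> B mass action conserves A + B
  r <- instantiate_law("mass_action_rev_uni", species = c(s1 = "A", p1 = "B"),
                       params = c(kf = 1.3, kr = 0.6), id = "r")
  m <- kinetic_model(list(r), initial = c(A = 2, B = 0.5))
  tr <- simulate_model(m, times = seq(0, 5, length.out = 21))
  expect_true(tr$success)
  expect_true(all(abs(colSums(tr$values) - 2.5) < 1e-8))
})

test_that("a stiff two-timescale system matches its closed-form solution", {
  # dx/dt = -x ; dy/dt = x - 1e4 y : rates separated by four decades.
  # Oracle: exact solution y(t) = c1 e^{-t} + c2 e^{-1e4 t} with
  # c1 = x0/(1e4 - 1), c2 = y0 - c1 (independent of any numerical solver).
  r1 <- instantiate_law("mass_action_irr_uni", species = c(s1 = "x"),
                        params = c(k = 1), id = "slow")
  r1$products <- c(y = 1)
  r2 <- instantiate_law("mass_action_irr_uni", species = c(s1 = "y"),
                        params = c(k = 1e4), id = "fast")
  m <- kinetic_model(list(r1, r2), initial = c(x = 1, y = 0.3))
  tr <- simulate_model(m, times = c(0, 0.5, 1))
  expect_true(tr$success)
  c1 <- 1 / (1e4 - 1)
  for (j in 2:3) {
    t <- tr$times[j]
    expect_equal(unname(tr$values["x", j]), exp(-t), tolerance = 1e-6)
    y_exact <- c1 * exp(-t) + (0.3 - c1) * exp(-1e4 * t)
    expect_equal(unname(tr$values["y", j]), y_exact, tolerance = 1e-6)
  }
})

test_that("simulation is deterministic and tolerance-convergent", {
  fx <- fixture_model("ring")
  tms <- seq(0, 6, length.out = 10)
  t1 <- simulate_model(fx$model, times = tms)
  t2 <- simulate_model(fx$model, times = tms)
  expect_identical(t1$values, t2$values)
  tighter <- simulate_model(fx$model, times = tms,
                            config = solver_config(rtol = 5e-9, atol = 5e-12))
  expect_lt(max(abs(tighter$values - t1$values)), 1e-7)
})

test_that("integration failure yields an unsuccessful trajectory, not an error", {
  # dm/dt = k m^2 blows up in finite time t* = 1/(k m0) = 0.1
  r <- instantiate_law("mass_action_irr_bi", species = c(s1 = "A", s2 = "A"),
                       params = c(k = 5), id = "blow")
  r$products <- c(A = 3)   # net +1 A per event => dA/dt = 5 A^2
  m <- kinetic_model(list(r), initial = c(A = 2))
  tr <- simulate_model(m, times = c(0, 1),
                       config = solver_config(max_steps = 10000))
  expect_false(tr$success)
  expect_true(is.character(tr$diagnostic))
  expect_error(simulate_model(m, times = numeric(0)), "times")
})

test_that("initial conditions come from the dataset with model fallbacks", {
  fx <- fixture_model("chain")
  ds <- time_series_dataset(
    c(0, 1, 2),
    matrix(c(3, NA, 2.5,
             NA, 0.4, 0.5), nrow = 2, byrow = TRUE,
           dimnames = list(c("A", "B"), NULL)))
  m0 <- initial_conditions_from_data(fx$model, ds)
  expect_equal(m0[["A"]], 3)     # observed at t0
  expect_equal(m0[["B"]], 0)     # missing at t0 -> model initial
  expect_equal(m0[["C"]], 0)     # absent from data -> model initial

  bad <- time_series_dataset(c(0, 1), matrix(c(1, 2), 1, 2,
                                             dimnames = list("Z", NULL)))
  expect_error(initial_conditions_from_data(fx$model, bad),
               class = "kx_unknown_species")
  expect_warning(initial_conditions_from_data(fx$model, bad,
                                              unknown = "warn"),
                 class = "kx_unknown_species")
})

test_that("trajectories round-trip through CSV", {
  fx <- fixture_model("chain")
  tr <- simulate_model(fx$model, times = seq(0, 10, length.out = 10))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(df), c("time", "A", "B", "C"))
  expect_equal(df$A, unname(tr$values["A", ]))
})
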