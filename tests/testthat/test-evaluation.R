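test_that("the synthetic-data protocol yields 10 points per species", {
  ring <- fixture_model("ring")
  ds <- generate_synthetic_dataset(ring$model, t_end = ring$t_end)
  expect_equal(sum(!is.na(ds$values)), 60)      # 6 species x 10 points
  expect_equal(ds$times[1], 0)
  expect_equal(ds$times[10], ring$t_end)
  expect_equal(diff(range(diff(ds$times))), 0, tolerance = 1e-12)

  # a 2-species model gives 20 observations
  r <- instantiate_law("mass_action_rev_uni", species = c(s1 = "A", p1 = "B"),
                       params = c(kf = 1, kr = 0.5), id = "r")
  m2 <- kinetic_model(list(r), initial = c(A = 1, B = 0.2))
  expect_equal(sum(!is.na(generate_synthetic_dataset(m2, t_end = 5)$values)),
               20)
})

test_that("noiseless sampling equals the simulated trajectory exactly", {
  fx <- fixture_model("chain")
  ds <- generate_synthetic_dataset(fx$model, t_end = 10)
  tr <- simulate_model(fx$model, times = ds$times)
  expect_identical(ds$values, tr$values)

  # multiplicative noise is seeded and reproducible
  d1 <- generate_synthetic_dataset(fx$model, t_end = 10, noise_pct = 1,
                                   seed = 4)
  d2 <- generate_synthetic_dataset(fx$model, t_end = 10, noise_pct = 1,
                                   seed = 4)
  expect_identical(d1$values, d2$values)
  rel <- (d1$values - tr$values) / tr$values
  expect_lt(max(abs(rel), na.rm = TRUE), 0.06)  # 1% sd, few sigma
})

test_that("prior bounds and degenerate LHS behave as specified", {
  th <- c(a = 0.5, b = 2)
  b <- prior_bounds(th, 10)
  expect_equal(b$lower, th / 10)
  expect_equal(b$upper, th * 10)
  expect_error(prior_bounds(c(a = -1), 10), class = "kx_invalid_bounds")

  # X = 1 degenerates to theta_true
  s <- lhs_sample(th, X = 1, n = 5, seed = 1)
  for (x in s) expect_equal(x, th)

  # containment for X = 50
  s2 <- lhs_sample(th, X = 50, n = 30, seed = 2)
  for (x in s2) {
    expect_true(all(x >= th / 50 - 1e-12))
    expect_true(all(x <= th * 50 + 1e-12))
  }
})

test_that("LHS stratifies every log-space marginal bin exactly once", {
  # fixed case: n = 10, one dimension -> each log-decile occupied once
  th1 <- c(k = 1)
  s <- lhs_sample(th1, X = 10, n = 10, seed = 3)
  u <- (log10(vapply(s, `[[`, 0, "k")) - log10(0.1)) / (log10(10) - log10(0.1))
  expect_equal(sort(findInterval(u, seq(0, 1, by = 0.1),
                                 rightmost.closed = TRUE)), 1:10)

  # property: random n and dimension, every marginal stratified
  set.seed(55)
  for (rep in 1:5) {
    n <- sample(3:25, 1)
    d <- sample(1:4, 1)
    th <- stats::setNames(10^stats::runif(d, -2, 2), paste0("p", seq_len(d)))
    X <- sample(c(2, 5, 10, 50, 100), 1)
    s <- lhs_sample(th, X = X, n = n, seed = rep)
    for (j in seq_len(d)) {
      lo <- log10(th[j] / X); hi <- log10(th[j] * X)
      u <- (log10(vapply(s, `[[`, 0, j)) - lo) / (hi - lo)
      bins <- findInterval(u, seq(0, 1, length.out = n + 1),
                           rightmost.closed = TRUE)
      expect_equal(sort(bins), seq_len(n))
    }
  }
})

test_that("initialization success counts solvable parameter draws", {
  fx <- fixture_model("decay")
  ds <- generate_synthetic_dataset(fx$model, t_end = fx$t_end)
  sc <- initialization_screen(fx$model, ds,
                              list(fx$theta_true, fx$theta_true))
  expect_equal(sc$success_pct, 100)
  sc1 <- initialization_screen(fx$model, ds, list(fx$theta_true))
  expect_equal(sc1$success_pct, 100)

  # finite-time blow-up model: dA/dt = k A^2 diverges at t* = 1/(k A0);
  # draws with large k over t_end = 1 must fail while small k succeeds
  r <- instantiate_law("mass_action_irr_bi", species = c(s1 = "A", s2 = "A"),
                       params = c(k = 0.2), id = "q")
  r$products <- c(A = 3)
  m <- kinetic_model(list(r), initial = c(A = 2))
  dsb <- generate_synthetic_dataset(m, t_end = 1)
  samples <- list(c(q_k = 0.05), c(q_k = 0.2), c(q_k = 5), c(q_k = 50))
  scb <- initialization_screen(m, dsb, samples)
  expect_true(all(scb$success[1:2]))
  expect_false(any(scb$success[3:4]))   # blow-up before t_end = 1
  expect_lt(scb$success_pct, 100)
  expect_true(all(nzchar(scb$diagnostics[!scb$success])))
})

test_that("screens are reproducible and training success never exceeds init", {
  fx <- fixture_model("decay")
  cfg <- trainer_config(max_iter = 300)
  s1 <- screen_model(fx$model, t_end = fx$t_end, X = 2, n = 6,
                     replicates = 2, seed = 42, config = cfg)
  s2 <- screen_model(fx$model, t_end = fx$t_end, X = 2, n = 6,
                     replicates = 2, seed = 42, config = cfg)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$replicates[[1]]$runs, s2$replicates[[1]]$runs)
  expect_true(all(s1$summary$train_pct <= s1$summary$init_pct))

  f <- tempfile(fileext = ".json")
  write_screen_json(s1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$summary$init_pct, s1$summary$init_pct)
})

test_that("datasets round-trip through CSV with missing cells", {
  fx <- fixture_model("chain")
  ds <- generate_synthetic_dataset(fx$model, t_end = 10)
  vals <- ds$values; vals["B", 3] <- NA
  ds2 <- time_series_dataset(ds$times, vals)
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(ds2, f)
  back <- read_dataset_csv(f)
  expect_equal(back$times, ds2$times)
  expect_equal(back$values, ds2$values)
  expect_true(is.na(back$values["B", 3]))
})
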