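test_that("masking removes a column, its flux, and its private parameters", {
  fx <- fixture_model("chain")
  masked <- mask_reaction(fx$model, 2)
  expect_equal(masked$n_reactions, 1)
  expect_equal(ncol(masked$S), 1)
  expect_false("v2_k" %in% masked$param_ids)
  expect_error(mask_reaction(fx$model, 3), "index")

  # full RHS - masked RHS = S[, i] * v_i at arbitrary states
  f_full <- assemble_rhs(fx$model)
  f_mask <- assemble_rhs(masked)
  set.seed(8)
  for (i in 1:10) {
    y <- stats::setNames(stats::runif(3, 0, 3), fx$model$species)
    v2 <- evaluate_rate(fx$model$spec$reactions[[2]], y, fx$theta_true)
    expect_equal(f_full(0, y) - f_mask(0, y),
                 stats::setNames(fx$model$S[, 2] * v2, fx$model$species),
                 tolerance = 1e-12)
  }

  # re-adding the masked reaction reproduces the original bit-for-bit
  spec2 <- masked$spec
  spec2$reactions <- append(spec2$reactions,
                            fx$model$spec$reactions[2], after = 1)
  restored <- compile_model(spec2)
  tms <- seq(0, 10, length.out = 10)
  expect_identical(simulate_model(restored, times = tms)$values,
                   simulate_model(fx$model, times = tms)$values)
})

test_that("a zero-initialized hybrid reproduces the masked model exactly", {
  fx <- fixture_model("ring")
  masked <- mask_reaction(fx$model, 3)
  hy <- hybridize(masked, neural_flux(6, seed = 1))
  tms <- seq(0, 6, length.out = 15)
  t_masked <- simulate_model(masked, times = tms)
  t_hybrid <- simulate_model(hy, times = tms)
  expect_true(t_hybrid$success)
  expect_equal(t_hybrid$values, t_masked$values, tolerance = 1e-10)

  # the hybrid RHS is exactly masked RHS + network output at random states
  w <- hy$theta_ref
  set.seed(2)
  w[-seq_len(hy$n_kinetic)] <- stats::rnorm(length(w) - hy$n_kinetic, 0, 0.3)
  rhs_h <- model_rhs(hy); rhs_m <- model_rhs(masked)
  for (i in 1:10) {
    y <- stats::runif(6, 0, 2)
    nn_out <- kinetix:::nn_forward(hy$nn, 0.4, y,
                                   w[-seq_len(hy$n_kinetic)])
    expect_equal(rhs_h(0.4, y, w),
                 rhs_m(0.4, y, w[seq_len(hy$n_kinetic)]) + nn_out,
                 tolerance = 1e-12)
  }

  expect_error(hybridize(masked, neural_flux(4)), "species")
})

test_that("network weight gradients match finite differences", {
  fx <- fixture_model("chain")
  ds <- generate_synthetic_dataset(fx$model, t_end = 10)
  masked <- mask_reaction(fx$model, 1)
  hy <- hybridize(masked, neural_flux(3, seed = 5))
  th <- hy$theta_ref
  set.seed(6)
  nk <- hy$n_kinetic
  th[-seq_len(nk)] <- th[-seq_len(nk)] + stats::rnorm(length(th) - nk, 0, 0.1)
  cfg <- trainer_config(substeps = 4)
  g <- loss_gradient(hy, th, ds, cfg)$gradient
  idx <- c(nk + 3, nk + 40, length(th) - 2)   # hidden, hidden, head
  for (j in idx) {
    tp <- th; tm <- th
    tp[j] <- tp[j] + 1e-5; tm[j] <- tm[j] - 1e-5
    fd <- (training_loss(hy, tp, ds, cfg) -
             training_loss(hy, tm, ds, cfg)) / 2e-5
    expect_equal(unname(g[j]), fd, tolerance = 1e-3)
  }
})

test_that("one training update moves at least one network weight", {
  fx <- fixture_model("chain")
  ds <- generate_synthetic_dataset(fx$model, t_end = 10)
  masked <- mask_reaction(fx$model, 2)
  hy <- hybridize(masked, neural_flux(3, seed = 9))
  fit <- train_hybrid(hy, ds, trainer_config(max_iter = 1, substeps = 4))
  w0 <- hy$theta_ref[-seq_len(hy$n_kinetic)]
  w1 <- fit$theta[-seq_len(hy$n_kinetic)]
  expect_gt(max(abs(w1 - w0)), 0)
})

test_that("all reactions masked reduces the hybrid to a pure neural ODE", {
  fx <- fixture_model("decay")
  spec <- fx$model$spec
  spec$reactions <- list()
  empty <- compile_model(spec)
  hy <- hybridize(empty, neural_flux(1, seed = 3))
  rhs <- model_rhs(hy)
  w <- hy$theta_ref
  set.seed(4)
  w[] <- stats::rnorm(length(w), 0, 0.2)
  expect_equal(unname(rhs(0.5, 1.2, w)),
               unname(kinetix:::nn_forward(hy$nn, 0.5, 1.2, unname(w))),
               tolerance = 1e-12)
})

test_that("the masking experiment returns one scored row per reaction", {
  fx <- fixture_model("chain")
  cfg <- trainer_config(max_iter = 3, substeps = 2)
  tab <- masking_experiment(fx$model, t_end = 10, n_points = 12,
                            noise_pct = 0.05, seed = 1, config = cfg)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$reaction, 1:2)
  expect_true(all(c("train_loss", "truth_loss", "recovered", "status")
                  %in% names(tab)))
  expect_type(tab$recovered, "logical")
})

test_that("neural-flux weights serialize with their manifest", {
  nn <- neural_flux(3, seed = 11)
  nn$weights <- seq_along(nn$weights) * 0.01
  f <- tempfile(fileext = ".json")
  write_neural_flux(nn, f)
  back <- read_neural_flux(f)
  expect_equal(back$weights, nn$weights)
  expect_equal(back$hidden, nn$hidden)
  expect_equal(back$include_time, nn$include_time)
})
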