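# Benchmarking machinery: built-in fixture models, the synthetic-data
# protocol (ten noiseless points per species by default), log-space Latin
# hypercube multi-start initialization, and the initialization / training
# success screens with per-run relative improvement.

#' Built-in fixture models
#'
#' Small, fully specified kinetic models with known true parameters, used
#' throughout the test and screening machinery (they stand in for an
#' external model collection so everything runs without downloads):
#' \describe{
#'   \item{`"decay"`}{1 species, first-order decay, 1 parameter
#'     (`k = 0.5`), `t_end = 10`.}
#'   \item{`"chain"`}{3-species mass-action chain A -> B -> C with rates
#'     `k = (0.7, 0.3)`, `t_end = 10`.}
#'   \item{`"enzyme"`}{2-reaction pathway A <-> B -> C: Haldane-reversible
#'     Michaelis-Menten followed by irreversible Michaelis-Menten,
#'     6 parameters, `t_end = 10`.}
#'   \item{`"ring"`}{6-species mass-action ring S1 -> S2 -> ... -> S6 -> S1
#'     (6 reactions, 6 parameters) with damped-oscillatory relaxation,
#'     `t_end = 6`.}
#' }
#'
#' @param name Fixture name.
#' @return List with `model` (a `kx_kinetic_model`), `theta_true` (named
#'   numeric), `t_end`, and `name`.
#' @export
fixture_model <- function(name = c("decay", "chain", "enzyme", "ring")) {
  name <- match.arg(name)
  fx <- switch(
    name,
    decay = {
      r <- instantiate_law("mass_action_irr_uni", species = c(s1 = "A"),
                           params = c(k = 0.5), id = "v1")
      # degradation: A -> (nothing)
      r$products <- stats::setNames(numeric(0), character(0))
      list(model = kinetic_model(list(r), initial = c(A = 2), id = "decay"),
           t_end = 10)
    },
    chain = {
      r1 <- instantiate_law("mass_action_irr_uni",
                            species = c(s1 = "A"),
                            params = c(k = 0.7), id = "v1")
      r1$products <- c(B = 1)
      r2 <- instantiate_law("mass_action_irr_uni",
                            species = c(s1 = "B"),
                            params = c(k = 0.3), id = "v2")
      r2$products <- c(C = 1)
      list(model = kinetic_model(list(r1, r2),
                                 initial = c(A = 2, B = 0, C = 0),
                                 id = "chain"),
           t_end = 10)
    },
    enzyme = {
      r1 <- instantiate_law("michaelis_menten_rev",
                            species = c(s1 = "A", p1 = "B"),
                            params = c(vmax = 1.5, km_s = 0.6, km_p = 1.2,
                                       keq = 4), id = "v1")
      r2 <- instantiate_law("michaelis_menten_irr",
                            species = c(s1 = "B"),
                            params = c(vmax = 0.8, km_s = 0.4), id = "v2")
      r2$products <- c(C = 1)
      list(model = kinetic_model(list(r1, r2),
                                 initial = c(A = 2, B = 0.2, C = 0.05),
                                 id = "enzyme"),
           t_end = 10)
    },
    ring = {
      ks <- c(1.2, 0.8, 1.5, 0.9, 1.1, 0.7)
      sp <- paste0("S", 1:6)
      rxs <- lapply(1:6, function(i) {
        r <- instantiate_law("mass_action_irr_uni",
                             species = stats::setNames(sp[i], "s1"),
                             params = c(k = ks[i]),
                             id = paste0("v", i))
        r$products <- stats::setNames(1, sp[if (i == 6) 1 else i + 1])
        r
      })
      init <- stats::setNames(c(3, 0.5, 0.4, 0.6, 0.5, 0.4), sp)
      list(model = kinetic_model(rxs, initial = init, id = "ring"),
           t_end = 6)
    })
  list(name = name, model = fx$model, theta_true = fx$model$theta_ref,
       t_end = fx$t_end)
}

#' Generate a synthetic time-series dataset from a model
#'
#' Simulates the model at the given parameters over `[0, t_end]` and samples
#' `n_points` uniformly spaced time points (inclusive of both endpoints) for
#' every dynamic species -- the default of 10 points per species mirrors the
#' sparse sampling typical of biotechnological time-series data, for a total
#' of `n_points * n_species` observations. Optional multiplicative Gaussian
#' noise `y * (1 + e)`, `e ~ N(0, (noise_pct/100)^2)`, is applied under the
#' given seed; the default is noiseless.
#'
#' @param model A `kx_kinetic_model`.
#' @param theta Parameters to simulate at (defaults to the model's reference
#'   values, i.e. the true parameters for fixture models).
#' @param t_end End of the sampled interval.
#' @param n_points Number of time points per species (default 10).
#' @param noise_pct Noise standard deviation as a percentage of the signal
#'   (e.g. `0.05` means 0.05\%, i.e. relative sd `5e-4`).
#' @param seed RNG seed for the noise draw.
#' @param config Solver configuration for the ground-truth simulation.
#' @return A [time_series_dataset()]. Integration failure at `theta` raises
#'   `kx_fixture_unsolvable`.
#' @export
generate_synthetic_dataset <- function(model, theta = NULL, t_end,
                                       n_points = 10L, noise_pct = 0,
                                       seed = NULL,
                                       config = solver_config()) {
  times <- seq(0, t_end, length.out = n_points)
  traj <- simulate_model(model, theta = theta, times = times,
                         config = config)
  if (!traj$success)
    kx_stop("fixture-unsolvable",
            sprintf("model cannot be simulated at the given parameters: %s",
                    traj$diagnostic))
  vals <- traj$values
  if (noise_pct > 0) {
    eps <- with_seed(seed, matrix(stats::rnorm(length(vals), 0,
                                               noise_pct / 100),
                                  nrow(vals), ncol(vals)))
    vals <- vals * (1 + eps)
  }
  time_series_dataset(times, vals)
}

#' Multiplicative prior bounds around true parameters
#'
#' Lower and upper initialization bounds `theta_true / X` and
#' `X * theta_true` (the study protocol uses `X` in 2, 5, 10, 50, 100;
#' any `X >= 1` is accepted).
#'
#' @param theta_true Named numeric vector of true parameter values
#'   (strictly positive).
#' @param X Bound factor.
#' @return List with `lower` and `upper` named vectors.
#' @export
prior_bounds <- function(theta_true, X) {
  stopifnot(X >= 1)
  if (any(theta_true <= 0) || any(!is.finite(theta_true)))
    kx_stop("invalid-bounds",
            "multiplicative bounds require strictly positive true parameters")
  list(lower = theta_true / X, upper = theta_true * X)
}

#' Latin hypercube sample of parameter initializations
#'
#' Draws `n` parameter vectors by Latin hypercube sampling, stratified in
#' log10 space over `[theta_true/X, X*theta_true]` per dimension: each of
#' the `n` equal log-width bins of every marginal contains exactly one
#' sample. Sampling in log space avoids oversampling the upper decades when
#' parameters span orders of magnitude. Deterministic under `seed`.
#'
#' @param theta_true Named numeric vector of true (positive) parameters.
#' @param X Bound factor (`X = 1` degenerates to every sample equal to
#'   `theta_true`).
#' @param n Number of samples (default 100).
#' @param seed RNG seed.
#' @return List of `n` named parameter vectors.
#' @export
lhs_sample <- function(theta_true, X, n = 100L, seed = NULL) {
  stopifnot(n >= 1)
  b <- prior_bounds(theta_true, X)
  d <- length(theta_true)
  u <- with_seed(seed, lhs::randomLHS(n, d))
  lo <- log10(b$lower); hi <- log10(b$upper)
  lapply(seq_len(n), function(i) {
    stats::setNames(10^(lo + u[i, ] * (hi - lo)), names(theta_true))
  })
}

#' Screen parameter initializations for solvability
#'
#' A sample is initialization-successful iff the loss and its gradient
#' evaluate finite at that sample, i.e. the first gradient-descent iteration
#' can be performed (integration succeeds). Failures carry their integration
#' diagnostics.
#'
#' @param model A `kx_kinetic_model` or `kx_hybrid_model`.
#' @param dataset A [time_series_dataset()].
#' @param samples Non-empty list of parameter vectors (e.g. from
#'   [lhs_sample()]).
#' @param config A [trainer_config()].
#' @return A `kx_init_screen`: `success` (logical), `loss` (initial losses,
#'   `NA` on failure), `diagnostics`, and `success_pct`.
#' @export
initialization_screen <- function(model, dataset, samples,
                                  config = trainer_config()) {
  stopifnot(length(samples) >= 1)
  res <- lapply(samples, function(th) {
    tryCatch({
      lg <- loss_gradient(model, th, dataset, config)
      if (!is.finite(lg$loss)) stop("non-finite loss")
      list(ok = TRUE, loss = lg$loss, diag = NA_character_)
    },
    error = function(e) list(ok = FALSE, loss = NA_real_,
                             diag = conditionMessage(e)))
  })
  success <- vapply(res, `[[`, TRUE, "ok")
  structure(
    list(success = success,
         loss = vapply(res, `[[`, 0, "loss"),
         diagnostics = vapply(res, `[[`, "", "diag"),
         success_pct = 100 * mean(success)),
    class = "kx_init_screen")
}

#' Train every successful initialization and score the screen
#'
#' Runs the full training loop on every initialization-successful sample and
#' aggregates: initialization success percentage, training success
#' percentage (final loss below `lambda_success`, reported over all
#' samples, hence never above the initialization percentage), and the
#' per-run relative improvement `r = (J_init - J_final)/J_init`.
#'
#' @inheritParams initialization_screen
#' @param init Optional precomputed [initialization_screen()] result for the
#'   same samples.
#' @return A `kx_screen_result`: per-sample `runs` data.frame (`sample`,
#'   `init_success`, `loss_init`, `loss_final`, `status`, `improvement`,
#'   `train_success`), the final parameter vectors per trained sample
#'   (`thetas`), plus aggregate `init_pct` and `train_pct`.
#' @export
training_screen <- function(model, dataset, samples,
                            config = trainer_config(), init = NULL) {
  if (is.null(init)) init <- initialization_screen(model, dataset, samples,
                                                   config)
  n <- length(samples)
  loss_final <- rep(NA_real_, n)
  status <- rep("init-failed", n)
  improvement <- rep(NA_real_, n)
  thetas <- vector("list", n)
  for (i in seq_len(n)) {
    if (!init$success[i]) next
    fit <- train(model, samples[[i]], dataset, config)
    loss_final[i] <- fit$final_loss
    status[i] <- fit$status
    thetas[[i]] <- fit$theta
    improvement[i] <- relative_improvement(init$loss[i], fit$final_loss,
                                           config$lambda_stop)
  }
  train_success <- init$success & !is.na(loss_final) &
    loss_final < config$lambda_success
  runs <- data.frame(sample = seq_len(n), init_success = init$success,
                     loss_init = init$loss, loss_final = loss_final,
                     status = status, improvement = improvement,
                     train_success = train_success)
  structure(
    list(runs = runs, thetas = thetas, init_pct = init$success_pct,
         train_pct = 100 * mean(train_success)),
    class = "kx_screen_result")
}

#' @export
print.kx_screen_result <- function(x, ...) {
  cat(sprintf("<kx_screen_result> %d runs: init %.1f%%, trained %.1f%%, median r %.3f\n",
              nrow(x$runs), x$init_pct, x$train_pct,
              stats::median(x$runs$improvement, na.rm = TRUE)))
  invisible(x)
}

#' Multi-start screening of a model over prior bound factors
#'
#' The full screening protocol for one model: simulate a synthetic dataset
#' at the true parameters, draw `n` Latin hypercube initializations within
#' `[theta_true/X, X*theta_true]`, screen initializations, train the
#' successful ones, and repeat over `replicates` (replicates differ only in
#' their RNG seed). Identical seeds reproduce the result exactly.
#'
#' @param model A `kx_kinetic_model`.
#' @param theta_true True parameters (defaults to the model's reference
#'   values).
#' @param t_end Simulated interval end for the synthetic dataset.
#' @param X Bound factor.
#' @param n Number of initializations per replicate.
#' @param replicates Number of repeats (default 3).
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @param n_points,noise_pct Passed to [generate_synthetic_dataset()].
#' @param config A [trainer_config()].
#' @return A `kx_screen_set`: list of per-replicate `kx_screen_result`s and
#'   a `summary` data.frame (`model`, `X`, `replicate`, `init_pct`,
#'   `train_pct`, `median_improvement`).
#' @export
screen_model <- function(model, theta_true = model$theta_ref, t_end, X,
                         n = 100L, replicates = 3L, seed = 1L,
                         n_points = 10L, noise_pct = 0,
                         config = trainer_config()) {
  results <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- seed + r - 1L
    dataset <- generate_synthetic_dataset(model, theta = theta_true,
                                          t_end = t_end,
                                          n_points = n_points,
                                          noise_pct = noise_pct,
                                          seed = rep_seed)
    samples <- lhs_sample(theta_true, X, n = n, seed = rep_seed)
    results[[r]] <- training_screen(model, dataset, samples, config)
  }
  summary <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(model = model$spec$id, X = X, replicate = r,
               init_pct = results[[r]]$init_pct,
               train_pct = results[[r]]$train_pct,
               median_improvement = stats::median(
                 results[[r]]$runs$improvement, na.rm = TRUE))
  }))
  structure(list(replicates = results, summary = summary),
            class = "kx_screen_set")
}

#' Serialize a screen result
#'
#' @param screen A `kx_screen_result` or `kx_screen_set`.
#' @param file Output path (JSON for results, CSV for the summary table).
#' @export
write_screen_json <- function(screen, file) {
  if (inherits(screen, "kx_screen_set")) {
    payload <- list(summary = screen$summary,
                    replicates = lapply(screen$replicates, `[[`, "runs"))
  } else {
    payload <- list(init_pct = screen$init_pct, train_pct = screen$train_pct,
                    runs = screen$runs)
  }
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(file)
}
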