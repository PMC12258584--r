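# Gradients through the integrator: a reverse-mode discrete adjoint of a
# fixed-step classical Runge-Kutta-4 discretization of the observation grid.
# The reverse pass is the exact transpose of the forward recursion, so the
# returned gradient matches finite differences of the same discretized loss
# to machine precision, and its cost is independent of the number of
# parameters -- which is what makes joint training of kinetic parameters and
# neural-network weights affordable.

# Subdivide each observation interval into `substeps` equal RK4 steps.
rk4_grid <- function(times, substeps) {
  n_int <- length(times) - 1L
  if (n_int == 0L)
    return(list(grid = times, obs_idx = 1L, h = numeric(0)))
  grid <- numeric(n_int * substeps + 1L)
  h <- numeric(n_int * substeps)
  grid[1] <- times[1]
  k <- 1L
  for (i in seq_len(n_int)) {
    hi <- (times[i + 1] - times[i]) / substeps
    for (s in seq_len(substeps)) {
      h[k] <- hi
      grid[k + 1L] <- times[i] + s * hi
      k <- k + 1L
    }
  }
  list(grid = grid, obs_idx = seq(1L, length(grid), by = substeps), h = h)
}

# Forward pass. Returns states at every grid node plus the four stage
# derivatives per step (needed to reconstruct stage states in reverse).
rk4_forward <- function(rhs, theta, grid, h, m0) {
  n <- length(m0)
  G <- length(grid)
  states <- matrix(NA_real_, n, G)
  states[, 1] <- m0
  stages <- if (G > 1) array(NA_real_, c(n, 4, G - 1)) else NULL
  y <- as.numeric(m0)
  for (i in seq_len(G - 1L)) {
    t0 <- grid[i]; hi <- h[i]
    k1 <- rhs(t0, y, theta)
    k2 <- rhs(t0 + hi / 2, y + (hi / 2) * k1, theta)
    k3 <- rhs(t0 + hi / 2, y + (hi / 2) * k2, theta)
    k4 <- rhs(t0 + hi, y + hi * k3, theta)
    y <- y + (hi / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y))) {
      return(list(success = FALSE, step = i, states = states,
                  stages = stages))
    }
    stages[, , i] <- c(k1, k2, k3, k4)
    states[, i + 1L] <- y
  }
  list(success = TRUE, states = states, stages = stages)
}

# Reverse pass: seeds is an n x n_obs matrix of dJ/dpred at the observation
# nodes; returns dJ/dtheta (linear space) of length n_params.
rk4_backward <- function(vjp, theta, grid, h, obs_idx, states, stages,
                         seeds, n_params) {
  n <- nrow(states)
  G <- length(grid)
  lam <- numeric(n)
  g <- numeric(n_params)
  obs_ptr <- length(obs_idx)
  if (obs_idx[obs_ptr] == G) {
    lam <- lam + seeds[, obs_ptr]
    obs_ptr <- obs_ptr - 1L
  }
  for (i in rev(seq_len(G - 1L))) {
    t0 <- grid[i]; hi <- h[i]
    y <- states[, i]
    k <- matrix(stages[, , i], nrow = n)
    u2 <- y + (hi / 2) * k[, 1]
    u3 <- y + (hi / 2) * k[, 2]
    u4 <- y + hi * k[, 3]

    v4 <- (hi / 6) * lam
    w4 <- vjp(t0 + hi, u4, theta, v4)
    v3 <- (2 * hi / 6) * lam + hi * w4$dy
    w3 <- vjp(t0 + hi / 2, u3, theta, v3)
    v2 <- (2 * hi / 6) * lam + (hi / 2) * w3$dy
    w2 <- vjp(t0 + hi / 2, u2, theta, v2)
    v1 <- (hi / 6) * lam + (hi / 2) * w2$dy
    w1 <- vjp(t0, y, theta, v1)

    lam <- lam + w1$dy + w2$dy + w3$dy + w4$dy
    g <- g + w1$dp + w2$dp + w3$dp + w4$dp

    if (obs_ptr >= 1L && obs_idx[obs_ptr] == i) {
      lam <- lam + seeds[, obs_ptr]
      obs_ptr <- obs_ptr - 1L
    }
  }
  g
}

# Resolve a user-supplied theta (named or model-ordered) to the model's
# canonical numeric parameter vector.
resolve_theta <- function(model, theta) {
  ids <- model$param_ids
  if (!is.null(names(theta)) && all(ids %in% names(theta))) {
    as.numeric(theta[ids])
  } else {
    if (length(theta) != length(ids))
      stop("`theta` must be named or match the model's parameter count")
    as.numeric(theta)
  }
}

#' Training loss of a model against a dataset
#'
#' Evaluates the (default mean-centered) loss on the same fixed-step RK4
#' discretization of the observation grid that [loss_gradient()]
#' differentiates, so loss and gradient always refer to the same objective.
#' Initial conditions are taken from the dataset's first time point.
#'
#' @param model A `kx_kinetic_model` or `kx_hybrid_model`.
#' @param theta Parameter vector (named or model-ordered), linear scale.
#' @param dataset A [time_series_dataset()].
#' @param config A [trainer_config()] (supplies `substeps` and the loss).
#' @return Scalar loss. Integration failure raises `kx_gradient_unavailable`.
#' @export
training_loss <- function(model, theta, dataset, config = trainer_config()) {
  fw <- forward_predict(model, theta, dataset, config)
  config$loss_value(fw$pred, dataset)
}

forward_predict <- function(model, theta, dataset, config) {
  th <- resolve_theta(model, theta)
  m0 <- initial_conditions_from_data(model, dataset)
  gr <- rk4_grid(dataset$times, config$substeps)
  fw <- rk4_forward(model_rhs(model), th, gr$grid, gr$h, m0)
  if (!fw$success)
    kx_stop("gradient-unavailable",
            sprintf("integration failed at grid step %d (t ~ %.6g)",
                    fw$step, gr$grid[fw$step]),
            data = list(step = fw$step, t = gr$grid[fw$step]))
  pred <- fw$states[, gr$obs_idx, drop = FALSE]
  rownames(pred) <- model$species
  list(pred = pred, fw = fw, gr = gr, theta = th)
}

#' Loss and gradient in log-parameter space
#'
#' Differentiates the training loss through the integrator with a discrete
#' adjoint (reverse-mode) pass and applies the log-space chain rule: for
#' positive-flagged parameters the returned component is
#' `dJ/d(log theta_i) = theta_i * dJ/dtheta_i`; non-positive-flagged
#' parameters (e.g. neural-network weights) are differentiated in linear
#' space.
#'
#' @inheritParams training_loss
#' @return List with `loss` (scalar), `gradient` (named, log-space for
#'   positive-flagged parameters), and `pred` (species x time prediction
#'   matrix at the observation times). Integration failure raises a
#'   `kx_gradient_unavailable` error carrying the failing step.
#' @export
loss_gradient <- function(model, theta, dataset, config = trainer_config()) {
  fp <- forward_predict(model, theta, dataset, config)
  J <- config$loss_value(fp$pred, dataset)

  seeds_obs <- config$loss_seeds(fp$pred, dataset)   # dataset species only
  seeds <- matrix(0, model$n, length(dataset$times))
  rownames(seeds) <- model$species
  seeds[rownames(seeds_obs), ] <- seeds_obs

  g_lin <- if (length(fp$gr$h) == 0) {
    numeric(length(model$param_ids))
  } else {
    rk4_backward(model_vjp(model), fp$theta, fp$gr$grid, fp$gr$h,
                 fp$gr$obs_idx, fp$fw$states, fp$fw$stages, seeds,
                 length(model$param_ids))
  }
  pos <- model$positive[model$param_ids]
  g <- ifelse(pos, g_lin * fp$theta, g_lin)
  if (any(!is.finite(g)))
    kx_stop("gradient-unavailable", "gradient evaluated non-finite")
  list(loss = J, gradient = stats::setNames(g, model$param_ids),
       pred = fp$pred)
}
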