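# Hybrid mechanistic / neural-network models: mask a reaction (drop its
# stoichiometric column and flux), add a multilayer-perceptron flux term
# whose output is a species-space rate vector added directly to dm/dt
# (absorbing the unknown stoichiometry), and train kinetic parameters
# (log space) and network weights (linear space) jointly:
#   dm/dt = S_(-i) v_(-i)(t, m, theta) + NN(t, m, w, b)

# numerically stable, branch-free forms
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Create a neural flux term
#'
#' A multilayer perceptron taking `(t, m)` (or just `m`) as input and
#' returning a rate vector of dimension `n_species` that is added to the
#' right-hand side of a masked model. Default architecture: two hidden
#' layers of 16 softplus units and a linear, zero-initialized output layer
#' -- so a freshly created hybrid model reproduces the masked model's
#' trajectories exactly until training moves the head weights.
#'
#' @param n_species Output dimension (= number of dynamic species).
#' @param hidden Sizes of the two hidden layers.
#' @param include_time Include `t` as a network input (set `FALSE` for
#'   autonomous systems).
#' @param seed Seed for the (Glorot-uniform) hidden-layer initialization.
#' @return A `kx_neural_flux`: layer shapes, flattened weight vector
#'   `weights`, and weight names.
#' @export
neural_flux <- function(n_species, hidden = c(16L, 16L),
                        include_time = TRUE, seed = NULL) {
  stopifnot(length(hidden) == 2, n_species >= 1)
  d0 <- n_species + as.integer(include_time)
  dims <- list(W1 = c(hidden[1], d0), b1 = hidden[1],
               W2 = c(hidden[2], hidden[1]), b2 = hidden[2],
               W3 = c(n_species, hidden[2]), b3 = n_species)
  glorot <- function(fan_out, fan_in) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(fan_out * fan_in, -lim, lim)
  }
  weights <- with_seed(seed, c(
    glorot(hidden[1], d0), numeric(hidden[1]),
    glorot(hidden[2], hidden[1]), numeric(hidden[2]),
    numeric(n_species * hidden[2]), numeric(n_species)))  # zero head
  structure(
    list(n_species = n_species, hidden = as.integer(hidden),
         include_time = include_time, d0 = d0, dims = dims,
         weights = weights,
         weight_ids = paste0("nn_w", seq_along(weights))),
    class = "kx_neural_flux")
}

nn_unpack <- function(nn, w) {
  w <- unname(w)
  h1 <- nn$hidden[1]; h2 <- nn$hidden[2]; n <- nn$n_species; d0 <- nn$d0
  i <- 0L
  take <- function(len) { out <- w[(i + 1L):(i + len)]; i <<- i + len; out }
  list(W1 = matrix(take(h1 * d0), h1, d0), b1 = take(h1),
       W2 = matrix(take(h2 * h1), h2, h1), b2 = take(h2),
       W3 = matrix(take(n * h2), n, h2), b3 = take(n))
}

nn_forward <- function(nn, t, y, w, L = nn_unpack(nn, w)) {
  x <- if (nn$include_time) c(t, y) else y
  h1 <- softplus(as.numeric(L$W1 %*% x) + L$b1)
  h2 <- softplus(as.numeric(L$W2 %*% h1) + L$b2)
  as.numeric(L$W3 %*% h2) + L$b3
}

# reverse-mode: adjoint vector a (n) -> (dJ/dy, dJ/dw) contributions
nn_vjp <- function(nn, t, y, w, a, L = nn_unpack(nn, w)) {
  x <- if (nn$include_time) c(t, y) else y
  z1 <- as.numeric(L$W1 %*% x) + L$b1; h1 <- softplus(z1)
  z2 <- as.numeric(L$W2 %*% h1) + L$b2; h2 <- softplus(z2)
  dW3 <- tcrossprod(a, h2); db3 <- a
  dh2 <- as.numeric(crossprod(L$W3, a))
  dz2 <- dh2 * sigmoid(z2)
  dW2 <- tcrossprod(dz2, h1); db2 <- dz2
  dh1 <- as.numeric(crossprod(L$W2, dz2))
  dz1 <- dh1 * sigmoid(z1)
  dW1 <- tcrossprod(dz1, x); db1 <- dz1
  dx <- as.numeric(crossprod(L$W1, dz1))
  dy <- if (nn$include_time) dx[-1] else dx
  list(dy = dy, dw = c(dW1, db1, dW2, db2, dW3, db3))
}

#' Mask one reaction of a model
#'
#' Removes reaction `i` (1-based index in document order): the
#' stoichiometric matrix loses column `i`, the flux vector loses entry `i`,
#' and parameters used only by that reaction leave the trainable registry.
#'
#' @param model A `kx_kinetic_model`.
#' @param i Reaction index, `1 <= i <= n_reactions`.
#' @return The masked `kx_kinetic_model`.
#' @export
mask_reaction <- function(model, i) {
  stopifnot(inherits(model, "kx_kinetic_model"))
  if (!(is.numeric(i) && length(i) == 1 && i >= 1 && i <= model$n_reactions))
    stop(sprintf("reaction index must be in [1, %d]", model$n_reactions))
  spec <- model$spec
  spec$reactions <- spec$reactions[-i]
  compile_model(spec)
}

#' Combine a masked model with a neural flux term
#'
#' The hybrid right-hand side is exactly the masked mechanistic RHS plus the
#' network output; gradients flow to both the kinetic parameters and the
#' network weights. With the default zero-initialized output layer the
#' network contributes exactly zero, so hybrid and masked trajectories
#' coincide before training.
#'
#' @param model A (typically masked) `kx_kinetic_model`.
#' @param nn A [neural_flux()] whose output dimension equals the model's
#'   number of dynamic species.
#' @return A `kx_hybrid_model`; its parameter vector is the concatenation
#'   of the kinetic parameters (positive-flagged, trained in log space) and
#'   the network weights (linear space).
#' @export
hybridize <- function(model, nn) {
  stopifnot(inherits(model, "kx_kinetic_model"),
            inherits(nn, "kx_neural_flux"))
  if (nn$n_species != model$n)
    stop(sprintf("neural flux outputs %d species, model has %d",
                 nn$n_species, model$n))
  param_ids <- c(model$param_ids, nn$weight_ids)
  positive <- stats::setNames(c(model$positive[model$param_ids],
                                rep(FALSE, length(nn$weight_ids))),
                              param_ids)
  structure(
    list(kinetic = model, nn = nn,
         species = model$species, n = model$n,
         n_reactions = model$n_reactions,
         S = model$S, comp = model$comp, initial = model$initial,
         spec = model$spec,
         n_kinetic = length(model$param_ids),
         param_ids = param_ids,
         theta_ref = stats::setNames(c(model$theta_ref, nn$weights),
                                     param_ids),
         positive = positive),
    class = "kx_hybrid_model")
}

#' @export
print.kx_hybrid_model <- function(x, ...) {
  cat(sprintf("<kx_hybrid_model> %d species, %d mechanistic reactions + MLP(%s), %d kinetic + %d network parameters\n",
              x$n, x$n_reactions, paste(x$nn$hidden, collapse = "x"),
              x$n_kinetic, length(x$nn$weight_ids)))
  invisible(x)
}

# The weight subvector is constant across the thousands of stage
# evaluations of one forward/backward sweep, so the layer matrices are
# re-unpacked only when the parameter vector actually changes.
#' @export
model_rhs.kx_hybrid_model <- function(model) {
  kin <- model_rhs(model$kinetic)
  nn <- model$nn
  nk <- model$n_kinetic
  kin_idx <- seq_len(nk)
  last_w <- NULL; L <- NULL
  function(t, y, p) {
    w <- if (nk > 0) p[-kin_idx] else p
    if (is.null(last_w) || !identical(w, last_w)) {
      L <<- nn_unpack(nn, w); last_w <<- w
    }
    as.numeric(kin(t, y, p[kin_idx])) + nn_forward(nn, t, y, w, L)
  }
}

#' @export
model_vjp.kx_hybrid_model <- function(model) {
  kin <- model_vjp(model$kinetic)
  nn <- model$nn
  nk <- model$n_kinetic
  kin_idx <- seq_len(nk)
  last_w <- NULL; L <- NULL
  function(t, y, p, a) {
    w <- if (nk > 0) p[-kin_idx] else p
    if (is.null(last_w) || !identical(w, last_w)) {
      L <<- nn_unpack(nn, w); last_w <<- w
    }
    vk <- kin(t, y, p[kin_idx], a)
    vn <- nn_vjp(nn, t, y, w, a, L)
    list(dy = vk$dy + vn$dy, dp = c(vk$dp, vn$dw))
  }
}

#' Train a hybrid model
#'
#' Joint training with the standard loop (mean-centered loss, clipping of
#' the concatenated gradient's global norm, AdaBelief): kinetic parameters
#' in log space, network weights in linear space.
#'
#' @param hybrid A [hybridize()]d model.
#' @param dataset A [time_series_dataset()] observed from the full
#'   (unmasked) system.
#' @param config A [trainer_config()].
#' @param theta0 Initial joint parameter vector; defaults to the hybrid's
#'   reference values (true remaining kinetics, zero-head network).
#' @return A `kx_train_result` (see [train()]).
#' @export
train_hybrid <- function(hybrid, dataset, config = trainer_config(),
                         theta0 = hybrid$theta_ref) {
  stopifnot(inherits(hybrid, "kx_hybrid_model"))
  train(hybrid, theta0, dataset, config)
}

#' Masking experiment: can a neural flux recover each reaction?
#'
#' For each reaction in turn: generate a noisy dataset from the full model
#' at the true parameters (default 100 time points, 0.05\% multiplicative
#' noise), mask the reaction, attach a fresh neural flux, train the hybrid
#' jointly, and score recovery as the mean-centered loss of the trained
#' hybrid against the noiseless ground-truth trajectories on the training
#' grid falling below `recovery_threshold`. Per-reaction failures are
#' recorded, not raised.
#'
#' @param model A `kx_kinetic_model` simulable at `theta_true`.
#' @param theta_true True parameters (defaults to the model's reference
#'   values).
#' @param t_end End of the sampled interval.
#' @param n_points Time points in the training dataset (default 100).
#' @param noise_pct Multiplicative noise percentage (default 0.05, i.e.
#'   relative sd `5e-4`).
#' @param seed Base RNG seed (reaction `i` uses `seed + i` for its noise
#'   and network initialization).
#' @param config A [trainer_config()].
#' @param recovery_threshold Mean-centered-loss threshold against the
#'   noiseless truth below which a reaction counts as recovered.
#' @param reactions Subset of reaction indices to run (default all).
#' @return A data.frame with one row per masked reaction: `reaction`, `id`,
#'   `train_loss`, `truth_loss`, `recovered`, `status`.
#' @export
masking_experiment <- function(model, theta_true = model$theta_ref, t_end,
                               n_points = 100L, noise_pct = 0.05,
                               seed = 1L, config = trainer_config(),
                               recovery_threshold = 1e-2,
                               reactions = seq_len(model$n_reactions)) {
  noiseless <- generate_synthetic_dataset(model, theta = theta_true,
                                          t_end = t_end,
                                          n_points = n_points)
  rows <- lapply(reactions, function(i) {
    rid <- model$spec$reactions[[i]]$id
    out <- tryCatch({
      noisy <- generate_synthetic_dataset(model, theta = theta_true,
                                          t_end = t_end,
                                          n_points = n_points,
                                          noise_pct = noise_pct,
                                          seed = seed + i)
      masked <- mask_reaction(model, i)
      hybrid <- hybridize(masked, neural_flux(model$n, seed = seed + i))
      fit <- train_hybrid(hybrid, noisy, config)
      truth_loss <- training_loss(hybrid, fit$theta, noiseless, config)
      list(train_loss = fit$final_loss, truth_loss = truth_loss,
           recovered = is.finite(truth_loss) &&
             truth_loss < recovery_threshold,
           status = fit$status)
    }, error = function(e) list(train_loss = NA_real_, truth_loss = NA_real_,
                                recovered = FALSE,
                                status = paste("error:",
                                               conditionMessage(e))))
    data.frame(reaction = i, id = rid, train_loss = out$train_loss,
               truth_loss = out$truth_loss, recovered = out$recovered,
               status = out$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize neural-flux weights
#'
#' Writes the flattened weight vector alongside a JSON manifest of the
#' architecture (layer sizes, activation, time input), and reads it back.
#'
#' @param nn A `kx_neural_flux`.
#' @param file Path to a JSON file.
#' @return `write_neural_flux()`: the path, invisibly.
#'   `read_neural_flux()`: a `kx_neural_flux`.
#' @export
write_neural_flux <- function(nn, file) {
  jsonlite::write_json(
    list(n_species = nn$n_species, hidden = nn$hidden,
         include_time = nn$include_time, activation = "softplus",
         weights = nn$weights),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_neural_flux
#' @export
read_neural_flux <- function(file) {
  spec <- jsonlite::read_json(file, simplifyVector = TRUE)
  nn <- neural_flux(spec$n_species, hidden = spec$hidden,
                    include_time = spec$include_time)
  stopifnot(length(spec$weights) == length(nn$weights))
  nn$weights <- as.numeric(spec$weights)
  nn
}
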