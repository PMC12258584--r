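# The training loop: iterate loss+gradient through the solver, clip the
# gradient global norm, update with AdaBelief in log-parameter space, stop
# early below the loss threshold. Full-batch (no mini-batching over time
# points); multiple datasets are fitted jointly by averaging per-dataset
# gradients before the (single, clipped) update.

#' Training configuration
#'
#' Defaults mirror the reference training protocol: learning rate `1e-3`,
#' at most 3000 iterations (raise to 10000 for large models), gradient
#' global-norm clip at 4, early stopping when the loss falls below
#' `lambda_stop = 1e-6`, and a training-success threshold
#' `lambda_success = 1e-3` used by the screening machinery. AdaBelief
#' moments use `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-16`.
#'
#' @param learning_rate AdaBelief learning rate.
#' @param max_iter Maximum number of gradient-descent iterations.
#' @param clip_norm Gradient global-norm clipping threshold.
#' @param lambda_stop Early-stopping loss threshold.
#' @param lambda_success Loss threshold below which a trained run counts as
#'   successful (must exceed `lambda_stop`).
#' @param beta1,beta2,epsilon AdaBelief moment/bias constants.
#' @param substeps RK4 steps per observation interval used by the
#'   differentiable forward pass (controls the discretization error of the
#'   training objective).
#' @param snapshot_stride Record a parameter snapshot every this many
#'   iterations (0 = none).
#' @param loss_value,loss_seeds Pluggable loss: `loss_value(pred, dataset)`
#'   returns the scalar loss, `loss_seeds(pred, dataset)` its derivative
#'   with respect to the prediction matrix. Defaults to the mean-centered
#'   loss.
#' @return A `kx_trainer_config`.
#' @export
trainer_config <- function(learning_rate = 1e-3, max_iter = 3000L,
                           clip_norm = 4, lambda_stop = 1e-6,
                           lambda_success = 1e-3, beta1 = 0.9,
                           beta2 = 0.999, epsilon = 1e-16, substeps = 10L,
                           snapshot_stride = 0L,
                           loss_value = mean_centered_loss,
                           loss_seeds = mean_centered_loss_seeds) {
  stopifnot(learning_rate > 0, max_iter >= 1, clip_norm > 0,
            lambda_stop > 0, lambda_success > 0,
            lambda_stop < lambda_success, substeps >= 1)
  structure(list(learning_rate = learning_rate,
                 max_iter = as.integer(max_iter), clip_norm = clip_norm,
                 lambda_stop = lambda_stop, lambda_success = lambda_success,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 substeps = as.integer(substeps),
                 snapshot_stride = as.integer(snapshot_stride),
                 loss_value = loss_value, loss_seeds = loss_seeds),
            class = "kx_trainer_config")
}

#' Train a kinetic model on time-series data
#'
#' Runs the gradient-descent loop: evaluate the (mean-centered) loss and its
#' log-space gradient by differentiating through the integrator, clip the
#' gradient by its global norm, apply one AdaBelief update, repeat. Training
#' stops early when the loss falls below `lambda_stop`, and otherwise runs
#' `max_iter` iterations. If integration fails mid-training the result
#' carries status `"failed-at-iteration-k"` together with the best
#' parameters seen so far.
#'
#' `train_multi()` fits several datasets jointly: per iteration it computes
#' the gradient for each dataset, averages them elementwise, then clips and
#' updates once; the reported loss is the mean of the per-dataset losses.
#' `train(model, theta0, dataset, ...)` is the single-dataset case.
#'
#' @param model A `kx_kinetic_model` or `kx_hybrid_model`.
#' @param theta0 Initial parameter vector (linear scale; positive-flagged
#'   entries strictly positive).
#' @param dataset,datasets One [time_series_dataset()], or a list of them.
#' @param config A [trainer_config()].
#' @return A `kx_train_result`: final `theta`, `status` (`"converged-early"`,
#'   `"max-iterations"` or `"failed-at-iteration-k"`), `final_loss`,
#'   best-so-far `best_theta`/`best_loss`, the per-iteration `trace`
#'   (`iteration`, `loss`, `grad_norm`), optional parameter `snapshots`,
#'   and `iterations` (number of updates applied).
#' @export
train <- function(model, theta0, dataset, config = trainer_config()) {
  train_multi(model, theta0, list(dataset), config)
}

#' @rdname train
#' @export
train_multi <- function(model, theta0, datasets, config = trainer_config()) {
  stopifnot(length(datasets) >= 1)
  pos <- model$positive[model$param_ids]
  th0 <- stats::setNames(resolve_theta(model, theta0), model$param_ids)
  state <- log_parameter_state(th0, pos)

  n_iter <- config$max_iter
  trace_loss <- rep(NA_real_, n_iter)
  trace_norm <- rep(NA_real_, n_iter)
  snapshots <- list()
  best_loss <- Inf
  best_theta <- th0
  status <- "max-iterations"
  failed_at <- NA_integer_
  rows <- 0L

  theta <- th0
  for (it in seq_len(n_iter)) {
    evals <- vector("list", length(datasets))
    ok <- TRUE
    for (d in seq_along(datasets)) {
      evals[[d]] <- tryCatch(
        loss_gradient(model, theta, datasets[[d]], config),
        kx_error = function(e) e)
      if (inherits(evals[[d]], "condition")) { ok <- FALSE; break }
    }
    if (!ok) {
      status <- "failed-at-iteration-k"
      failed_at <- it - 1L
      break
    }
    J <- mean(vapply(evals, `[[`, 0, "loss"))
    g <- Reduce(`+`, lapply(evals, `[[`, "gradient")) / length(datasets)
    rows <- rows + 1L
    trace_loss[rows] <- J
    trace_norm[rows] <- global_norm(g)
    if (J < best_loss) { best_loss <- J; best_theta <- theta }
    if (config$snapshot_stride > 0 &&
        (it - 1L) %% config$snapshot_stride == 0L) {
      snapshots[[length(snapshots) + 1L]] <- theta
    }
    if (J < config$lambda_stop) { status <- "converged-early"; break }
    g <- clip_by_global_norm(g, config$clip_norm)
    state <- adabelief_step(state, g, config)
    theta <- get_parameters(state)
  }

  # the trace records pre-update losses; after running out of iterations the
  # final parameters have had one more update, so evaluate them once more
  final_theta <- if (status == "failed-at-iteration-k") best_theta else theta
  final_loss <- if (status == "failed-at-iteration-k") {
    best_loss
  } else if (status == "converged-early") {
    trace_loss[rows]
  } else {
    fl <- tryCatch(
      mean(vapply(datasets, function(d)
        training_loss(model, theta, d, config), 0)),
      kx_error = function(e) NA_real_)
    if (!is.na(fl) && fl < best_loss) { best_loss <- fl; best_theta <- theta }
    if (is.na(fl)) {
      final_theta <- best_theta
      best_loss
    } else fl
  }

  structure(
    list(theta = final_theta, status = status, final_loss = final_loss,
         best_theta = best_theta, best_loss = best_loss,
         iterations = state$step, failed_at = failed_at,
         trace = data.frame(iteration = seq_len(rows) - 1L,
                            loss = trace_loss[seq_len(rows)],
                            grad_norm = trace_norm[seq_len(rows)]),
         snapshots = snapshots),
    class = "kx_train_result")
}

#' @export
print.kx_train_result <- function(x, ...) {
  cat(sprintf("<kx_train_result> status=%s, %d updates, final loss %.4g (best %.4g)\n",
              x$status, x$iterations, x$final_loss, x$best_loss))
  invisible(x)
}

#' Serialize training outputs
#'
#' `write_trace_csv()` writes the per-iteration loss and gradient global
#' norm; `write_train_result_json()` writes the final parameters, status and
#' final loss.
#'
#' @param result A `kx_train_result`.
#' @param file Output path.
#' @export
write_trace_csv <- function(result, file) {
  utils::write.csv(result$trace, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trace_csv
#' @export
write_train_result_json <- function(result, file) {
  jsonlite::write_json(
    list(theta = as.list(result$theta), status = result$status,
         final_loss = result$final_loss, iterations = result$iterations),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
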