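# Mean-centered loss and gradient-norm utilities. The loss normalizes each
# species' residuals by that species' mean observed concentration, so
# metabolites whose concentrations differ by orders of magnitude contribute
# comparably to the objective:
#   J = (1/N) sum_{s,t non-missing} ((pred[s,t] - obs[s,t]) / <obs[s]>)^2

#' Mean-centered mean-squared-error loss
#'
#' Computes the scale-invariant training loss over all non-missing
#' (species, time) observations: squared residuals divided by the squared
#' per-species observation mean, averaged over the number of non-missing
#' pairs. Only species present in the dataset enter the loss; model species
#' without data are unconstrained.
#'
#' @param pred Species-by-time prediction matrix with rownames covering the
#'   dataset's species, sampled at the dataset's times.
#' @param dataset A [time_series_dataset()].
#' @return Scalar loss `J`. A dataset species whose observation mean is zero
#'   raises a `kx_zero_mean_species` error (exclude or rescale it).
#' @export
mean_centered_loss <- function(pred, dataset) {
  stopifnot(inherits(dataset, "kx_dataset"))
  zero <- dataset$species[dataset$means == 0 | !is.finite(dataset$means)]
  if (length(zero) > 0)
    kx_stop("zero-mean-species",
            sprintf("species with zero observation mean: %s",
                    paste(zero, collapse = ", ")))
  missing_sp <- setdiff(dataset$species, rownames(pred))
  if (length(missing_sp) > 0)
    stop(sprintf("prediction lacks species: %s",
                 paste(missing_sp, collapse = ", ")))
  p <- pred[dataset$species, , drop = FALSE]
  resid <- (p - dataset$values) / dataset$means
  mean(resid[!is.na(dataset$values)]^2)
}

# dJ/dpred (species x time), zero at missing entries; internal seed for the
# reverse pass.
mean_centered_loss_seeds <- function(pred, dataset) {
  p <- pred[dataset$species, , drop = FALSE]
  n_obs <- sum(!is.na(dataset$values))
  seeds <- 2 * (p - dataset$values) / (dataset$means^2) / n_obs
  seeds[is.na(dataset$values)] <- 0
  seeds
}

#' Global (L2) norm of a gradient
#'
#' The square root of the sum of squared components across all parameters
#' (and, for hybrid models, network weights); the quantity tracked during
#' training and used for clipping.
#'
#' @param g Numeric gradient vector.
#' @return Scalar norm. Non-finite entries raise `kx_non_finite_gradient`.
#' @export
global_norm <- function(g) {
  if (any(!is.finite(g)))
    kx_stop("non-finite-gradient", "gradient contains non-finite entries")
  sqrt(sum(g^2))
}

#' Clip a gradient by its global norm
#'
#' Returns `g` unchanged when its global norm does not exceed `max_norm`;
#' otherwise rescales it to have norm exactly `max_norm`. Stabilizes
#' training against the exploding gradients common when differentiating
#' through ODE solvers.
#'
#' @param g Numeric gradient vector.
#' @param max_norm Positive clipping threshold (default 4).
#' @return The (possibly rescaled) gradient.
#' @export
clip_by_global_norm <- function(g, max_norm = 4) {
  stopifnot(max_norm > 0)
  nrm <- global_norm(g)
  if (nrm <= max_norm) g else g * (max_norm / nrm)
}

#' Relative improvement of the loss over its initialization
#'
#' `r = (J_init - J_final) / J_init`; reported per training run. When the
#' initialization is already converged (`J_init` below `lambda_stop`) or
#' zero, `r = 0` by convention. Negative values (the loss got worse) are
#' allowed and reported as-is.
#'
#' @param j_init Loss at initialization (iteration 0).
#' @param j_final Loss after training.
#' @param lambda_stop Early-stopping threshold (default `1e-6`).
#' @return Scalar `r`.
#' @export
relative_improvement <- function(j_init, j_final, lambda_stop = 1e-6) {
  if (!is.finite(j_init) || j_init <= 0 || j_init < lambda_stop) return(0)
  (j_init - j_final) / j_init
}
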