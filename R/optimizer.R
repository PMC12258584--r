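# Log-space parameter state and the AdaBelief optimizer. AdaBelief keeps an
# exponential moving average m of the gradient and an EMA s of the squared
# deviation (g - m)^2 -- the "belief" in the gradient direction -- and
# scales the step by 1/sqrt(s-hat):
#   m_t = b1 m_{t-1} + (1 - b1) g
#   s_t = b2 s_{t-1} + (1 - b2) (g - m_t)^2
#   x   <- x - lr * (m_t / (1 - b1^t)) / (sqrt(s_t / (1 - b2^t)) + eps)
# Updates are applied to the transformed coordinates: natural log for
# positive-flagged parameters (guaranteeing positive iterates), identity
# otherwise.

#' Create a log-space parameter state
#'
#' Stores parameter values as natural-log transforms for positive-flagged
#' entries (identity for the rest) together with the optimizer moment
#' accumulators and step counter.
#'
#' @param theta Named numeric vector of (linear-scale) parameter values;
#'   positive-flagged entries must be strictly positive.
#' @param positive Named/positional logical vector of positivity flags
#'   (default all `TRUE`).
#' @return A `kx_param_state`.
#' @seealso [adabelief_step()], [get_parameters()]
#' @export
log_parameter_state <- function(theta,
                                positive = rep(TRUE, length(theta))) {
  stopifnot(length(positive) == length(theta))
  positive <- as.logical(positive)
  if (any(positive & theta <= 0))
    kx_stop("invalid-bounds",
            "positive-flagged parameters must be strictly positive")
  x <- as.numeric(theta)
  x[positive] <- log(x[positive])
  structure(
    list(ids = names(theta), x = as.numeric(x), positive = positive,
         m = numeric(length(theta)), s = numeric(length(theta)),
         step = 0L),
    class = "kx_param_state")
}

#' Recover linear-scale parameters from a state
#'
#' Inverse of the log transform; exact to machine precision.
#'
#' @param state A `kx_param_state`.
#' @return Named numeric vector on the linear scale (strictly positive for
#'   positive-flagged entries).
#' @export
get_parameters <- function(state) {
  stats::setNames(ifelse(state$positive, exp(state$x), state$x), state$ids)
}

#' One AdaBelief update
#'
#' Applies a single AdaBelief step (reference formulation: gradient EMA,
#' belief EMA of the squared deviation, bias correction on both) to the
#' transformed parameter coordinates and increments the step counter.
#'
#' @param state A [log_parameter_state()].
#' @param g Gradient in the transformed (log) space, matching the state
#'   dimension.
#' @param config A [trainer_config()] supplying `learning_rate`, `beta1`,
#'   `beta2`, `epsilon`.
#' @return The updated `kx_param_state`. A non-finite update raises
#'   `kx_diverged_optimizer`.
#' @export
adabelief_step <- function(state, g, config = trainer_config()) {
  stopifnot(inherits(state, "kx_param_state"),
            length(g) == length(state$x))
  g <- as.numeric(g)
  t <- state$step + 1L
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$epsilon
  m <- b1 * state$m + (1 - b1) * g
  s <- b2 * state$s + (1 - b2) * (g - m)^2
  m_hat <- m / (1 - b1^t)
  s_hat <- s / (1 - b2^t)
  x <- state$x - config$learning_rate * m_hat / (sqrt(s_hat) + eps)
  if (any(!is.finite(x)))
    kx_stop("diverged-optimizer", "optimizer produced non-finite parameters")
  state$m <- m; state$s <- s; state$x <- x; state$step <- t
  state
}
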