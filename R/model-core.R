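# Executable form of a model: stoichiometric matrix, compiled flux vector
# and symbolic Jacobians, a pure right-hand side dm/dt = S v(t, m, theta)
# (with per-species compartment division), and stiff integration with
# deSolve's 5th-order implicit Radau IIA solver.

#' Assemble an executable kinetic model
#'
#' `kinetic_model()` builds a model directly from reactions created with
#' [instantiate_law()]; `compile_model()` turns any (possibly SBML-derived)
#' `kx_model_spec` into the same executable form: canonical species order,
#' stoichiometric matrix, bytecode-compiled flux vector `v(t, m, theta)` and
#' its symbolic Jacobians with respect to state and parameters.
#'
#' The trainable parameter registry consists of the global parameters that
#' actually appear in a rate expression, in specification order. All kinetic
#' parameters are flagged positive by default (they are trained in log
#' space); flags can be overridden via `positive`.
#'
#' @param reactions List of `kx_reaction` objects.
#' @param initial Named numeric vector of initial concentrations for every
#'   species appearing in the reactions (order defines the canonical species
#'   order).
#' @param params Optional named numeric vector overriding parameter values
#'   collected from the reactions.
#' @param compartments Named numeric vector of compartment sizes.
#' @param id Model identifier.
#' @return A `kx_kinetic_model`.
#' @export
kinetic_model <- function(reactions, initial, params = NULL,
                          compartments = c(default = 1), id = "model") {
  sp_ids <- names(initial)
  species <- data.frame(id = sp_ids, initial = as.numeric(initial),
                        compartment = names(compartments)[1],
                        boundary = FALSE, constant = FALSE,
                        stringsAsFactors = FALSE)
  theta <- unlist(lapply(reactions, attr, "param_values"))
  if (is.null(theta)) theta <- numeric()
  if (!is.null(params)) theta[names(params)] <- params
  spec <- model_spec(species = species, compartments = compartments,
                     params = theta, reactions = reactions, id = id)
  compile_model(spec)
}

#' @rdname kinetic_model
#' @param spec A `kx_model_spec` (flattened automatically if needed).
#' @param positive Optional named logical vector; `TRUE` entries are
#'   log-transformed during training. Defaults to all `TRUE`.
#' @export
compile_model <- function(spec, positive = NULL) {
  stopifnot(inherits(spec, "kx_model_spec"))
  spec <- flatten_model(spec)
  dyn <- dynamic_species(spec)
  n <- length(dyn)
  r <- length(spec$reactions)
  S <- build_stoichiometric_matrix(spec)

  flux_exprs <- lapply(spec$reactions, `[[`, "rate")
  used <- unique(unlist(lapply(flux_exprs, expr_vars)))
  param_ids <- names(spec$params)[names(spec$params) %in% used]
  theta_ref <- spec$params[param_ids]

  pos <- stats::setNames(rep(TRUE, length(param_ids)), param_ids)
  if (!is.null(positive)) pos[names(positive)] <- positive

  # compartment size per dynamic species (division in the RHS gives
  # concentration ODEs, per SBML semantics for concentration species)
  comp <- unname(vapply(dyn, function(s)
    spec$compartments[[spec$species$compartment[spec$species$id == s]]], 0))

  flux_fun <- compile_vector_fun(flux_exprs, dyn, param_ids)
  # dv/dm: r x n, column-major => expressions ordered (flux varies fastest)
  dvdy_exprs <- unlist(lapply(dyn, function(s)
    lapply(flux_exprs, expr_deriv, var = s)), recursive = FALSE)
  dvdp_exprs <- unlist(lapply(param_ids, function(p)
    lapply(flux_exprs, expr_deriv, var = p)), recursive = FALSE)
  jac_y_fun <- compile_matrix_fun(dvdy_exprs, r, n, dyn, param_ids)
  jac_p_fun <- if (length(param_ids) > 0) {
    compile_matrix_fun(dvdp_exprs, r, length(param_ids), dyn, param_ids)
  } else {
    function(t, y, p) matrix(0, r, 0)
  }

  initial <- stats::setNames(
    spec$species$initial[match(dyn, spec$species$id)], dyn)

  structure(
    list(spec = spec, species = dyn, n = n, n_reactions = r, S = S,
         comp = comp, param_ids = param_ids, theta_ref = theta_ref,
         positive = pos, initial = initial,
         flux_fun = flux_fun, jac_y_fun = jac_y_fun, jac_p_fun = jac_p_fun),
    class = "kx_kinetic_model")
}

#' @export
print.kx_kinetic_model <- function(x, ...) {
  cat(sprintf("<kx_kinetic_model> '%s': %d dynamic species, %d reactions, %d trainable parameters\n",
              x$spec$id, x$n, x$n_reactions, length(x$param_ids)))
  invisible(x)
}

# internal: RHS and vector-Jacobian products for the gradient engine.
# rhs: dm/dt = diag(1/comp) S v. vjp(a): given adjoint vector a (n), return
# list(dy = (d rhs/d m)^T a, dp = (d rhs/d theta)^T a).
model_rhs <- function(model) UseMethod("model_rhs")
model_vjp <- function(model) UseMethod("model_vjp")

#' @export
model_rhs.kx_kinetic_model <- function(model) {
  S <- model$S; comp <- model$comp
  flux <- model$flux_fun
  function(t, y, p) as.numeric(S %*% flux(t, y, p)) / comp
}

#' @export
model_vjp.kx_kinetic_model <- function(model) {
  S <- model$S; comp <- model$comp
  jy <- model$jac_y_fun; jp <- model$jac_p_fun
  function(t, y, p, a) {
    w <- as.numeric(crossprod(S, a / comp))       # r-vector
    list(dy = as.numeric(crossprod(jy(t, y, p), w)),
         dp = as.numeric(crossprod(jp(t, y, p), w)))
  }
}

#' Build the pure right-hand-side function of a model
#'
#' Returns `f(t, m, theta)` computing `dm/dt = S v(t, m, theta)` with each
#' species' row divided by its compartment size. The function is pure: the
#' same inputs always give identical outputs.
#'
#' @param model A `kx_kinetic_model` (or hybrid model).
#' @return A function `f(t, m, theta)` returning a named numeric vector.
#' @export
assemble_rhs <- function(model) {
  rhs <- model_rhs(model)
  ids <- model$param_ids
  sp <- model$species
  function(t, m, theta = model$theta_ref) {
    m <- if (!is.null(names(m))) as.numeric(m[sp]) else as.numeric(m)
    th <- if (!is.null(names(theta))) as.numeric(theta[ids]) else as.numeric(theta)
    stats::setNames(rhs(t, m, th), sp)
  }
}

#' Stiff-solver configuration
#'
#' Defaults follow the training framework's solver settings: a 5th-order
#' implicit adaptive-step stiff solver (Radau IIA) with relative tolerance
#' `1e-8`, absolute tolerance `1e-11`, initial step `1e-10`, and a cap of
#' one million internal steps (exceeding it counts as a failed integration,
#' not an exception, so multi-start screening can tally it).
#'
#' @param rtol,atol Relative / absolute error tolerances.
#' @param dt0 Initial step size.
#' @param max_steps Maximum number of internal solver steps.
#' @param method deSolve method name (`"radau"` or another stiff solver).
#' @return A `kx_solver_config` list.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-11, dt0 = 1e-10,
                          max_steps = 1000000L, method = "radau") {
  stopifnot(rtol > 0, atol > 0, dt0 > 0, max_steps > 0)
  structure(list(rtol = rtol, atol = atol, dt0 = dt0,
                 max_steps = as.integer(max_steps), method = method),
            class = "kx_solver_config")
}

#' Simulate a kinetic model
#'
#' Integrates the model ODEs with an adaptive stiff solver and samples the
#' solution exactly at `times`. Integration failure (step-size underflow,
#' step cap, or a non-finite state) never raises: it returns an unsuccessful
#' trajectory carrying a diagnostic, so screening code can count failures.
#'
#' @param model A `kx_kinetic_model` or `kx_hybrid_model`.
#' @param theta Named (or model-ordered) parameter vector; defaults to the
#'   model's reference values.
#' @param times Ascending numeric vector of output times; integration starts
#'   at `times[1]` (which need not be 0).
#' @param m0 Initial state in canonical species order; defaults to the
#'   model's initial concentrations.
#' @param config A [solver_config()].
#' @return A `kx_trajectory`: list with `times`, `values` (species x time
#'   matrix), `success`, `diagnostic`.
#' @export
simulate_model <- function(model, theta = NULL, times, m0 = NULL,
                           config = solver_config()) {
  if (is.null(theta)) theta <- model_theta_ref(model)
  if (is.null(m0)) m0 <- model$initial
  if (length(times) < 1 || is.unsorted(times, strictly = TRUE) ||
      any(!is.finite(times)))
    stop("`times` must be a non-empty, strictly ascending finite vector")
  if (length(m0) != model$n || any(!is.finite(m0)))
    stop("`m0` must be a finite vector matching the model's species order")
  th <- if (!is.null(names(theta)) && length(names(theta)) > 0) {
    as.numeric(theta[model_param_ids(model)])
  } else as.numeric(theta)

  rhs <- model_rhs(model)
  desolve_fun <- function(t, y, p) list(rhs(t, y, p))
  fail <- function(msg) structure(
    list(times = times,
         values = matrix(NA_real_, model$n, length(times),
                         dimnames = list(model$species, NULL)),
         success = FALSE, diagnostic = msg),
    class = "kx_trajectory")

  out <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = stats::setNames(as.numeric(m0), model$species), times = times,
      func = desolve_fun, parms = th, method = config$method,
      rtol = config$rtol, atol = config$atol, hini = config$dt0,
      maxsteps = config$max_steps)),
    error = function(e) NULL)
  if (is.null(out)) return(fail("solver raised an error (likely divergence)"))
  if (nrow(out) < length(times) ||
      !isTRUE(all.equal(as.numeric(out[, 1]), as.numeric(times))))
    return(fail(sprintf(
      "integration stopped at t = %.6g (step-size underflow or max-steps)",
      out[nrow(out), 1])))
  vals <- t(out[, -1, drop = FALSE])
  rownames(vals) <- model$species
  if (any(!is.finite(vals)))
    return(fail("non-finite state encountered during integration"))
  structure(list(times = times, values = vals, success = TRUE,
                 diagnostic = NULL),
            class = "kx_trajectory")
}

model_theta_ref <- function(model) {
  if (inherits(model, "kx_hybrid_model")) model$theta_ref else model$theta_ref
}
model_param_ids <- function(model) model$param_ids

#' @export
print.kx_trajectory <- function(x, ...) {
  cat(sprintf("<kx_trajectory> %d species x %d times [%g, %g], %s\n",
              nrow(x$values), length(x$times), min(x$times), max(x$times),
              if (x$success) "success" else paste("FAILED:", x$diagnostic)))
  invisible(x)
}

#' @export
as.data.frame.kx_trajectory <- function(x, ...) {
  data.frame(time = x$times, t(x$values), check.names = FALSE)
}

#' Write a trajectory as CSV
#'
#' First column `time`, remaining columns the species in canonical order.
#'
#' @param trajectory A `kx_trajectory`.
#' @param file Output path.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  utils::write.csv(as.data.frame(trajectory), file, row.names = FALSE)
  invisible(file)
}

#' Initial conditions from an observed dataset
#'
#' For each dynamic species, takes the value observed at the dataset's
#' earliest time point when present and non-missing, and falls back to the
#' model's declared initial concentration otherwise.
#'
#' @param model A `kx_kinetic_model` (or hybrid model).
#' @param dataset A [time_series_dataset()].
#' @param unknown What to do with dataset species that match no model
#'   species: `"error"` (default, raises `kx_unknown_species`), `"warn"`,
#'   or `"ignore"`.
#' @return Named numeric initial-state vector in canonical species order.
#' @export
initial_conditions_from_data <- function(model, dataset,
                                         unknown = c("error", "warn",
                                                     "ignore")) {
  unknown <- match.arg(unknown)
  stray <- setdiff(dataset$species, model$species)
  if (length(stray) > 0) {
    msg <- sprintf("dataset species not in model: %s",
                   paste(stray, collapse = ", "))
    if (unknown == "error") kx_stop("unknown-species", msg)
    if (unknown == "warn") kx_warn("unknown-species", msg)
  }
  m0 <- model$initial
  first <- dataset$values[, 1]
  for (sp in intersect(dataset$species, model$species)) {
    v <- first[[sp]]
    if (!is.na(v)) m0[[sp]] <- v
  }
  m0
}
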