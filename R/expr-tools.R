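# Utilities for symbolic rate expressions, represented as R language objects
# (calls/symbols/numerics). Rate laws only ever use arithmetic, powers and
# the elementary functions that stats::D can differentiate, which keeps both
# code generation and symbolic Jacobians simple and dependency-free.

expr_vars <- function(e) all.vars(e)

# Substitute symbols by the language objects / numbers in `map` (named list).
expr_sub <- function(e, map) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% names(map)) return(map[[nm]])
    return(e)
  }
  if (is.call(e)) {
    args <- lapply(as.list(e)[-1], expr_sub, map = map)
    return(as.call(c(e[[1]], args)))
  }
  e
}

# Derivative of expression wrt one symbol, via stats::D. Unsupported
# functions surface as a structured error naming the expression.
expr_deriv <- function(e, var) {
  tryCatch(
    stats::D(e, var),
    error = function(err) kx_stop(
      "unsupported-expression",
      sprintf("cannot differentiate '%s' with respect to '%s': %s",
              paste(deparse(e), collapse = " "), var, conditionMessage(err))
    )
  )
}

# Compile a list of expressions over species/parameter symbols into one
# bytecode-compiled function(t, y, p) returning a numeric vector. Species i
# becomes y[i], parameter j becomes p[j]; everything else must already be a
# literal constant or `t`.
compile_vector_fun <- function(exprs, species, params) {
  if (length(exprs) == 0) return(function(t, y, p) numeric(0))
  map <- c(
    stats::setNames(lapply(seq_along(species), function(i) bquote(y[.(i)])),
                    species),
    stats::setNames(lapply(seq_along(params), function(j) bquote(p[.(j)])),
                    params)
  )
  body_exprs <- lapply(exprs, expr_sub, map = map)
  f <- function(t, y, p) NULL
  body(f) <- as.call(c(quote(c), body_exprs))
  compiler::cmpfun(f)
}

# Same, but the expressions fill a nrow x ncol matrix (column-major order).
compile_matrix_fun <- function(exprs, nrow, ncol, species, params) {
  if (length(exprs) == 0) {
    force(nrow); force(ncol)
    return(function(t, y, p) matrix(0, nrow, ncol))
  }
  map <- c(
    stats::setNames(lapply(seq_along(species), function(i) bquote(y[.(i)])),
                    species),
    stats::setNames(lapply(seq_along(params), function(j) bquote(p[.(j)])),
                    params)
  )
  body_exprs <- lapply(exprs, expr_sub, map = map)
  f <- function(t, y, p) NULL
  body(f) <- bquote(matrix(.(as.call(c(quote(c), body_exprs))),
                           nrow = .(nrow), ncol = .(ncol)))
  compiler::cmpfun(f)
}

# Evaluate an expression against named values (list or named vector).
expr_eval <- function(e, values) {
  eval(e, envir = as.list(values), enclos = baseenv())
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
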