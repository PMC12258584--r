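# Registry of reusable kinetic rate laws for manual model building. Each law
# is data, not code: ordered species roles (substrates, products, modifiers),
# ordered parameter slots, and a symbolic expression over those slots.
# Instantiating a law substitutes concrete species / parameter identifiers
# into the template, producing a reaction indistinguishable from one parsed
# out of SBML.

rate_law <- function(name, expression, substrates = character(),
                     products = character(), modifiers = character(),
                     params = character()) {
  expr <- if (is.character(expression)) str2lang(expression) else expression
  slots <- c(substrates, products, modifiers, params)
  extra <- setdiff(expr_vars(expr), c(slots, "t"))
  if (length(extra) > 0)
    kx_stop("unresolved-symbol",
            sprintf("rate law '%s' references undeclared slots: %s",
                    name, paste(extra, collapse = ", ")))
  structure(list(name = name, substrates = substrates, products = products,
                 modifiers = modifiers, params = params, expr = expr),
            class = "kx_rate_law")
}

#' @export
print.kx_rate_law <- function(x, ...) {
  cat(sprintf("<kx_rate_law> %s: v = %s\n", x$name,
              paste(deparse(x$expr), collapse = " ")))
  invisible(x)
}

# The built-in catalog. Reversible laws are written in the Haldane form,
# parameterized by the equilibrium constant keq, so that the net flux
# vanishes exactly when p1/s1 = keq (thermodynamic consistency).
default_law_definitions <- function() list(
  rate_law("mass_action_irr_uni", "k * s1",
           substrates = "s1", params = "k"),
  rate_law("mass_action_irr_bi", "k * s1 * s2",
           substrates = c("s1", "s2"), params = "k"),
  rate_law("mass_action_rev_uni", "kf * s1 - kr * p1",
           substrates = "s1", products = "p1", params = c("kf", "kr")),
  rate_law("mass_action_rev_bi", "kf * s1 * s2 - kr * p1 * p2",
           substrates = c("s1", "s2"), products = c("p1", "p2"),
           params = c("kf", "kr")),
  rate_law("michaelis_menten_irr", "vmax * s1 / (km_s + s1)",
           substrates = "s1", params = c("vmax", "km_s")),
  rate_law("michaelis_menten_rev",
           "(vmax / km_s) * (s1 - p1 / keq) / (1 + s1 / km_s + p1 / km_p)",
           substrates = "s1", products = "p1",
           params = c("vmax", "km_s", "km_p", "keq")),
  rate_law("hill_activation",
           "vmax * s1^hill_n / (km_s^hill_n + s1^hill_n)",
           substrates = "s1", params = c("vmax", "km_s", "hill_n")),
  rate_law("michaelis_menten_comp_inh",
           "vmax * s1 / (km_s * (1 + m1 / ki) + s1)",
           substrates = "s1", modifiers = "m1",
           params = c("vmax", "km_s", "ki")),
  rate_law("michaelis_menten_noncomp_inh",
           "vmax * s1 / ((km_s + s1) * (1 + m1 / ki))",
           substrates = "s1", modifiers = "m1",
           params = c("vmax", "km_s", "ki")),
  rate_law("ordered_bi_bi_irr",
           "vmax * s1 * s2 / (ki_a * km_b + km_b * s1 + km_a * s2 + s1 * s2)",
           substrates = c("s1", "s2"), products = c("p1", "p2"),
           params = c("vmax", "ki_a", "km_a", "km_b")),
  rate_law("facilitated_diffusion", "vmax * (s1 - p1) / (km + s1 + p1)",
           substrates = "s1", products = "p1", params = c("vmax", "km")),
  rate_law("constant_flux", "v", products = "p1", params = "v")
)

.law_registry <- new.env(parent = emptyenv())

law_registry <- function() {
  if (is.null(.law_registry$laws)) {
    defs <- default_law_definitions()
    .law_registry$laws <- stats::setNames(
      defs, vapply(defs, `[[`, "", "name"))
  }
  .law_registry$laws
}

#' List or register kinetic rate laws
#'
#' `list_laws()` returns the names of all registered rate laws.
#' `register_law()` adds a user-defined law (see the examples in the
#' vignette); the registry is a superset of the canonical enzyme-kinetics
#' laws (mass action, Michaelis-Menten irreversible and Haldane-reversible,
#' Hill activation, competitive and non-competitive inhibition, ordered
#' bi-bi, facilitated diffusion, constant flux) and is freely extensible.
#'
#' @param name Law name.
#' @param expression Symbolic expression (string or language) over the slots.
#' @param substrates,products,modifiers Ordered species-role slot names.
#' @param params Ordered parameter slot names.
#' @return `list_laws()`: a character vector. `register_law()`: the new
#'   `kx_rate_law`, invisibly. `get_law()`: the `kx_rate_law` object.
#' @export
list_laws <- function() names(law_registry())

#' @rdname list_laws
#' @export
register_law <- function(name, expression, substrates = character(),
                         products = character(), modifiers = character(),
                         params = character()) {
  law <- rate_law(name, expression, substrates, products, modifiers, params)
  laws <- law_registry()
  laws[[name]] <- law
  .law_registry$laws <- laws
  invisible(law)
}

#' @rdname list_laws
#' @export
get_law <- function(name) {
  laws <- law_registry()
  if (!name %in% names(laws))
    kx_stop("unknown-mechanism", sprintf("no rate law named '%s'", name))
  laws[[name]]
}

#' Instantiate a kinetic rate law as a reaction
#'
#' Binds concrete species identifiers and parameter values into a registered
#' rate-law template. The resulting reaction carries its stoichiometry
#' (coefficient 1 per substrate/product slot occurrence; bind the same
#' species to two slots for a coefficient of 2) and a symbolic rate
#' expression, and can be mixed freely with SBML-derived reactions.
#' Parameter identifiers are namespaced as `"<id>_<slot>"`.
#'
#' @param name Name of a registered law (see [list_laws()]).
#' @param species Named list/vector mapping species-role slots (e.g. `s1`,
#'   `p1`, `m1`) to species ids.
#' @param params Named numeric vector mapping parameter slots (e.g. `vmax`,
#'   `km_s`) to values.
#' @param id Reaction identifier (defaults to the law name).
#' @return A `kx_reaction`; its `param_values` attribute holds the named
#'   values of the newly created parameters.
#' @examples
#' r <- instantiate_law("michaelis_menten_irr", species = c(s1 = "A"),
#'                      params = c(vmax = 1, km_s = 0.5), id = "v1")
#' @export
instantiate_law <- function(name, species, params, id = name) {
  law <- get_law(name)
  species <- lapply(species, as.character)

  need_sp <- c(law$substrates, law$products, law$modifiers)
  missing_sp <- setdiff(need_sp, names(species))
  if (length(missing_sp) > 0)
    kx_stop("missing-binding",
            sprintf("law '%s': unbound species slot(s): %s",
                    name, paste(missing_sp, collapse = ", ")))
  missing_par <- setdiff(law$params, names(params))
  if (length(missing_par) > 0)
    kx_stop("missing-binding",
            sprintf("law '%s': unbound parameter slot(s): %s",
                    name, paste(missing_par, collapse = ", ")))

  par_ids <- stats::setNames(paste0(id, "_", law$params), law$params)
  map <- c(lapply(species[need_sp], as.symbol),
           stats::setNames(lapply(par_ids, as.symbol), law$params))
  rate <- expr_sub(law$expr, map)

  count_roles <- function(slots) {
    if (length(slots) == 0) return(stats::setNames(numeric(0), character(0)))
    tab <- table(unlist(species[slots]))
    stats::setNames(as.numeric(tab), names(tab))
  }
  rx <- new_reaction(
    id = id,
    reactants = count_roles(law$substrates),
    products = count_roles(law$products),
    modifiers = unique(unlist(species[law$modifiers], use.names = FALSE)),
    rate = rate)
  attr(rx, "param_values") <- stats::setNames(as.numeric(params[law$params]),
                                              par_ids)
  attr(rx, "law") <- name
  rx
}

#' Evaluate the flux of a reaction at given concentrations and parameters
#'
#' @param reaction A `kx_reaction` (from [instantiate_law()] or a parsed
#'   model).
#' @param concentrations Named numeric vector of species concentrations.
#' @param params Named numeric vector of parameter values; defaults to the
#'   values bound at instantiation, if any.
#' @param t Time (for explicitly time-dependent laws).
#' @return Finite scalar flux; a non-finite result raises a
#'   `kx_rate_evaluation` error carrying the law name and inputs.
#' @export
evaluate_rate <- function(reaction, concentrations,
                          params = attr(reaction, "param_values"), t = 0) {
  vals <- c(as.list(concentrations), as.list(params), list(t = t))
  v <- tryCatch(expr_eval(reaction$rate, vals), error = function(e) NaN)
  if (!is.finite(v))
    kx_stop("rate-evaluation",
            sprintf("rate of reaction '%s' evaluated non-finite", reaction$id),
            data = list(reaction = reaction$id,
                        concentrations = concentrations, params = params))
  v
}

#' Serialize the rate-law registry to or from a JSON catalog
#'
#' The catalog stores each law as name, slot lists and the expression as a
#' string, so registries can be shared between sessions or edited by hand.
#'
#' @param file Path to a JSON file.
#' @return `registry_to_json()` returns the path invisibly;
#'   `registry_from_json()` registers all laws found and returns their names.
#' @export
registry_to_json <- function(file) {
  laws <- law_registry()
  cat_list <- lapply(unname(laws), function(l) list(
    name = l$name, substrates = l$substrates, products = l$products,
    modifiers = l$modifiers, params = l$params,
    expression = paste(deparse(l$expr), collapse = " ")))
  jsonlite::write_json(cat_list, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname registry_to_json
#' @export
registry_from_json <- function(file) {
  cat_list <- jsonlite::read_json(file, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  for (l in cat_list) {
    register_law(l$name, l$expression,
                 substrates = unlist(l$substrates) %||% character(),
                 products = unlist(l$products) %||% character(),
                 modifiers = unlist(l$modifiers) %||% character(),
                 params = unlist(l$params) %||% character())
  }
  vapply(cat_list, `[[`, "", "name")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
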