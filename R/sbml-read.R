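# SBML import: parse Level 2/3 documents into a flattened, symbolic model
# description. Supported feature set: compartments, species (amounts or
# concentrations, boundary/constant flags), global and local parameters,
# reactions with MathML kinetic laws, assignment rules, initial assignments
# and function definitions. Events, delays, rate rules and algebraic rules
# are rejected explicitly.

#' Parse an SBML document into a model specification
#'
#' Reads a Systems Biology Markup Language (Level 2 or 3) document and
#' returns a flattened, symbolic description of the model: species with
#' initial concentrations, compartment sizes, global parameters (local
#' reaction parameters are namespaced to `"<reaction>__<parameter>"`),
#' reactions with their stoichiometry and symbolic rate expressions,
#' assignment rules and initial assignments. Function definitions are
#' inlined into the rate expressions at parse time.
#'
#' Species declared through `initialAmount` are converted to concentrations
#' by dividing by their compartment size. Units are carried along but never
#' used for computation; all quantities are treated as concentrations.
#'
#' @param input Path to an SBML file, or a character scalar holding the
#'   document itself.
#' @return A `kx_model_spec` object; see [model_spec()] for the fields.
#' @seealso [flatten_model()], [compile_model()], [export_sbml()]
#' @export
parse_sbml <- function(input) {
  doc <- if (length(input) == 1 && grepl("^\\s*<", input)) {
    xml2::read_xml(input)
  } else {
    xml2::read_xml(input[[1]])
  }
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing"))
    kx_stop("unsupported-SBML-feature", "document contains no <model> element")

  reject <- function(xpath, what) {
    hits <- xml2::xml_find_all(model, xpath)
    if (length(hits) > 0)
      kx_stop("unsupported-SBML-feature",
              sprintf("%s are not supported (found <%s>)", what,
                      xml2::xml_name(hits[[1]])))
  }
  reject(".//listOfEvents/event", "events")
  reject(".//algebraicRule", "algebraic rules")
  reject(".//rateRule", "rate rules")
  reject(".//delay", "delay terms")

  num_attr <- function(node, attr, default = NA_real_) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else as.numeric(v)
  }
  bool_attr <- function(node, attr, default = FALSE) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else identical(v, "true")
  }

  # compartments
  comp_nodes <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  compartments <- stats::setNames(
    vapply(comp_nodes, function(n) {
      s <- num_attr(n, "size", num_attr(n, "volume", 1))
      if (is.na(s)) 1 else s
    }, 0),
    vapply(comp_nodes, xml2::xml_attr, "", attr = "id"))
  if (length(compartments) == 0) compartments <- c(default = 1)

  # species
  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  species <- do.call(rbind, lapply(sp_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    comp <- xml2::xml_attr(n, "compartment")
    if (is.na(comp)) comp <- names(compartments)[1]
    csize <- if (comp %in% names(compartments)) compartments[[comp]] else 1
    conc <- num_attr(n, "initialConcentration")
    if (is.na(conc)) {
      amt <- num_attr(n, "initialAmount")
      conc <- if (is.na(amt)) 0 else amt / csize
    }
    data.frame(id = id, initial = conc, compartment = comp,
               boundary = bool_attr(n, "boundaryCondition"),
               constant = bool_attr(n, "constant"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(species))
    species <- data.frame(id = character(), initial = numeric(),
                          compartment = character(), boundary = logical(),
                          constant = logical(), stringsAsFactors = FALSE)
  if (anyDuplicated(species$id))
    kx_stop("unresolved-symbol", "duplicate species ids in document")

  # global parameters
  par_nodes <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  # exclude kineticLaw-local <parameter> (L2 places them under kineticLaw)
  par_nodes <- par_nodes[!vapply(par_nodes, function(n) {
    any(xml2::xml_name(xml2::xml_parents(n)) == "kineticLaw")
  }, TRUE)]
  global_params <- stats::setNames(
    vapply(par_nodes, num_attr, 0, attr = "value", default = NA_real_),
    vapply(par_nodes, xml2::xml_attr, "", attr = "id"))

  # function definitions (lambda)
  fn_nodes <- xml2::xml_find_all(model,
                                 ".//listOfFunctionDefinitions/functionDefinition")
  functions <- stats::setNames(lapply(fn_nodes, function(n) {
    lam <- xml2::xml_find_first(n, ".//lambda")
    kids <- mathml_children(lam)
    bvars <- vapply(kids[-length(kids)], function(b)
      trimws(xml2::xml_text(xml2::xml_find_first(b, ".//ci"))), "")
    body <- mathml_to_expr(kids[[length(kids)]])
    list(args = bvars, body = body)
  }), vapply(fn_nodes, xml2::xml_attr, "", attr = "id"))

  math_of <- function(node) {
    m <- xml2::xml_find_first(node, "./math")
    if (inherits(m, "xml_missing"))
      kx_stop("unsupported-SBML-feature", "missing <math> element")
    inline_functions(mathml_to_expr(m), functions)
  }

  # rules / initial assignments
  rule_nodes <- xml2::xml_find_all(model, ".//assignmentRule")
  rules <- stats::setNames(lapply(rule_nodes, math_of),
                           vapply(rule_nodes, function(n) {
                             v <- xml2::xml_attr(n, "variable")
                             if (is.na(v)) xml2::xml_attr(n, "symbol") else v
                           }, ""))
  ia_nodes <- xml2::xml_find_all(model, ".//initialAssignment")
  initial_assignments <- stats::setNames(
    lapply(ia_nodes, math_of),
    vapply(ia_nodes, xml2::xml_attr, "", attr = "symbol"))

  # reactions
  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- list()
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    stoich_of <- function(xpath) {
      refs <- xml2::xml_find_all(rx, xpath)
      if (length(refs) == 0) return(stats::setNames(numeric(0), character(0)))
      ids <- vapply(refs, xml2::xml_attr, "", attr = "species")
      coefs <- vapply(refs, num_attr, 0, attr = "stoichiometry", default = 1)
      if (any(!is.finite(coefs)))
        kx_stop("unresolved-symbol",
                sprintf("non-finite stoichiometry in reaction '%s'", rid))
      tapply_sum <- tapply(coefs, ids, sum)
      stats::setNames(as.numeric(tapply_sum), names(tapply_sum))
    }
    reactants <- stoich_of("./listOfReactants/speciesReference")
    products <- stoich_of("./listOfProducts/speciesReference")
    modifiers <- vapply(
      xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference"),
      xml2::xml_attr, "", attr = "species")

    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      kx_stop("unsupported-SBML-feature",
              sprintf("reaction '%s' has no kineticLaw", rid))
    rate <- math_of(kl)

    # local parameters: namespace as "<reaction>__<param>"
    loc_nodes <- c(
      xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter"),
      xml2::xml_find_all(kl, "./listOfParameters/parameter"))
    if (length(loc_nodes) > 0) {
      loc_ids <- vapply(loc_nodes, xml2::xml_attr, "", attr = "id")
      loc_vals <- vapply(loc_nodes, num_attr, 0, attr = "value",
                         default = NA_real_)
      new_ids <- paste0(rid, "__", loc_ids)
      rate <- expr_sub(rate, stats::setNames(lapply(new_ids, as.symbol),
                                             loc_ids))
      global_params[new_ids] <- loc_vals
    }

    reactions[[length(reactions) + 1]] <- new_reaction(
      id = rid, reactants = reactants, products = products,
      modifiers = modifiers, rate = rate)
  }

  spec <- model_spec(
    species = species, compartments = compartments,
    params = global_params, reactions = reactions,
    rules = rules, initial_assignments = initial_assignments,
    functions = functions,
    id = xml2::xml_attr(model, "id"))
  validate_spec_symbols(spec)
  spec
}

# Recursively replace calls to functionDefinitions by their inlined body.
inline_functions <- function(e, fns, depth = 0) {
  if (depth > 50)
    kx_stop("cyclic-rule", "function definitions are cyclically nested")
  if (is.call(e)) {
    fname <- if (is.symbol(e[[1]])) as.character(e[[1]]) else ""
    args <- lapply(as.list(e)[-1], inline_functions, fns = fns, depth = depth)
    if (fname %in% names(fns)) {
      fd <- fns[[fname]]
      if (length(args) != length(fd$args))
        kx_stop("unresolved-symbol",
                sprintf("function '%s' called with %d arguments, expects %d",
                        fname, length(args), length(fd$args)))
      inlined <- expr_sub(fd$body, stats::setNames(args, fd$args))
      return(inline_functions(inlined, fns, depth + 1))
    }
    return(as.call(c(e[[1]], args)))
  }
  e
}

#' Construct a model specification
#'
#' Low-level constructor for the declarative model description that
#' [parse_sbml()] produces and [compile_model()] consumes. Most users build
#' models from SBML or from the rate-law registry instead of calling this.
#'
#' @param species `data.frame` with columns `id`, `initial` (concentration),
#'   `compartment`, `boundary`, `constant`.
#' @param compartments Named numeric vector of compartment sizes.
#' @param params Named numeric vector of global parameter values (local
#'   reaction parameters already namespaced).
#' @param reactions List of reaction objects (see [instantiate_law()]).
#' @param rules Named list of assignment-rule expressions (target -> expr).
#' @param initial_assignments Named list of initial-assignment expressions.
#' @param functions Named list of function definitions (`args`, `body`).
#' @param id Model identifier.
#' @return A `kx_model_spec` list.
#' @export
model_spec <- function(species, compartments = c(default = 1),
                       params = numeric(), reactions = list(),
                       rules = list(), initial_assignments = list(),
                       functions = list(), id = "model") {
  stopifnot(is.data.frame(species),
            all(c("id", "initial", "compartment", "boundary", "constant")
                %in% names(species)))
  if (any(!is.finite(species$initial)))
    kx_stop("unresolved-symbol", "non-finite species initial value")
  ids <- c(species$id, names(params), names(compartments),
           vapply(reactions, `[[`, "", "id"))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    kx_stop("unresolved-symbol",
            sprintf("duplicated identifiers: %s",
                    paste(unique(dup), collapse = ", ")))
  structure(
    list(species = species, compartments = compartments, params = params,
         reactions = reactions, rules = rules,
         initial_assignments = initial_assignments, functions = functions,
         id = if (is.na(id) || is.null(id)) "model" else id,
         flattened = FALSE),
    class = "kx_model_spec")
}

new_reaction <- function(id, reactants, products, modifiers, rate) {
  if (any(modifiers %in% c(names(reactants), names(products))))
    kx_stop("unresolved-symbol",
            sprintf("modifiers of reaction '%s' overlap its stoichiometry", id))
  structure(list(id = id, reactants = reactants, products = products,
                 modifiers = modifiers, rate = rate),
            class = "kx_reaction")
}

# every free symbol in every rate/rule must resolve
validate_spec_symbols <- function(spec) {
  known <- c(spec$species$id, names(spec$params), names(spec$compartments),
             names(spec$rules), "t")
  for (rx in spec$reactions) {
    unknown <- setdiff(expr_vars(rx$rate), known)
    if (length(unknown) > 0)
      kx_stop("unresolved-symbol",
              sprintf("reaction '%s' references unknown symbols: %s",
                      rx$id, paste(unknown, collapse = ", ")))
  }
  for (nm in names(spec$rules)) {
    unknown <- setdiff(expr_vars(spec$rules[[nm]]), known)
    if (length(unknown) > 0)
      kx_stop("unresolved-symbol",
              sprintf("rule for '%s' references unknown symbols: %s",
                      nm, paste(unknown, collapse = ", ")))
  }
  invisible(spec)
}

#' @export
print.kx_model_spec <- function(x, ...) {
  dyn <- dynamic_species(x)
  cat(sprintf("<kx_model_spec> '%s': %d species (%d dynamic), %d reactions, %d parameters%s\n",
              x$id, nrow(x$species), length(dyn), length(x$reactions),
              length(x$params),
              if (x$flattened) " [flattened]" else ""))
  invisible(x)
}

dynamic_species <- function(spec) {
  keep <- !spec$species$boundary & !spec$species$constant &
    !(spec$species$id %in% names(spec$rules))
  spec$species$id[keep]
}

#' Flatten a model specification
#'
#' Resolves everything that stands between a parsed model and a pure
#' right-hand side: assignment rules are substituted into the rate
#' expressions (iterated to a fixpoint; cycles raise a `kx_cyclic_rule`
#' error), initial assignments are evaluated and applied to initial values,
#' compartment sizes are substituted as numeric constants, and boundary /
#' constant species are replaced by their (fixed) initial concentrations and
#' removed from the dynamic state.
#'
#' @param spec A `kx_model_spec` from [parse_sbml()] or [model_spec()].
#' @return A flattened `kx_model_spec` (idempotent).
#' @export
flatten_model <- function(spec) {
  stopifnot(inherits(spec, "kx_model_spec"))
  if (isTRUE(spec$flattened)) return(spec)

  # resolve rules against each other to fixpoint
  rules <- spec$rules
  if (length(rules) > 0) {
    for (i in seq_len(length(rules) + 1)) {
      resolved <- lapply(rules, expr_sub, map = rules)
      if (identical(deparse(resolved), deparse(rules))) break
      rules <- resolved
      if (i == length(rules) + 1 &&
          any(vapply(rules, function(e)
            any(expr_vars(e) %in% names(rules)), TRUE)))
        kx_stop("cyclic-rule", "assignment rules are cyclic")
    }
    if (any(vapply(rules, function(e) any(expr_vars(e) %in% names(rules)), TRUE)))
      kx_stop("cyclic-rule", "assignment rules are cyclic")
  }

  # initial assignments: evaluate numerically against current values
  env0 <- c(as.list(spec$params), as.list(spec$compartments),
            stats::setNames(as.list(spec$species$initial), spec$species$id))
  for (nm in names(spec$initial_assignments)) {
    val <- tryCatch(expr_eval(spec$initial_assignments[[nm]], env0),
                    error = function(e) kx_stop(
                      "unresolved-symbol",
                      sprintf("cannot evaluate initial assignment for '%s'", nm)))
    if (nm %in% spec$species$id) {
      spec$species$initial[spec$species$id == nm] <- val
    } else if (nm %in% names(spec$params)) {
      spec$params[[nm]] <- val
    } else if (nm %in% names(spec$compartments)) {
      spec$compartments[[nm]] <- val
    }
    env0[[nm]] <- val
  }

  # constants to substitute into expressions: compartments, fixed species,
  # and rule targets (rules themselves substituted symbolically first)
  fixed <- spec$species$boundary | spec$species$constant
  const_map <- c(
    stats::setNames(as.list(spec$compartments), names(spec$compartments)),
    stats::setNames(as.list(spec$species$initial[fixed]),
                    spec$species$id[fixed]))

  spec$reactions <- lapply(spec$reactions, function(rx) {
    rx$rate <- expr_sub(expr_sub(rx$rate, rules), const_map)
    rx
  })
  spec$rules <- rules
  spec$flattened <- TRUE
  spec
}

#' Build the stoichiometric matrix of a flattened model
#'
#' Entry `S[i, j]` is the net stoichiometric coefficient (products minus
#' reactants) of dynamic species `i` in reaction `j`. Modifiers contribute
#' zero. Rows follow the canonical species order (document order of dynamic
#' species), columns follow document reaction order.
#'
#' @param spec A `kx_model_spec` (flattened or not; boundary and constant
#'   species are excluded either way).
#' @return Numeric matrix of dimension `n_dynamic_species x n_reactions`
#'   with dimnames.
#' @export
build_stoichiometric_matrix <- function(spec) {
  stopifnot(inherits(spec, "kx_model_spec"))
  dyn <- dynamic_species(spec)
  S <- matrix(0, nrow = length(dyn), ncol = length(spec$reactions),
              dimnames = list(dyn, vapply(spec$reactions, `[[`, "", "id")))
  for (j in seq_along(spec$reactions)) {
    rx <- spec$reactions[[j]]
    for (sp in names(rx$reactants)) {
      if (sp %in% dyn) S[sp, j] <- S[sp, j] - rx$reactants[[sp]]
    }
    for (sp in names(rx$products)) {
      if (sp %in% dyn) S[sp, j] <- S[sp, j] + rx$products[[sp]]
    }
  }
  S
}
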