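# Content-MathML <-> R expression conversion for SBML kinetic laws, rules,
# initial assignments and function definitions. The supported operator set
# covers the arithmetic/elementary-function subset used by kinetic rate laws;
# anything else (piecewise, relational operators, delay, ...) is rejected
# with an "unsupported-SBML-feature" error rather than silently misparsed.

MATHML_TIME_URL <- "http://www.sbml.org/sbml/symbols/time"
MATHML_DELAY_URL <- "http://www.sbml.org/sbml/symbols/delay"
MATHML_AVOGADRO_URL <- "http://www.sbml.org/sbml/symbols/avogadro"

mathml_children <- function(node) {
  kids <- xml2::xml_children(node)
  kids[xml2::xml_name(kids) != "annotation"]
}

# node: an element inside <math>. Returns an R language object.
mathml_to_expr <- function(node, time_symbol = "t") {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- mathml_children(node)
    if (length(kids) != 1L)
      kx_stop("unsupported-SBML-feature", "<math> must contain one expression")
    return(mathml_to_expr(kids[[1]], time_symbol))
  }
  switch(
    name,
    cn = mathml_parse_cn(node),
    ci = as.symbol(trimws(xml2::xml_text(node))),
    csymbol = {
      url <- xml2::xml_attr(node, "definitionURL")
      if (!is.na(url) && grepl("symbols/time$", url)) as.symbol(time_symbol)
      else if (!is.na(url) && grepl("avogadro$", url)) 6.02214076e23
      else kx_stop("unsupported-SBML-feature",
                   sprintf("csymbol '%s' (%s) is not supported",
                           trimws(xml2::xml_text(node)), url))
    },
    apply = mathml_parse_apply(node, time_symbol),
    pi = pi,
    exponentiale = exp(1),
    `true` = TRUE,
    `false` = FALSE,
    notanumber = NaN,
    infinity = Inf,
    piecewise = kx_stop("unsupported-SBML-feature",
                        "piecewise expressions are not supported"),
    kx_stop("unsupported-SBML-feature",
            sprintf("MathML element <%s> is not supported", name))
  )
}

mathml_parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (is.na(type)) type <- "real"
  if (type %in% c("real", "integer")) {
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  # e-notation / rational hold two numbers separated by <sep/>
  parts <- strsplit(xml2::xml_text(node), "\\s+")[[1]]
  parts <- as.numeric(parts[nzchar(parts)])
  if (length(parts) != 2 || anyNA(parts))
    kx_stop("unsupported-SBML-feature",
            sprintf("cannot parse <cn type='%s'>", type))
  if (type == "e-notation") return(parts[1] * 10^parts[2])
  if (type == "rational") return(parts[1] / parts[2])
  kx_stop("unsupported-SBML-feature", sprintf("<cn type='%s'>", type))
}

mathml_parse_apply <- function(node, time_symbol) {
  kids <- mathml_children(node)
  if (length(kids) < 1L)
    kx_stop("unsupported-SBML-feature", "empty <apply>")
  op <- xml2::xml_name(kids[[1]])
  argnodes <- kids[-1]

  if (op == "ci") {
    # user-defined function call (functionDefinition), inlined later
    fname <- as.symbol(trimws(xml2::xml_text(kids[[1]])))
    args <- lapply(argnodes, mathml_to_expr, time_symbol = time_symbol)
    return(as.call(c(fname, args)))
  }

  nary <- function(fun, identity) {
    args <- lapply(argnodes, mathml_to_expr, time_symbol = time_symbol)
    if (length(args) == 0L) return(identity)
    Reduce(function(a, b) call(fun, a, b), args)
  }
  unary_named <- function(fun) {
    if (length(argnodes) != 1L)
      kx_stop("unsupported-SBML-feature", sprintf("<%s> expects 1 argument", op))
    call(fun, mathml_to_expr(argnodes[[1]], time_symbol))
  }

  switch(
    op,
    plus = nary("+", 0),
    times = nary("*", 1),
    minus = {
      args <- lapply(argnodes, mathml_to_expr, time_symbol = time_symbol)
      if (length(args) == 1L) call("-", args[[1]])
      else if (length(args) == 2L) call("-", args[[1]], args[[2]])
      else kx_stop("unsupported-SBML-feature", "<minus> expects 1 or 2 arguments")
    },
    divide = {
      args <- lapply(argnodes, mathml_to_expr, time_symbol = time_symbol)
      if (length(args) != 2L)
        kx_stop("unsupported-SBML-feature", "<divide> expects 2 arguments")
      call("/", args[[1]], args[[2]])
    },
    power = {
      args <- lapply(argnodes, mathml_to_expr, time_symbol = time_symbol)
      if (length(args) != 2L)
        kx_stop("unsupported-SBML-feature", "<power> expects 2 arguments")
      call("^", args[[1]], args[[2]])
    },
    root = {
      degree <- xml2::xml_find_first(node, "./*[local-name()='degree']")
      arg <- mathml_to_expr(argnodes[[length(argnodes)]], time_symbol)
      if (inherits(degree, "xml_missing")) call("sqrt", arg)
      else call("^", arg, call("/", 1,
                               mathml_to_expr(mathml_children(degree)[[1]],
                                              time_symbol)))
    },
    exp = unary_named("exp"),
    ln = unary_named("log"),
    log = {
      base_node <- xml2::xml_find_first(node, "./*[local-name()='logbase']")
      arg <- mathml_to_expr(argnodes[[length(argnodes)]], time_symbol)
      base <- if (inherits(base_node, "xml_missing")) 10 else
        mathml_to_expr(mathml_children(base_node)[[1]], time_symbol)
      call("log", arg, base)
    },
    abs = unary_named("abs"),
    floor = unary_named("floor"),
    ceiling = unary_named("ceiling"),
    sin = unary_named("sin"),
    cos = unary_named("cos"),
    tan = unary_named("tan"),
    sinh = unary_named("sinh"),
    cosh = unary_named("cosh"),
    tanh = unary_named("tanh"),
    kx_stop("unsupported-SBML-feature",
            sprintf("MathML operator <%s> is not supported", op))
  )
}

# ---- writer ----------------------------------------------------------------

mathml_num <- function(x) {
  if (x == round(x) && abs(x) < 1e15) {
    return(sprintf("<cn type=\"integer\"> %d </cn>", as.integer(x)))
  }
  s <- sprintf("%.17g", x)
  if (grepl("[eE]", s)) {
    parts <- strsplit(s, "[eE]")[[1]]
    return(sprintf("<cn type=\"e-notation\"> %s <sep/> %s </cn>",
                   parts[1], as.integer(parts[2])))
  }
  sprintf("<cn> %s </cn>", s)
}

expr_to_mathml <- function(e, time_symbol = "t") {
  if (is.numeric(e) || is.integer(e)) return(mathml_num(as.numeric(e)))
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm == time_symbol) {
      return(sprintf(
        "<csymbol encoding=\"text\" definitionURL=\"%s\"> t </csymbol>",
        MATHML_TIME_URL))
    }
    return(sprintf("<ci> %s </ci>", nm))
  }
  if (!is.call(e))
    kx_stop("unsupported-expression",
            sprintf("cannot serialize '%s' to MathML", deparse(e)))
  fun <- as.character(e[[1]])
  args <- as.list(e)[-1]
  wrap <- function(op, parts)
    sprintf("<apply> <%s/> %s </apply>", op, paste(parts, collapse = " "))
  parts <- function() vapply(args, expr_to_mathml, "", time_symbol = time_symbol)
  switch(
    fun,
    "(" = expr_to_mathml(args[[1]], time_symbol),
    "+" = wrap("plus", parts()),
    "-" = wrap("minus", parts()),
    "*" = wrap("times", parts()),
    "/" = wrap("divide", parts()),
    "^" = wrap("power", parts()),
    exp = wrap("exp", parts()),
    sqrt = wrap("root", parts()),
    abs = wrap("abs", parts()),
    sin = wrap("sin", parts()),
    cos = wrap("cos", parts()),
    tan = wrap("tan", parts()),
    tanh = wrap("tanh", parts()),
    log = {
      if (length(args) == 1L) wrap("ln", parts())
      else sprintf(
        "<apply> <log/> <logbase> %s </logbase> %s </apply>",
        expr_to_mathml(args[[2]], time_symbol),
        expr_to_mathml(args[[1]], time_symbol))
    },
    kx_stop("unsupported-expression",
            sprintf("function '%s' cannot be serialized to MathML", fun))
  )
}
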