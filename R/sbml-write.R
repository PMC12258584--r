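# SBML export: write a model specification (possibly re-parameterized) as an
# SBML Level 3 Version 2 document. The writer emits exactly the feature
# subset the reader supports, so parse -> export -> parse is idempotent.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a model specification to SBML
#'
#' Writes a `kx_model_spec` as an SBML Level 3 Version 2 document, optionally
#' overriding parameter values first. All parameters (including namespaced
#' former local parameters) are written as global parameters. Re-parsing the
#' exported document yields an equivalent flattened model.
#'
#' @param spec A `kx_model_spec`.
#' @param theta Optional named numeric vector of parameter values to write;
#'   every name must be an existing parameter id (otherwise a
#'   `kx_unknown_parameter` error is raised).
#' @param file Optional path; when given, the document is written there.
#' @return The SBML document as a character scalar (invisibly when `file`
#'   is given).
#' @export
export_sbml <- function(spec, theta = NULL, file = NULL) {
  stopifnot(inherits(spec, "kx_model_spec"))
  params <- spec$params
  if (!is.null(theta)) {
    unknown <- setdiff(names(theta), names(params))
    if (length(unknown) > 0)
      kx_stop("unknown-parameter",
              sprintf("unknown parameter id(s): %s",
                      paste(unknown, collapse = ", ")))
    params[names(theta)] <- theta
  }

  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" ",
           "level=\"3\" version=\"2\">"),
    sprintf("  <model id=\"%s\">", xml_escape(spec$id)))

  lines <- c(lines, "    <listOfCompartments>")
  for (nm in names(spec$compartments)) {
    lines <- c(lines, sprintf(
      "      <compartment id=\"%s\" size=\"%s\" constant=\"true\"/>",
      xml_escape(nm), num(spec$compartments[[nm]])))
  }
  lines <- c(lines, "    </listOfCompartments>")

  if (nrow(spec$species) > 0) {
    lines <- c(lines, "    <listOfSpecies>")
    for (i in seq_len(nrow(spec$species))) {
      sp <- spec$species[i, ]
      lines <- c(lines, sprintf(
        paste0("      <species id=\"%s\" compartment=\"%s\" ",
               "initialConcentration=\"%s\" boundaryCondition=\"%s\" ",
               "constant=\"%s\" hasOnlySubstanceUnits=\"false\"/>"),
        xml_escape(sp$id), xml_escape(sp$compartment), num(sp$initial),
        tolower(sp$boundary), tolower(sp$constant)))
    }
    lines <- c(lines, "    </listOfSpecies>")
  }

  if (length(params) > 0) {
    lines <- c(lines, "    <listOfParameters>")
    for (nm in names(params)) {
      lines <- c(lines, sprintf(
        "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
        xml_escape(nm), num(params[[nm]])))
    }
    lines <- c(lines, "    </listOfParameters>")
  }

  math_block <- function(e, indent) {
    paste0(indent,
           "<math xmlns=\"http://www.w3.org/1998/Math/MathML\"> ",
           expr_to_mathml(e), " </math>")
  }

  if (length(spec$rules) > 0) {
    lines <- c(lines, "    <listOfRules>")
    for (nm in names(spec$rules)) {
      lines <- c(lines,
                 sprintf("      <assignmentRule variable=\"%s\">", xml_escape(nm)),
                 math_block(spec$rules[[nm]], "        "),
                 "      </assignmentRule>")
    }
    lines <- c(lines, "    </listOfRules>")
  }

  if (length(spec$reactions) > 0) {
    lines <- c(lines, "    <listOfReactions>")
    for (rx in spec$reactions) {
      lines <- c(lines, sprintf(
        "      <reaction id=\"%s\" reversible=\"false\">", xml_escape(rx$id)))
      ref_block <- function(tag, stoich) {
        if (length(stoich) == 0) return(character(0))
        c(sprintf("        <listOf%ss>", tag),
          vapply(names(stoich), function(sp) sprintf(
            paste0("          <speciesReference species=\"%s\" ",
                   "stoichiometry=\"%s\" constant=\"true\"/>"),
            xml_escape(sp), num(stoich[[sp]])), ""),
          sprintf("        </listOf%ss>", tag))
      }
      lines <- c(lines, ref_block("Reactant", rx$reactants),
                 ref_block("Product", rx$products))
      if (length(rx$modifiers) > 0) {
        lines <- c(lines, "        <listOfModifiers>",
                   vapply(rx$modifiers, function(sp) sprintf(
                     "          <modifierSpeciesReference species=\"%s\"/>",
                     xml_escape(sp)), ""),
                   "        </listOfModifiers>")
      }
      lines <- c(lines,
                 "        <kineticLaw>",
                 math_block(rx$rate, "          "),
                 "        </kineticLaw>",
                 "      </reaction>")
    }
    lines <- c(lines, "    </listOfReactions>")
  }

  lines <- c(lines, "  </model>", "</sbml>")
  doc <- paste(lines, collapse = "\n")

  # sanity: emitted document must be well-formed XML
  xml2::read_xml(doc)

  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
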