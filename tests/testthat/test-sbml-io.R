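test_that("a toy mass-action document parses into the expected model", {
  spec <- parse_sbml(toy_sbml(0.5))
  expect_s3_class(spec, "kx_model_spec")
  expect_equal(spec$species$id, c("A", "B"))
  expect_equal(spec$species$initial, c(2, 0))
  expect_length(spec$reactions, 1)
  expect_equal(spec$params, c(k = 0.5))
  rx <- spec$reactions[[1]]
  expect_equal(rx$reactants, c(A = 1))
  expect_equal(rx$products, c(B = 1))
  expect_equal(deparse(rx$rate), "k * A")
})

test_that("local parameters are namespaced per reaction and do not collide", {
  doc <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="m">
    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" initialConcentration="1" boundaryCondition="false" constant="false"/>
      <species id="B" compartment="c" initialConcentration="1" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1"><listOfReactants><speciesReference species="A" constant="true"/></listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci>k</ci><ci>A</ci></apply></math>
          <listOfLocalParameters><localParameter id="k" value="0.1"/></listOfLocalParameters>
        </kineticLaw></reaction>
      <reaction id="R2"><listOfReactants><speciesReference species="B" constant="true"/></listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci>k</ci><ci>B</ci></apply></math>
          <listOfLocalParameters><localParameter id="k" value="0.2"/></listOfLocalParameters>
        </kineticLaw></reaction>
    </listOfReactions>
  </model>
</sbml>'
  spec <- parse_sbml(doc)
  expect_setequal(names(spec$params), c("R1__k", "R2__k"))
  expect_equal(spec$params[["R1__k"]], 0.1)
  expect_equal(spec$params[["R2__k"]], 0.2)
  expect_equal(deparse(spec$reactions[[1]]$rate), "R1__k * A")
})

test_that("function definitions are inlined into kinetic laws", {
  doc <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="m">
    <listOfFunctionDefinitions>
      <functionDefinition id="f">
        <math xmlns="http://www.w3.org/1998/Math/MathML">
          <lambda><bvar><ci>x</ci></bvar>
            <apply><times/><cn type="integer">2</cn><ci>x</ci></apply>
          </lambda>
        </math>
      </functionDefinition>
    </listOfFunctionDefinitions>
    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" initialConcentration="1" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1"><listOfReactants><speciesReference species="A" constant="true"/></listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><ci>f</ci><ci>A</ci></apply>
          </math>
        </kineticLaw></reaction>
    </listOfReactions>
  </model>
</sbml>'
  spec <- parse_sbml(doc)
  # manual substitution oracle: f(A) = 2*A
  expect_equal(deparse(spec$reactions[[1]]$rate), "2 * A")
})

test_that("unsupported features and unresolved symbols raise structured errors", {
  ev <- sub("<listOfReactions>",
            "<listOfEvents><event id=\"e\"/></listOfEvents><listOfReactions>",
            toy_sbml())
  expect_error(parse_sbml(ev), class = "kx_unsupported_SBML_feature")
  bad <- sub("<ci> k </ci>", "<ci> nosuch </ci>", toy_sbml())
  expect_error(parse_sbml(bad), class = "kx_unresolved_symbol")
})

test_that("flattening substitutes rules, fixes boundary species, detects cycles", {
  base <- function(rules) sprintf('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="m">
    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" initialConcentration="1" boundaryCondition="false" constant="false"/>
      <species id="P" compartment="c" initialConcentration="0.5" boundaryCondition="false" constant="false"/>
      <species id="Glc_ext" compartment="c" initialConcentration="7" boundaryCondition="true" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k" value="0.3" constant="true"/>
      <parameter id="E" value="0" constant="false"/>
      <parameter id="a" value="0" constant="false"/>
      <parameter id="b" value="0" constant="false"/>
      <parameter id="cc" value="4" constant="true"/>
    </listOfParameters>
    %s
    <listOfReactions>
      <reaction id="R1"><listOfReactants><speciesReference species="A" constant="true"/></listOfReactants>
        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">
          <apply><times/><ci>k</ci><ci>E</ci><ci>A</ci><ci>Glc_ext</ci></apply>
        </math></kineticLaw></reaction>
    </listOfReactions>
  </model>
</sbml>', rules)

  rules_ok <- '<listOfRules>
    <assignmentRule variable="E"><math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><cn type="integer">2</cn><ci>P</ci></apply></math></assignmentRule>
    <assignmentRule variable="a"><math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><cn type="integer">2</cn><ci>b</ci></apply></math></assignmentRule>
    <assignmentRule variable="b"><math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><cn type="integer">3</cn><ci>cc</ci></apply></math></assignmentRule>
  </listOfRules>'
  spec <- flatten_model(parse_sbml(base(rules_ok)))
  rate <- spec$reactions[[1]]$rate
  # rule E = 2*P substituted; boundary species Glc_ext fixed at 7
  vals <- c(A = 1.5, P = 0.5, k = 0.3)
  expect_equal(eval(rate, as.list(vals)), 0.3 * (2 * 0.5) * 1.5 * 7)
  expect_false("Glc_ext" %in% all.vars(rate))
  # chained rules resolve to a fixpoint: a = 2*b = 6*cc
  expect_equal(eval(spec$rules[["a"]], list(cc = 4)), 24)
  # boundary species excluded from the dynamic state
  m <- compile_model(spec)
  expect_setequal(m$species, c("A", "P"))

  rules_cyclic <- '<listOfRules>
    <assignmentRule variable="a"><math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><cn type="integer">2</cn><ci>b</ci></apply></math></assignmentRule>
    <assignmentRule variable="b"><math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><cn type="integer">3</cn><ci>a</ci></apply></math></assignmentRule>
  </listOfRules>'
  expect_error(flatten_model(parse_sbml(base(rules_cyclic))),
               class = "kx_cyclic_rule")
})

test_that("initial assignments are applied to initial values", {
  doc <- sub("</listOfParameters>",
             '</listOfParameters>
  <listOfInitialAssignments>
    <initialAssignment symbol="A"><math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><times/><cn type="integer">3</cn><ci>k</ci></apply></math></initialAssignment>
  </listOfInitialAssignments>',
             toy_sbml(0.5))
  spec <- flatten_model(parse_sbml(doc))
  expect_equal(spec$species$initial[spec$species$id == "A"], 1.5)
})

test_that("stoichiometric matrix columns follow net coefficients", {
  # A -> B
  S <- build_stoichiometric_matrix(parse_sbml(toy_sbml()))
  expect_equal(dim(S), c(2, 1))
  expect_equal(unname(S[, 1]), c(-1, 1))
  # 2A -> B
  doc2 <- sub('species="A" stoichiometry="1"', 'species="A" stoichiometry="2"',
              toy_sbml())
  expect_equal(unname(build_stoichiometric_matrix(parse_sbml(doc2))[, 1]),
               c(-2, 1))
  # modifiers contribute zero
  doc3 <- sub("</listOfProducts>",
              '</listOfProducts><listOfModifiers><modifierSpeciesReference species="B"/></listOfModifiers>',
              sub('<speciesReference species="B" stoichiometry="1" constant="true"/>',
                  "", toy_sbml()))
  S3 <- build_stoichiometric_matrix(parse_sbml(doc3))
  expect_equal(unname(S3["B", 1]), 0)
})

test_that("parse-export-parse is idempotent and theta overrides apply", {
  specs <- list(
    parse_sbml(toy_sbml(0.5)),
    fixture_model("enzyme")$model$spec,
    fixture_model("ring")$model$spec)
  for (spec in specs) {
    doc1 <- export_sbml(spec)
    spec1 <- flatten_model(parse_sbml(doc1))
    doc2 <- export_sbml(spec1)
    expect_identical(doc1, doc2)
    m0 <- compile_model(spec)
    m1 <- compile_model(spec1)
    expect_identical(m0$species, m1$species)
    expect_equal(m0$S, m1$S)
    expect_equal(m0$theta_ref, m1$theta_ref)
    # symbolic rates agree numerically at random states
    set.seed(11)
    for (rep in 1:5) {
      y <- stats::runif(m0$n, 0.1, 2)
      expect_equal(m1$flux_fun(0.3, y, m1$theta_ref),
                   m0$flux_fun(0.3, y, m0$theta_ref), tolerance = 1e-12)
    }
  }
})

test_that("export writes new parameter values and rejects unknown ids", {
  spec <- parse_sbml(toy_sbml(0.5))
  doc <- export_sbml(spec, theta = c(k = 0.9))
  expect_equal(parse_sbml(doc)$params[["k"]], 0.9)
  expect_error(export_sbml(spec, theta = c(nope = 1)),
               class = "kx_unknown_parameter")
})

test_that("a registry-built model survives an SBML round trip", {
  fx <- fixture_model("enzyme")
  doc <- export_sbml(fx$model$spec)
  # independent well-formedness check of the emitted XML
  parsed_xml <- xml2::read_xml(doc)
  expect_equal(xml2::xml_name(parsed_xml), "sbml")
  m2 <- compile_model(parse_sbml(doc))
  set.seed(5)
  y <- stats::runif(3, 0.05, 2)
  expect_equal(m2$flux_fun(0, y, m2$theta_ref),
               fx$model$flux_fun(0, y, fx$model$theta_ref), tolerance = 1e-12)
})

test_that("amounts are converted to concentrations by compartment size", {
  doc <- sub('initialConcentration="2"', 'initialAmount="6"',
             sub('size="1"', 'size="3"', toy_sbml()))
  spec <- parse_sbml(doc)
  expect_equal(spec$species$initial[spec$species$id == "A"], 2)
})
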