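# Shared fixtures and independent oracles used across the suite.

# A minimal SBML document: one reaction A -> B with mass-action rate k*A.
toy_sbml <- function(k = 0.5) {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="toy">
    <listOfCompartments>
      <compartment id="cell" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="cell" initialConcentration="2" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="B" compartment="cell" initialConcentration="0" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k" value="%g" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="r1" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply> <times/> <ci> k </ci> <ci> A </ci> </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', k)
}

# Random mass-action chain A -> B -> C -> D with 3 rate parameters; used by
# the gradient finite-difference property tests.
random_chain3 <- function(ks) {
  sp <- c("A", "B", "C", "D")
  rxs <- lapply(1:3, function(i) {
    r <- instantiate_law("mass_action_irr_uni",
                         species = stats::setNames(sp[i], "s1"),
                         params = c(k = ks[i]), id = paste0("v", i))
    r$products <- stats::setNames(1, sp[i + 1])
    r
  })
  kinetic_model(rxs, initial = c(A = 2, B = 0.3, C = 0.1, D = 0),
                id = "chain3")
}

# Independent central finite-difference gradient of the training loss in
# log space (the oracle for the adjoint gradients).
fd_gradient <- function(model, theta, dataset, config = trainer_config(),
                        h = 1e-4) {
  vapply(seq_along(theta), function(j) {
    tp <- theta; tm <- theta
    if (model$positive[model$param_ids][j]) {
      tp[j] <- tp[j] * exp(h); tm[j] <- tm[j] * exp(-h)
    } else {
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    }
    (training_loss(model, tp, dataset, config) -
       training_loss(model, tm, dataset, config)) / (2 * h)
  }, 0)
}

# Independent re-implementation of the published AdaBelief update equations
# (plain loops, no shared code with the package's optimizer).
adabelief_reference <- function(x0, grads, lr, b1 = 0.9, b2 = 0.999,
                                eps = 1e-16) {
  x <- x0
  m <- numeric(length(x0))
  s <- numeric(length(x0))
  for (t in seq_along(grads)) {
    g <- grads[[t]]
    m <- b1 * m + (1 - b1) * g
    s <- b2 * s + (1 - b2) * (g - m)^2
    mhat <- m / (1 - b1^t)
    shat <- s / (1 - b2^t)
    x <- x - lr * mhat / (sqrt(shat) + eps)
  }
  x
}
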