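# A hand-written SBML Level 2 fixture: 3 species (one boundary), 2 reactions,
# bounds in the legacy kinetic-law parameter encoding for R1, none for R2.
sbml_l2_fixture <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="fixture2">
    <listOfCompartments>
      <compartment id="c"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="met A" compartment="c" boundaryCondition="false"/>
      <species id="B" name="met B" compartment="c" boundaryCondition="false"/>
      <species id="X_b" name="ext X" compartment="c" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1" reversible="true">
        <listOfReactants>
          <speciesReference species="X_b" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-5"/>
            <parameter id="UPPER_BOUND" value="8"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R2" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="2"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  path
}

# structural equality of two models, ignoring row order artifacts
expect_models_equal <- function(a, b) {
  expect_equal(a$metabolites$id, b$metabolites$id)
  expect_equal(a$metabolites$boundary, b$metabolites$boundary)
  expect_equal(a$metabolites$compartment, b$metabolites$compartment)
  expect_equal(a$reactions$id, b$reactions$id)
  expect_equal(a$reactions$lower_bound, b$reactions$lower_bound)
  expect_equal(a$reactions$upper_bound, b$reactions$upper_bound)
  for (i in seq_len(nrow(a$reactions))) {
    sa <- a$reactions$stoichiometry[[i]]
    sb <- b$reactions$stoichiometry[[i]]
    expect_equal(sa[order(names(sa))], sb[order(names(sb))])
  }
  expect_equal(a$objective_id, b$objective_id)
}
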