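sbml_l3_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="mini" fbc:strict="true">',
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="A_e" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>',
    '      <species id="A_c" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>',
    '      <species id="B_c" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>',
    '    </listOfSpecies>',
    '    <listOfParameters>',
    '      <parameter id="lb_neg" value="-15" constant="true"/>',
    '      <parameter id="lb_zero" value="0" constant="true"/>',
    '      <parameter id="ub_def" value="999" constant="true"/>',
    '    </listOfParameters>',
    '    <fbc:listOfGeneProducts>',
    '      <fbc:geneProduct fbc:id="G_b001" fbc:label="b001"/>',
    '      <fbc:geneProduct fbc:id="G_b002" fbc:label="b002"/>',
    '      <fbc:geneProduct fbc:id="G_b003" fbc:label="b003"/>',
    '    </fbc:listOfGeneProducts>',
    '    <listOfReactions>',
    '      <reaction id="EX_A" reversible="true" fast="false" fbc:lowerFluxBound="lb_neg" fbc:upperFluxBound="ub_def">',
    '        <listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '      </reaction>',
    '      <reaction id="TAT" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_def">',
    '        <listOfReactants><speciesReference species="A_e" stoichiometry="1" constant="true"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfProducts>',
    '        <fbc:geneProductAssociation>',
    '          <fbc:or>',
    '            <fbc:and>',
    '              <fbc:geneProductRef fbc:geneProduct="G_b001"/>',
    '              <fbc:geneProductRef fbc:geneProduct="G_b002"/>',
    '            </fbc:and>',
    '            <fbc:geneProductRef fbc:geneProduct="G_b003"/>',
    '          </fbc:or>',
    '        </fbc:geneProductAssociation>',
    '      </reaction>',
    '      <reaction id="GROW" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_def">',
    '        <listOfReactants>',
    '          <speciesReference species="A_c" stoichiometry="2" constant="true"/>',
    '        </listOfReactants>',
    '        <listOfProducts><speciesReference species="B_c" stoichiometry="1" constant="true"/></listOfProducts>',
    '      </reaction>',
    '      <reaction id="EX_B" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_def">',
    '        <listOfReactants><speciesReference species="B_c" stoichiometry="1" constant="true"/></listOfReactants>',
    '      </reaction>',
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    '          <fbc:fluxObjective fbc:reaction="GROW" fbc:coefficient="1"/>',
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>'), path)
  path
}

sbml_l2_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '  <model id="mini2">',
    '    <listOfSpecies>',
    '      <species id="A_b" compartment="e" boundaryCondition="true"/>',
    '      <species id="A_c" compartment="c"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="TAT" reversible="false">',
    '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '          <p>GENE_ASSOCIATION: b001 and b002</p>',
    '        </body></notes>',
    '        <listOfReactants><speciesReference species="A_b" stoichiometry="1"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="A_c" stoichiometry="1"/></listOfProducts>',
    '        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>',
    '          <listOfParameters>',
    '            <parameter id="LOWER_BOUND" value="0"/>',
    '            <parameter id="UPPER_BOUND" value="20"/>',
    '            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>',
    '          </listOfParameters>',
    '        </kineticLaw>',
    '      </reaction>',
    '      <reaction id="GROW" reversible="false">',
    '        <listOfReactants><speciesReference species="A_c" stoichiometry="1"/></listOfReactants>',
    '        <kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>',
    '          <listOfParameters>',
    '            <parameter id="LOWER_BOUND" value="0"/>',
    '            <parameter id="UPPER_BOUND" value="1000"/>',
    '            <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '          </listOfParameters>',
    '        </kineticLaw>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  path
}

test_that("the JSON dialect round-trips models bit-for-bit", {
  toy <- toy2(with_atpm = TRUE, with_cofactor = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(toy$model, path)
  back <- read_model(path)
  expect_identical(back$S, toy$model$S)
  expect_identical(back$lower, toy$model$lower)
  expect_identical(back$upper, toy$model$upper)
  expect_identical(back$biomass_reaction, toy$model$biomass_reaction)
  expect_identical(back$atpm_reaction, toy$model$atpm_reaction)
  for (j in seq_along(back$gpr)) {
    if (is.null(toy$model$gpr[[j]])) {
      expect_null(back$gpr[[j]])
    } else {
      expect_identical(gpr_to_string(back$gpr[[j]]),
                       gpr_to_string(toy$model$gpr[[j]]))
    }
  }
})

test_that("toy JSON fixture loads with expected structure", {
  toy <- toy2()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(toy$model, path)
  m <- read_model(path)
  expect_length(m$reaction_ids, 10)
  expect_identical(m$reaction_ids[m$biomass_reaction], "BIOMASS")
  expect_identical(m$reaction_ids[m$exchange_reactions],
                   c("EX_glc", "EX_ac"))
})

test_that("invalid models are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".json")
  # all-zero stoichiometry column
  writeLines('{"schema":"fluxprior-model/1",
    "metabolites":[{"id":"A"}],
    "reactions":[{"id":"R1","stoichiometry":{"A":0},"lower":0,"upper":1,
                  "objective":true}]}', path)
  expect_error(read_model(path), "all-zero")
  # no objective flag and no explicit biomass
  writeLines('{"schema":"fluxprior-model/1",
    "metabolites":[{"id":"A"}],
    "reactions":[{"id":"R1","stoichiometry":{"A":-1},"lower":0,"upper":1}]}',
    path)
  expect_error(read_model(path), "biomass")
  expect_identical(
    read_model(path, biomass = "R1")$biomass_reaction, 1L)
  writeLines("{not json", path)
  expect_error(read_model(path), "unparsable")
})

test_that("SBML level 3 fbc models read bounds, GPRs and the objective", {
  path <- withr::local_tempfile(fileext = ".xml")
  m <- read_model(sbml_l3_fixture(path))
  expect_identical(m$reaction_ids, c("EX_A", "TAT", "GROW", "EX_B"))
  expect_identical(m$reaction_ids[m$biomass_reaction], "GROW")
  expect_equal(m$lower, c(-15, 0, 0, 0))
  expect_equal(m$upper, rep(999, 4))
  expect_identical(gpr_to_string(m$gpr[[2]]), "(b001 and b002) or b003")
  expect_equal(unname(m$S[, "GROW"]), c(0, -2, 1))
  # it actually grows
  sol <- solve_fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 7.5) # uptake 15 / 2
})

test_that("SBML level 2 models read notes GPRs and kinetic-law bounds", {
  path <- withr::local_tempfile(fileext = ".sbml")
  m <- read_model(sbml_l2_fixture(path))
  # boundary species dropped -> TAT becomes the sole-metabolite exchange
  expect_identical(m$metabolite_ids, "A_c")
  expect_equal(m$upper[1], 20)
  expect_identical(gpr_to_string(m$gpr[[1]]), "b001 and b002")
  expect_identical(m$reaction_ids[m$biomass_reaction], "GROW")
})

test_that("biomass constituent removal touches only the biomass column", {
  toy <- toy2(with_cofactor = TRUE)
  model <- toy$model
  jb <- model$biomass_reaction
  expect_lt(model$S["cof_c", jb], 0)

  trimmed <- remove_biomass_constituents(model, "cof_c")
  expect_equal(trimmed$S["cof_c", jb], 0)
  expect_identical(trimmed$S[, -jb], model$S[, -jb])

  # identity on the empty list
  expect_identical(remove_biomass_constituents(model, character(0)), model)
  # ids not in the biomass reaction are refused by name
  expect_error(remove_biomass_constituents(model, c("cof_c", "glc_e")),
               "glc_e")
})

test_that("removing a cofactor cannot decrease the optimum (LP oracle)", {
  toy <- toy2(with_cofactor = TRUE)
  lim <- sole_carbon_limits(toy, "glucose", uptake = 1)
  before <- oracle_fba(toy$model, lim)
  trimmed <- remove_biomass_constituents(toy$model, "cof_c")
  after <- oracle_fba(trimmed, lim)
  expect_gte(after$objective + 1e-9, before$objective)
  # and the package solver agrees with the oracle on both models
  expect_equal(solve_fba(toy$model, lim)$objective_value, before$objective,
               tolerance = 1e-8)
  expect_equal(solve_fba(trimmed, lim)$objective_value, after$objective,
               tolerance = 1e-8)
})

test_that("the iAF1260 cofactor list matches the published stoichiometry", {
  cof <- iaf1260_biomass_cofactors()
  expect_identical(nrow(cof), 15L)
  expect_equal(cof$coefficient[cof$metabolite == "nad_c"], 0.001831)
  expect_true(all(cof$coefficient > 0 & cof$coefficient < 0.002))
})
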