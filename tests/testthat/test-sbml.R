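test_that("model summaries count species, reactions, parameters and rules", {
  expect_equal(unlist(model_summary(network_model())[1:4], use.names = FALSE),
               c(0, 0, 0, 0))
  s <- model_summary(toy_binding())
  expect_equal(s$n_species, 3)
  expect_equal(s$n_reactions, 1)
  expect_equal(s$n_parameters, 2)   # kf and kr
  # builder SF and DF models summarise identically (shared topology)
  expect_equal(unclass(model_summary(build_scenario(scenario_spec("SF"))))[1:4],
               unclass(model_summary(build_scenario(scenario_spec("DF"))))[1:4])
})

test_that("SBML write/read round-trip preserves structure exactly", {
  dir <- withr::local_tempdir()
  for (m in list(network_model(id = "empty"), toy_binding(), toy_chain(),
                 build_scenario(scenario_spec("DF_miRNA")))) {
    path <- file.path(dir, paste0(m$id, ".xml"))
    write_sbml(m, path)
    back <- read_sbml(path)
    expect_equal(unclass(model_summary(back))[1:4],
                 unclass(model_summary(m))[1:4], info = m$id)
    expect_identical(sort(vapply(back$species, `[[`, "", "id")),
                     sort(vapply(m$species, `[[`, "", "id")))
  }
})

test_that("round-trip preserves trajectories within solver tolerance", {
  m <- build_scenario(scenario_spec("SF"))
  path <- file.path(withr::local_tempdir(), "sf.xml")
  write_sbml(m, path)
  back <- read_sbml(path)
  st <- simulation_settings(t_end = 300, n_output_points = 61)
  tc1 <- simulate(m, settings = st)
  tc2 <- simulate(back, settings = st)
  v2 <- tc2$values[tc1$species_ids, ]
  scale <- pmax(apply(abs(tc1$values), 1, max), 1e-8)
  expect_lt(max(abs(tc1$values - v2) / scale), 1e-6)
})

test_that("a minimal hand-written SBML document parses", {
  doc <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="mini"><listOfSpecies>',
    '<species id="X" compartment="c" initialAmount="2" constant="false"/>',
    '<species id="Y" compartment="c" initialAmount="0" constant="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="conv" reversible="false">',
    '<listOfReactants><speciesReference species="X" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="Y" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfLocalParameters><localParameter id="kf" value="0.5"/></listOfLocalParameters></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>')
  path <- file.path(withr::local_tempdir(), "mini.xml")
  writeLines(doc, path)
  m <- read_sbml(path)
  expect_equal(model_summary(m)$n_species, 2)
  expect_equal(model_summary(m)$n_reactions, 1)
  expect_equal(m$reactions[[1]]$kf, 0.5)
  expect_equal(m$species[[1]]$initial, 2)
})

test_that("unsupported kinetic laws and malformed files raise named errors", {
  dir <- withr::local_tempdir()
  bad1 <- file.path(dir, "bad.xml")
  writeLines("<sbml><model><listOfReactions><reaction id='mystery'>",
             bad1)
  expect_error(read_sbml(bad1))
  bad2 <- file.path(dir, "nokf.xml")
  writeLines(c(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies><species id="X" initialAmount="1"/></listOfSpecies>',
    '<listOfReactions><reaction id="mystery">',
    '<listOfReactants><speciesReference species="X"/></listOfReactants>',
    '<kineticLaw><listOfLocalParameters><localParameter id="weird" value="1"/></listOfLocalParameters></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>'), bad2)
  expect_error(read_sbml(bad2), "mystery")
  expect_error(read_sbml(file.path(dir, "absent.xml")), "no such file")
})

test_that("assignment rules and annotations survive the round-trip", {
  m <- toy_chain()
  m$species[[length(m$species) + 1L]] <- species_def("obs")
  m$rules <- list(list(target = "obs", math = "B + 2 * C"))
  m$species[[1]]$annotation <- "<annotation><extra xmlns=\"urn:x\">blob</extra></annotation>"
  path <- file.path(withr::local_tempdir(), "rules.xml")
  write_sbml(m, path)
  back <- read_sbml(path)
  expect_length(back$rules, 1L)
  expect_identical(back$rules[[1]]$target, "obs")
  env <- list(B = 3, C = 4)
  expect_equal(eval(parse(text = back$rules[[1]]$math), env), 11)
  expect_match(back$species[[1]]$annotation, "blob")
})

test_that("canonical readouts resolve through the pattern map", {
  m <- build_scenario(scenario_spec("SF"))
  res <- map_names(m)
  expect_length(res$unresolved, 0L)
  expect_setequal(res$resolved$pMYC, c("pMYC", "ppMYC"))
  expect_setequal(res$resolved$MYC_total, c("MYC", "pMYC", "ppMYC"))
  # phospho-anchored patterns are many-to-one over complex species
  toy <- network_model(species = list(species_def("ppMEK"),
                                      species_def("ppMEK_ERK")))
  got <- map_names(toy, c(ppMEK = "^ppMEK"))
  expect_setequal(got$resolved$ppMEK, c("ppMEK", "ppMEK_ERK"))
  # empty models leave every readout unresolved, reported not dropped
  none <- map_names(network_model())
  expect_setequal(none$unresolved, names(default_name_map()))
})
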