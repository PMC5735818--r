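test_that("receptor module: no ligand, no signal; ANGPT2 is a silent antagonist", {
  led <- default_ledger()
  led$initials[c("ANGPT1", "ANGPT2")] <- 0
  tc <- simulate(build_receptor_module(led),
                 settings = simulation_settings(t_end = 70, n_output_points = 71))
  expect_true(all(tc$values["ANGPT1_TEK_p", ] == 0))
  # ANGPT2 alone binds TEK but emits no phospho-receptor
  led$initials["ANGPT2"] <- 5
  tc2 <- simulate(build_receptor_module(led),
                  settings = simulation_settings(t_end = 70, n_output_points = 71))
  expect_true(all(tc2$values["ANGPT1_TEK_p", ] == 0))
  expect_gt(max(tc2$values["ANGPT2_TEK", ]), 0)
})

test_that("raising the ANGPT2 antagonist lowers the phospho-receptor peak", {
  peaks <- vapply(c(1, 5, 25), function(a2) {
    led <- default_ledger()
    led$initials["ANGPT2"] <- a2
    tc <- simulate(build_receptor_module(led),
                   settings = simulation_settings(t_end = 200, n_output_points = 201))
    max(tc$values["ANGPT1_TEK_p", ])
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("Ras stays at rest without phospho-receptor and total Ras is conserved", {
  sf <- build_scenario(scenario_spec("SF"))
  led <- default_ledger()
  led$initials[c("ANGPT1", "ANGPT2")] <- 0
  quiet <- build_scenario(scenario_spec("SF"), led)
  tc <- simulate(quiet, settings = simulation_settings(t_end = 500,
                                                       n_output_points = 101))
  expect_true(all(tc$values["RasGTP", ] == 0))
  expect_equal(max(abs(tc$values["RasGDP", ] - tc$values["RasGDP", 1])), 0,
               tolerance = 1e-8)
  # conservation analysis reports the cascade totals implied by construction
  cm <- conserved_moieties(sf)
  totals <- lapply(cm, function(v) sort(names(v)[v != 0]))
  expect_true(list(sort(c("RasGDP", "RasGTP"))) %in% totals ||
                any(vapply(totals, identical, TRUE,
                           y = sort(c("RasGDP", "RasGTP")))))
  has <- function(ids) any(vapply(totals, identical, TRUE, y = sort(ids)))
  expect_true(has(c("MEK", "pMEK", "ppMEK")))
  expect_true(has(c("ERK", "pERK", "ppERK")))
  expect_true(has(c("Akt", "pAkt")))
  expect_true(has(c("PIP2", "PIP3", "PDK1_PIP3")))
  expect_true(has(c("EIF4EBP1", "pEIF4EBP1")))
})

test_that("cascade ordering: ppERK peaks after ppMEK; PI3K arm half-max ordered", {
  tc <- scenario_runs()$SF
  expect_gt(as.numeric(peak_time(evaluate_readout(tc, "ppERK"))),
            as.numeric(peak_time(evaluate_readout(tc, "ppMEK"))))
  hm <- vapply(c("pAkt", "pmTORC1", "pEIF4EBP1"), function(rd)
    as.numeric(time_to_half_max(evaluate_readout(tc, rd))), numeric(1))
  expect_true(all(diff(hm) > 0))
})

test_that("the PTEN limit shuts the Akt arm down", {
  led <- default_ledger()
  led$rates["k_pten"] <- led$rates[["k_pten"]] * 1e4
  tc <- simulate(build_scenario(scenario_spec("SF"), led),
                 settings = simulation_settings(t_end = 1500, n_output_points = 301))
  expect_lt(tc$values["pAkt", 301], 1e-3 * default_ledger()$initials[["Akt"]])
})

test_that("scenario assembly: shared SF/DF topology, DF+miRNA strict superset", {
  sf <- build_scenario(scenario_spec("SF"))
  df <- build_scenario(scenario_spec("DF"))
  dfm <- build_scenario(scenario_spec("DF_miRNA"))
  expect_identical(length(sf$reactions), length(df$reactions))
  expect_identical(vapply(sf$reactions, `[[`, "", "id"),
                   vapply(df$reactions, `[[`, "", "id"))
  expect_gt(length(dfm$species), length(df$species))
  expect_gt(length(dfm$reactions), length(df$reactions))
  expect_gt(model_summary(dfm)$n_parameters, model_summary(df)$n_parameters)
  # a DF spec with unit multipliers reduces exactly to SF
  df_unit <- build_scenario(scenario_spec("DF", expression_multipliers =
    c(ANGPT1 = 1, ANGPT2 = 1, TEK = 1, RAS = 1, PIK3R1 = 1)))
  expect_equal(vapply(df_unit$species, `[[`, numeric(1), "initial"),
               vapply(sf$species, `[[`, numeric(1), "initial"))
  # every assembled scenario validates cleanly
  for (m in list(sf, df, dfm))
    expect_length(validate_model(m)$errors, 0L)
})

test_that("scenario specifications enforce their invariants", {
  expect_error(scenario_spec("SF", expression_multipliers = c(TEK = 2)),
               "baseline")
  expect_error(scenario_spec("DF", mirna_levels = c(hsa_miR_451a = 1)),
               "no miRNA")
  expect_error(scenario_spec("DF_miRNA",
                             mirna_levels = c(`hsa-miR-451a` = 0)),
               "strictly positive")
  expect_error(scenario_spec("DF", expression_multipliers = c(BOGUS = 2)),
               "unknown expression axis")
  # hyphenated ids canonicalise
  sp <- scenario_spec("DF_miRNA", mirna_levels = c(`hsa-miR-451a` = 2))
  expect_equal(sp$mirna_levels[["hsa_miR_451a"]], 2)
})

test_that("miRNA repression: zero strength is inert, repeated blocks multiply", {
  df <- build_scenario(scenario_spec("DF"))
  st <- simulation_settings(t_end = 400, n_output_points = 101)
  base <- simulate(df, settings = st)
  inert <- add_mirna_repression(df, "hsa-miR-451a", "MYC",
                                "translation_block", strength = 0)
  tc0 <- simulate(inert, settings = st)
  expect_equal(tc0$values[base$species_ids, ], base$values, tolerance = 1e-10)

  twice <- add_mirna_repression(df, "hsa-miR-451a", "MYC",
                                "translation_block", strength = 0.6, level = 1)
  twice <- add_mirna_repression(twice, "hsa-miR-451a", "MYC",
                                "translation_block", strength = 0.8, level = 1)
  syn <- Filter(function(rx) length(rx$reactants) == 0L, twice$reactions)[[1]]
  m <- 1
  expect_equal(prod(1 + syn$inhibitors * m), (1 + 0.6) * (1 + 0.8))
  once <- add_mirna_repression(df, "hsa-miR-451a", "MYC",
                               "translation_block",
                               strength = (1 + 0.6) * (1 + 0.8) - 1, level = 1)
  tc_twice <- simulate(twice, settings = st)
  tc_once <- simulate(once, settings = st)
  expect_equal(tc_twice$values["MYC", ], tc_once$values["MYC", ],
               tolerance = 1e-8)
  expect_error(add_mirna_repression(df, "x", "GHOST", "translation_block", 1),
               "unknown target")
  expect_error(add_mirna_repression(df, "x", "MYC", "translation_block", -1),
               "strength")
})

test_that("MYC-directed miRNAs lower steady total MYC below the DF level", {
  runs <- scenario_runs()
  late <- vapply(runs, function(tc) {
    s <- evaluate_readout(tc, "MYC_total")
    s$value[length(s$value)]
  }, numeric(1))
  expect_gt(late[["SF"]], late[["DF"]])
  expect_gt(late[["DF"]], late[["DF_miRNA"]])
})

test_that("parameter sampling is seed-deterministic with cv = 0 the identity", {
  led <- default_ledger()
  expect_identical(sample_parameters(led, 1, 0), led)
  a <- sample_parameters(led, 11, 0.2)
  b <- sample_parameters(led, 11, 0.2)
  c <- sample_parameters(led, 12, 0.2)
  expect_identical(a$rates, b$rates)
  expect_false(identical(a$rates, c$rates))
  expect_true(all(a$rates > 0))
})

test_that("scenario/ledger configuration round-trips through YAML", {
  spec <- scenario_spec("DF_miRNA", mirna_levels = c(hsa_miR_30d_3p = 2,
                                                     hsa_miR_451a = 1,
                                                     hsa_miR_548v = 1,
                                                     bta_miR_22_3p = 3))
  led <- default_ledger()
  led$rates["k_gap"] <- 0.123
  path <- file.path(withr::local_tempdir(), "scenario.yaml")
  write_scenario_config(spec, led, path)
  got <- read_scenario_config(path)
  expect_equal(got$spec$mirna_levels, spec$mirna_levels)
  expect_equal(got$ledger$rates[["k_gap"]], 0.123)
  expect_identical(got$spec$scenario, "DF_miRNA")
})
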