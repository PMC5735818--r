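test_that("peak time matches the two-step chain closed form", {
  # intermediate of A -> B -> C peaks at ln(k2/k1)/(k2-k1)
  tc <- simulate(toy_chain(k1 = 1, k2 = 2),
                 settings = simulation_settings(t_end = 5, n_output_points = 501))
  s <- evaluate_readout(tc, "B")
  expect_equal(as.numeric(peak_time(s)), log(2), tolerance = 5 / 500)
})

test_that("peak detection flags boundary maxima and zero series", {
  tt <- seq(0, 10, length.out = 11)
  rising <- structure(list(name = "r", time = tt, value = tt), class = "sbn_series")
  pt <- peak_time(rising)
  expect_equal(as.numeric(pt), 10)
  expect_true(attr(pt, "non_interior"))
  zero <- structure(list(name = "z", time = tt, value = rep(0, 11)),
                    class = "sbn_series")
  pz <- peak_time(zero)
  expect_equal(as.numeric(pz), 0)
  expect_true(attr(pz, "zero_amplitude"))
  # ties broken by the earliest time
  flat2 <- structure(list(name = "f", time = tt, value = c(0, 1, 1, rep(0, 8))),
                     class = "sbn_series")
  expect_lte(as.numeric(peak_time(flat2)), tt[3])
})

test_that("half-maximum crossing is linearly interpolated on the rise", {
  tt <- c(0, 1, 2, 3, 4)
  tri <- structure(list(name = "t", time = tt, value = c(0, 0.5, 1, 0.5, 0)),
                   class = "sbn_series")
  expect_equal(as.numeric(time_to_half_max(tri)), 1)
  expect_lte(as.numeric(time_to_half_max(tri)), as.numeric(peak_time(tri)))
  never <- structure(list(name = "n", time = tt, value = rep(0, 5)),
                     class = "sbn_series")
  expect_true(is.na(time_to_half_max(never)))
  expect_false(attr(time_to_half_max(never), "reached"))
  expect_equal(auc(never), 0)
})

test_that("area under the curve matches the exponential closed form", {
  tt <- seq(0, 10, length.out = 1500)
  s <- structure(list(name = "e", time = tt, value = exp(-tt)),
                 class = "sbn_series")
  expect_equal(auc(s), 1 - exp(-10), tolerance = 1e-4)
})

test_that("readouts sum their member species and reject missing ones", {
  tc <- simulate(toy_chain(), settings = simulation_settings(
    t_end = 5, n_output_points = 21))
  single <- evaluate_readout(tc, "B")
  expect_equal(single$value, unname(tc$values["B", ]))
  both <- evaluate_readout(tc, c("B", "C"))
  expect_equal(both$value, unname(colSums(tc$values[c("B", "C"), ])))
  expect_error(evaluate_readout(tc, c("B", "NOPE")), "NOPE")
  # canonical-name resolution matches a brute-force regex sum
  sf <- scenario_runs()$SF
  r <- evaluate_readout(sf, "pMYC")
  members <- grep(default_name_map()[["pMYC"]], sf$species_ids, value = TRUE)
  expect_identical(sort(members), sort(c("pMYC", "ppMYC")))
  expect_equal(r$value, pmax(colSums(sf$values[members, , drop = FALSE]), 0))
})

test_that("scenario comparison is complete, permutation-invariant, and ties flagged", {
  runs <- scenario_runs()
  tab1 <- compare_scenarios(runs, readouts = c("ppMEK", "ppERK"))
  tab2 <- compare_scenarios(rev(runs), readouts = c("ppMEK", "ppERK"))
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))
  expect_identical(nrow(tab1), 6L)
  # identical runs in every slot -> all ordering flags tie, DF>SF checks fail
  same <- list(SF = runs$SF, DF = runs$SF, DF_miRNA = runs$SF)
  tabs <- compare_scenarios(same, readouts = c("ppMEK", "ppERK", "pMYC",
                                               "MYC_total"))
  expect_true(all(attr(tabs, "orderings")$highest_peak == "tie"))
  checks <- qualitative_check(tabs, same,
                              checks = subset(default_check_set(),
                                              readout %in% c("ppMEK", "ppERK")))
  expect_true(all(!checks$pass[grepl("DF_above_SF", checks$check)]))
  # but they are reported, not raised
  expect_s3_class(checks, "sbn_checks")
  expect_error(compare_scenarios(list(SF = runs$SF)), "at least two")
})

test_that("check-set definitions round-trip through config files", {
  path <- file.path(withr::local_tempdir(), "checks.yaml")
  write_check_set(default_check_set(), path)
  got <- read_check_set(path)
  expect_equal(got, default_check_set())
})
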