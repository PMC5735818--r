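test_that("mass-action rate law evaluates the printed second-order form", {
  rx <- reaction_def("bind", c(A = 1, B = 1), c(AB = 1), kf = 1, kr = 0.5)
  # all contributing terms vanish
  expect_identical(mass_action_rate(rx, c(A = 0, B = 5, AB = 0)), 0)
  # direct evaluation: 1*2*3 - 0.5*4
  expect_equal(mass_action_rate(rx, c(A = 2, B = 3, AB = 4)), 4.0)
  # detailed balance at [AB]/([A][B]) = kf/kr
  expect_equal(mass_action_rate(rx, c(A = 1.3, B = 0.7, AB = 2 * 1.3 * 0.7)), 0)
  expect_error(mass_action_rate(rx, c(A = 1, B = 1)), "missing species")
  expect_error(mass_action_rate(rx, c(A = -1, B = 1, AB = 0)), "negative")
})

test_that("detailed balance holds at machine precision for random reversible steps", {
  set.seed(42)
  for (i in 1:20) {
    kf <- runif(1, 0.1, 5); kr <- runif(1, 0.1, 5)
    rx <- reaction_def("r", c(A = 1, B = 1), c(AB = 1), kf = kf, kr = kr)
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    st <- c(A = a, B = b, AB = kf / kr * a * b)
    expect_lt(abs(mass_action_rate(rx, st)), 1e-12 * kf * a * b)
  }
})

test_that("stoichiometric matrix encodes net changes, one column per reaction", {
  m <- toy_binding()
  N <- stoichiometric_matrix(m)
  expect_identical(dim(N), c(3L, 1L))
  expect_identical(unname(N[, "bind"]), c(-1L, -1L, 1L))
  # a reversible reaction stays a single column
  expect_identical(ncol(stoichiometric_matrix(toy_binding(kr = 2))), 1L)
  N2 <- stoichiometric_matrix(toy_chain())
  expect_identical(unname(N2), matrix(c(-1L, 1L, 0L, 0L, -1L, 1L), nrow = 3))
})

test_that("ODE right-hand side equals N v, with boundary species frozen", {
  rhs <- build_ode_rhs(toy_decay(k = 0.1))
  expect_equal(unname(rhs(0, c(A = 1, B = 0))), c(-0.1, 0.1))
  # constant species have zero net rate even with incident reactions
  m <- network_model(
    species = list(species_def("M", initial = 2, constant = TRUE),
                   species_def("X", initial = 0)),
    reactions = list(reaction_def("use", c(M = 1), c(X = 1), kf = 1)))
  d <- build_ode_rhs(m)(0, c(M = 2, X = 0))
  expect_identical(unname(d["M"]), 0)
  expect_equal(unname(d["X"]), 2)
})

test_that("vectorised right-hand side matches a brute-force loop on random models", {
  set.seed(7)
  for (i in 1:15) {
    m <- random_model(n_species = sample(3:10, 1), n_reactions = sample(2:12, 1))
    rhs <- build_ode_rhs(m)
    y <- vapply(m$species, `[[`, numeric(1), "initial")
    names(y) <- vapply(m$species, `[[`, character(1), "id")
    expect_equal(rhs(0, y), brute_force_rhs(m, y), tolerance = 1e-12)
  }
})

test_that("conserved moieties are exact integer left-null vectors", {
  cm <- conserved_moieties(toy_binding())
  expect_length(cm, 2L)           # A + AB and B + AB
  N <- stoichiometric_matrix(toy_binding())
  for (v in cm) expect_identical(max(abs(t(v) %*% N)), 0)
  # linear chain conserves the grand total
  cm2 <- conserved_moieties(toy_chain())
  expect_length(cm2, 1L)
  expect_identical(unname(cm2[[1]]), c(1, 1, 1))
  # a degradation sink destroys the naive total
  m <- network_model(
    species = list(species_def("A", initial = 1), species_def("B")),
    reactions = list(reaction_def("conv", c(A = 1), c(B = 1), kf = 1),
                     reaction_def("sink", c(B = 1), NULL, kf = 0.1)))
  expect_length(conserved_moieties(m), 0L)
  # every vector reported on the assembled follicle model annihilates N
  sf <- build_scenario(scenario_spec("SF"))
  Nsf <- stoichiometric_matrix(sf)
  keep <- rownames(Nsf) != "ERK_active_total" &
    !vapply(sf$species, `[[`, logical(1), "constant")
  for (v in conserved_moieties(sf))
    expect_identical(max(abs(t(v) %*% Nsf[names(v), , drop = FALSE])), 0)
})

test_that("validation reports counts, dangling references and duplicates", {
  empty <- network_model()
  rep <- validate_model(empty)
  expect_identical(unname(rep$counts), c(0L, 0L, 0L, 0L))
  expect_length(rep$errors, 0L)

  bad <- network_model(
    species = list(species_def("A", initial = 1)),
    reactions = list(reaction_def("r", c(A = 1), c(GHOST = 1), kf = 1)))
  expect_match(validate_model(bad)$errors, "GHOST")

  dup <- network_model(species = list(species_def("A"), species_def("A")))
  expect_match(validate_model(dup)$errors, "duplicate species")

  # constant rule targets are contradictions
  m <- network_model(
    species = list(species_def("A", initial = 1, constant = TRUE)),
    rules = list(list(target = "A", math = "1")))
  expect_match(validate_model(m)$errors, "both constant and a rule target")
})

test_that("elementary mass-action steps are capped at order two", {
  expect_error(reaction_def("r", c(A = 2, B = 1), c(C = 1), kf = 1),
               "order <= 2")
  expect_silent(reaction_def("r", c(A = 2), c(C = 1), kf = 1))
})
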