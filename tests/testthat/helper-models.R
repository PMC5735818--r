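# Small fixture models and independent oracles, built in code.

toy_decay <- function(k = 0.1, a0 = 1) {
  network_model(
    species = list(species_def("A", initial = a0), species_def("B")),
    reactions = list(reaction_def("decay", c(A = 1), c(B = 1), kf = k)))
}

toy_binding <- function(kf = 1, kr = 0.5, a0 = 1, b0 = 1, ab0 = 0) {
  network_model(
    species = list(species_def("A", initial = a0), species_def("B", initial = b0),
                   species_def("AB", initial = ab0)),
    reactions = list(reaction_def("bind", c(A = 1, B = 1), c(AB = 1),
                                  kf = kf, kr = kr)))
}

toy_chain <- function(k1 = 1, k2 = 2, a0 = 1) {
  network_model(
    species = list(species_def("A", initial = a0), species_def("B"),
                   species_def("C")),
    reactions = list(reaction_def("r1", c(A = 1), c(B = 1), kf = k1),
                     reaction_def("r2", c(B = 1), c(C = 1), kf = k2)))
}

# Random small mass-action network for property tests (<= 10 species).
random_model <- function(n_species = 6, n_reactions = 8) {
  sp_ids <- paste0("S", seq_len(n_species))
  species <- lapply(sp_ids, function(id)
    species_def(id, initial = stats::runif(1, 0.1, 5)))
  reactions <- lapply(seq_len(n_reactions), function(j) {
    nr <- sample(1:2, 1); np <- sample(1:2, 1)
    reaction_def(paste0("r", j),
                 setNames(rep(1, nr), sample(sp_ids, nr)),
                 setNames(rep(1, np), sample(sp_ids, np)),
                 kf = stats::runif(1, 0.01, 1),
                 kr = sample(c(0, stats::runif(1, 0.01, 1)), 1))
  })
  network_model(species = species, reactions = reactions)
}

# Independent brute-force right-hand side: explicit per-species loop over
# reactions with hand-written mass-action rates. Deliberately naive.
brute_force_rhs <- function(model, state) {
  dy <- setNames(numeric(length(model$species)),
                 vapply(model$species, `[[`, character(1), "id"))
  for (rx in model$reactions) {
    fwd <- rx$kf
    for (s in names(rx$reactants)) fwd <- fwd * state[[s]]^rx$reactants[[s]]
    if (length(rx$inhibitors))
      for (m in names(rx$inhibitors))
        fwd <- fwd / (1 + rx$inhibitors[[m]] * state[[m]])
    rev <- 0
    if (rx$kr > 0) {
      rev <- rx$kr
      for (s in names(rx$products)) rev <- rev * state[[s]]^rx$products[[s]]
    }
    v <- fwd - rev
    for (s in names(rx$reactants)) dy[s] <- dy[s] - rx$reactants[[s]] * v
    for (s in names(rx$products)) dy[s] <- dy[s] + rx$products[[s]] * v
  }
  for (i in seq_along(model$species))
    if (model$species[[i]]$constant) dy[model$species[[i]]$id] <- 0
  dy
}

# Fixed-step classical Runge-Kutta reference integrator. Steps are counted
# per output interval so output times align exactly with the grid.
rk4_integrate <- function(model, t_end, dt, times_out) {
  rhs <- build_ode_rhs(model)
  y <- vapply(model$species, `[[`, numeric(1), "initial")
  names(y) <- vapply(model$species, `[[`, character(1), "id")
  out <- matrix(NA_real_, nrow = length(y), ncol = length(times_out),
                dimnames = list(names(y), NULL))
  out[, 1] <- y
  t <- times_out[1]
  for (k in 2:length(times_out)) {
    n_sub <- max(1L, round((times_out[k] - times_out[k - 1]) / dt))
    h <- (times_out[k] - times_out[k - 1]) / n_sub
    for (j in seq_len(n_sub)) {
      k1 <- rhs(t, y)
      k2 <- rhs(t + h / 2, y + h / 2 * k1)
      k3 <- rhs(t + h / 2, y + h / 2 * k2)
      k4 <- rhs(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    t <- times_out[k]
    out[, k] <- y
  }
  out
}

# Three-scenario default runs, computed once per test session.
scenario_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      models <- lapply(c(SF = "SF", DF = "DF", DF_miRNA = "DF_miRNA"),
                       function(sc) build_scenario(scenario_spec(sc)))
      cache <<- lapply(models, simulate, settings = simulation_settings())
    }
    cache
  }
})
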