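#' Define a chemical species
#'
#' A species is a state variable of the kinetic model: a protein, complex,
#' second messenger or miRNA, tracked as a dimensionless concentration.
#' Constant (boundary) species keep their initial amount throughout a
#' simulation; they are used for pools assumed to be buffered, such as
#' constitutively supplied miRNAs.
#'
#' @param id Unique identifier (character scalar). Used as the state-vector
#'   name and as the SBML species id.
#' @param name Human-readable display name; defaults to `id`.
#' @param initial Non-negative initial concentration (concentration units).
#' @param constant Logical; if `TRUE` the species has zero net rate.
#' @return An object of class `sbn_species`.
#' @export
#' @examples
#' species_def("TEK", initial = 3)
species_def <- function(id, name = id, initial = 0, constant = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(initial) || length(initial) != 1L || is.na(initial) || initial < 0)
    stop("initial amount of '", id, "' must be a non-negative number", call. = FALSE)
  structure(
    list(id = id, name = name, initial = as.numeric(initial),
         constant = isTRUE(constant)),
    class = "sbn_species"
  )
}

#' Define an elementary reaction
#'
#' Reactions follow mass-action kinetics by default: a reversible step
#' `A + B <-> AB` has net rate `kf*[A]*[B] - kr*[AB]`. A reversible reaction
#' is stored as a single entity with forward and reverse rate constants
#' (`kr = 0` means irreversible), mirroring the K/Kr presentation common in
#' published signalling models. Elementary steps are capped at order two on
#' each side. A saturable Michaelis-Menten form is available for the rare
#' steps where it is wanted (`rate_form = "michaelis_menten"`, rate
#' `vmax*[S]/(km+[S])` on the first reactant).
#'
#' `inhibitors` implements competitive translational repression: the forward
#' rate is divided by `prod(1 + strength_i * [miRNA_i])`. Factors from
#' repeated application multiply.
#'
#' @param id Unique reaction identifier.
#' @param reactants,products Named numeric vectors of stoichiometric
#'   coefficients (names are species ids, values >= 1). `NULL` or an empty
#'   vector denotes a synthesis source / degradation sink.
#' @param kf,kr Forward and reverse rate constants (>= 0). Units are 1/s for
#'   first-order and 1/(concentration*s) for second-order steps.
#' @param rate_form `"mass_action"` (default) or `"michaelis_menten"`.
#' @param km,vmax Saturable-kinetics parameters, used only for
#'   `rate_form = "michaelis_menten"`.
#' @param inhibitors Named numeric vector: names are inhibiting species ids,
#'   values are non-negative strengths.
#' @return An object of class `sbn_reaction`.
#' @export
#' @examples
#' reaction_def("bind", c(ANGPT1 = 1, TEK = 1), c(ANGPT1_TEK = 1),
#'              kf = 1, kr = 0.5)
reaction_def <- function(id, reactants = NULL, products = NULL,
                         kf = 0, kr = 0,
                         rate_form = c("mass_action", "michaelis_menten"),
                         km = NA_real_, vmax = NA_real_,
                         inhibitors = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  rate_form <- match.arg(rate_form)
  norm_side <- function(x, what) {
    if (is.null(x) || length(x) == 0L) return(numeric(0))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("reaction '", id, "': ", what, " must be a named vector", call. = FALSE)
    if (any(x < 1) || any(x != round(x)))
      stop("reaction '", id, "': stoichiometric coefficients must be integers >= 1",
           call. = FALSE)
    x
  }
  reactants <- norm_side(reactants, "reactants")
  products  <- norm_side(products, "products")
  if (kf < 0 || kr < 0)
    stop("reaction '", id, "': rate constants must be non-negative", call. = FALSE)
  if (rate_form == "mass_action" && (sum(reactants) > 2 || sum(products) > 2))
    stop("reaction '", id, "': mass-action steps are elementary (order <= 2 per side)",
         call. = FALSE)
  if (!is.null(inhibitors)) {
    if (is.null(names(inhibitors)) || any(inhibitors < 0))
      stop("reaction '", id, "': inhibitors must be a named vector of non-negative strengths",
           call. = FALSE)
  }
  structure(
    list(id = id, reactants = reactants, products = products,
         kf = as.numeric(kf), kr = as.numeric(kr), rate_form = rate_form,
         km = as.numeric(km), vmax = as.numeric(vmax),
         inhibitors = inhibitors),
    class = "sbn_reaction"
  )
}

#' Assemble a reaction-network model
#'
#' Bundles species, reactions, global parameters and assignment rules into a
#' single kinetic model. Assignment rules set the value of a target species
#' algebraically from other species at every instant (the target is excluded
#' from mass balance); they are used for derived observables such as total
#' active ERK.
#'
#' @param species List of [species_def()] objects.
#' @param reactions List of [reaction_def()] objects.
#' @param parameters Named numeric vector of global constants.
#' @param rules List of `list(target =, math =)` assignment rules; `math` is
#'   an arithmetic expression over species ids and parameter names.
#' @param scenario One of `"SF"`, `"DF"`, `"DF_miRNA"`, `"custom"`.
#' @param id Model identifier used on SBML export.
#' @return An object of class `sbn_model`.
#' @seealso [validate_model()], [build_scenario()], [simulate.sbn_model()]
#' @export
network_model <- function(species = list(), reactions = list(),
                          parameters = numeric(0), rules = list(),
                          scenario = c("custom", "SF", "DF", "DF_miRNA"),
                          id = "model") {
  scenario <- match.arg(scenario)
  structure(
    list(id = id, species = species, reactions = reactions,
         parameters = parameters, rules = rules, scenario = scenario),
    class = "sbn_model"
  )
}

species_ids <- function(model) vapply(model$species, `[[`, character(1), "id")
reaction_ids <- function(model) vapply(model$reactions, `[[`, character(1), "id")
initial_state <- function(model) {
  y <- vapply(model$species, `[[`, numeric(1), "initial")
  names(y) <- species_ids(model)
  y
}
constant_flags <- function(model) {
  f <- vapply(model$species, `[[`, logical(1), "constant")
  names(f) <- species_ids(model)
  f
}

#' Validate a model's internal consistency
#'
#' Checks for duplicate ids, dangling species references, negative constants,
#' rule targets that are also constant, and species untouched by any reaction
#' or rule. Returns a report rather than raising, so a builder can inspect
#' partial models.
#'
#' @param model An `sbn_model`.
#' @return A list of class `sbn_validation` with elements `errors`,
#'   `warnings` and `counts` (species, reactions, parameters, rules).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "sbn_model"))
  errors <- character(0)
  warnings <- character(0)
  sp <- species_ids(model)
  if (anyDuplicated(sp))
    errors <- c(errors, paste0("duplicate species id: ",
                               paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  rid <- reaction_ids(model)
  if (anyDuplicated(rid))
    errors <- c(errors, paste0("duplicate reaction id: ",
                               paste(unique(rid[duplicated(rid)]), collapse = ", ")))
  touched <- character(0)
  for (rx in model$reactions) {
    refs <- c(names(rx$reactants), names(rx$products), names(rx$inhibitors))
    touched <- c(touched, refs)
    missing <- setdiff(refs, sp)
    if (length(missing))
      errors <- c(errors, paste0("reaction '", rx$id,
                                 "' references undeclared species: ",
                                 paste(missing, collapse = ", ")))
    if (rx$kf < 0 || rx$kr < 0)
      errors <- c(errors, paste0("reaction '", rx$id, "' has a negative rate constant"))
    if (rx$rate_form == "michaelis_menten" &&
        (is.na(rx$km) || is.na(rx$vmax) || rx$km <= 0))
      errors <- c(errors, paste0("reaction '", rx$id,
                                 "' is michaelis_menten but km/vmax are not set"))
  }
  const <- constant_flags(model)
  rule_targets <- vapply(model$rules, `[[`, character(1), "target")
  for (tg in rule_targets) {
    if (!tg %in% sp)
      errors <- c(errors, paste0("rule target '", tg, "' is not a declared species"))
    else if (isTRUE(const[tg]))
      errors <- c(errors, paste0("species '", tg, "' is both constant and a rule target"))
  }
  if (any(vapply(model$species, function(s) s$initial < 0, logical(1))))
    errors <- c(errors, "negative initial amount")
  untouched <- setdiff(sp, c(touched, rule_targets))
  if (length(untouched) && length(model$reactions))
    warnings <- c(warnings, paste0("species unreachable from any reaction: ",
                                   paste(untouched, collapse = ", ")))
  structure(
    list(errors = errors, warnings = warnings,
         counts = c(species = length(model$species),
                    reactions = length(model$reactions),
                    parameters = n_parameters(model),
                    rules = length(model$rules))),
    class = "sbn_validation"
  )
}

# Parameter count convention: global parameters plus reaction-local rate
# constants (kf, a non-zero kr, km/vmax when saturable, and one strength per
# inhibitor), matching how per-reaction constants are declared in SBML
# kinetic laws.
n_parameters <- function(model) {
  n_local <- 0L
  for (rx in model$reactions) {
    n_local <- n_local + 1L                       # kf
    if (rx$kr > 0) n_local <- n_local + 1L        # kr
    if (rx$rate_form == "michaelis_menten") n_local <- n_local + 2L
    n_local <- n_local + length(rx$inhibitors)
  }
  n_local + length(model$parameters)
}

#' @export
print.sbn_validation <- function(x, ...) {
  cat("Model validation:", if (length(x$errors)) "FAILED" else "ok", "\n")
  cat(sprintf("  %d species, %d reactions, %d parameters, %d rules\n",
              x$counts["species"], x$counts["reactions"],
              x$counts["parameters"], x$counts["rules"]))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Net rate of a single reaction
#'
#' Evaluates the mass-action rate law
#' `v = kf * prod([reactants]^stoich) - kr * prod([products]^stoich)`,
#' optionally divided by the competitive-inhibition factor
#' `prod(1 + strength*[inhibitor])` (forward term only).
#'
#' @param reaction An `sbn_reaction` with `rate_form = "mass_action"`.
#' @param state Named numeric vector (or list) of species concentrations.
#' @return Signed scalar flux (concentration / s).
#' @export
#' @examples
#' rx <- reaction_def("b", c(A = 1, B = 1), c(AB = 1), kf = 1, kr = 0.5)
#' mass_action_rate(rx, c(A = 2, B = 3, AB = 4))  # 1*2*3 - 0.5*4 = 4
mass_action_rate <- function(reaction, state) {
  stopifnot(inherits(reaction, "sbn_reaction"))
  if (reaction$rate_form != "mass_action")
    stop("mass_action_rate() requires rate_form = 'mass_action'", call. = FALSE)
  state <- unlist(state)
  refs <- c(names(reaction$reactants), names(reaction$products),
            names(reaction$inhibitors))
  missing <- setdiff(refs, names(state))
  if (length(missing))
    stop("state is missing species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(state[refs] < 0))
    stop("negative concentration supplied to mass_action_rate()", call. = FALSE)
  fwd <- reaction$kf * prod(state[names(reaction$reactants)]^reaction$reactants)
  if (length(reaction$inhibitors))
    fwd <- fwd / prod(1 + reaction$inhibitors * state[names(reaction$inhibitors)])
  rev <- if (reaction$kr > 0)
    reaction$kr * prod(state[names(reaction$products)]^reaction$products)
  else 0
  fwd - rev
}

#' Stoichiometric matrix
#'
#' The species-by-reactions integer matrix N with entry (i, j) equal to the
#' net stoichiometric change of species i in reaction j. The ODE system is
#' `dx/dt = N v(x)` with `v` the vector of net reaction rates (one column per
#' reaction; reversibility is carried by the rate, not by a second column).
#'
#' @param model An `sbn_model`.
#' @return Integer matrix with species ids as rownames and reaction ids as
#'   colnames.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "sbn_model"))
  sp <- species_ids(model)
  rid <- reaction_ids(model)
  N <- matrix(0L, nrow = length(sp), ncol = length(rid),
              dimnames = list(sp, rid))
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    for (s in names(rx$reactants))
      N[s, j] <- N[s, j] - as.integer(rx$reactants[[s]])
    for (s in names(rx$products))
      N[s, j] <- N[s, j] + as.integer(rx$products[[s]])
  }
  N
}

# Evaluate all net reaction rates at a state. Used by the ODE right-hand
# side; kept separate so tests can compare against a brute-force loop.
reaction_rates <- function(model, state) {
  v <- numeric(length(model$reactions))
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    if (rx$rate_form == "mass_action") {
      fwd <- rx$kf
      for (s in names(rx$reactants)) fwd <- fwd * state[[s]]^rx$reactants[[s]]
      if (length(rx$inhibitors))
        fwd <- fwd / prod(1 + rx$inhibitors * state[names(rx$inhibitors)])
      rev <- 0
      if (rx$kr > 0) {
        rev <- rx$kr
        for (s in names(rx$products)) rev <- rev * state[[s]]^rx$products[[s]]
      }
      v[j] <- fwd - rev
    } else {
      s1 <- names(rx$reactants)[1L]
      v[j] <- rx$vmax * state[[s1]] / (rx$km + state[[s1]])
    }
  }
  v
}

apply_rules <- function(model, state, env_extra = NULL) {
  if (!length(model$rules)) return(state)
  env <- as.list(state)
  if (length(model$parameters)) env <- c(env, as.list(model$parameters))
  if (!is.null(env_extra)) env <- c(env, env_extra)
  for (rule in model$rules) {
    val <- eval(parse(text = rule$math), envir = env)
    state[[rule$target]] <- val
    env[[rule$target]] <- val
  }
  state
}

#' Build the ODE right-hand side of a model
#'
#' Returns `f(t, y)` computing `dy/dt = N v(y)`, with assignment rules
#' applied before flux evaluation and the derivative of constant species and
#' rule targets forced to zero. Reaction indices are resolved once at build
#' time, so the returned closure evaluates all mass-action fluxes in a few
#' vectorised operations per call.
#'
#' @param model A validated `sbn_model`.
#' @return Function of `(t, y)` returning the derivative vector in species
#'   order.
#' @export
build_ode_rhs <- function(model) {
  rep <- validate_model(model)
  if (length(rep$errors))
    stop("model does not validate: ", paste(rep$errors, collapse = "; "),
         call. = FALSE)
  N <- stoichiometric_matrix(model)
  storage.mode(N) <- "double"
  sp <- species_ids(model)
  n <- length(sp)
  pad <- n + 1L                    # index of a constant 1 in the padded state
  frozen <- constant_flags(model)
  rule_targets <- vapply(model$rules, `[[`, character(1), "target")
  frozen[rule_targets] <- TRUE
  has_rules <- length(model$rules) > 0L

  nr <- length(model$reactions)
  i1 <- i2 <- p1 <- p2 <- rep(pad, nr)
  kfv <- krv <- numeric(nr)
  is_mm <- logical(nr)
  mm_s <- integer(nr); mm_km <- mm_vmax <- numeric(nr)
  inh <- list()
  for (j in seq_len(nr)) {
    rx <- model$reactions[[j]]
    ri <- rep(match(names(rx$reactants), sp), times = rx$reactants)
    pi <- rep(match(names(rx$products), sp), times = rx$products)
    if (length(ri) >= 1L) i1[j] <- ri[1L]
    if (length(ri) >= 2L) i2[j] <- ri[2L]
    if (length(pi) >= 1L) p1[j] <- pi[1L]
    if (length(pi) >= 2L) p2[j] <- pi[2L]
    kfv[j] <- rx$kf; krv[j] <- rx$kr
    if (rx$rate_form == "michaelis_menten") {
      is_mm[j] <- TRUE
      mm_s[j] <- match(names(rx$reactants)[1L], sp)
      mm_km[j] <- rx$km; mm_vmax[j] <- rx$vmax
    }
    if (length(rx$inhibitors))
      inh[[length(inh) + 1L]] <- list(
        j = j, m = match(names(rx$inhibitors), sp),
        s = unname(rx$inhibitors))
  }

  function(t, y) {
    names(y) <- sp
    if (has_rules) y <- apply_rules(model, y)
    yp <- c(unname(y), 1)
    vf <- kfv * yp[i1] * yp[i2]
    for (b in inh) vf[b$j] <- vf[b$j] / prod(1 + b$s * yp[b$m])
    v <- vf - krv * yp[p1] * yp[p2]
    if (any(is_mm)) {
      jj <- which(is_mm)
      v[jj] <- mm_vmax[jj] * yp[mm_s[jj]] / (mm_km[jj] + yp[mm_s[jj]])
    }
    dy <- as.numeric(N %*% v)
    dy[frozen] <- 0
    names(dy) <- sp
    dy
  }
}

#' Conserved moieties of a reaction network
#'
#' Computes an integer basis of the left null space of the stoichiometric
#' matrix restricted to non-constant species: vectors `c` with `t(c) %*% N
#' == 0`, i.e. weighted species totals that no reaction can change (total
#' receptor, total Ras, total MEK across phospho-forms, ...). Exact integer
#' arithmetic (gcd-based column elimination), so `max(abs(t(c) %*% N))` is
#' exactly zero for every returned vector.
#'
#' @param model An `sbn_model`.
#' @return List of named integer vectors (names are the non-constant species
#'   ids); empty list if the network has no conservation law.
#' @export
#' @examples
#' m <- network_model(
#'   species = list(species_def("A", initial = 1), species_def("B", initial = 1),
#'                  species_def("AB")),
#'   reactions = list(reaction_def("b", c(A = 1, B = 1), c(AB = 1), kf = 1, kr = 0.5)))
#' conserved_moieties(m)   # A + AB and B + AB
conserved_moieties <- function(model) {
  N <- stoichiometric_matrix(model)
  keep <- !constant_flags(model)
  rule_targets <- vapply(model$rules, `[[`, character(1), "target")
  keep[rule_targets] <- FALSE
  N <- N[keep, , drop = FALSE]
  if (nrow(N) == 0L) return(list())
  basis <- integer_kernel(t(N))       # columns c with N^T c = 0
  lapply(seq_len(ncol(basis)), function(j) {
    v <- basis[, j]
    names(v) <- rownames(N)
    v
  })
}

# Integer kernel of an integer matrix A: basis of {x : A x = 0}.
# Column-reduction of rbind(A, I) with exact gcd (Euclidean) column
# operations; columns whose A-block vanishes carry kernel vectors in the
# identity block. Entries stay integral throughout.
integer_kernel <- function(A) {
  A <- round(A)
  r <- nrow(A); c <- ncol(A)
  M <- rbind(A, diag(c))
  active <- seq_len(c)
  for (i in seq_len(r)) {
    nz <- active[M[i, active] != 0]
    while (length(nz) > 1L) {
      o <- nz[order(abs(M[i, nz]))]
      k <- o[1L]; j <- o[2L]
      q <- M[i, j] %/% M[i, k]
      M[, j] <- M[, j] - q * M[, k]
      nz <- active[M[i, active] != 0]
    }
    if (length(nz) == 1L) active <- setdiff(active, nz)
  }
  ker <- M[(r + 1):(r + c), active, drop = FALSE]
  if (ncol(ker)) {
    for (j in seq_len(ncol(ker))) {
      v <- ker[, j]
      g <- Reduce(gcd2, abs(v[v != 0]))
      if (!is.null(g) && g > 1) v <- v / g
      if (v[which(v != 0)[1L]] < 0) v <- -v
      ker[, j] <- v
    }
  }
  ker
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' @export
print.sbn_model <- function(x, ...) {
  cnt <- validate_model(x)$counts
  cat(sprintf("<sbn_model '%s'> scenario %s: %d species, %d reactions, %d parameters, %d rules\n",
              x$id, x$scenario, cnt["species"], cnt["reactions"],
              cnt["parameters"], cnt["rules"]))
  invisible(x)
}

#' @export
summary.sbn_model <- function(object, ...) model_summary(object)
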