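#' Default parameter ledger
#'
#' Baseline rate constants (1/s or 1/(concentration*s)) and initial amounts
#' (concentration units) for every reaction and species the scenario builder
#' emits, each tagged with its provenance. Values are literature-style
#' defaults for receptor-tyrosine-kinase MAPK / PI3K cascade models,
#' calibrated once so that the subordinate-follicle (SF) versus
#' dominant-follicle (DF) comparisons show the expected pattern: stronger
#' and earlier downstream activation in DF, a later and weaker response in
#' SF, and loss of total MYC under miRNA translational repression.
#'
#' @return List of class `sbn_ledger` with `rates`, `initials`,
#'   `provenance`.
#' @export
default_ledger <- function() {
  rates <- c(
    # receptor layer
    kf_bind1 = 0.1,    kr_bind1 = 0.01,   # ANGPT1 + TEK
    kf_bind2 = 0.1,    kr_bind2 = 0.01,   # ANGPT2 + TEK (antagonist arm)
    kf_dim   = 0.05,   kr_dim   = 0.01,   # ligand-bound receptor dimerization
    k_autophos = 0.1,                      # dimer autophosphorylation
    k_internal = 0.08,                     # phospho-receptor internalization
    # adaptors and Ras
    k_shc = 0.02,      k_shc_off = 0.03,
    kf_grb_shc = 0.02, kr_grb_shc = 0.03,
    kf_sos_shc = 0.02, kr_sos_shc = 0.03,
    kf_grb_rt = 0.01,  kr_grb_rt = 0.03,
    kf_sos_rt = 0.01,  kr_sos_rt = 0.03,
    k_gef = 0.01,      k_gap = 0.04,
    # MAPK tier
    k_rafact = 0.01,   k_rafdeact = 0.03,
    k_mekp = 0.008,    k_mekdp = 0.03,
    k_erkp = 0.01,     k_erkdp = 0.002,
    # MYC turnover and phosphorylation
    k_mycsyn = 0.001,  k_mycdeg = 0.0001,
    k_mycp = 0.004,    k_mycp2 = 0.001,   k_mycdp = 0.002,
    k_pmycdeg = 0.004, k_myc_destab = 0.012,
    # PI3K / Akt tier
    kf_p85 = 0.02,     kr_p85 = 0.02,
    kf_p110 = 0.05,    kr_p110 = 0.02,
    k_irs = 0.01,      k_irsdp = 0.01,
    k_pi3k = 0.004,    k_pten = 0.03,
    kf_pdk = 0.02,     kr_pdk = 0.01,
    k_aktp = 0.005,    k_aktdp = 0.008,
    k_crebp = 0.003,   k_crebdp = 0.004,
    k_mclp = 0.003,    k_mcldp = 0.004,
    k_torp = 0.002,    k_tordp = 0.004,
    k_4ebp = 0.0015,   k_4ebpdp = 0.003,
    # miRNA action (DF+miRNA scenario)
    s_mir_myc = 1.0,                       # translation-block strength per miRNA
    k_mir_tek = 1e-05                      # TEK removal per unit miRNA
  )
  initials <- c(
    ANGPT1 = 5, ANGPT2 = 5, TEK = 3,
    Shc = 5, Grb2 = 5, SOS = 2,
    RasGDP = 10, Raf1 = 5, MEK = 10, ERK = 10,
    MYC = 10,                              # = k_mycsyn / k_mycdeg (rest state)
    PIK3R1 = 5, PIK3CA = 5, IRS1 = 10,
    PIP2 = 20, PTEN = 1, PDK1 = 2, Akt = 10,
    CREB = 5, Mcl1 = 5, mTORC1 = 5, EIF4EBP1 = 10
  )
  structure(
    list(rates = rates, initials = initials,
         provenance = stats::setNames(
           rep("literature-default", length(rates) + length(initials)),
           c(names(rates), names(initials)))),
    class = "sbn_ledger"
  )
}

#' Log-normal perturbation of a parameter ledger
#'
#' Multiplies every rate constant by an independent mean-one log-normal
#' factor with the given coefficient of variation; used for robustness
#' analysis of the cross-scenario orderings. Deterministic for a fixed seed;
#' `cv = 0` returns the ledger unchanged.
#'
#' @param ledger An `sbn_ledger`.
#' @param seed Integer RNG seed.
#' @param coefficient_of_variation cv >= 0 of the multiplicative noise.
#' @return A perturbed `sbn_ledger` (provenance marked "sampled").
#' @export
sample_parameters <- function(ledger, seed, coefficient_of_variation = 0.2) {
  stopifnot(inherits(ledger, "sbn_ledger"))
  cv <- coefficient_of_variation
  if (cv < 0) stop("coefficient_of_variation must be >= 0", call. = FALSE)
  if (cv == 0) return(ledger)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  fac <- stats::rlnorm(length(ledger$rates), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  ledger$rates <- ledger$rates * fac
  ledger$provenance[names(ledger$rates)] <- "sampled"
  ledger
}

.Random.seed_save <- function()
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

#' Scenario specification
#'
#' Declarative description of how the three follicle models differ.
#' Subordinate follicles (SF) are the baseline: all expression multipliers 1
#' and no miRNAs. Dominant follicles (DF) share the identical reaction
#' topology but start from different initial amounts — ANGPT1 and the TEK
#' receptor elevated, the antagonist ANGPT2 reduced, Ras and the PI3K
#' regulatory subunit elevated (defaults 2x / 0.5x). The DF+miRNA scenario
#' is DF plus four constitutively supplied miRNA species: hsa-miR-30d-3p and
#' hsa-miR-451a repress MYC translation; hsa-miR-548v and bta-miR-22-3p
#' drive TEK removal.
#'
#' @param scenario `"SF"`, `"DF"` or `"DF_miRNA"`.
#' @param expression_multipliers Named positive fold-changes for the axes
#'   `ANGPT1`, `ANGPT2`, `TEK`, `RAS`, `PIK3R1`, applied to initial amounts.
#'   Defaults depend on the scenario.
#' @param mirna_levels Named non-negative initial amounts for the four
#'   miRNAs (zero in SF/DF; 1 each in DF_miRNA by default). Hyphenated ids
#'   (`hsa-miR-30d-3p`) are accepted and canonicalised to underscores.
#' @param seed Integer seed recorded for parameter sampling.
#' @return List of class `sbn_scenario`.
#' @export
scenario_spec <- function(scenario = c("SF", "DF", "DF_miRNA"),
                          expression_multipliers = NULL,
                          mirna_levels = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  axes <- c("ANGPT1", "ANGPT2", "TEK", "RAS", "PIK3R1")
  mults <- stats::setNames(rep(1, length(axes)), axes)
  if (scenario != "SF")
    mults[] <- c(ANGPT1 = 2, ANGPT2 = 0.5, TEK = 2, RAS = 2, PIK3R1 = 2)[axes]
  if (!is.null(expression_multipliers)) {
    bad <- setdiff(names(expression_multipliers), axes)
    if (length(bad)) stop("unknown expression axis: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (any(expression_multipliers <= 0))
      stop("expression multipliers must be positive", call. = FALSE)
    mults[names(expression_multipliers)] <- expression_multipliers
  }
  mirs <- c(hsa_miR_30d_3p = 0, hsa_miR_451a = 0,
            hsa_miR_548v = 0, bta_miR_22_3p = 0)
  if (scenario == "DF_miRNA") mirs[] <- 1
  if (!is.null(mirna_levels)) {
    names(mirna_levels) <- canonical_mirna_id(names(mirna_levels))
    bad <- setdiff(names(mirna_levels), names(mirs))
    if (length(bad)) stop("unknown miRNA: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (any(mirna_levels < 0)) stop("miRNA levels must be >= 0", call. = FALSE)
    mirs[names(mirna_levels)] <- mirna_levels
  }
  if (scenario == "SF" && (any(mults != 1) || any(mirs != 0)))
    stop("SF is the baseline: all multipliers 1 and all miRNA levels 0",
         call. = FALSE)
  if (scenario == "DF" && any(mirs != 0))
    stop("DF carries no miRNA species", call. = FALSE)
  if (scenario == "DF_miRNA" && any(mirs == 0))
    stop("DF_miRNA requires strictly positive levels for all four miRNAs",
         call. = FALSE)
  structure(list(scenario = scenario, expression_multipliers = mults,
                 mirna_levels = mirs, seed = as.integer(seed)),
            class = "sbn_scenario")
}

canonical_mirna_id <- function(x) gsub("-", "_", x, fixed = TRUE)

sp <- function(id, init = 0, constant = FALSE) species_def(id, initial = init, constant = constant)

#' Receptor-layer module
#'
#' Angiopoietin binding to the TEK receptor tyrosine kinase: ANGPT1 and
#' ANGPT2 compete for TEK; only the ANGPT1-bound receptor homodimerizes and
#' autophosphorylates (ANGPT2 is the non-signalling antagonist arm); the
#' phosphorylated receptor is slowly internalized, which makes the signal a
#' transient that decays with a mild slope.
#'
#' @param ledger An `sbn_ledger` supplying rate constants and initial
#'   amounts.
#' @return A partial `sbn_model` (receptor species and reactions only).
#' @export
build_receptor_module <- function(ledger = default_ledger()) {
  k <- ledger$rates; x0 <- ledger$initials
  network_model(
    id = "receptor",
    species = list(
      sp("ANGPT1", x0[["ANGPT1"]]), sp("ANGPT2", x0[["ANGPT2"]]),
      sp("TEK", x0[["TEK"]]),
      sp("ANGPT1_TEK"), sp("ANGPT2_TEK"),
      sp("ANGPT1_TEK_dimer"), sp("ANGPT1_TEK_p"), sp("TEK_internalized")),
    reactions = list(
      reaction_def("bind_angpt1", c(ANGPT1 = 1, TEK = 1), c(ANGPT1_TEK = 1),
                   kf = k[["kf_bind1"]], kr = k[["kr_bind1"]]),
      reaction_def("bind_angpt2", c(ANGPT2 = 1, TEK = 1), c(ANGPT2_TEK = 1),
                   kf = k[["kf_bind2"]], kr = k[["kr_bind2"]]),
      reaction_def("dimerize", c(ANGPT1_TEK = 2), c(ANGPT1_TEK_dimer = 1),
                   kf = k[["kf_dim"]], kr = k[["kr_dim"]]),
      reaction_def("autophos", c(ANGPT1_TEK_dimer = 1), c(ANGPT1_TEK_p = 1),
                   kf = k[["k_autophos"]]),
      reaction_def("internalize", c(ANGPT1_TEK_p = 1), c(TEK_internalized = 1),
                   kf = k[["k_internal"]])))
}

#' Adaptor and Ras module
#'
#' Shc phosphorylation on the active receptor, Grb2/SOS recruitment through
#' Shc and directly on receptor phospho-tyrosines, SOS-catalysed
#' Ras-GDP to Ras-GTP exchange and a GAP-like first-order return step.
#' Total Ras (GDP + GTP) is conserved by construction.
#'
#' @inheritParams build_receptor_module
#' @return A partial `sbn_model`.
#' @export
build_adaptor_ras_module <- function(ledger = default_ledger()) {
  k <- ledger$rates; x0 <- ledger$initials
  network_model(
    id = "adaptor_ras",
    species = list(
      sp("Shc", x0[["Shc"]]), sp("pShc"), sp("Grb2", x0[["Grb2"]]),
      sp("SOS", x0[["SOS"]]), sp("pShc_Grb2"), sp("pShc_Grb2_SOS"),
      sp("RTp_Grb2"), sp("RTp_Grb2_SOS"),
      sp("RasGDP", x0[["RasGDP"]]), sp("RasGTP")),
    reactions = list(
      reaction_def("shc_phos", c(Shc = 1, ANGPT1_TEK_p = 1),
                   c(pShc = 1, ANGPT1_TEK_p = 1), kf = k[["k_shc"]]),
      reaction_def("shc_dephos", c(pShc = 1), c(Shc = 1), kf = k[["k_shc_off"]]),
      reaction_def("grb2_shc", c(pShc = 1, Grb2 = 1), c(pShc_Grb2 = 1),
                   kf = k[["kf_grb_shc"]], kr = k[["kr_grb_shc"]]),
      reaction_def("sos_shc", c(pShc_Grb2 = 1, SOS = 1), c(pShc_Grb2_SOS = 1),
                   kf = k[["kf_sos_shc"]], kr = k[["kr_sos_shc"]]),
      reaction_def("grb2_rt", c(ANGPT1_TEK_p = 1, Grb2 = 1), c(RTp_Grb2 = 1),
                   kf = k[["kf_grb_rt"]], kr = k[["kr_grb_rt"]]),
      reaction_def("sos_rt", c(RTp_Grb2 = 1, SOS = 1), c(RTp_Grb2_SOS = 1),
                   kf = k[["kf_sos_rt"]], kr = k[["kr_sos_rt"]]),
      reaction_def("ras_exchange_shc", c(RasGDP = 1, pShc_Grb2_SOS = 1),
                   c(RasGTP = 1, pShc_Grb2_SOS = 1), kf = k[["k_gef"]]),
      reaction_def("ras_exchange_rt", c(RasGDP = 1, RTp_Grb2_SOS = 1),
                   c(RasGTP = 1, RTp_Grb2_SOS = 1), kf = k[["k_gef"]]),
      reaction_def("ras_gap", c(RasGTP = 1), c(RasGDP = 1), kf = k[["k_gap"]])))
}

#' MAPK cascade and MYC module
#'
#' Ras-GTP-dependent Raf1 activation, distributive two-site phosphorylation
#' of MEK (by active Raf1) and of ERK (by ppMEK) with phosphatase return
#' steps at every tier, and ERK-catalysed two-site MYC phosphorylation. MYC
#' is the one pool with explicit turnover (zero-order synthesis, first-order
#' decay) so translational repression can lower its total; phosphorylated
#' MYC decays faster than the unmodified protein, which lets a strongly
#' ERK-activated cell run its MYC pool down.
#'
#' @inheritParams build_receptor_module
#' @return A partial `sbn_model`.
#' @export
build_mapk_myc_module <- function(ledger = default_ledger()) {
  k <- ledger$rates; x0 <- ledger$initials
  network_model(
    id = "mapk_myc",
    species = list(
      sp("Raf1", x0[["Raf1"]]), sp("Raf1_active"),
      sp("MEK", x0[["MEK"]]), sp("pMEK"), sp("ppMEK"),
      sp("ERK", x0[["ERK"]]), sp("pERK"), sp("ppERK"),
      sp("MYC", x0[["MYC"]]), sp("pMYC"), sp("ppMYC")),
    reactions = list(
      reaction_def("raf_activate", c(Raf1 = 1, RasGTP = 1),
                   c(Raf1_active = 1, RasGTP = 1), kf = k[["k_rafact"]]),
      reaction_def("raf_deactivate", c(Raf1_active = 1), c(Raf1 = 1),
                   kf = k[["k_rafdeact"]]),
      reaction_def("mek_phos1", c(MEK = 1, Raf1_active = 1),
                   c(pMEK = 1, Raf1_active = 1), kf = k[["k_mekp"]]),
      reaction_def("mek_phos2", c(pMEK = 1, Raf1_active = 1),
                   c(ppMEK = 1, Raf1_active = 1), kf = k[["k_mekp"]]),
      reaction_def("mek_dephos2", c(ppMEK = 1), c(pMEK = 1), kf = k[["k_mekdp"]]),
      reaction_def("mek_dephos1", c(pMEK = 1), c(MEK = 1), kf = k[["k_mekdp"]]),
      reaction_def("erk_phos1", c(ERK = 1, ppMEK = 1),
                   c(pERK = 1, ppMEK = 1), kf = k[["k_erkp"]]),
      reaction_def("erk_phos2", c(pERK = 1, ppMEK = 1),
                   c(ppERK = 1, ppMEK = 1), kf = k[["k_erkp"]]),
      reaction_def("erk_dephos2", c(ppERK = 1), c(pERK = 1), kf = k[["k_erkdp"]]),
      reaction_def("erk_dephos1", c(pERK = 1), c(ERK = 1), kf = k[["k_erkdp"]]),
      reaction_def("myc_synthesis", NULL, c(MYC = 1), kf = k[["k_mycsyn"]]),
      reaction_def("myc_decay", c(MYC = 1), NULL, kf = k[["k_mycdeg"]]),
      reaction_def("myc_phos1", c(MYC = 1, ppERK = 1),
                   c(pMYC = 1, ppERK = 1), kf = k[["k_mycp"]]),
      reaction_def("myc_phos2", c(pMYC = 1, ppERK = 1),
                   c(ppMYC = 1, ppERK = 1), kf = k[["k_mycp2"]]),
      reaction_def("myc_dephos2", c(ppMYC = 1), c(pMYC = 1), kf = k[["k_mycdp"]]),
      reaction_def("myc_dephos1", c(pMYC = 1), c(MYC = 1), kf = k[["k_mycdp"]]),
      reaction_def("pmyc_decay", c(pMYC = 1), NULL, kf = k[["k_pmycdeg"]]),
      reaction_def("ppmyc_decay", c(ppMYC = 1), NULL, kf = k[["k_pmycdeg"]]),
      reaction_def("myc_destab", c(MYC = 1, RasGTP = 1), c(RasGTP = 1),
                   kf = k[["k_myc_destab"]])))
}

#' PI3K / Akt / mTORC1 module
#'
#' Recruitment of the p85 regulatory subunit (PIK3R1) to the phosphorylated
#' receptor and assembly with the p110 catalytic subunit (PIK3CA) into
#' active PI3K; IRS1 phosphorylation; PI3K-catalysed PIP2 to PIP3 conversion
#' opposed by PTEN; PIP3-dependent PDK1 activation of Akt; and the two Akt
#' output branches — CREB to Mcl1, and mTORC1 to EIF4EBP1 (phosphorylation
#' of the translation repressor inactivates it).
#'
#' @inheritParams build_receptor_module
#' @return A partial `sbn_model`.
#' @export
build_pi3k_akt_module <- function(ledger = default_ledger()) {
  k <- ledger$rates; x0 <- ledger$initials
  network_model(
    id = "pi3k_akt",
    species = list(
      sp("PIK3R1", x0[["PIK3R1"]]), sp("PIK3CA", x0[["PIK3CA"]]),
      sp("RTp_PIK3R1"), sp("PI3K_active"),
      sp("IRS1", x0[["IRS1"]]), sp("pIRS1"),
      sp("PIP2", x0[["PIP2"]]), sp("PIP3"), sp("PTEN", x0[["PTEN"]]),
      sp("PDK1", x0[["PDK1"]]), sp("PDK1_PIP3"),
      sp("Akt", x0[["Akt"]]), sp("pAkt"),
      sp("CREB", x0[["CREB"]]), sp("pCREB"),
      sp("Mcl1", x0[["Mcl1"]]), sp("pMcl1"),
      sp("mTORC1", x0[["mTORC1"]]), sp("pmTORC1"),
      sp("EIF4EBP1", x0[["EIF4EBP1"]]), sp("pEIF4EBP1")),
    reactions = list(
      reaction_def("p85_recruit", c(ANGPT1_TEK_p = 1, PIK3R1 = 1),
                   c(RTp_PIK3R1 = 1), kf = k[["kf_p85"]], kr = k[["kr_p85"]]),
      reaction_def("p110_assemble", c(RTp_PIK3R1 = 1, PIK3CA = 1),
                   c(PI3K_active = 1), kf = k[["kf_p110"]], kr = k[["kr_p110"]]),
      reaction_def("irs1_phos", c(IRS1 = 1, ANGPT1_TEK_p = 1),
                   c(pIRS1 = 1, ANGPT1_TEK_p = 1), kf = k[["k_irs"]]),
      reaction_def("irs1_dephos", c(pIRS1 = 1), c(IRS1 = 1), kf = k[["k_irsdp"]]),
      reaction_def("pip2_to_pip3", c(PIP2 = 1, PI3K_active = 1),
                   c(PIP3 = 1, PI3K_active = 1), kf = k[["k_pi3k"]]),
      reaction_def("pten_reverse", c(PIP3 = 1, PTEN = 1),
                   c(PIP2 = 1, PTEN = 1), kf = k[["k_pten"]]),
      reaction_def("pdk1_bind", c(PDK1 = 1, PIP3 = 1), c(PDK1_PIP3 = 1),
                   kf = k[["kf_pdk"]], kr = k[["kr_pdk"]]),
      reaction_def("akt_phos", c(Akt = 1, PDK1_PIP3 = 1),
                   c(pAkt = 1, PDK1_PIP3 = 1), kf = k[["k_aktp"]]),
      reaction_def("akt_dephos", c(pAkt = 1), c(Akt = 1), kf = k[["k_aktdp"]]),
      reaction_def("creb_phos", c(CREB = 1, pAkt = 1),
                   c(pCREB = 1, pAkt = 1), kf = k[["k_crebp"]]),
      reaction_def("creb_dephos", c(pCREB = 1), c(CREB = 1), kf = k[["k_crebdp"]]),
      reaction_def("mcl1_activate", c(Mcl1 = 1, pCREB = 1),
                   c(pMcl1 = 1, pCREB = 1), kf = k[["k_mclp"]]),
      reaction_def("mcl1_deactivate", c(pMcl1 = 1), c(Mcl1 = 1), kf = k[["k_mcldp"]]),
      reaction_def("mtorc1_activate", c(mTORC1 = 1, pAkt = 1),
                   c(pmTORC1 = 1, pAkt = 1), kf = k[["k_torp"]]),
      reaction_def("mtorc1_deactivate", c(pmTORC1 = 1), c(mTORC1 = 1),
                   kf = k[["k_tordp"]]),
      reaction_def("eif4ebp1_phos", c(EIF4EBP1 = 1, pmTORC1 = 1),
                   c(pEIF4EBP1 = 1, pmTORC1 = 1), kf = k[["k_4ebp"]]),
      reaction_def("eif4ebp1_dephos", c(pEIF4EBP1 = 1), c(EIF4EBP1 = 1),
                   kf = k[["k_4ebpdp"]])))
}

merge_models <- function(..., id = "assembled", scenario = "custom") {
  parts <- list(...)
  species <- list(); reactions <- list(); params <- numeric(0); rules <- list()
  seen <- character(0)
  for (p in parts) {
    for (s in p$species) if (!s$id %in% seen) {
      species[[length(species) + 1L]] <- s
      seen <- c(seen, s$id)
    }
    reactions <- c(reactions, p$reactions)
    params <- c(params, p$parameters)
    rules <- c(rules, p$rules)
  }
  network_model(species = species, reactions = reactions, parameters = params,
                rules = rules, scenario = scenario, id = id)
}

#' Add a miRNA repression motif to a model
#'
#' Two repression modes are supported, matching how the four follicle miRNAs
#' act. `translation_block` divides the target's synthesis flux by
#' `(1 + strength * [miRNA])` (competitive repression of translation;
#' repeated application multiplies factors). `receptor_suppression` adds a
#' miRNA-dependent removal reaction, first order in the target
#' (`target + miRNA -> miRNA`, rate `strength*[target]*[miRNA]`). The miRNA
#' is added as a constant (buffered) species if not already present.
#'
#' @param model An `sbn_model`.
#' @param mirna_id miRNA identifier (hyphens are canonicalised to
#'   underscores).
#' @param target_id Species whose synthesis is blocked
#'   (`translation_block`) or which is removed (`receptor_suppression`).
#' @param mode `"translation_block"` or `"receptor_suppression"`.
#' @param strength Non-negative repression strength (dimensionless per unit
#'   miRNA for the block; 1/(concentration*s) for suppression).
#' @param level Initial amount of the miRNA species if it must be created.
#' @return The augmented `sbn_model`.
#' @export
add_mirna_repression <- function(model, mirna_id, target_id,
                                 mode = c("translation_block", "receptor_suppression"),
                                 strength, level = 1) {
  mode <- match.arg(mode)
  if (strength < 0) stop("strength must be >= 0", call. = FALSE)
  mirna_id <- canonical_mirna_id(mirna_id)
  ids <- species_ids(model)
  if (!target_id %in% ids)
    stop("unknown target species: ", target_id, call. = FALSE)
  if (!mirna_id %in% ids)
    model$species[[length(model$species) + 1L]] <-
      species_def(mirna_id, name = gsub("_", "-", mirna_id),
                  initial = level, constant = TRUE)
  if (mode == "translation_block") {
    hit <- FALSE
    for (j in seq_along(model$reactions)) {
      rx <- model$reactions[[j]]
      if (length(rx$reactants) == 0L && target_id %in% names(rx$products)) {
        inh <- c(rx$inhibitors, stats::setNames(strength, mirna_id))
        model$reactions[[j]]$inhibitors <- inh
        hit <- TRUE
      }
    }
    if (!hit)
      stop("no synthesis reaction found for target '", target_id, "'",
           call. = FALSE)
  } else {
    rid <- paste0("suppress_", target_id, "_by_", mirna_id)
    model$reactions[[length(model$reactions) + 1L]] <-
      reaction_def(rid,
                   stats::setNames(c(1, 1), c(target_id, mirna_id)),
                   stats::setNames(1, mirna_id),
                   kf = strength)
  }
  model
}

#' Build a complete scenario model
#'
#' Assembles the receptor, adaptor/Ras, MAPK/MYC and PI3K/Akt/mTORC1 modules
#' into one network, applies the scenario's expression multipliers to the
#' initial amounts, and, for DF_miRNA, adds the four miRNA species with
#' their repression reactions. SF and DF share the identical topology
#' (identical reaction list; the scenarios differ only in initial values);
#' DF_miRNA is a strict superset. The assembled model carries one assignment
#' rule defining the total-active-ERK observable (`ERK_active_total`), the
#' substitution point for any model-specific algebraic rule.
#'
#' @param spec An [scenario_spec()] object.
#' @param ledger An `sbn_ledger` of rate constants and baseline initial
#'   amounts.
#' @return A validated `sbn_model` (zero validation errors).
#' @export
#' @examples
#' sf <- build_scenario(scenario_spec("SF"))
#' df <- build_scenario(scenario_spec("DF"))
#' length(sf$reactions) == length(df$reactions)
build_scenario <- function(spec = scenario_spec("SF"), ledger = default_ledger()) {
  stopifnot(inherits(spec, "sbn_scenario"), inherits(ledger, "sbn_ledger"))
  m <- merge_models(
    build_receptor_module(ledger),
    build_adaptor_ras_module(ledger),
    build_mapk_myc_module(ledger),
    build_pi3k_akt_module(ledger),
    id = paste0("follicle_", spec$scenario),
    scenario = spec$scenario)
  # total-active-ERK observable via the generic assignment-rule mechanism
  m$species[[length(m$species) + 1L]] <- species_def("ERK_active_total")
  m$rules <- list(list(target = "ERK_active_total", math = "ppERK"))
  # expression multipliers act on initial amounts only
  axis_species <- c(ANGPT1 = "ANGPT1", ANGPT2 = "ANGPT2", TEK = "TEK",
                    RAS = "RasGDP", PIK3R1 = "PIK3R1")
  ids <- species_ids(m)
  for (ax in names(axis_species)) {
    i <- match(axis_species[[ax]], ids)
    m$species[[i]]$initial <- m$species[[i]]$initial * spec$expression_multipliers[[ax]]
  }
  if (spec$scenario == "DF_miRNA") {
    k <- ledger$rates
    lv <- spec$mirna_levels
    m <- add_mirna_repression(m, "hsa_miR_30d_3p", "MYC", "translation_block",
                              strength = k[["s_mir_myc"]], level = lv[["hsa_miR_30d_3p"]])
    m <- add_mirna_repression(m, "hsa_miR_451a", "MYC", "translation_block",
                              strength = k[["s_mir_myc"]], level = lv[["hsa_miR_451a"]])
    m <- add_mirna_repression(m, "hsa_miR_548v", "TEK", "receptor_suppression",
                              strength = k[["k_mir_tek"]], level = lv[["hsa_miR_548v"]])
    m <- add_mirna_repression(m, "bta_miR_22_3p", "TEK", "receptor_suppression",
                              strength = k[["k_mir_tek"]], level = lv[["bta_miR_22_3p"]])
  }
  rep <- validate_model(m)
  if (length(rep$errors))
    stop("assembled scenario fails validation: ",
         paste(rep$errors, collapse = "; "), call. = FALSE)
  m
}

#' Serialize / restore scenario and ledger configuration
#'
#' Human-editable YAML round-trip for a scenario specification together with
#' its parameter ledger.
#'
#' @param spec An `sbn_scenario`.
#' @param ledger An `sbn_ledger`.
#' @param path Output YAML file.
#' @return `path` invisibly ([write_scenario_config()]); a list with `spec`
#'   and `ledger` ([read_scenario_config()]).
#' @export
write_scenario_config <- function(spec, ledger, path) {
  yaml::write_yaml(list(
    scenario = spec$scenario,
    expression_multipliers = as.list(spec$expression_multipliers),
    mirna_levels = as.list(spec$mirna_levels),
    seed = spec$seed,
    rates = as.list(ledger$rates),
    initials = as.list(ledger$initials)), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ledger <- default_ledger()
  if (!is.null(cfg$rates)) ledger$rates[names(cfg$rates)] <- unlist(cfg$rates)
  if (!is.null(cfg$initials))
    ledger$initials[names(cfg$initials)] <- unlist(cfg$initials)
  spec <- scenario_spec(
    cfg$scenario,
    expression_multipliers = unlist(cfg$expression_multipliers),
    mirna_levels = if (cfg$scenario == "DF_miRNA") unlist(cfg$mirna_levels) else NULL,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  list(spec = spec, ledger = ledger)
}
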