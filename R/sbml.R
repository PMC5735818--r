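#' Structural summary of a model
#'
#' Counts species, reactions, parameters and rules. The parameter count is
#' the number of global parameters plus reaction-local rate constants (kf,
#' non-zero kr, km/vmax for saturable steps, inhibition strengths), the same
#' convention used by the SBML kinetic laws this package writes, so the
#' summary is invariant under an SBML write/read round-trip.
#'
#' @param model An `sbn_model`.
#' @param source Provenance label (file path or `"builder"`).
#' @return Object of class `sbn_summary`: `n_species`, `n_reactions`,
#'   `n_parameters`, `n_rules`, `source`.
#' @export
model_summary <- function(model, source = "builder") {
  stopifnot(inherits(model, "sbn_model"))
  cnt <- validate_model(model)$counts
  structure(
    list(n_species = unname(cnt["species"]),
         n_reactions = unname(cnt["reactions"]),
         n_parameters = unname(cnt["parameters"]),
         n_rules = unname(cnt["rules"]),
         source = source),
    class = "sbn_summary"
  )
}

#' @export
print.sbn_summary <- function(x, ...) {
  cat(sprintf("%d species, %d reactions, %d parameters, %d rules [%s]\n",
              x$n_species, x$n_reactions, x$n_parameters, x$n_rules, x$source))
  invisible(x)
}

#' @export
as.data.frame.sbn_summary <- function(x, ...) {
  data.frame(n_species = x$n_species, n_reactions = x$n_reactions,
             n_parameters = x$n_parameters, n_rules = x$n_rules,
             source = x$source, stringsAsFactors = FALSE)
}

sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
mathml_ns <- "http://www.w3.org/1998/Math/MathML"

#' Write a model to SBML
#'
#' Emits SBML Level 3 Version 1 with one compartment, full species and
#' reaction lists, assignment rules, and kinetic laws of the form
#' `kf*reactants - kr*products` (optionally divided by competitive-inhibition
#' factors) with reaction-local parameters. The document round-trips through
#' [read_sbml()] preserving counts and trajectories.
#'
#' @param model A validated `sbn_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  rep <- validate_model(model)
  if (length(rep$errors))
    stop("refusing to write invalid model: ",
         paste(rep$errors, collapse = "; "), call. = FALSE)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = TRUE)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', sbml_ns),
    sprintf('  <model id="%s" name="%s">', esc(model$id), esc(model$id)),
    '    <listOfCompartments>',
    '      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>',
    '    </listOfCompartments>'
  )
  if (length(model$species)) {
    out <- c(out, "    <listOfSpecies>")
    for (s in model$species) {
      out <- c(out, sprintf(
        '      <species id="%s" name="%s" compartment="cell" initialAmount="%s" hasOnlySubstanceUnits="false" boundaryCondition="%s" constant="%s"%s',
        esc(s$id), esc(s$name), num(s$initial),
        tolower(as.character(s$constant)), tolower(as.character(s$constant)),
        if (is.null(s$annotation)) "/>" else
          paste0(">", s$annotation, "</species>")))
    }
    out <- c(out, "    </listOfSpecies>")
  }
  if (length(model$parameters)) {
    out <- c(out, "    <listOfParameters>")
    for (pn in names(model$parameters))
      out <- c(out, sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                            esc(pn), num(model$parameters[[pn]])))
    out <- c(out, "    </listOfParameters>")
  }
  if (length(model$rules)) {
    out <- c(out, "    <listOfRules>")
    for (rule in model$rules) {
      out <- c(out,
        sprintf('      <assignmentRule variable="%s">', esc(rule$target)),
        sprintf('        <math xmlns="%s">', mathml_ns),
        infix_to_mathml(rule$math, indent = "          "),
        "        </math>",
        "      </assignmentRule>")
    }
    out <- c(out, "    </listOfRules>")
  }
  if (length(model$reactions)) {
    out <- c(out, "    <listOfReactions>")
    for (rx in model$reactions) {
      out <- c(out, sprintf('      <reaction id="%s" reversible="%s">',
                            esc(rx$id), tolower(as.character(rx$kr > 0))))
      side <- function(tag, v) {
        if (!length(v)) return(character(0))
        c(sprintf("        <listOf%s>", tag),
          sprintf('          <speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                  vapply(names(v), esc, ""), as.integer(v)),
          sprintf("        </listOf%s>", tag))
      }
      out <- c(out, side("Reactants", rx$reactants), side("Products", rx$products))
      if (length(rx$inhibitors))
        out <- c(out, "        <listOfModifiers>",
                 sprintf('          <modifierSpeciesReference species="%s"/>',
                         vapply(names(rx$inhibitors), esc, "")),
                 "        </listOfModifiers>")
      out <- c(out,
        "        <kineticLaw>",
        sprintf('          <math xmlns="%s">', mathml_ns),
        infix_to_mathml(rate_law_infix(rx), indent = "            "),
        "          </math>",
        "          <listOfLocalParameters>")
      lp <- local_parameters(rx)
      out <- c(out,
        sprintf('            <localParameter id="%s" value="%s"/>',
                names(lp), vapply(lp, num, "")),
        "          </listOfLocalParameters>",
        "        </kineticLaw>",
        "      </reaction>")
    }
    out <- c(out, "    </listOfReactions>")
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

local_parameters <- function(rx) {
  lp <- list(kf = rx$kf)
  if (rx$kr > 0) lp$kr <- rx$kr
  if (rx$rate_form == "michaelis_menten") { lp$km <- rx$km; lp$vmax <- rx$vmax }
  if (length(rx$inhibitors))
    for (m in names(rx$inhibitors)) lp[[paste0("inh_", m)]] <- rx$inhibitors[[m]]
  lp
}

# Infix rendering of a reaction's rate law (also the documented dialect the
# reader recognises).
rate_law_infix <- function(rx) {
  pw <- function(v) paste(vapply(names(v), function(s) {
    if (v[[s]] == 1) s else sprintf("%s^%d", s, as.integer(v[[s]]))
  }, ""), collapse = " * ")
  if (rx$rate_form == "michaelis_menten") {
    s1 <- names(rx$reactants)[1L]
    return(sprintf("vmax * %s / (km + %s)", s1, s1))
  }
  fwd <- if (length(rx$reactants)) paste("kf *", pw(rx$reactants)) else "kf"
  if (length(rx$inhibitors)) {
    fac <- paste(sprintf("(1 + inh_%s * %s)", names(rx$inhibitors),
                         names(rx$inhibitors)), collapse = " * ")
    fwd <- sprintf("%s / (%s)", fwd, fac)
  }
  if (rx$kr > 0) {
    rev <- if (length(rx$products)) paste("kr *", pw(rx$products)) else "kr"
    paste(fwd, "-", rev)
  } else fwd
}

# -- MathML (subset): emit from an R arithmetic expression, and parse back --

infix_to_mathml <- function(math, indent = "") {
  expr_to_mathml(parse(text = math)[[1]], indent)
}

expr_to_mathml <- function(e, ind) {
  if (is.numeric(e)) return(sprintf("%s<cn> %s </cn>", ind, format(e, digits = 17)))
  if (is.name(e)) return(sprintf("%s<ci> %s </ci>", ind, as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(expr_to_mathml(e[[2]], ind))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", NULL)
    if (is.null(tag))
      stop("unsupported operator in math expression: ", op, call. = FALSE)
    args <- lapply(as.list(e)[-1], expr_to_mathml, ind = paste0(ind, "    "))
    return(c(sprintf("%s<apply>", ind),
             sprintf("%s  <%s/>", ind, tag),
             unlist(args),
             sprintf("%s</apply>", ind)))
  }
  stop("unsupported math expression", call. = FALSE)
}

mathml_to_infix <- function(node) {
  kids <- xml2::xml_find_all(node, "./*")
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    if (length(kids) != 1L) stop("malformed MathML", call. = FALSE)
    return(mathml_to_infix(kids[[1]]))
  }
  if (nm == "ci") return(trimws(xml2::xml_text(node)))
  if (nm == "cn") return(trimws(xml2::xml_text(node)))
  if (nm == "apply") {
    op <- xml2::xml_name(kids[[1]])
    args <- vapply(kids[-1], mathml_to_infix, "")
    sym <- switch(op, plus = "+", minus = "-", times = "*",
                  divide = "/", power = "^", NULL)
    if (is.null(sym))
      stop("unsupported MathML operator: ", op, call. = FALSE)
    if (op == "minus" && length(args) == 1L)
      return(sprintf("(-%s)", args[1]))
    return(paste0("(", paste(args, collapse = paste0(" ", sym, " ")), ")"))
  }
  stop("unsupported MathML node: ", nm, call. = FALSE)
}

#' Read a model from SBML
#'
#' Parses SBML (Level 2 or Level 3 core) into an `sbn_model`: species with
#' initial amounts and constant/boundary flags, reactions with integer
#' stoichiometries, kinetic laws via their local parameters (`kf`, `kr`,
#' `km`/`vmax`, `inh_*` — the dialect [write_sbml()] emits), global
#' parameters and assignment rules. Kinetic laws without a recognisable
#' parameterisation raise an unsupported-feature error naming the reaction.
#' Annotation subtrees (e.g. CellDesigner extensions) are preserved as
#' opaque blobs and re-emitted on write.
#'
#' @param path SBML file path.
#' @return An `sbn_model`; its summary carries `path` as source.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, "./model")
  if (inherits(mdl, "xml_missing")) stop("not an SBML document: ", path, call. = FALSE)
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- "model"

  species <- lapply(xml2::xml_find_all(mdl, "./listOfSpecies/species"), function(nd) {
    id <- xml2::xml_attr(nd, "id")
    init <- xml2::xml_attr(nd, "initialAmount")
    if (is.na(init)) init <- xml2::xml_attr(nd, "initialConcentration")
    s <- species_def(
      id = id,
      name = if (is.na(xml2::xml_attr(nd, "name"))) id else xml2::xml_attr(nd, "name"),
      initial = if (is.na(init)) 0 else as.numeric(init),
      constant = isTRUE(xml2::xml_attr(nd, "constant") == "true") ||
        isTRUE(xml2::xml_attr(nd, "boundaryCondition") == "true"))
    ann <- xml2::xml_find_first(nd, "./annotation")
    if (!inherits(ann, "xml_missing")) s$annotation <- as.character(ann)
    s
  })

  pnodes <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  parameters <- stats::setNames(
    as.numeric(xml2::xml_attr(pnodes, "value")),
    xml2::xml_attr(pnodes, "id"))
  parameters <- parameters[!is.na(names(parameters))]

  rules <- lapply(xml2::xml_find_all(mdl, "./listOfRules/assignmentRule"), function(nd) {
    math <- xml2::xml_find_first(nd, "./math")
    list(target = xml2::xml_attr(nd, "variable"),
         math = mathml_to_infix(math))
  })

  reactions <- lapply(xml2::xml_find_all(mdl, "./listOfReactions/reaction"), function(nd) {
    rid <- xml2::xml_attr(nd, "id")
    side <- function(xp) {
      refs <- xml2::xml_find_all(nd, xp)
      if (!length(refs)) return(NULL)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, xml2::xml_attr(refs, "species"))
    }
    kl <- xml2::xml_find_first(nd, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction '", rid, "': missing kinetic law (unsupported)", call. = FALSE)
    lp <- xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
    lpv <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                           xml2::xml_attr(lp, "id"))
    if (!"kf" %in% names(lpv) && !all(c("km", "vmax") %in% names(lpv)))
      stop("reaction '", rid,
           "': unsupported kinetic-law construct (no kf or km/vmax local parameters)",
           call. = FALSE)
    inh <- lpv[startsWith(names(lpv), "inh_")]
    reaction_def(
      id = rid,
      reactants = side("./listOfReactants/speciesReference"),
      products = side("./listOfProducts/speciesReference"),
      kf = if ("kf" %in% names(lpv)) lpv[["kf"]] else 0,
      kr = if ("kr" %in% names(lpv)) lpv[["kr"]] else 0,
      rate_form = if (all(c("km", "vmax") %in% names(lpv)))
        "michaelis_menten" else "mass_action",
      km = if ("km" %in% names(lpv)) lpv[["km"]] else NA_real_,
      vmax = if ("vmax" %in% names(lpv)) lpv[["vmax"]] else NA_real_,
      inhibitors = if (length(inh))
        stats::setNames(unname(inh), sub("^inh_", "", names(inh))) else NULL)
  })

  network_model(species = species, reactions = reactions,
                parameters = parameters, rules = rules,
                scenario = "custom", id = model_id)
}

#' Canonical readout name map
#'
#' Pattern-based, many-to-one mapping from species identifiers to the
#' canonical kinetic readouts (ppMEK, ppERK, pMYC, total MYC, pAkt, ...).
#' `pMYC` aggregates singly and doubly phosphorylated MYC; `MYC_total`
#' aggregates all MYC phospho-forms.
#'
#' @return Named character vector: readout name -> regular expression over
#'   species ids.
#' @export
default_name_map <- function() {
  c(TEK          = "^TEK$",
    ANGPT1_TEK_p = "^ANGPT1_TEK_p$",
    RasGTP       = "^RasGTP$",
    Raf1_active  = "^Raf1_active$",
    ppMEK        = "^ppMEK$",
    ppERK        = "^ppERK$",
    pMYC         = "^p{1,2}MYC$",
    MYC_total    = "^(MYC|pMYC|ppMYC)$",
    pIRS1        = "^pIRS1$",
    PI3K         = "^PI3K_active$",
    pAkt         = "^pAkt$",
    pCREB        = "^pCREB$",
    pMcl1        = "^pMcl1$",
    pmTORC1      = "^pmTORC1$",
    pEIF4EBP1    = "^pEIF4EBP1$")
}

#' Resolve canonical readouts to species id sets
#'
#' @param model An `sbn_model`.
#' @param map Named character vector of regular expressions, as returned by
#'   [default_name_map()].
#' @return List with `resolved` (named list: readout -> character vector of
#'   species ids) and `unresolved` (character vector of readouts with no
#'   match); unmatched readouts are reported, never silently dropped.
#' @export
map_names <- function(model, map = default_name_map()) {
  sp <- species_ids(model)
  resolved <- lapply(map, function(p) sp[grepl(p, sp)])
  names(resolved) <- names(map)
  unresolved <- names(map)[vapply(resolved, length, 0L) == 0L]
  list(resolved = resolved[setdiff(names(map), unresolved)],
       unresolved = unresolved)
}
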