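# SBML Level 3 Version 2 serialization of the purinome model.
# No SBML library binding is available to R here, so the document is
# emitted directly (explicit MathML, strings assembled then re-parsed
# with xml2 to guarantee well-formedness) and validated structurally.

mathml <- function(e) {
  if (is.numeric(e)) {
    return(sprintf('<cn type="real"> %.17g </cn>', e))
  }
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm == "time")
      return(paste0('<csymbol encoding="text" definitionURL=',
                    '"http://www.sbml.org/sbml/symbols/time"> t </csymbol>'))
    return(sprintf("<ci> %s </ci>", nm))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (op == "(") return(mathml(args[[1]]))
    fn <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                 "/" = "divide", "^" = "power", "exp" = "exp",
                 ">=" = "geq", stop("unsupported operator in MathML: ", op))
    return(paste0("<apply><", fn, "/>",
                  paste(vapply(args, mathml, character(1)), collapse = ""),
                  "</apply>"))
  }
  stop("cannot convert to MathML: ", deparse(e))
}

mathml_piecewise <- function(expr_true, condition, expr_false) {
  paste0("<piecewise><piece>", mathml(expr_true), mathml(condition),
         "</piece><otherwise>", mathml(expr_false),
         "</otherwise></piecewise>")
}

sbml_reaction <- function(id, reactants, products, math,
                          reversible = FALSE) {
  sr <- function(tag, x) {
    if (!length(x)) return("")
    rows <- vapply(names(x), function(sp) sprintf(
      '<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
      sp, x[[sp]]), character(1))
    sprintf("<listOf%s>%s</listOf%s>", tag, paste(rows, collapse = ""), tag)
  }
  sprintf(paste0(
    '<reaction id="%s" reversible="%s">%s%s',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    "%s</math></kineticLaw></reaction>"),
    id, tolower(as.character(reversible)),
    sr("Reactants", reactants), sr("Products", products), math)
}

flatten_params <- function(p, protocol) {
  c(k_ATPase = p$k_ATPase, k_ADPase = p$k_ADPase,
    Vmax_AMPase = p$Vmax_AMPase, Km_AMPase = p$Km_AMPase,
    Ftr_AK = p$Ftr_AK, k1 = p$k1, k_minus2 = p$k_minus2,
    Vmax_AK = vmax_ak(p), K_AK_half = p$K_AK_half, Keq_AK = p$Keq_AK,
    Vmax_NDPK = p$Vmax_NDPK, Km_AD = p$Km_AD, Km_AT = p$Km_AT,
    Km_NTP_U = p$Km_NTP[[protocol$utp_species]],
    Km_NTP_C = p$Km_NTP[["CTP"]],
    Ki_NDP = p$Ki_NDP, Ki_ADP = p$Ki_ADP, Keq_NDPK = p$Keq_NDPK,
    k_NTPase_U = p$k_NTPase[[protocol$utp_species]],
    k_NTPase_C = p$k_NTPase[["CTP"]],
    J_leakage = p$J_leakage,
    A_NL_active = if (is.null(protocol$osmolarity)) 0 else
      a_nl_amplitude(protocol$osmolarity, p),
    k_obs = p$k_obs,
    k_L_active = if (!is.null(protocol$osmolarity) &&
                     protocol$osmolarity <= 100) p$k_L else 0,
    M_cell = p$M_cell,
    t_stim = protocol$t_stim,
    osmolarity = if (is.null(protocol$osmolarity)) -1 else
      protocol$osmolarity,
    ak_active = as.numeric(!protocol$ap5a),
    utp_slot_is_gtp = as.numeric(protocol$utp_species == "GTP"))
}

#' Export the purinome model as an SBML Level 3 document
#'
#' Serializes one protocol/parameter pairing as SBML L3V2 core: the 8
#' extracellular species in a unit assay compartment (concentrations in
#' uM), every kinetic constant as a global parameter (vector constants
#' flattened, e.g. `Km_NTP_U`), nine reactions with their rate laws as
#' explicit MathML (the release flux as a time-piecewise expression),
#' and the protocol's addition events as SBML events. The document is
#' checked with [validate_sbml()] before writing.
#'
#' @param p A [parameter_set()].
#' @param protocol A [protocol()] (default: the `adp_12` scenario).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(p, protocol = build_scenario("adp_12"), path) {
  validate_parameters(p)
  pars <- flatten_params(p, protocol)

  species <- vapply(PURINOME_SPECIES, function(sp) sprintf(
    paste0('<species id="%s" compartment="assay" ',
           'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
           'boundaryCondition="false" constant="false"/>'),
    sp, as_nucleotide_state(protocol$init)[[sp]]), character(1))
  params <- vapply(names(pars), function(nm) sprintf(
    '<parameter id="%s" value="%.17g" constant="true"/>',
    nm, pars[[nm]]), character(1))

  q <- function(s) str2lang(s)
  ndpk_math <- function(ntp, ndp, KmN) {
    num <- sprintf("M_cell * Vmax_NDPK * (eATP * %s / Keq_NDPK - eADP * %s)",
                   ndp, ntp)
    den <- sprintf(paste0(
      "Km_AD * %s * (1 + (eUDP + eCDP) / Ki_NDP) + ",
      "%s * eADP * (1 + eATP / Ki_ADP) + eADP * %s + ",
      "(Km_AT * %s + %s * eATP + eATP * %s) / Keq_NDPK"),
      ntp, KmN, ntp, ndp, KmN, ndp)
    mathml(q(sprintf("(%s) / (%s)", num, den)))
  }
  release_math <- mathml_piecewise(
    q(paste0("M_cell * (J_leakage + k_L_active + ",
             "A_NL_active * exp(-k_obs * (time - t_stim)))")),
    q("time >= t_stim"),
    q("M_cell * J_leakage"))
  ak_math <- mathml(q(paste0(
    "ak_active * M_cell * Vmax_AK * ",
    "(eATP * eAMP / Keq_AK - eADP^2) / ",
    "(K_AK_half^2 + eADP^2 + eATP * eAMP / Keq_AK)")))

  reactions <- c(
    sbml_reaction("J_release", NULL, c(eATP = 1L), release_math),
    sbml_reaction("J_ecto_ATPase", c(eATP = 1L), c(eADP = 1L),
                  mathml(q("M_cell * k_ATPase * eATP"))),
    sbml_reaction("J_ecto_ADPase", c(eADP = 1L), c(eAMP = 1L),
                  mathml(q("M_cell * k_ADPase * eADP"))),
    sbml_reaction("J_ecto_AMPase", c(eAMP = 1L), c(eADO = 1L),
                  mathml(q(paste0("M_cell * Vmax_AMPase * eAMP",
                                  " / (Km_AMPase + eAMP)")))),
    sbml_reaction("J_ecto_AK", c(eATP = 1L, eAMP = 1L), c(eADP = 2L),
                  ak_math, reversible = TRUE),
    sbml_reaction("J_ecto_NDPK_U", c(eATP = 1L, eUDP = 1L),
                  c(eADP = 1L, eUTP = 1L),
                  ndpk_math("eUTP", "eUDP", "Km_NTP_U"),
                  reversible = TRUE),
    sbml_reaction("J_ecto_NDPK_C", c(eATP = 1L, eCDP = 1L),
                  c(eADP = 1L, eCTP = 1L),
                  ndpk_math("eCTP", "eCDP", "Km_NTP_C"),
                  reversible = TRUE),
    sbml_reaction("J_ecto_NTPase_U", c(eUTP = 1L), c(eUDP = 1L),
                  mathml(q("M_cell * k_NTPase_U * eUTP"))),
    sbml_reaction("J_ecto_NTPase_C", c(eCTP = 1L), c(eCDP = 1L),
                  mathml(q("M_cell * k_NTPase_C * eCTP"))))

  events <- ""
  if (nrow(protocol$events)) {
    ev <- vapply(seq_len(nrow(protocol$events)), function(i) {
      sp <- protocol$events$species[i]
      sprintf(paste0(
        '<event id="addition_%d" useValuesFromTriggerTime="true">',
        '<trigger initialValue="false" persistent="true">',
        '<math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>',
        "</trigger><listOfEventAssignments>",
        '<eventAssignment variable="%s">',
        '<math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>',
        "</eventAssignment></listOfEventAssignments></event>"),
        i,
        mathml(q(sprintf("time >= %.17g", protocol$events$time[i]))),
        sp,
        mathml(q(sprintf("%s + %.17g", sp, protocol$events$amount[i]))))
    }, character(1))
    events <- sprintf("<listOfEvents>%s</listOfEvents>",
                      paste(ev, collapse = ""))
  }

  doc_str <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">',
    '<model id="purinome_%s" name="Extracellular purinome model (%s)" ',
    'timeUnits="minute" extentUnits="micromole">',
    '<listOfCompartments><compartment id="assay" spatialDimensions="3" ',
    'size="1" constant="true"/></listOfCompartments>',
    "<listOfSpecies>%s</listOfSpecies>",
    "<listOfParameters>%s</listOfParameters>",
    "<listOfReactions>%s</listOfReactions>%s</model></sbml>"),
    gsub("[^A-Za-z0-9_]", "_", protocol$name), protocol$name,
    paste(species, collapse = ""), paste(params, collapse = ""),
    paste(reactions, collapse = ""), events)

  doc <- xml2::read_xml(doc_str)
  validate_sbml(doc)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Structural validation of a purinome SBML document
#'
#' Checks that the document is well-formed SBML Level 3 core with the
#' elements the model requires: an `sbml` root in the L3 namespace, one
#' model with a compartment, exactly the 8 purinome species (each with
#' an initial concentration), global parameters, at least 7 reactions
#' each carrying a `kineticLaw` with MathML, and that every species
#' referenced by a reaction is declared.
#'
#' @param doc Path or `xml2` document.
#' @return `TRUE` invisibly; stops with a message on the first defect.
#' @export
validate_sbml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("root element is not <sbml>")
  if (!identical(xml2::xml_attr(doc, "level"), "3"))
    stop("not an SBML Level 3 document")
  d <- xml2::xml_ns_strip(xml2::read_xml(as.character(doc)))
  model <- xml2::xml_find_first(d, "./model")
  if (inherits(model, "xml_missing")) stop("missing <model>")
  sp <- xml2::xml_find_all(d, ".//listOfSpecies/species")
  ids <- xml2::xml_attr(sp, "id")
  if (!setequal(ids, PURINOME_SPECIES) || length(ids) != 8)
    stop("species list must contain exactly the 8 purinome species")
  if (anyNA(as.numeric(xml2::xml_attr(sp, "initialConcentration"))))
    stop("species missing initialConcentration")
  if (!length(xml2::xml_find_all(d, ".//listOfCompartments/compartment")))
    stop("missing compartment")
  rx <- xml2::xml_find_all(d, ".//listOfReactions/reaction")
  if (length(rx) < 7) stop("fewer than 7 reactions")
  for (r in rx) {
    if (!length(xml2::xml_find_all(r, ".//kineticLaw/math")))
      stop("reaction ", xml2::xml_attr(r, "id"), " lacks kineticLaw math")
    refs <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//speciesReference"), "species")
    bad <- setdiff(refs, ids)
    if (length(bad))
      stop("reaction references undeclared species: ",
           paste(bad, collapse = ", "))
  }
  pids <- xml2::xml_attr(
    xml2::xml_find_all(d, ".//listOfParameters/parameter"), "id")
  if (anyDuplicated(c(ids, pids))) stop("duplicated identifiers")
  invisible(TRUE)
}

#' Import a purinome SBML document
#'
#' Reads back a document written by [export_sbml()]: global parameters
#' are un-flattened into a [parameter_set()], species initial
#' concentrations into the initial [nucleotide_state()], and SBML events
#' into protocol addition events, yielding a protocol/parameter pairing
#' that simulates natively.
#'
#' @param path SBML file path.
#' @return List with elements `params` ([parameter_set()]) and
#'   `protocol` ([protocol()]).
#' @export
import_sbml <- function(path) {
  validate_sbml(path)
  d <- xml2::xml_ns_strip(xml2::read_xml(path))
  sp <- xml2::xml_find_all(d, ".//listOfSpecies/species")
  init <- stats::setNames(
    as.numeric(xml2::xml_attr(sp, "initialConcentration")),
    xml2::xml_attr(sp, "id"))
  pe <- xml2::xml_find_all(d, ".//listOfParameters/parameter")
  pars <- stats::setNames(as.numeric(xml2::xml_attr(pe, "value")),
                          xml2::xml_attr(pe, "id"))

  utp_species <- if (isTRUE(pars[["utp_slot_is_gtp"]] == 1)) "GTP" else "UTP"
  Km_NTP <- c(UTP = 100, CTP = 100, GTP = 100)
  k_NTPase <- c(UTP = 0, CTP = 0, GTP = 0)
  Km_NTP[[utp_species]] <- pars[["Km_NTP_U"]]
  Km_NTP[["CTP"]] <- pars[["Km_NTP_C"]]
  k_NTPase[[utp_species]] <- pars[["k_NTPase_U"]]
  k_NTPase[["CTP"]] <- pars[["k_NTPase_C"]]
  osm <- pars[["osmolarity"]]
  A_NL <- if (osm > 0)
    stats::setNames(pars[["A_NL_active"]], as.character(osm)) else
    c("300" = 0)

  p <- parameter_set(
    k_ATPase = pars[["k_ATPase"]], k_ADPase = pars[["k_ADPase"]],
    Vmax_AMPase = pars[["Vmax_AMPase"]], Km_AMPase = pars[["Km_AMPase"]],
    Ftr_AK = pars[["Ftr_AK"]], k1 = pars[["k1"]],
    k_minus2 = pars[["k_minus2"]], K_AK_half = pars[["K_AK_half"]],
    Keq_AK = pars[["Keq_AK"]], Vmax_NDPK = pars[["Vmax_NDPK"]],
    Km_AD = pars[["Km_AD"]], Km_AT = pars[["Km_AT"]], Km_NTP = Km_NTP,
    Ki_NDP = pars[["Ki_NDP"]], Ki_ADP = pars[["Ki_ADP"]],
    Keq_NDPK = pars[["Keq_NDPK"]], k_NTPase = k_NTPase,
    J_leakage = pars[["J_leakage"]], A_NL = A_NL,
    k_obs = pars[["k_obs"]], k_L = pars[["k_L_active"]],
    M_cell = pars[["M_cell"]])

  evs <- xml2::xml_find_all(d, ".//listOfEvents/event")
  events <- NULL
  if (length(evs)) {
    events <- do.call(rbind, lapply(evs, function(e) {
      tcn <- xml2::xml_find_all(e, ".//trigger//cn")
      var <- xml2::xml_attr(
        xml2::xml_find_first(e, ".//eventAssignment"), "variable")
      amt <- as.numeric(xml2::xml_text(
        xml2::xml_find_all(e, ".//eventAssignment//cn")))
      data.frame(time = as.numeric(xml2::xml_text(tcn))[1],
                 species = var, amount = amt[length(amt)])
    }))
  }
  name <- sub("^Extracellular purinome model \\((.*)\\)$", "\\1",
              xml2::xml_attr(xml2::xml_find_first(d, ".//model"), "name"))
  t_end <- max(pars[["t_stim"]] + 30,
               if (!is.null(events)) max(events$time) + 30 else 0)
  proto <- protocol(name = name,
                    osmolarity = if (osm > 0) osm else NULL,
                    t_stim = pars[["t_stim"]], events = events,
                    ap5a = pars[["ak_active"]] == 0,
                    utp_species = utp_species,
                    init = init[PURINOME_SPECIES],
                    times = seq(0, t_end, by = 0.25))
  list(params = p, protocol = proto)
}
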