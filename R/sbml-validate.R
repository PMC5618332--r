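#' Validate an SBML-RAM document
#'
#' Checks a document against the structural rules of the RAM dialect
#' without building a model: every species carries a `ram:species`
#' annotation with a known type; storage/enzyme/quota species declare
#' molecular and objective weights; every reaction carries a `ram:reaction`
#' annotation whose `kcatForward`, `kcatBackward`, and
#' `maintenanceScaling` resolve to numbers (literal or declared parameter
#' id); irreversible reactions have a backward turnover rate of zero;
#' reactions are catalyzed by at most one gene-product reference;
#' maintenance reactions are spontaneous; gene products point at declared
#' species; and ids are unique (sharing one macromolecule id across
#' compartments is flagged as a warning).
#'
#' @param source Path to the SBML file (or an `xml_document`).
#' @return A tibble of findings with columns `severity` (`"error"` or
#'   `"warning"`), `rule`, `location`, and `message`; zero rows for a
#'   conforming document.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' write_ram_sbml(toy_model(), f)
#' validate_ram_document(f)
#' @export
validate_ram_document <- function(source) {
  doc <- if (inherits(source, "xml_document")) source else xml2::read_xml(source)
  ns <- sbml_ns_map()
  findings <- list()
  flag <- function(severity, rule, location, message) {
    findings[[length(findings) + 1]] <<- tibble(
      severity = severity, rule = rule, location = location, message = message
    )
  }

  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (xml_missing(mdl)) {
    flag("error", "sbml-model", "document", "No <model> element found.")
    return(bind_rows(findings))
  }
  params <- read_parameter_table(mdl, ns)
  resolves <- function(value) {
    !is.na(value) &&
      (value %in% names(params) || !is.na(parse_sbml_num(value)))
  }

  sp_nodes <- xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", ns)
  sp_ids <- map_chr(sp_nodes, node_attr, "id")
  sp_types <- rep(NA_character_, length(sp_nodes))

  dup <- unique(sp_ids[duplicated(sp_ids)])
  for (d in dup) {
    flag("warning", "ram-unique-macromolecule-ids", paste0("species ", d),
         paste0("Species id '", d, "' is used more than once; enzymes ",
                "acting in several compartments must be distinct species ",
                "with compartment-suffixed ids (Main_id_[compartment])."))
  }

  for (i in seq_along(sp_nodes)) {
    node <- sp_nodes[[i]]
    where <- paste0("species ", sp_ids[i])
    for (a in c("id", "compartment", "constant", "boundaryCondition",
                "hasOnlySubstanceUnits")) {
      if (is.na(node_attr(node, a))) {
        flag("error", "sbml-species-mandatory", where,
             paste0("Missing mandatory attribute ", a, "."))
      }
    }
    if (is.na(node_attr(node, "initialAmount")) &&
        is.na(node_attr(node, "initialConcentration"))) {
      flag("error", "sbml-species-initial", where,
           "Species needs initialAmount or initialConcentration.")
    }
    ram_node <- xml2::xml_find_first(node, ".//ram:RAM/ram:species", ns)
    if (xml_missing(ram_node)) {
      flag("error", "ram-species-annotation", where,
           "Missing ram:species annotation.")
      next
    }
    type <- node_attr(ram_node, "speciesType", "ram")
    sp_types[i] <- type
    if (is.na(type) || !(type %in% RAM_SPECIES_TYPES)) {
      flag("error", "ram-species-type", where,
           paste0("ram:speciesType '", type, "' is not one of: ",
                  paste(RAM_SPECIES_TYPES, collapse = ", "), "."))
      next
    }
    if (type %in% c("storage", "enzyme", "quota")) {
      for (a in c("molecularWeight", "objectiveWeight")) {
        v <- node_attr(ram_node, a, "ram")
        if (is.na(v)) {
          flag("error", "ram-biomass-weights", where,
               paste0("Biomass species must declare ram:", a, "."))
        } else if (!resolves(v)) {
          flag("error", "ram-parameter-resolve", where,
               paste0("ram:", a, " = '", v, "' resolves to neither a ",
                      "number nor a declared parameter."))
        }
      }
      bp <- node_attr(ram_node, "biomassPercentage", "ram")
      if (!is.na(bp) && !resolves(bp)) {
        flag("error", "ram-parameter-resolve", where,
             paste0("ram:biomassPercentage = '", bp, "' resolves to ",
                    "neither a number nor a declared parameter."))
      }
    }
  }

  gp_nodes <- xml2::xml_find_all(mdl, "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_ids <- map_chr(gp_nodes, node_attr, "id", "fbc")
  for (i in seq_along(gp_nodes)) {
    assoc <- node_attr(gp_nodes[[i]], "associatedSpecies", "fbc")
    if (is.na(assoc) || !(assoc %in% sp_ids)) {
      flag("error", "fbc-associated-species",
           paste0("geneProduct ", gp_ids[i]),
           paste0("fbc:associatedSpecies '", assoc,
                  "' is not a declared species."))
    }
  }

  rx_nodes <- xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction", ns)
  for (node in rx_nodes) {
    id <- node_attr(node, "id")
    where <- paste0("reaction ", if (is.na(id)) "<no id>" else id)
    reversible <- identical(node_attr(node, "reversible"), "true")
    if (is.na(node_attr(node, "reversible"))) {
      flag("error", "sbml-reaction-mandatory", where,
           "Missing mandatory attribute reversible.")
    }
    ram_node <- xml2::xml_find_first(node, ".//ram:RAM/ram:reaction", ns)
    if (xml_missing(ram_node)) {
      flag("error", "ram-reaction-annotation", where,
           "Missing ram:reaction annotation.")
      next
    }
    vals <- list()
    for (a in c("kcatForward", "kcatBackward", "maintenanceScaling")) {
      v <- node_attr(ram_node, a, "ram")
      if (is.na(v)) {
        flag("error", "ram-reaction-attrs", where,
             paste0("ram:reaction must declare ram:", a, "."))
      } else if (!resolves(v)) {
        flag("error", "ram-parameter-resolve", where,
             paste0("ram:", a, " = '", v, "' resolves to neither a number ",
                    "nor a declared parameter."))
      } else {
        vals[[a]] <- if (v %in% names(params)) params[[v]] else parse_sbml_num(v)
      }
    }
    if (!reversible && !is.null(vals$kcatBackward) && vals$kcatBackward != 0) {
      flag("error", "ram-kcat-backward-zero", where,
           "Irreversible reactions must have ram:kcatBackward resolve to 0.")
    }
    gpr <- xml2::xml_find_all(
      node, "./fbc:geneProductAssociation//fbc:geneProductRef", ns
    )
    if (length(gpr) > 1) {
      flag("error", "fbc-single-gene-product", where,
           paste0("Reactions must be catalyzed by exactly one ",
                  "fbc:geneProductRef; found ", length(gpr),
                  " (pre-split complexes and isoenzymes)."))
    }
    if (length(gpr) >= 1) {
      gref <- node_attr(gpr[[1]], "geneProduct", "fbc")
      if (!(gref %in% gp_ids)) {
        flag("error", "fbc-gene-product-declared", where,
             paste0("fbc:geneProductRef '", gref,
                    "' is not a declared gene product."))
      }
      if (!is.null(vals$maintenanceScaling) && vals$maintenanceScaling > 0) {
        flag("error", "ram-maintenance-spontaneous", where,
             paste0("Maintenance reactions (maintenanceScaling > 0) must ",
                    "be spontaneous (no gene-product association)."))
      }
    }
  }

  out <- bind_rows(findings)
  if (nrow(out) == 0) {
    tibble(severity = character(), rule = character(),
           location = character(), message = character())
  } else {
    out
  }
}
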