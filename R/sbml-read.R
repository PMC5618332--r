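sbml_ns_map <- function() {
  c(s = SBML_NS, fbc = FBC_NS, ram = RAM_NS, rdf = RDF_NS)
}

node_attr <- function(node, name, prefix = NULL) {
  attrs <- xml2::xml_attrs(node)
  for (key in c(if (!is.null(prefix)) paste0(prefix, ":", name), name)) {
    if (key %in% names(attrs)) return(attrs[[key]])
  }
  NA_character_
}

parse_sbml_num <- function(x) {
  if (x == "INF") return(Inf)
  if (x == "-INF") return(-Inf)
  suppressWarnings(as.numeric(x))
}

# Resolve a RAM numeric attribute: a literal number or a parameter id.
resolve_ram_value <- function(value, params, where, attribute,
                              default = NULL) {
  if (is.na(value)) {
    if (!is.null(default)) return(default)
    abort(paste0(where, ": missing attribute ", attribute, "."))
  }
  if (value %in% names(params)) return(params[[value]])
  num <- parse_sbml_num(value)
  if (is.na(num)) {
    abort(paste0(where, ": attribute ", attribute, " = '", value,
                 "' is neither a number nor a declared parameter id."))
  }
  num
}

read_parameter_table <- function(mdl, ns) {
  nodes <- xml2::xml_find_all(mdl, "./s:listOfParameters/s:parameter", ns)
  params <- list()
  for (node in nodes) {
    id <- node_attr(node, "id")
    value <- node_attr(node, "value")
    if (is.na(id)) abort("Parameter without id.")
    params[[id]] <- parse_sbml_num(value)
  }
  params
}

xml_missing <- function(x) {
  inherits(x, "xml_missing") || length(x) == 0
}

extra_annotation_strings <- function(ann_node, drop_rdf = FALSE) {
  if (xml_missing(ann_node)) return(NULL)
  out <- character(0)
  ns <- sbml_ns_map()
  for (child in xml2::xml_children(ann_node)) {
    if (!xml_missing(xml2::xml_find_first(child, "self::ram:RAM", ns))) next
    if (drop_rdf &&
        !xml_missing(xml2::xml_find_first(child, "self::rdf:RDF", ns))) next
    out <- c(out, as.character(child))
  }
  if (length(out) == 0) NULL else out
}

#' Read an SBML-RAM document into a model
#'
#' Parses an SBML Level 3 + fbc v2 document with RAM annotations (the
#' inverse of [write_ram_sbml()]). All parameter references in RAM numeric
#' attributes are resolved to numbers; species amounts are taken from
#' `initialAmount` or reconstructed as `initialConcentration` times the
#' compartment size; reactions without an fbc gene-product association are
#' spontaneous; EC numbers are recovered from MIRIAM annotations. Unknown
#' species types, dangling parameter or species references, and missing
#' mandatory attributes raise located errors.
#'
#' @param source Path to the SBML file (or an `xml_document`).
#' @return A [ram_model()].
#' @export
read_ram_sbml <- function(source) {
  doc <- if (inherits(source, "xml_document")) source else xml2::read_xml(source)
  ns <- sbml_ns_map()
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (xml_missing(mdl)) abort("No <model> element found.")
  params <- read_parameter_table(mdl, ns)

  comp_nodes <- xml2::xml_find_all(mdl, "./s:listOfCompartments/s:compartment", ns)
  compartments <- tibble(
    id = map_chr(comp_nodes, node_attr, "id"),
    size = map_dbl(comp_nodes, function(n) {
      v <- node_attr(n, "size")
      if (is.na(v)) 1 else parse_sbml_num(v)
    })
  )

  sp_nodes <- xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", ns)
  species <- map(sp_nodes, function(node) {
    id <- node_attr(node, "id")
    where <- paste0("species ", id %||% "<no id>")
    for (a in c("id", "compartment", "constant", "boundaryCondition",
                "hasOnlySubstanceUnits")) {
      if (is.na(node_attr(node, a))) {
        abort(paste0(where, ": missing mandatory attribute ", a, "."))
      }
    }
    amount_attr <- node_attr(node, "initialAmount")
    if (is.na(amount_attr)) {
      conc <- node_attr(node, "initialConcentration")
      if (is.na(conc)) {
        abort(paste0(where, ": needs initialAmount or initialConcentration."))
      }
      comp <- node_attr(node, "compartment")
      size <- compartments$size[match(comp, compartments$id)]
      if (is.na(size)) {
        abort(paste0(where, ": compartment ", comp,
                     " has no size; cannot convert concentration."))
      }
      amount <- parse_sbml_num(conc) * size
    } else {
      amount <- parse_sbml_num(amount_attr)
    }
    ram_node <- xml2::xml_find_first(node, ".//ram:RAM/ram:species", ns)
    if (xml_missing(ram_node)) {
      abort(paste0(where, ": missing ram:species annotation."))
    }
    type <- node_attr(ram_node, "speciesType", "ram")
    if (is.na(type) || !(type %in% RAM_SPECIES_TYPES)) {
      abort(paste0(where, ": unknown ram:speciesType '", type, "'."))
    }
    get_num <- function(attribute, default) {
      resolve_ram_value(node_attr(ram_node, attribute, "ram"), params,
                        where, paste0("ram:", attribute), default = default)
    }
    is_biomass <- type %in% c("storage", "enzyme", "quota")
    ann <- xml2::xml_find_first(node, "./s:annotation", ns)
    tibble(
      id = id, name = node_attr(node, "name") %|NA|% id,
      compartment = node_attr(node, "compartment"),
      type = type,
      boundary = node_attr(node, "boundaryCondition") == "true",
      constant = node_attr(node, "constant") == "true",
      molecular_weight = if (is_biomass) get_num("molecularWeight", NULL) else 0,
      objective_weight = if (is_biomass) get_num("objectiveWeight", NULL) else 0,
      biomass_percentage = get_num("biomassPercentage", 0),
      initial_amount = amount,
      annotation_extra = list(extra_annotation_strings(ann))
    )
  }) |> bind_rows()

  gp_nodes <- xml2::xml_find_all(mdl, "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_products <- if (length(gp_nodes) == 0) NULL else tibble(
    id = map_chr(gp_nodes, node_attr, "id", "fbc"),
    label = map_chr(gp_nodes, node_attr, "label", "fbc"),
    associated_species = map_chr(gp_nodes, node_attr, "associatedSpecies", "fbc")
  )
  if (!is.null(gene_products)) {
    dangling <- setdiff(gene_products$associated_species, species$id)
    if (length(dangling) > 0) {
      abort(paste0("fbc:associatedSpecies references unknown species: ",
                   paste(dangling, collapse = ", ")))
    }
  }

  rx_nodes <- xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction", ns)
  reactions <- map(rx_nodes, function(node) {
    id <- node_attr(node, "id")
    where <- paste0("reaction ", id %||% "<no id>")
    if (is.na(id)) abort("Reaction without id.")
    rev_attr <- node_attr(node, "reversible")
    if (is.na(rev_attr)) {
      abort(paste0(where, ": missing mandatory attribute reversible."))
    }
    reversible <- rev_attr == "true"
    ram_node <- xml2::xml_find_first(node, ".//ram:RAM/ram:reaction", ns)
    if (xml_missing(ram_node)) {
      abort(paste0(where, ": missing ram:reaction annotation."))
    }
    get_num <- function(attribute) {
      resolve_ram_value(node_attr(ram_node, attribute, "ram"), params,
                        where, paste0("ram:", attribute))
    }
    ref <- function(list_name, sign) {
      refs <- xml2::xml_find_all(
        node, paste0("./s:", list_name, "/s:speciesReference"), ns
      )
      setNames(
        sign * map_dbl(refs, function(r) parse_sbml_num(node_attr(r, "stoichiometry"))),
        map_chr(refs, node_attr, "species")
      )
    }
    stoich <- c(ref("listOfReactants", -1), ref("listOfProducts", 1))
    if (anyDuplicated(names(stoich))) {
      stoich <- tapply(stoich, names(stoich), sum)
      stoich <- setNames(as.numeric(stoich), names(stoich))
    }
    gpr <- xml2::xml_find_all(
      node, "./fbc:geneProductAssociation//fbc:geneProductRef", ns
    )
    if (length(gpr) > 1) {
      abort(paste0(where, ": must be catalyzed by exactly one ",
                   "fbc:geneProductRef (split isoenzymes/complexes first)."))
    }
    gene_product <- if (length(gpr) == 1) {
      node_attr(gpr[[1]], "geneProduct", "fbc")
    } else {
      NA_character_
    }
    ec <- xml2::xml_find_first(
      node,
      ".//rdf:li[contains(@rdf:resource, 'ec-code/')]", ns
    )
    ec_number <- if (xml_missing(ec)) NA_character_ else {
      sub("^.*ec-code/", "", node_attr(ec, "resource", "rdf"))
    }
    bound <- function(attribute, default) {
      v <- node_attr(node, attribute, "fbc")
      if (is.na(v)) return(default)
      if (!(v %in% names(params))) {
        abort(paste0(where, ": flux bound parameter '", v, "' undeclared."))
      }
      params[[v]]
    }
    ann <- xml2::xml_find_first(node, "./s:annotation", ns)
    tibble(
      id = id, name = node_attr(node, "name") %|NA|% id,
      reversible = reversible,
      stoichiometry = list(stoich),
      kcat_forward = get_num("kcatForward"),
      kcat_backward = get_num("kcatBackward"),
      maintenance_scaling = get_num("maintenanceScaling"),
      lower_bound = bound("lowerFluxBound", if (reversible) -Inf else 0),
      upper_bound = bound("upperFluxBound", Inf),
      gene_product = gene_product,
      ec_number = ec_number,
      annotation_extra = list(
        extra_annotation_strings(ann, drop_rdf = !is.na(ec_number))
      )
    )
  }) |> bind_rows()

  ram_model(
    species, reactions, gene_products,
    id = node_attr(mdl, "id") %|NA|% "ram_model",
    name = node_attr(mdl, "name") %|NA|% (node_attr(mdl, "id") %|NA|% "ram_model"),
    compartments = compartments
  )
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x
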