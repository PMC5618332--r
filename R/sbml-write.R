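SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
RAM_NS <- "https://www.fairdomhub.org/sops/304"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

fmt_sbml_num <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "INF" else "-INF")
  sprintf("%.17g", x)
}

fmt_sbml_bool <- function(x) if (isTRUE(x)) "true" else "false"

# Registry mapping numeric values to SBML parameter ids: numeric RAM
# attributes are emitted as parameter references ("weight_R", "zero", ...),
# sharing one parameter per (preferred name, value) and a global "zero".
param_registry <- function() {
  values <- list()
  register <- function(value, preferred) {
    if (value == 0) {
      values[["zero"]] <<- 0
      return("zero")
    }
    name <- preferred
    k <- 1
    while (!is.null(values[[name]]) && values[[name]] != value) {
      k <- k + 1
      name <- paste0(preferred, "_", k)
    }
    values[[name]] <<- value
    name
  }
  list(register = register, table = function() values)
}

#' Write a model as an SBML-RAM document
#'
#' Serializes a [ram_model()] as SBML Level 3 Version 1 with the
#' flux-balance-constraints (fbc) version 2 package and the resource
#' allocation modeling (RAM) annotation (namespace
#' `https://www.fairdomhub.org/sops/304`). Every species carries a
#' `ram:species` annotation with its type; storage, enzyme, and quota
#' species additionally carry molecular weight, objective weight, and
#' biomass percentage, all emitted as references into the parameter list
#' (`weight_<species>`, `bp_<species>`, `kcat_fwd_<reaction>`, ...; zeros
#' share a single `zero` parameter). Nonlimiting extracellular species get
#' `boundaryCondition="true"`; every reaction carries a `ram:reaction`
#' annotation with its forward/backward turnover rates and maintenance
#' coefficient, spontaneous reactions (maintenance included) have no
#' gene-product association, and EC numbers are attached as MIRIAM
#' `isVersionOf` annotations. Flux bounds are written (as fbc bound
#' parameters) only when they differ from the reversibility defaults.
#'
#' @param model A [ram_model()].
#' @param path Destination file; `NULL` returns the `xml_document` without
#'   writing.
#' @return Invisibly, the `xml_document`.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' write_ram_sbml(toy_model(), f)
#' @export
write_ram_sbml <- function(model, path = NULL) {
  validate_ram_model(model)
  sp <- model$species
  rx <- model$reactions
  gp <- model$gene_products
  biomass_types <- c("storage", "enzyme", "quota")
  missing_w <- sp$id[sp$type == "quota" & sp$molecular_weight == 0]
  if (length(missing_w) > 0) {
    abort(paste0("Cannot serialize: quota species without molecular ",
                 "weight: ", paste(missing_w, collapse = ", ")))
  }
  params <- param_registry()

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS, "xmlns:ram" = RAM_NS,
    "xmlns:rdf" = RDF_NS, "xmlns:bqbiol" = BQBIOL_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = model$id, name = model$name,
                             "fbc:strict" = "false")

  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments))) {
    xml2::xml_add_child(
      loc, "compartment", id = model$compartments$id[i],
      size = fmt_sbml_num(model$compartments$size[i]), constant = "true"
    )
  }

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(sp))) {
    node <- xml2::xml_add_child(
      los, "species",
      id = sp$id[i], name = sp$name[i], compartment = sp$compartment[i],
      initialAmount = fmt_sbml_num(sp$initial_amount[i]),
      constant = fmt_sbml_bool(sp$constant[i]),
      boundaryCondition = fmt_sbml_bool(sp$boundary[i]),
      hasOnlySubstanceUnits = "true"
    )
    ann <- xml2::xml_add_child(node, "annotation")
    ram <- xml2::xml_add_child(ann, "ram:RAM")
    attrs <- c("ram:speciesType" = sp$type[i])
    if (sp$type[i] %in% biomass_types) {
      wname <- params$register(sp$molecular_weight[i], paste0("weight_", sp$id[i]))
      oname <- if (sp$objective_weight[i] == sp$molecular_weight[i]) {
        wname
      } else {
        params$register(sp$objective_weight[i], paste0("ow_", sp$id[i]))
      }
      bname <- params$register(sp$biomass_percentage[i], paste0("bp_", sp$id[i]))
      attrs <- c(
        "ram:molecularWeight" = wname, "ram:objectiveWeight" = oname,
        "ram:biomassPercentage" = bname, attrs
      )
    }
    spec_node <- xml2::xml_add_child(ram, "ram:species")
    for (a in names(attrs)) xml2::xml_set_attr(spec_node, a, attrs[[a]])
    add_extra_annotations(ann, sp$annotation_extra[[i]])
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rx))) {
    node <- xml2::xml_add_child(
      lor, "reaction", id = rx$id[i], name = rx$name[i],
      reversible = fmt_sbml_bool(rx$reversible[i]), fast = "false"
    )
    default_lb <- if (rx$reversible[i]) -Inf else 0
    if (rx$lower_bound[i] != default_lb) {
      xml2::xml_set_attr(node, "fbc:lowerFluxBound",
                         params$register(rx$lower_bound[i], paste0("lb_", rx$id[i])))
    }
    if (rx$upper_bound[i] != Inf) {
      xml2::xml_set_attr(node, "fbc:upperFluxBound",
                         params$register(rx$upper_bound[i], paste0("ub_", rx$id[i])))
    }
    ann <- xml2::xml_add_child(node, "annotation")
    ram <- xml2::xml_add_child(ann, "ram:RAM")
    rnode <- xml2::xml_add_child(ram, "ram:reaction")
    xml2::xml_set_attr(rnode, "ram:kcatForward",
                       params$register(rx$kcat_forward[i], paste0("kcat_fwd_", rx$id[i])))
    xml2::xml_set_attr(rnode, "ram:kcatBackward",
                       params$register(rx$kcat_backward[i], paste0("kcat_bwd_", rx$id[i])))
    xml2::xml_set_attr(rnode, "ram:maintenanceScaling",
                       params$register(rx$maintenance_scaling[i], paste0("psi_", rx$id[i])))
    if (!is.na(rx$ec_number[i])) {
      add_miriam_ec(ann, rx$id[i], rx$ec_number[i])
    }
    add_extra_annotations(ann, rx$annotation_extra[[i]])
    if (!is.na(rx$gene_product[i])) {
      gpa <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      xml2::xml_add_child(gpa, "fbc:geneProductRef",
                          "fbc:geneProduct" = rx$gene_product[i])
    }
    stoich <- rx$stoichiometry[[i]]
    reactants <- stoich[stoich < 0]
    products <- stoich[stoich > 0]
    lre <- xml2::xml_add_child(node, "listOfReactants")
    for (s in names(reactants)) {
      xml2::xml_add_child(lre, "speciesReference", species = s,
                          stoichiometry = fmt_sbml_num(-reactants[[s]]),
                          constant = "true")
    }
    lpr <- xml2::xml_add_child(node, "listOfProducts")
    for (s in names(products)) {
      xml2::xml_add_child(lpr, "speciesReference", species = s,
                          stoichiometry = fmt_sbml_num(products[[s]]),
                          constant = "true")
    }
  }

  ptab <- params$table()
  if (length(ptab) > 0) {
    lop <- xml2::xml_add_child(mdl, "listOfParameters", .where = 2)
    for (nm in names(ptab)) {
      xml2::xml_add_child(lop, "parameter", id = nm,
                          value = fmt_sbml_num(ptab[[nm]]),
                          constant = "true")
    }
  }

  if (nrow(gp) > 0) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (i in seq_len(nrow(gp))) {
      xml2::xml_add_child(
        logp, "fbc:geneProduct", "fbc:id" = gp$id[i],
        "fbc:label" = gp$label[i],
        "fbc:associatedSpecies" = gp$associated_species[i]
      )
    }
  }

  if (!is.null(path)) xml2::write_xml(doc, path)
  invisible(doc)
}

add_miriam_ec <- function(ann, reaction_id, ec) {
  rdf <- xml2::xml_add_child(ann, "rdf:RDF")
  desc <- xml2::xml_add_child(rdf, "rdf:Description",
                              "rdf:about" = paste0("#", reaction_id))
  ivo <- xml2::xml_add_child(desc, "bqbiol:isVersionOf")
  bag <- xml2::xml_add_child(ivo, "rdf:Bag")
  xml2::xml_add_child(
    bag, "rdf:li",
    "rdf:resource" = paste0("http://identifiers.org/ec-code/", ec)
  )
}

add_extra_annotations <- function(ann, extra) {
  if (is.null(extra) || length(extra) == 0) return(invisible())
  for (fragment in extra) {
    frag_doc <- xml2::read_xml(fragment)
    xml2::xml_add_child(ann, frag_doc)
  }
  invisible()
}
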