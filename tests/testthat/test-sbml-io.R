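write_tmp <- function(model) {
  f <- tempfile(fileext = ".xml")
  write_ram_sbml(model, f)
  f
}

test_that("the toy model round-trips through SBML unchanged", {
  toy <- toy_model()
  f <- write_tmp(toy)
  m2 <- read_ram_sbml(f)
  expect_model_equal(toy, m2)
  # the published initial amounts survive exactly
  expect_identical(
    m2$species$initial_amount[m2$species$id == "R"], 0.03364
  )
  expect_identical(
    m2$species$initial_amount[m2$species$id == "S"], 0.7499
  )
  # nonlimiting oxygen is a constant boundary species
  expect_true(m2$species$boundary[m2$species$id == "O2"])
  expect_true(m2$species$constant[m2$species$id == "O2"])
  expect_false(any(m2$species$boundary[m2$species$id %in% c("N1", "N2")]))
})

test_that("the writer output validates with zero findings", {
  expect_equal(nrow(validate_ram_document(write_tmp(toy_model()))), 0)
  for (seed in c(2, 9, 31)) {
    expect_equal(nrow(validate_ram_document(write_tmp(random_ram_model(seed)))), 0)
  }
})

test_that("annotations carry the RAM namespace and parameter references", {
  doc <- xml2::read_xml(write_tmp(toy_model()))
  txt <- as.character(doc)
  expect_match(txt, "https://www.fairdomhub.org/sops/304", fixed = TRUE)
  # ribosome: enzyme type, weight via parameter, zero biomass percentage
  expect_match(txt, "ram:speciesType=\"enzyme\"", fixed = TRUE)
  expect_match(txt, "ram:molecularWeight=\"weight_R\"", fixed = TRUE)
  # structural component: quota type with its own fraction parameter
  expect_match(txt, "ram:speciesType=\"quota\"", fixed = TRUE)
  expect_match(txt, "ram:biomassPercentage=\"bp_S\"", fixed = TRUE)
  # maintenance: psi parameter, no gene association, fast="false"
  expect_match(txt, "ram:maintenanceScaling=\"psi_Maintenance\"", fixed = TRUE)
  rxn <- xml2::xml_find_first(
    doc, "//s:reaction[@id='Maintenance']",
    c(s = "http://www.sbml.org/sbml/level3/version1/core")
  )
  expect_equal(xml2::xml_attr(rxn, "fast"), "false")
  expect_length(xml2::xml_find_all(rxn, ".//*[local-name()='geneProductRef']"), 0)
})

test_that("a reaction annotated via parameter ids reads back resolved", {
  # hand-built document fragment in the dialect's reaction style
  xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'xmlns:ram="https://www.fairdomhub.org/sops/304" level="3" version="1" ',
    'fbc:required="false"><model id="mini">',
    '<listOfCompartments><compartment id="cytosol" size="1" constant="true"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="N" compartment="cytosol" initialAmount="0" constant="false"',
    ' boundaryCondition="false" hasOnlySubstanceUnits="true">',
    '<annotation><ram:RAM><ram:species ram:speciesType="metabolite"/></ram:RAM></annotation></species>',
    '<species id="AA" compartment="cytosol" initialAmount="0" constant="false"',
    ' boundaryCondition="false" hasOnlySubstanceUnits="true">',
    '<annotation><ram:RAM><ram:species ram:speciesType="metabolite"/></ram:RAM></annotation></species>',
    '<species id="ATP" compartment="cytosol" initialAmount="0" constant="false"',
    ' boundaryCondition="false" hasOnlySubstanceUnits="true">',
    '<annotation><ram:RAM><ram:species ram:speciesType="metabolite"/></ram:RAM></annotation></species>',
    '<species id="Emetab2" compartment="cytosol" initialAmount="0.5" constant="false"',
    ' boundaryCondition="false" hasOnlySubstanceUnits="true">',
    '<annotation><ram:RAM><ram:species ram:speciesType="enzyme"',
    ' ram:molecularWeight="weight_E" ram:objectiveWeight="weight_E"',
    ' ram:biomassPercentage="zero"/></ram:RAM></annotation></species>',
    '</listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="kcat2" value="2500" constant="true"/>',
    '<parameter id="weight_E" value="0.16" constant="true"/>',
    '<parameter id="zero" value="0" constant="true"/>',
    '</listOfParameters>',
    '<listOfReactions><reaction id="Metab1_2" reversible="false" fast="false">',
    '<annotation><ram:RAM><ram:reaction ram:kcatForward="kcat2"',
    ' ram:kcatBackward="zero" ram:maintenanceScaling="zero"/></ram:RAM></annotation>',
    '<fbc:geneProductAssociation fbc:id="ga1">',
    '<fbc:geneProductRef fbc:geneProduct="Emetab2"/></fbc:geneProductAssociation>',
    '<listOfReactants><speciesReference species="N" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="AA" stoichiometry="1" constant="true"/>',
    '<speciesReference species="ATP" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction></listOfReactions>',
    '<fbc:listOfGeneProducts><fbc:geneProduct fbc:id="Emetab2" fbc:label="1*GMETAB2"',
    ' fbc:associatedSpecies="Emetab2"/></fbc:listOfGeneProducts>',
    '</model></sbml>'
  )
  f <- tempfile(fileext = ".xml")
  writeLines(xml, f)
  m <- read_ram_sbml(f)
  rxn <- ram_reactions(m)
  expect_equal(rxn$kcat_forward, 2500)
  expect_equal(rxn$kcat_backward, 0)
  expect_equal(rxn$gene_product, "Emetab2")
  expect_equal(rxn$stoichiometry[[1]], c(N = -1, AA = 1, ATP = 1))
  expect_equal(m$species$molecular_weight[m$species$id == "Emetab2"], 0.16)

  # the same attributes as literal numbers give the identical model
  xml_lit <- gsub("\"kcat2\"", "\"2500\"", xml, fixed = TRUE)
  xml_lit <- gsub("ram:kcatBackward=\"zero\"", "ram:kcatBackward=\"0\"",
                  xml_lit, fixed = TRUE)
  f2 <- tempfile(fileext = ".xml")
  writeLines(xml_lit, f2)
  m_lit <- read_ram_sbml(f2)
  expect_equal(ram_reactions(m_lit)$kcat_forward, 2500)
  expect_model_equal(m, m_lit)
})

test_that("initialConcentration plus compartment size reconstructs amounts", {
  toy <- toy_model()
  f <- write_tmp(toy)
  doc <- xml2::read_xml(f)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  # re-encode the ribosome as a concentration in a sized compartment
  comp <- xml2::xml_find_first(doc, "//s:compartment[@id='cytosol']", ns)
  xml2::xml_set_attr(comp, "size", "2")
  rib <- xml2::xml_find_first(doc, "//s:species[@id='R']", ns)
  xml2::xml_set_attr(rib, "initialAmount", NULL)
  xml2::xml_set_attr(rib, "initialConcentration", "0.01682")
  xml2::xml_set_attr(rib, "hasOnlySubstanceUnits", "false")
  f2 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc, f2)
  m <- read_ram_sbml(f2)
  expect_equal(m$species$initial_amount[m$species$id == "R"], 0.03364)
})

test_that("50 random models round-trip with exact field equality", {
  for (seed in 1:50) {
    m <- random_ram_model(seed)
    m2 <- read_ram_sbml(write_tmp(m))
    expect_model_equal(m, m2)
  }
})

test_that("EC numbers and foreign annotations survive a round trip", {
  m <- random_ram_model(4)
  m$reactions$ec_number[1] <- "2.7.1.17"
  m$reactions$annotation_extra[[1]] <-
    '<foreign xmlns="http://example.org/x"><note>kept</note></foreign>'
  m2 <- read_ram_sbml(write_tmp(m))
  expect_equal(m2$reactions$ec_number[1], "2.7.1.17")
  expect_match(m2$reactions$annotation_extra[[1]], "kept")
  m3 <- read_ram_sbml(write_tmp(m2))
  expect_model_equal(m2, m3)
})

test_that("validator reports located findings for dialect violations", {
  toy <- toy_model()
  f <- write_tmp(toy)

  # irreversible reaction with nonzero backward turnover rate
  doc <- xml2::read_xml(f)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          ram = "https://www.fairdomhub.org/sops/304")
  r3 <- xml2::xml_find_first(
    doc, "//s:reaction[@id='R3']//ram:reaction", ns
  )
  xml2::xml_set_attr(r3, "ram:kcatBackward", "30")
  f_bad <- tempfile(fileext = ".xml")
  xml2::write_xml(doc, f_bad)
  rep <- validate_ram_document(f_bad)
  expect_true("ram-kcat-backward-zero" %in% rep$rule)
  expect_match(rep$location[rep$rule == "ram-kcat-backward-zero"], "R3")

  # unknown species type
  doc2 <- xml2::read_xml(f)
  sp <- xml2::xml_find_first(doc2, "//s:species[@id='N']//ram:species", ns)
  xml2::xml_set_attr(sp, "ram:speciesType", "mystery")
  f_bad2 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc2, f_bad2)
  rep2 <- validate_ram_document(f_bad2)
  expect_true("ram-species-type" %in% rep2$rule)

  # dangling parameter reference
  doc3 <- xml2::read_xml(f)
  r1 <- xml2::xml_find_first(doc3, "//s:reaction[@id='R1']//ram:reaction", ns)
  xml2::xml_set_attr(r1, "ram:kcatForward", "kcat_ghost")
  f_bad3 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc3, f_bad3)
  rep3 <- validate_ram_document(f_bad3)
  expect_true("ram-parameter-resolve" %in% rep3$rule)
  expect_error(read_ram_sbml(f_bad3), "kcat_ghost")

  # duplicated macromolecule id across compartments is a warning
  doc4 <- xml2::read_xml(f)
  rib <- xml2::xml_find_first(doc4, "//s:species[@id='R']", ns)
  copy <- xml2::xml_add_sibling(rib, rib)
  xml2::xml_set_attr(copy, "compartment", "external")
  f_warn <- tempfile(fileext = ".xml")
  xml2::write_xml(doc4, f_warn)
  rep4 <- validate_ram_document(f_warn)
  expect_true("ram-unique-macromolecule-ids" %in% rep4$rule)
  expect_equal(
    unique(rep4$severity[rep4$rule == "ram-unique-macromolecule-ids"]),
    "warning"
  )
})

test_that("reader rejects documents with missing mandatory pieces", {
  toy <- toy_model()
  f <- write_tmp(toy)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")

  doc <- xml2::read_xml(f)
  sp <- xml2::xml_find_first(doc, "//s:species[@id='N1']", ns)
  xml2::xml_set_attr(sp, "initialAmount", NULL)
  f_bad <- tempfile(fileext = ".xml")
  xml2::write_xml(doc, f_bad)
  expect_error(read_ram_sbml(f_bad), "initialAmount|initialConcentration")

  doc2 <- xml2::read_xml(f)
  ann <- xml2::xml_find_first(doc2, "//s:species[@id='N1']/s:annotation", ns)
  xml2::xml_remove(ann)
  f_bad2 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc2, f_bad2)
  expect_error(read_ram_sbml(f_bad2), "ram:species annotation")
})
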