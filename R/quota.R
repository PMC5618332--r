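#' Specify a lumped quota compound
#'
#' A quota compound lumps a group of biomass-reaction substrates (e.g. all
#' charged tRNAs for the protein quota, or the DNA nucleotides for the DNA
#' quota) into a single noncatalytic species whose production is enforced as
#' a fixed fraction of total biomass.
#'
#' @param quota_id Identifier of the quota species to be produced.
#' @param components Data frame with columns `species` (id), `coefficient`
#'   (stoichiometric coefficient in the biomass reaction, mmol/g), and
#'   `weight` (molecular weight of the underlying monomer, g/mmol). These are
#'   the biomass-reaction reactants assigned to this quota.
#' @param byproducts Optional data frame with columns `species`,
#'   `coefficient`: species released when the quota unit is formed (e.g. the
#'   uncharged tRNAs). Coefficients are positive.
#' @return A `quota_spec` object.
#' @export
quota_spec <- function(quota_id, components, byproducts = NULL) {
  components <- as_tibble(components)
  stopifnot(all(c("species", "coefficient", "weight") %in% names(components)))
  if (any(components$coefficient <= 0) || any(components$weight <= 0)) {
    abort("Component coefficients and weights must be positive.")
  }
  if (is.null(byproducts)) {
    byproducts <- tibble(species = character(), coefficient = numeric())
  } else {
    byproducts <- as_tibble(byproducts)
    stopifnot(all(c("species", "coefficient") %in% names(byproducts)))
    if (any(byproducts$coefficient <= 0)) {
      abort("Byproduct coefficients must be positive.")
    }
  }
  structure(
    list(quota_id = quota_id, components = components, byproducts = byproducts),
    class = "quota_spec"
  )
}

#' Build the normalized production reaction of a quota compound
#'
#' From the biomass-reaction coefficients S_i (mmol/g) of the components and
#' their molecular weights w_i, the quota fraction is
#' `phi = sum over components of S_i w_i` (the mass of this group per gram of
#' biomass). All component, byproduct, and polymerization-energy coefficients
#' are divided by phi so that one unit of the quota compound has a weighted
#' reactant-minus-byproduct mass of exactly 1 g; the quota species is then
#' assigned molecular weight 1 g/mmol and biomass fraction phi.
#'
#' @param quota A [quota_spec()].
#' @param polymerization_energy Optional named numeric vector of signed
#'   coefficients for the energy species of the quota reaction, on the
#'   biomass-reaction scale (e.g. `c(ATP = -23.09, ADP = 23.09, ...)`);
#'   divided by phi like everything else. For the protein quota this is the
#'   fraction phi of the total polymerization ATP of the original biomass
#'   reaction.
#' @return A list with `reaction` (one-row reaction tibble, id
#'   `synth_<quota_id>`, producing 1 unit of the quota species), `phi` (the
#'   quota fraction), and `total_component_coefficient` (sum of the
#'   normalized component coefficients, the "protein length" entering
#'   [quota_reaction_kcat()]).
#' @export
build_quota_reaction <- function(quota, polymerization_energy = NULL) {
  stopifnot(inherits(quota, "quota_spec"))
  phi <- sum(quota$components$coefficient * quota$components$weight)
  if (phi == 0) abort("Quota fraction phi is zero; check the coefficients.")
  comp <- setNames(-quota$components$coefficient / phi,
                   quota$components$species)
  byp <- setNames(quota$byproducts$coefficient / phi,
                  quota$byproducts$species)
  energy <- if (is.null(polymerization_energy)) numeric(0) else {
    polymerization_energy / phi
  }
  stoich <- c(comp, byp, energy, setNames(1, quota$quota_id))
  stoich <- tapply(stoich, names(stoich), sum) # merge duplicated species
  stoich <- setNames(as.numeric(stoich), names(stoich))
  reaction <- tibble(
    id = paste0("synth_", quota$quota_id),
    name = paste0("synthesis of ", quota$quota_id),
    reversible = FALSE,
    stoichiometry = list(stoich[stoich != 0]),
    kcat_forward = 0, kcat_backward = 0, maintenance_scaling = 0,
    lower_bound = 0, upper_bound = Inf,
    gene_product = NA_character_, ec_number = NA_character_
  )
  list(
    reaction = reaction,
    phi = phi,
    total_component_coefficient = sum(quota$components$coefficient) / phi
  )
}

#' Adjust the protein quota for explicitly modeled enzymes
#'
#' The biomass reaction's protein term covers all protein mass, but enzymes
#' and the ribosome are modeled explicitly. Given the fraction `fe` of the
#' proteome (from a quantitative proteomics dataset normalized to sum to 1)
#' that is modeled explicitly, the noncatalytic protein quota fraction is
#' `phi_quota = phi_protein * (1 - fe)`.
#'
#' @param phi_protein Protein quota fraction before adjustment.
#' @param explicit_fraction Proteome fraction fe of explicitly modeled
#'   proteins, in \[0, 1\].
#' @return The adjusted quota fraction.
#' @export
adjust_protein_quota <- function(phi_protein, explicit_fraction) {
  if (any(explicit_fraction < 0) || any(explicit_fraction > 1)) {
    abort("`explicit_fraction` must be in [0, 1].")
  }
  phi_protein * (1 - explicit_fraction)
}

#' Yeast biomass charged-tRNA coefficients (synthetic reconstruction)
#'
#' The standard yeast biomass protein composition: per-amino-acid
#' charged-tRNA coefficients (mmol per gram dry weight) of the consensus
#' yeast biomass reaction lineage, with average free amino-acid molecular
#' weights. This table is a reconstruction from the published composition
#' data, shipped for examples and tests; it is read from
#' `inst/extdata/yeast_protein_quota_synthetic.csv`.
#'
#' @return A tibble with columns `species`, `coefficient` (mmol/g),
#'   `weight` (g/mmol), `byproduct` (the released uncharged tRNA id).
#' @export
yeast_protein_quota_table <- function() {
  path <- system.file("extdata", "yeast_protein_quota_synthetic.csv",
                      package = "ramtool", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
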