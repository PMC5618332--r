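#' The self-replicator toy model
#'
#' A 14-species, 14-reaction resource-allocation model of a minimal cell:
#' three external nutrients (N1, N2, O2, with O2 nonlimiting), three internal
#' metabolites (N, AA, ATP), a storage compound (Stor), five enzymes
#' (ETrans1, ETrans2, EMetab1, EMetab2, EStor), a structural quota compound
#' (S), and the ribosome (R). Two transport reactions import N from either
#' nutrient, three metabolic reactions convert N into amino acids and
#' energy, a spontaneous maintenance reaction drains amino acids and ATP in
#' proportion to biomass, a reversible storage reaction banks amino acids
#' and energy, and seven ribosome-catalyzed synthesis reactions produce the
#' macromolecules.
#'
#' Quantities not fixed by the published model structure (molecular and
#' objective weights, the maintenance coefficient, the structural biomass
#' fraction, initial enzyme amounts, the N2 amount) are exposed as
#' parameters with documented fixture defaults: enzyme, ribosome, and
#' storage weights equal the synthesis chain length divided by 1000
#' (g/mmol); the structural component weighs 0.08 g/mmol, below the
#' mass-yield parity point of the ribosome-catalyzed products, so that
#' structural biomass is produced to satisfy the quota rather than as an
#' objective shortcut (with the printed turnover rates, a weight
#' proportional to its chain length would make S by far the cheapest way
#' to accumulate biomass and the optimal strategy would degenerate);
#' psi = 0.01 mmol/(g h), bp_S = 0.3, 0.01 mmol of each enzyme at t = 0,
#' and 10 mmol N2.
#'
#' @param psi_maintenance Maintenance coefficient of the AA/ATP drain,
#'   mmol/(g h).
#' @param bp_S Biomass fraction of the structural component S.
#' @param structural_weight Molecular (and objective) weight of S, g/mmol.
#' @param enzyme_init Initial amount (mmol) of each of the five enzymes.
#' @param n1_init,n2_init Initial nutrient amounts (mmol).
#' @param nonlimiting Ids of external species treated as nonlimiting
#'   boundary species (default O2 only; add N1/N2 to emulate saturating
#'   nutrient conditions).
#' @return A [ram_model()].
#' @examples
#' toy <- toy_model()
#' partition_model(toy)
#' @export
toy_model <- function(psi_maintenance = 0.01, bp_S = 0.3, enzyme_init = 0.01,
                      n1_init = 10, n2_init = 10, structural_weight = 0.08,
                      nonlimiting = "O2") {
  chain <- c(ETrans1 = 100, ETrans2 = 160, EMetab1 = 200, EMetab2 = 160,
             EStor = 150, S = 1500, R = 1000, Stor = 200)
  w <- chain / 1000
  w["S"] <- structural_weight
  enz <- c("ETrans1", "ETrans2", "EMetab1", "EMetab2", "EStor")

  species <- tibble(
    id = c("N1", "N2", "O2", "N", "AA", "ATP", "Stor",
           enz, "S", "R"),
    name = c("Nutrient 1", "Nutrient 2", "Oxygen", "Nitrogen source",
             "Amino acids", "Energy", "Storage",
             "Transporter 1", "Transporter 2", "Metabolic enzyme 1",
             "Metabolic enzyme 2", "Storage enzyme",
             "Structural biomass component", "Ribosome"),
    compartment = c(rep("external", 3), rep("cytosol", 11)),
    type = c(rep("extracellular", 3), rep("metabolite", 3), "storage",
             rep("enzyme", 5), "quota", "enzyme"),
    molecular_weight = c(rep(0, 6), w[c("Stor", enz, "S", "R")]),
    biomass_percentage = c(rep(0, 12), bp_S, 0),
    initial_amount = c(n1_init, n2_init, 10, 0, 0, 0, 0,
                       rep(enzyme_init, 5), 0.7499, 0.03364)
  )
  species$boundary <- species$id %in% nonlimiting
  species$constant <- species$boundary

  st <- function(...) list(c(...))
  reactions <- bind_rows(
    tibble(id = "R1", stoichiometry = st(N1 = -1, O2 = -1, N = 1),
           reversible = TRUE, kcat_forward = 1800, kcat_backward = 1800,
           gene_product = "ETrans1"),
    tibble(id = "R2", stoichiometry = st(N2 = -1, O2 = -1, N = 1),
           reversible = TRUE, kcat_forward = 2400, kcat_backward = 2400,
           gene_product = "ETrans2"),
    tibble(id = "R3", stoichiometry = st(N = -1, AA = 1, ATP = 1),
           kcat_forward = 2000, gene_product = "EMetab1"),
    tibble(id = "R4", stoichiometry = st(N = -1, AA = 1, ATP = 1),
           kcat_forward = 2500, gene_product = "EMetab2"),
    tibble(id = "R5", stoichiometry = st(N = -1, AA = 1, ATP = 2),
           kcat_forward = 2000, gene_product = "EMetab2"),
    tibble(id = "Maintenance", stoichiometry = st(AA = -50, ATP = -60),
           maintenance_scaling = psi_maintenance),
    tibble(id = "R7", stoichiometry = st(AA = -200, ATP = -300, Stor = 1),
           reversible = TRUE, kcat_forward = 25, kcat_backward = 30,
           gene_product = "EStor"),
    tibble(id = "synth_ETrans1",
           stoichiometry = st(AA = -100, ATP = -400, ETrans1 = 1),
           kcat_forward = 10, gene_product = "R"),
    tibble(id = "synth_ETrans2",
           stoichiometry = st(AA = -160, ATP = -640, ETrans2 = 1),
           kcat_forward = 6.25, gene_product = "R"),
    tibble(id = "synth_EMetab1",
           stoichiometry = st(AA = -200, ATP = -800, EMetab1 = 1),
           kcat_forward = 5, gene_product = "R"),
    tibble(id = "synth_EMetab2",
           stoichiometry = st(AA = -160, ATP = -640, EMetab2 = 1),
           kcat_forward = 6.25, gene_product = "R"),
    tibble(id = "synth_EStor",
           stoichiometry = st(AA = -150, ATP = -500, EStor = 1),
           kcat_forward = 5, gene_product = "R"),
    tibble(id = "synth_S",
           stoichiometry = st(AA = -1500, ATP = -200, S = 1),
           kcat_forward = 10, gene_product = "R"),
    tibble(id = "synth_R",
           stoichiometry = st(AA = -1000, ATP = -4000, R = 1),
           kcat_forward = 1, gene_product = "R")
  )

  gene_products <- tibble(
    id = c(enz, "R"),
    label = c("1*GTRANS1", "1*GTRANS2 AND 1*GTRANS3", "1*GMETAB1",
              "1*GMETAB2", "1*GSTOR", "RIBOSOME"),
    associated_species = c(enz, "R")
  )

  ram_model(species, reactions, gene_products, id = "toy_ram",
            name = "self-replicator toy model")
}
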