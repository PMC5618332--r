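# Shared micro-model fixtures built in code.

# Two isoenzymes for one reaction: used for the flux-cone equivalence check.
isoenzyme_micro_model <- function(kcat = 5) {
  ram_model(
    species = tibble::tibble(
      id = c("Sx", "M", "e1", "e2"),
      type = c("extracellular", "metabolite", "enzyme", "enzyme"),
      molecular_weight = c(0, 0, 1, 1),
      initial_amount = c(10, 0, 0.4, 0.6),
      boundary = c(TRUE, FALSE, FALSE, FALSE)
    ),
    reactions = tibble::tibble(
      id = "r",
      stoichiometry = list(c(Sx = -1, M = 1)),
      kcat_forward = kcat
    ),
    gene_products = tibble::tibble(
      id = c("e1", "e2"), label = c("1*G1", "1*G2"),
      associated_species = c("e1", "e2")
    )
  )
}

expect_model_equal <- function(m1, m2) {
  expect_equal(as.data.frame(m1$species), as.data.frame(m2$species),
               tolerance = 0)
  expect_equal(as.data.frame(m1$reactions), as.data.frame(m2$reactions),
               tolerance = 0)
  expect_equal(as.data.frame(m1$gene_products),
               as.data.frame(m2$gene_products), tolerance = 0)
}

# Rebuild a model with extra reaction rows (runs the full normalization
# and validation instead of editing the reaction table in place).
with_extra_reactions <- function(model, reactions) {
  ram_model(
    model$species,
    dplyr::bind_rows(model$reactions, reactions),
    model$gene_products,
    id = model$id
  )
}

# Maximal net flux through a set of reactions under the capacity
# constraint at fixed enzyme amounts; independent route used as the LP
# oracle for isoenzyme splitting.
max_capacity_flux <- function(model, p) {
  cap <- build_capacity_matrices(model)
  fc <- cap$flux_columns
  part <- partition_model(model)
  obj <- fc$sign
  res <- lp_solve(
    obj, A_ub = cap$HC, b_ub = as.numeric(cap$HE %*% p[part$P]),
    maximize = TRUE
  )
  res$objective
}
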