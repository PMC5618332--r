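test_that("toy model partitions into the published species and reaction classes", {
  part <- partition_model(toy_model())
  expect_equal(part$Y, c("N1", "N2", "O2"))
  expect_equal(part$X, c("N", "AA", "ATP"))
  expect_equal(part$C, "Stor")
  expect_equal(part$P,
               c("ETrans1", "ETrans2", "EMetab1", "EMetab2", "EStor", "S", "R"))
  # all seven macromolecule-producing reactions end up in R_p
  expect_equal(part$R_p, paste0("synth_", part$P))
  expect_equal(part$R_y, c("R1", "R2"))
  expect_equal(part$R_c, "R7")
  expect_true("Maintenance" %in% part$R_x)
})

test_that("partition is disjoint and exhaustive, also on random models", {
  for (seed in 1:10) {
    m <- random_ram_model(seed)
    part <- partition_model(m)
    expect_setequal(c(part$Y, part$X, part$C, part$P), m$species$id)
    expect_equal(length(c(part$Y, part$X, part$C, part$P)),
                 nrow(m$species))
    expect_setequal(c(part$R_y, part$R_x, part$R_c, part$R_p),
                    m$reactions$id)
    expect_equal(length(c(part$R_y, part$R_x, part$R_c, part$R_p)),
                 nrow(m$reactions))
  }
})

test_that("empty model yields empty partitions", {
  m <- ram_model(
    species = tibble::tibble(id = character(), type = character()),
    reactions = tibble::tibble(id = character(), stoichiometry = list())
  )
  part <- partition_model(m)
  expect_true(all(lengths(part) == 0))
})

test_that("a reaction converting a nutrient directly into a macromolecule is rejected", {
  m <- ram_model(
    species = tibble::tibble(
      id = c("ext1", "enz1"), type = c("extracellular", "enzyme"),
      molecular_weight = c(0, 1)
    ),
    reactions = tibble::tibble(
      id = "shortcut", stoichiometry = list(c(ext1 = -1, enz1 = 1))
    )
  )
  expect_error(partition_model(m), "shortcut")
})

test_that("capacity matrices encode the per-enzyme kcat-weighted flux sums", {
  toy <- toy_model()
  cap <- build_capacity_matrices(toy)
  fc <- cap$flux_columns

  # EMetab2 catalyzes two reactions with different turnover rates
  row <- cap$HC["EMetab2", ]
  c4 <- fc$col[fc$reaction_id == "R4"]
  c5 <- fc$col[fc$reaction_id == "R5"]
  expect_equal(row[c4], 1 / 2500)
  expect_equal(row[c5], 1 / 2000)
  expect_equal(sum(row != 0), 2)

  # the spontaneous maintenance reaction appears in no capacity row
  maint_cols <- fc$col[fc$reaction_id == "Maintenance"]
  expect_true(all(cap$HC[, maint_cols] == 0))

  # the ribosome row couples all seven synthesis reactions
  expect_equal(sum(cap$HC["R", ] != 0), 7)
})

test_that("capacity product equals the explicit per-enzyme sum (oracle equivalence)", {
  toy <- toy_model()
  cap <- build_capacity_matrices(toy)
  fc <- cap$flux_columns
  cat_tbl <- catalysis_map(toy)
  withr::with_seed(11, {
    for (rep in 1:100) {
      v <- runif(nrow(fc), 0, 10)
      lhs <- as.numeric(cap$HC %*% v)
      oracle <- purrr::map_dbl(cap$enzymes, function(e) {
        rxs <- cat_tbl$reaction_id[cat_tbl$enzyme == e]
        cols <- fc[fc$reaction_id %in% rxs, ]
        sum(v[cols$col] / cols$kcat)
      })
      expect_equal(lhs, oracle, tolerance = 1e-12)
    }
  })
})

test_that("HE is a filter matrix with exactly one unit entry per row", {
  for (m in list(toy_model(), random_ram_model(3), random_ram_model(7))) {
    cap <- build_capacity_matrices(m)
    if (nrow(cap$HE) == 0) next
    expect_true(all(Matrix::rowSums(cap$HE != 0) == 1))
    expect_true(all(cap$HE@x == 1))
  }
})

test_that("catalyzed reactions without a positive kcat are a parameterization error", {
  m <- toy_model()
  m$reactions$kcat_forward[m$reactions$id == "R3"] <- 0
  expect_error(build_capacity_matrices(m), "R3")
})

test_that("quota rows encode w_s p_s >= phi_s B_t", {
  toy <- toy_model(bp_S = 0.2)
  HB <- build_biomass_composition_matrix(toy)
  part <- partition_model(toy)
  sp <- toy$species
  w_S <- sp$molecular_weight[sp$id == "S"]
  withr::with_seed(21, {
    for (rep in 1:20) {
      cc <- runif(length(part$C), 0, 5)
      p <- runif(length(part$P), 0, 5)
      lhs <- as.numeric(HB %*% c(cc, p))
      Bt <- total_biomass(toy, cc, p)
      p_S <- p[match("S", part$P)]
      expect_equal(lhs, 0.2 * Bt - w_S * p_S, tolerance = 1e-12)
    }
  })
})

test_that("a zero quota fraction is trivially satisfied for nonnegative amounts", {
  toy <- toy_model(bp_S = 0)
  HB <- build_biomass_composition_matrix(toy)
  part <- partition_model(toy)
  withr::with_seed(5, {
    for (rep in 1:20) {
      amounts <- runif(length(part$C) + length(part$P), 0, 10)
      expect_lte(as.numeric(HB %*% amounts), 0)
    }
  })
})

test_that("quota species without molecular weight cannot enter the quota matrix", {
  m <- toy_model()
  m$species$molecular_weight[m$species$id == "S"] <- 0
  expect_error(build_biomass_composition_matrix(m), "S")
})

test_that("maintenance rows reproduce psi * B_t as the flux floor", {
  psi <- 0.037
  toy <- toy_model(psi_maintenance = psi)
  maint <- build_maintenance_matrix(toy)
  part <- partition_model(toy)
  expect_equal(maint$reactions, "Maintenance")
  withr::with_seed(31, {
    for (rep in 1:20) {
      cc <- runif(length(part$C), 0, 5)
      p <- runif(length(part$P), 0, 5)
      floor_val <- as.numeric(maint$HM %*% c(cc, p))
      expect_equal(floor_val, psi * total_biomass(toy, cc, p),
                   tolerance = 1e-12)
    }
  })
})

test_that("without maintenance reactions H_M is empty", {
  maint <- build_maintenance_matrix(toy_model(psi_maintenance = 0))
  expect_equal(nrow(maint$HM), 0)
  expect_length(maint$reactions, 0)
})

test_that("objective and total biomass follow the weight chain", {
  toy <- toy_model()
  part <- partition_model(toy)
  nC <- length(part$C); nP <- length(part$P)
  expect_equal(objective_biomass(toy, rep(0, nP)), 0)
  expect_equal(total_biomass(toy, rep(0, nC), rep(0, nP)), 0)

  # storage counts toward B_t but not B_o
  expect_equal(objective_biomass(toy, rep(0, nP)), 0)
  expect_equal(total_biomass(toy, setNames(2, "Stor"), rep(0, nP)),
               2 * toy$species$molecular_weight[toy$species$id == "Stor"])

  withr::with_seed(41, {
    for (rep in 1:20) {
      cc <- runif(nC, 0, 5); p <- runif(nP, 0, 5)
      Bo <- objective_biomass(toy, p)
      Bt <- total_biomass(toy, cc, p)
      expect_gte(Bt, Bo)
      if (all(cc == 0)) expect_equal(Bt, Bo)
    }
  })
  expect_error(objective_biomass(toy, rep(-1, nP)), "negative")
})

test_that("model invariants are enforced", {
  sp <- tibble::tibble(
    id = c("a", "e"), type = c("extracellular", "enzyme"),
    molecular_weight = c(0, 1)
  )
  rx <- tibble::tibble(id = "r", stoichiometry = list(c(a = -1)))
  expect_silent(ram_model(sp, rx))

  # irreversible reaction with backward kcat
  bad <- tibble::tibble(id = "r", stoichiometry = list(c(a = -1)),
                        reversible = FALSE, kcat_backward = 5)
  expect_error(ram_model(sp, bad), "kcat_backward")

  # maintenance must be spontaneous
  bad2 <- tibble::tibble(id = "r", stoichiometry = list(c(a = -1)),
                         maintenance_scaling = 0.1, gene_product = "gp")
  expect_error(ram_model(sp, bad2, tibble::tibble(
    id = "gp", label = "x", associated_species = "e"
  )), "spontaneous")

  # quota fraction on a non-quota species
  sp_bad <- sp; sp_bad$biomass_percentage <- c(0, 0.2)
  expect_error(ram_model(sp_bad, rx), "non-quota")

  # boundary flag restricted to extracellular species
  sp_bad2 <- sp; sp_bad2$boundary <- c(FALSE, TRUE)
  expect_error(ram_model(sp_bad2, rx), "boundary")

  # stoichiometry keys must resolve
  rx_bad <- tibble::tibble(id = "r", stoichiometry = list(c(nope = -1)))
  expect_error(ram_model(sp, rx_bad), "undeclared species")
})
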