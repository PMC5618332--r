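test_that("amino-acid counting tallies residues and reports positions of bad characters", {
  expect_equal(unclass(amino_acid_counts("M"))[["M"]], 1L)
  expect_equal(attr(amino_acid_counts("M"), "length"), 1L)

  cnt <- amino_acid_counts("MKM")
  expect_equal(cnt[["M"]], 2L)
  expect_equal(cnt[["K"]], 1L)
  expect_equal(attr(cnt, "length"), 3L)

  # stop characters are stripped
  expect_equal(attr(amino_acid_counts("MKM*"), "length"), 3L)

  # ambiguity codes rejected by default, mapped on request
  expect_error(amino_acid_counts("MBM"), "position 2")
  expect_equal(amino_acid_counts("MBM", map_ambiguous = TRUE)[["D"]], 1L)

  withr::with_seed(7, {
    seqs <- replicate(5, paste(sample(names(default_residue_map()), 200,
                                      replace = TRUE), collapse = ""))
    for (s in seqs) {
      cnt <- amino_acid_counts(s)
      expect_equal(sum(cnt), 200L)
      # brute-force tally oracle
      oracle <- table(strsplit(s, "")[[1]])
      expect_equal(sum(cnt[names(oracle)] == as.integer(oracle)),
                   length(oracle))
    }
  })
})

test_that("synthesis reaction of a one-residue monomer carries the per-residue energy costs", {
  spec <- protein_spec("E_m", tibble::tibble(gene = "g", sequence = "M"))
  st <- protein_synthesis_reaction(spec, energy_model("detailed"))$stoichiometry[[1]]
  expect_equal(st[["Met"]], -1)
  expect_equal(st[["ATP"]], -1)
  expect_equal(st[["GTP"]], -2)
  expect_equal(st[["AMP"]], 1)
  expect_equal(st[["PPi"]], 1)
  expect_equal(st[["GDP"]], 2)
  expect_equal(st[["Pi"]], 2)
  expect_equal(st[["E_m"]], 1)
})

test_that("homotrimer stoichiometry is the monomer stoichiometry times three", {
  seq <- "MKTAYIAK"
  mono <- protein_synthesis_reaction(
    protein_spec("E", tibble::tibble(gene = "g", sequence = seq, copies = 1)),
    energy_model("detailed")
  )$stoichiometry[[1]]
  tri <- protein_synthesis_reaction(
    protein_spec("E", tibble::tibble(gene = "g", sequence = seq, copies = 3)),
    energy_model("detailed")
  )$stoichiometry[[1]]
  reactants <- setdiff(names(mono), "E")
  expect_equal(tri[reactants], 3 * mono[reactants])
  expect_equal(tri[["E"]], 1)
})

test_that("complexes sum copy-weighted counts over genes (dimer-of-dimers pattern)", {
  spec <- protein_spec("IDH", tibble::tibble(
    gene = c("YOR136W_like", "YNL037C_like"),
    sequence = c("MKT", "AYI"),
    copies = c(2L, 2L)
  ))
  st <- protein_synthesis_reaction(spec, energy_model("detailed"))$stoichiometry[[1]]
  # each gene's residues times two, then summed
  expect_equal(st[["Met"]], -2)
  expect_equal(st[["Lys"]], -2)
  expect_equal(st[["Thr"]], -2)
  expect_equal(st[["Ala"]], -2)
  expect_equal(st[["Tyr"]], -2)
  expect_equal(st[["Ile"]], -2)
  expect_equal(st[["ATP"]], -12)
  expect_equal(st[["GTP"]], -24)
})

test_that("energy cofactor totals equal copies-weighted residue count times per-residue costs", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      n_sub <- sample(1:3, 1)
      subunits <- tibble::tibble(
        gene = paste0("g", seq_len(n_sub)),
        sequence = replicate(n_sub, paste(
          sample(names(default_residue_map()), sample(10:60, 1),
                 replace = TRUE), collapse = "")),
        copies = sample(1:3, n_sub, replace = TRUE)
      )
      total <- sum(nchar(subunits$sequence) * subunits$copies)
      rxn <- protein_synthesis_reaction(
        protein_spec("E", subunits), energy_model("detailed")
      )
      st <- rxn$stoichiometry[[1]]
      expect_equal(attr(rxn, "total_residues"), total)
      expect_equal(st[["ATP"]], -total)
      expect_equal(st[["GTP"]], -2 * total)
      expect_equal(st[["AMP"]], total)
      aa <- st[names(st) %in% default_residue_map()]
      expect_equal(sum(-aa), total)
    }
  })
})

test_that("lumped energy mode charges atp_per_aa ATP -> ADP + Pi per residue", {
  spec <- protein_spec("E", tibble::tibble(gene = "g", sequence = "MKTAY"))
  st <- protein_synthesis_reaction(spec, energy_model("lumped", atp_per_aa = 4))$
    stoichiometry[[1]]
  expect_equal(st[["ATP"]], -20)
  expect_equal(st[["ADP"]], 20)
  expect_equal(st[["Pi"]], 20)
  expect_false("GTP" %in% names(st))
})

test_that("ribosome turnover rate is the elongation rate over the protein length", {
  expect_equal(ribosome_kcat(15, 100), 540)
  expect_equal(ribosome_kcat(1 / 3600 * 100, 100), 1)
  # elongation rate implied by the toy ribosome self-synthesis (1000 aa/h)
  expect_equal(ribosome_kcat(1000 / 3600, 100), 10)
  expect_equal(ribosome_kcat(1000 / 3600, 160), 6.25)
  expect_error(ribosome_kcat(0, 100), "positive")
  expect_error(ribosome_kcat(15, -1), "positive")
})

test_that("quota-synthesis turnover rate scales inversely with the lumped chain length", {
  expect_equal(as.numeric(quota_reaction_kcat(1, 3600)), 1)
  expect_equal(attr(quota_reaction_kcat(1, 3600), "unit"), "1/(mmol*h)")
  # toy structural reaction: 1500 amino acids at rate 10 implies a = 25/6 aa/s
  a_implied <- 10 * 1500 / 3600
  expect_equal(as.numeric(quota_reaction_kcat(a_implied, 1500)), 10)
  expect_equal(as.numeric(quota_reaction_kcat(a_implied, 3000)), 5)
})

test_that("isoenzyme splitting copies the reaction once per enzyme", {
  m <- isoenzyme_micro_model()
  split <- split_isoenzyme_reactions(m, list(r = c("e1", "e2")))
  rx <- ram_reactions(split)
  expect_equal(rx$id, c("r_iso1", "r_iso2"))
  expect_equal(rx$gene_product, c("e1", "e2"))
  expect_equal(rx$stoichiometry[[1]], rx$stoichiometry[[2]])
  expect_equal(rx$stoichiometry[[1]], c(Sx = -1, M = 1))

  # single-enzyme mapping only assigns the gene product
  single <- split_isoenzyme_reactions(m, list(r = "e1"))
  expect_equal(ram_reactions(single)$id, "r")
  expect_equal(ram_reactions(single)$gene_product, "e1")

  expect_error(split_isoenzyme_reactions(m, list(r = "nope")), "nope")
  expect_error(split_isoenzyme_reactions(m, list(zz = "e1")), "zz")
})

test_that("splitting preserves the reachable flux through the reaction (LP oracle)", {
  kcat <- 5
  m <- isoenzyme_micro_model(kcat)
  p <- c(e1 = 0.4, e2 = 0.6)
  split <- split_isoenzyme_reactions(m, list(r = c("e1", "e2")))
  v_split <- max_capacity_flux(split, p)
  # combined bound of the original shared-capacity formulation
  expect_equal(v_split, kcat * sum(p), tolerance = 1e-9)
})

test_that("compartment-resolved enzyme ids are deterministic and unique", {
  expect_equal(make_enzyme_id("FUM", "cytosol"), "FUM_cytosol")
  expect_equal(make_enzyme_id("ETrans2", c("e", "c")), "ETrans2_e_c")
  expect_equal(make_enzyme_id("FUM", "cytosol"), make_enzyme_id("FUM", "cytosol"))

  spec <- protein_spec("FUM", tibble::tibble(gene = "YPL262W", sequence = "MKT"),
                       compartments = c("cytosol", "mitochondrion"))
  dup <- duplicate_enzyme_per_compartment(spec)
  expect_length(dup, 2)
  ids <- purrr::map_chr(dup, "enzyme_id")
  expect_equal(ids, c("FUM_cytosol", "FUM_mitochondrion"))
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(dup[[1]]$subunits, spec$subunits)

  single <- duplicate_enzyme_per_compartment(
    protein_spec("E", tibble::tibble(gene = "g", sequence = "M"),
                 compartments = "cytosol")
  )
  expect_length(single, 1)
})

test_that("median turnover-rate aggregation matches a sort-based oracle", {
  expect_equal(aggregate_kcat(tibble::tibble(value = c(1, 2, 100))), 2)
  expect_equal(aggregate_kcat(tibble::tibble(value = 42)), 42)
  expect_equal(aggregate_kcat(tibble::tibble(value = c(1, 3)), "mean"), 2)

  sort_median <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  withr::with_seed(17, {
    for (rep in 1:1000) {
      x <- runif(sample(1:12, 1), 0.01, 5000)
      expect_identical(aggregate_kcat(tibble::tibble(value = x)),
                       sort_median(x))
    }
    # permutation invariance and scale equivariance
    x <- runif(9, 1, 100)
    expect_equal(aggregate_kcat(tibble::tibble(value = sample(x))),
                 aggregate_kcat(tibble::tibble(value = x)))
    expect_equal(aggregate_kcat(tibble::tibble(value = 7 * x)),
                 7 * aggregate_kcat(tibble::tibble(value = x)))
  })
})

test_that("wild-type filtering precedes aggregation and empty sets are an error", {
  obs <- tibble::tibble(value = c(10, 1000), wild_type = c(TRUE, FALSE))
  expect_equal(aggregate_kcat(obs), 10)
  expect_error(
    aggregate_kcat(tibble::tibble(value = 5, wild_type = FALSE)),
    class = "ramtool_missing_kcat"
  )
})

test_that("kcat assignment falls back from same organism to other organisms to default", {
  obs <- tibble::tibble(
    value = c(10, 100, 200), organism = c("yeast", "coli", "subtilis"),
    wild_type = TRUE
  )
  same <- assign_kcat(obs, "yeast")
  expect_equal(as.numeric(same), 10)
  expect_equal(attr(same, "source"), "same_organism")

  expect_message(other <- assign_kcat(obs, "human"), "other organisms")
  expect_equal(as.numeric(other), 100)
  expect_equal(
    as.numeric(suppressMessages(assign_kcat(obs, "human", strategy = "mean"))),
    mean(c(10, 100, 200))
  )

  expect_message(
    def <- assign_kcat(obs[0, ], "human", default = 50), "default"
  )
  expect_equal(as.numeric(def), 50)
  expect_error(assign_kcat(obs[0, ], "human"),
               class = "ramtool_missing_kcat")
})
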