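#' Random builder inputs for offline testing
#'
#' Generates a reproducible set of synthetic builder inputs: amino-acid
#' FASTA records, a gene-reaction map in which every reaction is covered by
#' at least one gene, and subunit stoichiometries. Useful for exercising
#' the builder protocol without any database access.
#'
#' @param seed Integer seed; the output is a pure function of it.
#' @param n_genes Number of genes.
#' @param length_range Integer range of sequence lengths.
#' @param fasta_path Optional path; when given, the records are also
#'   written as a FASTA file.
#' @return A list with tibbles `fasta` (`id`, `sequence`),
#'   `gene_reaction_map` (`reaction_id`, `gene_id`), and `subunits`
#'   (`enzyme_id`, `gene_id`, `copies`).
#' @export
random_builder_fixture <- function(seed, n_genes = 5,
                                   length_range = c(50, 300),
                                   fasta_path = NULL) {
  withr::with_seed(seed, {
    if (n_genes == 0) {
      return(list(
        fasta = tibble(id = character(), sequence = character()),
        gene_reaction_map = tibble(reaction_id = character(),
                                   gene_id = character()),
        subunits = tibble(enzyme_id = character(), gene_id = character(),
                          copies = integer())
      ))
    }
    genes <- sprintf("g%03d", seq_len(n_genes))
    lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    fasta <- tibble(
      id = genes,
      sequence = map_chr(lens, function(l) {
        paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = "")
      })
    )
    reactions <- sprintf("rxn%03d", seq_len(n_genes))
    gene_reaction_map <- tibble(
      reaction_id = reactions,
      gene_id = sample(genes, n_genes, replace = TRUE)
    )
    subunits <- tibble(
      enzyme_id = paste0("E_", gene_reaction_map$gene_id),
      gene_id = gene_reaction_map$gene_id,
      copies = sample(1:3, n_genes, replace = TRUE)
    )
    out <- list(fasta = fasta, gene_reaction_map = gene_reaction_map,
                subunits = subunits)
    if (!is.null(fasta_path)) write_fasta(fasta, fasta_path)
    out
  })
}

#' Read and write amino-acid FASTA files
#'
#' Thin wrappers around `Biostrings` returning/consuming a tidy table.
#'
#' @param path FASTA file path.
#' @param records A data frame with columns `id` and `sequence`.
#' @return `read_fasta()`: a tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set))
  )
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  records <- as_tibble(records)
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Generate a random valid resource-allocation model
#'
#' Draws a small structurally valid model — a handful of nutrients,
#' metabolites, storage and quota compounds, enzymes with gene products,
#' uptake/metabolic/storage/synthesis reactions with random turnover rates,
#' some reversible, one optional maintenance reaction — for round-trip and
#' property tests. The model is valid by construction (it passes
#' [validate_ram_model()]); it is not necessarily growable.
#'
#' @param seed Integer seed.
#' @return A [ram_model()].
#' @export
random_ram_model <- function(seed) {
  withr::with_seed(seed, {
    n_y <- sample(1:3, 1); n_x <- sample(1:3, 1)
    n_c <- sample(0:2, 1); n_e <- sample(1:4, 1); n_q <- sample(0:2, 1)
    y <- sprintf("ext%d", seq_len(n_y))
    x <- sprintf("met%d", seq_len(n_x))
    cc <- if (n_c > 0) sprintf("stor%d", seq_len(n_c)) else character()
    ee <- sprintf("enz%d", seq_len(n_e))
    qq <- if (n_q > 0) sprintf("quota%d", seq_len(n_q)) else character()

    species <- tibble(
      id = c(y, x, cc, ee, qq),
      type = c(rep("extracellular", n_y), rep("metabolite", n_x),
               rep("storage", n_c), rep("enzyme", n_e), rep("quota", n_q)),
      molecular_weight = c(rep(0, n_y + n_x),
                           round(runif(n_c + n_e + n_q, 0.05, 2), 4)),
      biomass_percentage = c(rep(0, n_y + n_x + n_c + n_e),
                             round(runif(n_q, 0.01, 0.3), 4)),
      initial_amount = round(runif(n_y + n_x + n_c + n_e + n_q, 0, 5), 4),
      boundary = c(runif(n_y) < 0.3, rep(FALSE, n_x + n_c + n_e + n_q))
    )

    gene_products <- tibble(
      id = ee,
      label = paste0("1*G_", toupper(ee)),
      associated_species = ee
    )

    rxn <- list(); rid <- 0
    add <- function(stoich, rev = FALSE, kf = 0, kb = 0, gp = NA_character_,
                    psi = 0, ec = NA_character_) {
      rid <<- rid + 1
      rxn[[rid]] <<- tibble(
        id = sprintf("rxn%02d", rid), stoichiometry = list(stoich),
        reversible = rev, kcat_forward = kf, kcat_backward = kb,
        gene_product = gp, maintenance_scaling = psi, ec_number = ec
      )
    }
    # uptake reactions: one per nutrient, random catalysis
    for (i in seq_len(n_y)) {
      rev <- runif(1) < 0.4
      gp <- if (runif(1) < 0.8) sample(ee, 1) else NA_character_
      kf <- if (is.na(gp)) 0 else round(runif(1, 100, 3000), 2)
      add(setNames(c(-1, 1), c(y[i], sample(x, 1))), rev = rev, kf = kf,
          kb = if (rev && !is.na(gp)) round(runif(1, 100, 3000), 2) else 0,
          gp = gp,
          ec = if (runif(1) < 0.3) "1.1.1.1" else NA_character_)
    }
    # a metabolic interconversion when possible
    if (n_x >= 2) {
      gp <- sample(ee, 1)
      add(setNames(c(-1, 1), x[1:2]), kf = round(runif(1, 100, 3000), 2),
          gp = gp)
    }
    # storage reactions
    for (s in cc) {
      gp <- sample(ee, 1)
      add(setNames(c(-2, 1), c(sample(x, 1), s)),
          kf = round(runif(1, 10, 100), 2), gp = gp)
    }
    # synthesis reactions: one per macromolecule, ribosome-style catalysis
    ribo <- ee[1]
    for (m in c(ee, qq)) {
      add(setNames(c(-round(runif(1, 10, 500)), 1), c(sample(x, 1), m)),
          kf = round(runif(1, 1, 20), 3), gp = ribo)
    }
    # optional spontaneous maintenance
    if (runif(1) < 0.5) {
      add(setNames(-round(runif(1, 1, 50)), sample(x, 1)),
          psi = round(runif(1, 0.001, 0.05), 4))
    }

    ram_model(species, bind_rows(rxn), gene_products,
              id = sprintf("random_%d", seed))
  })
}

#' Minimal self-replicator model
#'
#' One boundary nutrient, one internal precursor, and one enzyme E that
#' catalyzes its own synthesis from the precursor with turnover rate
#' `kcat`; uptake is spontaneous and unbounded. Under unlimited nutrient
#' the optimal policy saturates the capacity constraint, `dp/dt = kcat p`,
#' so the amount of E grows exponentially at rate `kcat` and the biomass
#' integral has the closed form `(p0 / kcat) (exp(kcat T) - 1)`. Used as an
#' analytic benchmark for the dynamic and balanced-growth solvers.
#'
#' @param kcat Turnover rate of the self-replication reaction (1/h).
#' @param p0 Initial enzyme amount (mmol).
#' @param nutrient_init Initial amount of the (nonlimiting) nutrient.
#' @return A [ram_model()].
#' @export
self_replicator_model <- function(kcat = 1, p0 = 1, nutrient_init = 10) {
  ram_model(
    species = tibble(
      id = c("Next", "M", "E"),
      type = c("extracellular", "metabolite", "enzyme"),
      molecular_weight = c(0, 0, 1),
      initial_amount = c(nutrient_init, 0, p0),
      boundary = c(TRUE, FALSE, FALSE)
    ),
    reactions = tibble(
      id = c("uptake", "synth_E"),
      stoichiometry = list(c(Next = -1, M = 1), c(M = -1, E = 1)),
      kcat_forward = c(0, kcat),
      gene_product = c(NA_character_, "E")
    ),
    gene_products = tibble(id = "E", label = "1*GE",
                           associated_species = "E"),
    id = "self_replicator"
  )
}
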