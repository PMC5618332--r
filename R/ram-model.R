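#' Resource-allocation model species types
#'
#' The five species classes of the RAM dialect. `extracellular` species live in
#' the environment (set Y), `metabolite` species are internal precursors kept
#' at quasi-steady state (set X), `storage` species accumulate reserves
#' (set C), and `enzyme` / `quota` species are the macromolecules (set P) that
#' carry the catalytic capacity and biomass-composition constraints.
#'
#' @export
RAM_SPECIES_TYPES <- c("extracellular", "metabolite", "storage", "enzyme", "quota")

ram_required_species_cols <- c(
  "id", "name", "compartment", "type", "boundary", "constant",
  "molecular_weight", "objective_weight", "biomass_percentage", "initial_amount"
)

ram_required_reaction_cols <- c(
  "id", "name", "reversible", "stoichiometry", "kcat_forward", "kcat_backward",
  "maintenance_scaling", "lower_bound", "upper_bound", "gene_product", "ec_number"
)

#' Construct a resource-allocation model
#'
#' Assembles a `ram_model` object from tidy tables of species, reactions, and
#' gene products. Missing optional columns are filled with defaults; the result
#' is validated against the structural invariants of the formalism (see
#' [validate_ram_model()]).
#'
#' @param species A data frame with one row per species. Required columns:
#'   `id`, `type` (one of `r paste(RAM_SPECIES_TYPES, collapse = ", ")`).
#'   Optional: `name` (defaults to `id`), `compartment` (defaults to
#'   `"external"` for extracellular species, `"cytosol"` otherwise),
#'   `boundary` (logical; nonlimiting extracellular species, default `FALSE`),
#'   `constant` (logical, defaults to `boundary`), `molecular_weight` (w, in
#'   g/mmol, default 0), `objective_weight` (b, g/mmol, defaults to
#'   `molecular_weight` for enzyme/quota species and 0 otherwise),
#'   `biomass_percentage` (the quota fraction phi, default 0), and
#'   `initial_amount` (mmol, default 0).
#' @param reactions A data frame with one row per reaction. Required columns:
#'   `id` and `stoichiometry`, a list column of named numeric vectors mapping
#'   species ids to signed coefficients (negative = consumed). Optional:
#'   `name`, `reversible` (default `FALSE`), `kcat_forward` and
#'   `kcat_backward` (1/h, default 0; irreversible reactions must have
#'   `kcat_backward = 0`), `maintenance_scaling` (psi, mmol/(g h), default 0),
#'   `lower_bound` / `upper_bound` (mmol/h; default `-Inf`/`Inf` for
#'   reversible reactions and `0`/`Inf` otherwise), `gene_product` (id of the
#'   catalyzing gene product, `NA` for spontaneous reactions), `ec_number`.
#' @param gene_products A data frame with columns `id`, `label` (free-text
#'   complex recipe, e.g. `"1*GTRANS2 AND 1*GTRANS3"`), and
#'   `associated_species` (id of the enzyme species whose amount bounds the
#'   catalyzed fluxes). May be `NULL` when no reaction is catalyzed.
#' @param id,name Model identifier and display name.
#' @param compartments Optional data frame with columns `id` and `size`
#'   (defaults to size 1 for every compartment mentioned by the species).
#' @param validate Check invariants and abort on violations (default `TRUE`).
#'
#' @return A `ram_model` object: a list with tibbles `species`, `reactions`,
#'   `gene_products`, `compartments`, and scalars `id`, `name`.
#'
#' @examples
#' m <- ram_model(
#'   species = tibble::tribble(
#'     ~id,  ~type,           ~molecular_weight, ~initial_amount, ~boundary,
#'     "S",  "extracellular", 0,                 10,              TRUE,
#'     "E",  "enzyme",        1,                 0.1,             FALSE
#'   ),
#'   reactions = tibble::tibble(
#'     id = "synth_E",
#'     stoichiometry = list(c(S = -1, E = 1)),
#'     kcat_forward = 2,
#'     gene_product = "E"
#'   ),
#'   gene_products = tibble::tibble(id = "E", label = "1*GE", associated_species = "E")
#' )
#' ram_species(m)
#' @export
ram_model <- function(species, reactions, gene_products = NULL,
                      id = "ram_model", name = id, compartments = NULL,
                      validate = TRUE) {
  species <- normalize_species(species)
  reactions <- normalize_reactions(reactions)
  gene_products <- normalize_gene_products(gene_products)

  if (is.null(compartments)) {
    compartments <- tibble(id = unique(species$compartment), size = 1)
  } else {
    compartments <- as_tibble(compartments)
    if (!"size" %in% names(compartments)) compartments$size <- 1
  }

  model <- structure(
    list(
      id = id, name = name,
      species = species, reactions = reactions,
      gene_products = gene_products, compartments = compartments
    ),
    class = "ram_model"
  )
  if (validate) validate_ram_model(model)
  model
}

normalize_species <- function(species) {
  species <- as_tibble(species)
  if (!all(c("id", "type") %in% names(species))) {
    abort("`species` must have columns `id` and `type`.")
  }
  n <- nrow(species)
  if (!"name" %in% names(species)) species$name <- species$id
  if (!"compartment" %in% names(species)) {
    species$compartment <- ifelse(species$type == "extracellular", "external", "cytosol")
  }
  if (!"boundary" %in% names(species)) species$boundary <- FALSE
  if (!"constant" %in% names(species)) species$constant <- species$boundary
  if (!"molecular_weight" %in% names(species)) species$molecular_weight <- 0
  if (!"objective_weight" %in% names(species)) {
    species$objective_weight <- ifelse(
      species$type %in% c("enzyme", "quota"), species$molecular_weight, 0
    )
  }
  if (!"biomass_percentage" %in% names(species)) species$biomass_percentage <- 0
  if (!"initial_amount" %in% names(species)) species$initial_amount <- 0
  if (!"annotation_extra" %in% names(species)) {
    species$annotation_extra <- vector("list", n)
  }
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]
  for (col in c("molecular_weight", "objective_weight", "biomass_percentage",
                "initial_amount")) {
    species[[col]] <- as.numeric(species[[col]])
    species[[col]][is.na(species[[col]])] <- 0
  }
  species$boundary[is.na(species$boundary)] <- FALSE
  species$constant[is.na(species$constant)] <- FALSE
  species[c(ram_required_species_cols, "annotation_extra")]
}

normalize_reactions <- function(reactions) {
  reactions <- as_tibble(reactions)
  if (!all(c("id", "stoichiometry") %in% names(reactions))) {
    abort("`reactions` must have columns `id` and `stoichiometry`.")
  }
  n <- nrow(reactions)
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  if (!"kcat_forward" %in% names(reactions)) reactions$kcat_forward <- 0
  if (!"kcat_backward" %in% names(reactions)) reactions$kcat_backward <- 0
  if (!"maintenance_scaling" %in% names(reactions)) reactions$maintenance_scaling <- 0
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- NA_real_
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- NA_real_
  if (!"gene_product" %in% names(reactions)) reactions$gene_product <- NA_character_
  if (!"ec_number" %in% names(reactions)) reactions$ec_number <- NA_character_
  if (!"annotation_extra" %in% names(reactions)) {
    reactions$annotation_extra <- vector("list", n)
  }
  reactions$reversible[is.na(reactions$reversible)] <- FALSE
  for (col in c("kcat_forward", "kcat_backward", "maintenance_scaling")) {
    reactions[[col]] <- as.numeric(reactions[[col]])
    reactions[[col]][is.na(reactions[[col]])] <- 0
  }
  reactions$lower_bound <- ifelse(
    is.na(reactions$lower_bound), ifelse(reactions$reversible, -Inf, 0),
    as.numeric(reactions$lower_bound)
  )
  reactions$upper_bound <- ifelse(
    is.na(reactions$upper_bound), Inf, as.numeric(reactions$upper_bound)
  )
  reactions$name[is.na(reactions$name)] <- reactions$id[is.na(reactions$name)]
  reactions$stoichiometry <- map(reactions$stoichiometry, function(s) {
    s <- unlist(s)
    storage.mode(s) <- "double"
    s[s != 0]
  })
  reactions[c(ram_required_reaction_cols, "annotation_extra")]
}

normalize_gene_products <- function(gene_products) {
  if (is.null(gene_products) || nrow(as_tibble(gene_products)) == 0) {
    return(tibble(
      id = character(), label = character(), associated_species = character()
    ))
  }
  gene_products <- as_tibble(gene_products)
  if (!"id" %in% names(gene_products)) {
    abort("`gene_products` must have a column `id`.")
  }
  if (!"label" %in% names(gene_products)) gene_products$label <- gene_products$id
  if (!"associated_species" %in% names(gene_products)) {
    gene_products$associated_species <- gene_products$id
  }
  gene_products[c("id", "label", "associated_species")]
}

#' Validate the structural invariants of a resource-allocation model
#'
#' Checks, among others: unique ids; known species types; stoichiometry keys
#' resolving to declared species; biomass percentages in \[0, 1\] and nonzero
#' only on quota species; nonnegative molecular and objective weights;
#' boundary flags only on extracellular species; irreversible reactions with
#' zero backward turnover rate; maintenance reactions (psi > 0) spontaneous;
#' and gene products pointing at declared enzyme species.
#'
#' @param model A [ram_model()].
#' @return Invisibly, `model`. Aborts with the full list of violations
#'   otherwise.
#' @export
validate_ram_model <- function(model) {
  problems <- ram_model_problems(model)
  if (length(problems) > 0) {
    abort(c("Invalid resource-allocation model:", problems))
  }
  invisible(model)
}

ram_model_problems <- function(model) {
  sp <- model$species
  rx <- model$reactions
  gp <- model$gene_products
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (anyDuplicated(sp$id)) {
    note(paste0("duplicated species ids: ",
                paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rx$id)) {
    note(paste0("duplicated reaction ids: ",
                paste(unique(rx$id[duplicated(rx$id)]), collapse = ", ")))
  }
  if (anyDuplicated(gp$id)) {
    note(paste0("duplicated gene product ids: ",
                paste(unique(gp$id[duplicated(gp$id)]), collapse = ", ")))
  }
  bad_type <- setdiff(unique(sp$type), RAM_SPECIES_TYPES)
  if (length(bad_type) > 0) {
    note(paste0("unknown species type(s): ", paste(bad_type, collapse = ", ")))
  }
  if (any(sp$molecular_weight < 0)) {
    note(paste0("negative molecular_weight for: ",
                paste(sp$id[sp$molecular_weight < 0], collapse = ", ")))
  }
  if (any(sp$objective_weight < 0)) {
    note(paste0("negative objective_weight for: ",
                paste(sp$id[sp$objective_weight < 0], collapse = ", ")))
  }
  bad_phi <- sp$biomass_percentage < 0 | sp$biomass_percentage > 1
  if (any(bad_phi)) {
    note(paste0("biomass_percentage outside [0, 1] for: ",
                paste(sp$id[bad_phi], collapse = ", ")))
  }
  phi_nonquota <- sp$biomass_percentage != 0 & sp$type != "quota"
  if (any(phi_nonquota)) {
    note(paste0("nonzero biomass_percentage on non-quota species: ",
                paste(sp$id[phi_nonquota], collapse = ", ")))
  }
  bad_boundary <- sp$boundary & sp$type != "extracellular"
  if (any(bad_boundary)) {
    note(paste0("boundary flag on non-extracellular species: ",
                paste(sp$id[bad_boundary], collapse = ", ")))
  }
  if (any(sp$initial_amount < 0)) {
    note(paste0("negative initial_amount for: ",
                paste(sp$id[sp$initial_amount < 0], collapse = ", ")))
  }

  for (i in seq_len(nrow(rx))) {
    unknown <- setdiff(names(rx$stoichiometry[[i]]), sp$id)
    if (length(unknown) > 0) {
      note(paste0("reaction ", rx$id[i], " references undeclared species: ",
                  paste(unknown, collapse = ", ")))
    }
  }
  irrev_back <- !rx$reversible & rx$kcat_backward != 0
  if (any(irrev_back)) {
    note(paste0("irreversible reaction with nonzero kcat_backward: ",
                paste(rx$id[irrev_back], collapse = ", ")))
  }
  if (any(rx$maintenance_scaling < 0)) {
    note(paste0("negative maintenance_scaling for: ",
                paste(rx$id[rx$maintenance_scaling < 0], collapse = ", ")))
  }
  maint_catalyzed <- rx$maintenance_scaling > 0 & !is.na(rx$gene_product)
  if (any(maint_catalyzed)) {
    note(paste0("maintenance reaction must be spontaneous (no gene product): ",
                paste(rx$id[maint_catalyzed], collapse = ", ")))
  }
  dangling_gp <- setdiff(rx$gene_product[!is.na(rx$gene_product)], gp$id)
  if (length(dangling_gp) > 0) {
    note(paste0("reactions reference undeclared gene products: ",
                paste(dangling_gp, collapse = ", ")))
  }
  if (nrow(gp) > 0) {
    enz_ids <- sp$id[sp$type == "enzyme"]
    bad_assoc <- !(gp$associated_species %in% enz_ids)
    if (any(bad_assoc)) {
      note(paste0("gene product associated_species is not a declared enzyme: ",
                  paste(gp$id[bad_assoc], collapse = ", ")))
    }
  }
  problems
}

#' @export
print.ram_model <- function(x, ...) {
  part <- tryCatch(partition_model(x), error = function(e) NULL)
  cat("<ram_model> ", x$id, "\n", sep = "")
  cat("  species:   ", nrow(x$species), sep = "")
  if (!is.null(part)) {
    cat("  (Y: ", length(part$Y), ", X: ", length(part$X),
        ", C: ", length(part$C), ", P: ", length(part$P), ")", sep = "")
  }
  cat("\n  reactions: ", nrow(x$reactions), sep = "")
  if (!is.null(part)) {
    cat("  (Ry: ", length(part$R_y), ", Rx: ", length(part$R_x),
        ", Rc: ", length(part$R_c), ", Rp: ", length(part$R_p), ")", sep = "")
  }
  cat("\n  gene products: ", nrow(x$gene_products), "\n", sep = "")
  invisible(x)
}

#' Access the component tables of a model
#'
#' @param model A [ram_model()].
#' @return A tibble (`ram_species()`: one row per species; `ram_reactions()`:
#'   one row per reaction; `ram_gene_products()`: one row per gene product).
#' @export
ram_species <- function(model) model$species

#' @rdname ram_species
#' @export
ram_reactions <- function(model) model$reactions

#' @rdname ram_species
#' @export
ram_gene_products <- function(model) model$gene_products

#' Map gene products to the reactions they catalyze
#'
#' Builds the catalysis map cat(P_i): for every enzyme species that is the
#' `associated_species` of some gene product, the set of reactions carrying
#' that gene product.
#'
#' @param model A [ram_model()].
#' @return A tibble with columns `enzyme` (species id), `reaction_id`.
#' @export
catalysis_map <- function(model) {
  rx <- model$reactions
  gp <- model$gene_products
  cat_tbl <- rx |>
    filter(!is.na(.data$gene_product)) |>
    select(reaction_id = "id", gene_product = "gene_product") |>
    left_join(
      gp |> select(gene_product = "id", enzyme = "associated_species"),
      by = "gene_product"
    )
  cat_tbl[c("enzyme", "reaction_id", "gene_product")]
}
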