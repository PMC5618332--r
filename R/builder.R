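AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE_LETTER <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

# nearest standard residue for the common ambiguity codes
AA_AMBIGUITY_MAP <- c(B = "D", Z = "E", X = "A", U = "C")

#' Count amino-acid residues in a protein sequence
#'
#' Tallies the 20 standard residues of a single-letter amino-acid sequence.
#' Trailing or embedded stop characters (`*`) are stripped. Ambiguity codes
#' (B, Z, X, U) are rejected by default; with `map_ambiguous = TRUE` they are
#' mapped to the nearest standard residue (B to D, Z to E, X to A, U to C).
#'
#' @param sequence A single amino-acid sequence string.
#' @param map_ambiguous Map ambiguity codes instead of failing.
#' @return A named integer vector of residue counts (only residues that
#'   occur), with attribute `length`, the total residue count l.
#' @examples
#' amino_acid_counts("MKM")
#' @export
amino_acid_counts <- function(sequence, map_ambiguous = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars <- chars[chars != "*"]
  if (map_ambiguous) {
    amb <- chars %in% names(AA_AMBIGUITY_MAP)
    chars[amb] <- AA_AMBIGUITY_MAP[chars[amb]]
  }
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0) {
    abort(paste0(
      "Illegal amino-acid character '", chars[bad[1]], "' at position ",
      bad[1], if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)"),
      "."
    ))
  }
  counts <- table(factor(chars, levels = AA_ALPHABET))
  counts <- setNames(as.integer(counts), AA_ALPHABET)
  counts <- counts[counts > 0]
  attr(counts, "length") <- length(chars)
  counts
}

#' Default residue-to-species map
#'
#' Maps the single-letter residue codes to three-letter metabolite ids
#' (Ala, Arg, ...). The builder accepts any such map so reactions can target
#' the namespace of the host reconstruction.
#'
#' @return A named character vector (residue letter to species id).
#' @export
default_residue_map <- function() AA_THREE_LETTER

#' Specify the polypeptide composition of an enzyme
#'
#' @param enzyme_id Identifier of the enzyme species to be produced.
#' @param subunits A data frame with columns `gene` (gene id), `sequence`
#'   (amino-acid sequence), and `copies` (integer copy number with which the
#'   gene product participates in the complex; 1 for monomers, 2 for dimers,
#'   ...). For the ribosome, rRNA components may be included as additional
#'   subunits whose "sequence" is a nucleotide string handled via a custom
#'   residue map.
#' @param compartments Compartment ids in which the enzyme acts (one for
#'   resident enzymes, two for transporters).
#' @return A `protein_spec` object.
#' @export
protein_spec <- function(enzyme_id, subunits, compartments = "cytosol") {
  subunits <- as_tibble(subunits)
  stopifnot(all(c("gene", "sequence") %in% names(subunits)))
  if (!"copies" %in% names(subunits)) subunits$copies <- 1L
  if (nrow(subunits) == 0) abort("`subunits` must contain at least one gene.")
  if (any(subunits$copies < 1 | subunits$copies != round(subunits$copies))) {
    abort("Subunit copy numbers must be integers >= 1.")
  }
  structure(
    list(enzyme_id = enzyme_id, subunits = subunits,
         compartments = compartments),
    class = "protein_spec"
  )
}

#' Translation energy accounting
#'
#' In `detailed` mode, each peptide bond costs one ATP hydrolyzed to AMP and
#' PPi (amino-acid activation) plus two GTP hydrolyzed to GDP and Pi
#' (ribosomal elongation). In `lumped` mode (recommended for small models
#' where GTP is not modeled separately), the energy requirement is merged
#' into a single ATP-to-ADP+Pi term of `atp_per_aa` per residue; the default
#' of 4 counts the 1 ATP + 2 GTP as 3 equivalents plus 1 for amino-acid
#' charging, and can be overridden.
#'
#' @param mode `"detailed"` or `"lumped"`.
#' @param atp_per_aa ATP equivalents per residue (lumped mode only).
#' @return An `energy_model` object.
#' @export
energy_model <- function(mode = c("detailed", "lumped"), atp_per_aa = 4) {
  mode <- match.arg(mode)
  stopifnot(atp_per_aa >= 0)
  structure(list(mode = mode, atp_per_aa = atp_per_aa), class = "energy_model")
}

#' Build the synthesis reaction for an enzyme or complex
#'
#' Residue counts of every subunit are multiplied by that subunit's copy
#' number and summed over subunits; the resulting amino acids are the
#' reactants, together with the energy cofactors scaled by the total residue
#' count; the product is one unit of the enzyme. The reaction id is prefixed
#' `synth_`.
#'
#' @param spec A [protein_spec()].
#' @param energy An [energy_model()].
#' @param residue_map Named map from residue letters to metabolite species
#'   ids; see [default_residue_map()].
#' @param map_ambiguous Passed to [amino_acid_counts()].
#' @return A one-row reaction tibble (same schema as
#'   `ram_reactions()`), with attribute `total_residues`, the copy-weighted
#'   residue count used for the energy terms and for the ribosome turnover
#'   rate.
#' @examples
#' sp <- protein_spec("E_toy", tibble::tibble(gene = "g1", sequence = "MKM", copies = 2))
#' protein_synthesis_reaction(sp, energy_model("detailed"))
#' @export
protein_synthesis_reaction <- function(spec, energy = energy_model("lumped"),
                                       residue_map = default_residue_map(),
                                       map_ambiguous = FALSE) {
  stopifnot(inherits(spec, "protein_spec"), inherits(energy, "energy_model"))
  counts <- setNames(numeric(length(AA_ALPHABET)), AA_ALPHABET)
  total <- 0
  for (i in seq_len(nrow(spec$subunits))) {
    cnt <- amino_acid_counts(spec$subunits$sequence[i], map_ambiguous)
    counts[names(cnt)] <- counts[names(cnt)] +
      as.numeric(cnt) * spec$subunits$copies[i]
    total <- total + attr(cnt, "length") * spec$subunits$copies[i]
  }
  counts <- counts[counts > 0]
  unmapped <- setdiff(names(counts), names(residue_map))
  if (length(unmapped) > 0) {
    abort(paste0("No species mapping for residue(s): ",
                 paste(unmapped, collapse = ", ")))
  }
  stoich <- setNames(-unname(counts), residue_map[names(counts)])
  if (energy$mode == "detailed") {
    stoich <- c(stoich, ATP = -total, GTP = -2 * total,
                AMP = total, PPi = total, GDP = 2 * total, Pi = 2 * total)
  } else if (energy$atp_per_aa > 0) {
    stoich <- c(stoich, ATP = -energy$atp_per_aa * total,
                ADP = energy$atp_per_aa * total, Pi = energy$atp_per_aa * total)
  }
  stoich <- c(stoich, setNames(1, spec$enzyme_id))
  out <- tibble(
    id = paste0("synth_", spec$enzyme_id),
    name = paste0("synthesis of ", spec$enzyme_id),
    reversible = FALSE,
    stoichiometry = list(stoich),
    kcat_forward = 0, kcat_backward = 0, maintenance_scaling = 0,
    lower_bound = 0, upper_bound = Inf,
    gene_product = NA_character_, ec_number = NA_character_
  )
  attr(out, "total_residues") <- total
  out
}

#' Ribosome turnover rate for translating one protein
#'
#' The ribosome acts as an enzyme whose rate for producing a given protein is
#' its elongation rate divided by the protein length: `kcat = a / l`,
#' converted to per-hour units.
#'
#' @param a Ribosome elongation rate in amino acids per second.
#' @param l Protein length in amino acids (copy-weighted total residue count
#'   for complexes).
#' @return Turnover rate in 1/h.
#' @examples
#' ribosome_kcat(15, 100) # 540 enzyme units per hour and ribosome unit
#' @export
ribosome_kcat <- function(a, l) {
  if (!is.numeric(a) || !is.numeric(l) || any(a <= 0) || any(l <= 0)) {
    abort("`a` and `l` must be positive.")
  }
  3600 * a / l
}

#' Turnover rate of a lumped quota-synthesis reaction
#'
#' The noncatalytic-protein quota reaction is catalyzed by the ribosome; its
#' rate follows the same elongation-rate formula with the sum of the
#' amino-acid stoichiometric coefficients of the (normalized) quota reaction
#' playing the role of the protein length. Because that sum is in mmol per
#' quota unit rather than a count, the resulting rate carries the
#' non-standard unit 1/(mmol h) rather than 1/h; the return value is tagged
#' accordingly.
#'
#' @param a Ribosome elongation rate in amino acids per second.
#' @param total_aa_coefficient Summed amino-acid coefficients of the quota
#'   reaction, mmol per quota unit.
#' @return The rate, with attribute `unit = "1/(mmol*h)"`.
#' @export
quota_reaction_kcat <- function(a, total_aa_coefficient) {
  if (any(a <= 0) || any(total_aa_coefficient <= 0)) {
    abort("`a` and `total_aa_coefficient` must be positive.")
  }
  structure(3600 * a / total_aa_coefficient, unit = "1/(mmol*h)")
}

#' Split reactions catalyzed by isoenzymes
#'
#' A reaction catalyzed by several alternative enzymes is replaced by one
#' identical copy per isoenzyme, each copy catalyzed by exactly one gene
#' product. This keeps every reaction bound by a single enzyme amount and
#' removes OR-associations from the model.
#'
#' @param model A [ram_model()].
#' @param mapping A named list: reaction id -> character vector of gene
#'   product ids (each must exist in the model, associated with an enzyme
#'   species).
#' @return A new `ram_model` with the listed reactions split. Copies are
#'   named `<reaction>_iso1`, `_iso2`, ...; single-enzyme entries leave the
#'   reaction unchanged apart from the gene product assignment.
#' @export
split_isoenzyme_reactions <- function(model, mapping) {
  rx <- model$reactions
  gp_ids <- model$gene_products$id
  unknown_rx <- setdiff(names(mapping), rx$id)
  if (length(unknown_rx) > 0) {
    abort(paste0("Unknown reaction id(s) in mapping: ",
                 paste(unknown_rx, collapse = ", ")))
  }
  unknown_gp <- setdiff(unlist(mapping), gp_ids)
  if (length(unknown_gp) > 0) {
    abort(paste0("Unknown gene product id(s) in mapping: ",
                 paste(unknown_gp, collapse = ", ")))
  }
  pieces <- map(seq_len(nrow(rx)), function(i) {
    row <- rx[i, ]
    enzymes <- mapping[[row$id]]
    if (is.null(enzymes)) return(row)
    if (length(enzymes) == 1) {
      row$gene_product <- enzymes
      return(row)
    }
    copies <- map(seq_along(enzymes), function(k) {
      cp <- row
      cp$id <- paste0(row$id, "_iso", k)
      cp$name <- paste0(row$name, " (", enzymes[k], ")")
      cp$gene_product <- enzymes[k]
      cp
    })
    bind_rows(copies)
  })
  model$reactions <- bind_rows(pieces)
  validate_ram_model(model)
  model
}

#' Compartment-resolved enzyme identifiers
#'
#' Enzymes acting in several compartments must be distinct species (a
#' cytosolic enzyme cannot catalyze a mitochondrial reaction), so ids combine
#' the main id with the acting compartment(s): `Main_id_[compartment]` for
#' resident enzymes and `Main_id_[compartment1]_[compartment2]` for
#' transporters.
#'
#' @param main_id Base enzyme identifier.
#' @param compartments Character vector of acting compartment ids.
#' @return A single identifier, deterministic in its inputs.
#' @examples
#' make_enzyme_id("FUM", "cytosol")
#' make_enzyme_id("ETrans2", c("e", "c"))
#' @export
make_enzyme_id <- function(main_id, compartments) {
  paste(c(main_id, compartments), collapse = "_")
}

#' Duplicate an enzyme specification per acting compartment
#'
#' @param spec A [protein_spec()] whose `compartments` field lists the
#'   compartments in which (copies of) the enzyme act independently.
#' @return A list of `protein_spec` objects, one per compartment, with ids
#'   from [make_enzyme_id()]. A single-compartment spec is returned as a
#'   one-element list with its id resolved the same way.
#' @export
duplicate_enzyme_per_compartment <- function(spec) {
  stopifnot(inherits(spec, "protein_spec"))
  map(spec$compartments, function(cmp) {
    protein_spec(
      enzyme_id = make_enzyme_id(spec$enzyme_id, cmp),
      subunits = spec$subunits,
      compartments = cmp
    )
  })
}
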