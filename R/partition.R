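#' Partition a model into the four species and reaction classes
#'
#' Species are classified by their RAM type: extracellular species form the
#' environment set Y, internal metabolites the quasi-steady-state set X,
#' storage compounds the set C, and enzymes plus quota compounds the
#' macromolecule set P. Reactions are classified deterministically from the
#' species types they touch: a reaction involving any extracellular species is
#' an exchange reaction (R_y); otherwise, if it produces any macromolecule it
#' is a biomass synthesis reaction (R_p); otherwise, if it involves storage it
#' is a storage reaction (R_c); all remaining reactions are internal metabolic
#' reactions (R_x). Maintenance reactions stay inside R_x and are recognized
#' only by their `maintenance_scaling > 0`.
#'
#' A reaction mixing incompatible classes (e.g. converting an extracellular
#' species directly into a macromolecule or storage compound) raises a
#' classification error naming the reaction.
#'
#' @param model A [ram_model()].
#' @return A list of character vectors `Y`, `X`, `C`, `P` (species ids, in
#'   model order) and `R_y`, `R_x`, `R_c`, `R_p` (reaction ids, in model
#'   order), of class `ram_partition`. Classes are pairwise disjoint and
#'   jointly exhaustive.
#' @examples
#' partition_model(toy_model())$P
#' @export
partition_model <- function(model) {
  sp <- model$species
  rx <- model$reactions
  type_of <- setNames(sp$type, sp$id)

  classify_reaction <- function(id, stoich) {
    types <- type_of[names(stoich)]
    has_ext <- any(types == "extracellular")
    has_macro <- any(types %in% c("enzyme", "quota"))
    has_storage <- any(types == "storage")
    if (has_ext) {
      if (has_macro || has_storage) {
        abort(paste0(
          "Reaction ", id, " mixes extracellular species with ",
          "macromolecules/storage; it cannot be classified."
        ))
      }
      return("R_y")
    }
    produces_macro <- any(types %in% c("enzyme", "quota") & stoich > 0)
    if (produces_macro) return("R_p")
    if (has_storage) return("R_c")
    "R_x"
  }

  rclass <- map_chr(seq_len(nrow(rx)), function(i) {
    classify_reaction(rx$id[i], rx$stoichiometry[[i]])
  })

  structure(
    list(
      Y = sp$id[sp$type == "extracellular"],
      X = sp$id[sp$type == "metabolite"],
      C = sp$id[sp$type == "storage"],
      P = sp$id[sp$type %in% c("enzyme", "quota")],
      R_y = rx$id[rclass == "R_y"],
      R_x = rx$id[rclass == "R_x"],
      R_c = rx$id[rclass == "R_c"],
      R_p = rx$id[rclass == "R_p"]
    ),
    class = "ram_partition"
  )
}

#' @export
print.ram_partition <- function(x, ...) {
  cat("<ram_partition>\n")
  for (nm in names(x)) {
    cat("  ", format(nm, width = 4), ": ", paste(x[[nm]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
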