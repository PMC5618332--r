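#' Stoichiometric matrix of a model
#'
#' @param model A [ram_model()].
#' @return A sparse `n x r` matrix (species by reactions, model order) of
#'   signed stoichiometric coefficients.
#' @export
stoichiometric_matrix <- function(model) {
  sp_id <- model$species$id
  rx <- model$reactions
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(rx))) {
    s <- rx$stoichiometry[[j]]
    if (length(s) == 0) next
    ii <- c(ii, match(names(s), sp_id))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(length(sp_id), nrow(rx)),
    dimnames = list(sp_id, rx$id)
  )
}

#' Direction-split flux columns
#'
#' Every reversible flux is represented internally by two nonnegative parts,
#' `v = v_plus - v_minus`, so that the capacity constraint can bound both
#' directions linearly: `v_plus / kcat_forward + v_minus / kcat_backward <=
#' enzyme amount`. Irreversible reactions keep a single forward column.
#'
#' @param model A [ram_model()].
#' @return A tibble with one row per split column: `col` (column index),
#'   `reaction_id`, `direction` (+1 forward, -1 backward), `sign` (the
#'   coefficient of the column in the net flux), `kcat` (the turnover rate of
#'   that direction). Forward columns come first, in reaction order, followed
#'   by the backward columns of reversible reactions.
#' @export
flux_columns <- function(model) {
  rx <- model$reactions
  fwd <- tibble(
    reaction_id = rx$id, direction = 1, sign = 1, kcat = rx$kcat_forward
  )
  bwd <- tibble(
    reaction_id = rx$id[rx$reversible], direction = -1, sign = -1,
    kcat = rx$kcat_backward[rx$reversible]
  )
  out <- bind_rows(fwd, bwd)
  out$col <- seq_len(nrow(out))
  out[c("col", "reaction_id", "direction", "sign", "kcat")]
}

# n_split x r mapping matrix D with v_net = D_net %*% v_split;
# here returned as r x n_split so that S_split = S %*% D.
split_map_matrix <- function(model) {
  fc <- flux_columns(model)
  r_ids <- model$reactions$id
  sparseMatrix(
    i = match(fc$reaction_id, r_ids), j = fc$col, x = fc$sign,
    dims = c(length(r_ids), nrow(fc)), dimnames = list(r_ids, NULL)
  )
}

#' Enzyme capacity matrices H_C and H_E
#'
#' Builds the linear form of the enzyme capacity constraint
#' `H_C v <= H_E p`: for every enzyme P_i with catalyzed reaction set
#' cat(P_i), the row reads `sum over Rj in cat(P_i) of v_Rj / kcat_Rj <=
#' p_i`, with reversible fluxes split into nonnegative forward and backward
#' parts so the row bounds both directions (see [flux_columns()]). `H_E` is a
#' filter matrix with exactly one entry 1 per row, selecting the catalyzing
#' enzyme's amount among the macromolecules P.
#'
#' @param model A [ram_model()].
#' @return A list with sparse matrices `HC` (rows x split flux columns) and
#'   `HE` (rows x |P|), the `enzymes` (row ids) and the `flux_columns` map.
#' @export
build_capacity_matrices <- function(model) {
  part <- partition_model(model)
  fc <- flux_columns(model)
  cat_tbl <- catalysis_map(model)
  rx <- model$reactions

  catalyzed <- rx$id[!is.na(rx$gene_product)]
  bad_fwd <- catalyzed[rx$kcat_forward[match(catalyzed, rx$id)] <= 0]
  if (length(bad_fwd) > 0) {
    abort(paste0("Catalyzed reaction(s) with nonpositive kcat_forward: ",
                 paste(bad_fwd, collapse = ", ")))
  }
  rev_cat <- catalyzed[rx$reversible[match(catalyzed, rx$id)]]
  bad_bwd <- rev_cat[rx$kcat_backward[match(rev_cat, rx$id)] <= 0]
  if (length(bad_bwd) > 0) {
    abort(paste0("Reversible catalyzed reaction(s) with nonpositive ",
                 "kcat_backward: ", paste(bad_bwd, collapse = ", ")))
  }

  enzymes <- part$P[part$P %in% cat_tbl$enzyme]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(enzymes)) {
    rxs <- cat_tbl$reaction_id[cat_tbl$enzyme == enzymes[k]]
    cols <- fc[fc$reaction_id %in% rxs, ]
    ii <- c(ii, rep.int(k, nrow(cols)))
    jj <- c(jj, cols$col)
    xx <- c(xx, 1 / cols$kcat)
  }
  HC <- sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(length(enzymes), nrow(fc)),
    dimnames = list(enzymes, NULL)
  )
  HE <- sparseMatrix(
    i = seq_along(enzymes), j = match(enzymes, part$P), x = 1,
    dims = c(length(enzymes), length(part$P)),
    dimnames = list(enzymes, part$P)
  )
  list(HC = HC, HE = HE, enzymes = enzymes, flux_columns = fc)
}

# b over P and w over C, the weight vectors entering B_o and B_t
biomass_weights <- function(model) {
  part <- partition_model(model)
  sp <- model$species
  list(
    part = part,
    w_C = setNames(sp$molecular_weight[match(part$C, sp$id)], part$C),
    b_P = setNames(sp$objective_weight[match(part$P, sp$id)], part$P),
    w_P = setNames(sp$molecular_weight[match(part$P, sp$id)], part$P)
  )
}

#' Biomass composition (quota) matrix H_B
#'
#' For every quota species s with fraction phi_s, the biomass composition
#' constraint demands `w_s p_s >= phi_s B_t`, i.e. the quota compound must
#' make up at least the fraction phi_s of the total biomass
#' `B_t = b_P' p + w_C' c`. In matrix form this is `H_B [c; p] <= 0`, with
#' one row per quota species over the stacked storage and macromolecule
#' amounts.
#'
#' @param model A [ram_model()]. Quota species must have a positive molecular
#'   weight.
#' @return A sparse `|quota| x (|C| + |P|)` matrix with rownames the quota
#'   species ids and colnames `c(C, P)`.
#' @export
build_biomass_composition_matrix <- function(model) {
  bw <- biomass_weights(model)
  part <- bw$part
  sp <- model$species
  quota <- sp$id[sp$type == "quota"]
  bad_w <- quota[sp$molecular_weight[match(quota, sp$id)] == 0]
  if (length(bad_w) > 0) {
    abort(paste0("Quota species with zero molecular weight: ",
                 paste(bad_w, collapse = ", ")))
  }
  cols <- c(part$C, part$P)
  HB <- matrix(0, nrow = length(quota), ncol = length(cols),
               dimnames = list(quota, cols))
  for (s in quota) {
    phi <- sp$biomass_percentage[match(s, sp$id)]
    HB[s, ] <- phi * c(bw$w_C, bw$b_P)
    HB[s, s] <- HB[s, s] - sp$molecular_weight[match(s, sp$id)]
  }
  Matrix(HB, sparse = TRUE)
}

#' Maintenance matrix H_M
#'
#' Maintenance reactions (those with `maintenance_scaling` psi > 0) carry a
#' biomass-proportional flux floor `v_m >= psi_m B_t`. In matrix form,
#' `v >= H_M [c; p]` restricted to the maintenance rows: one row per
#' maintenance reaction with entries `psi_m * w` over storage and
#' `psi_m * b` over macromolecules.
#'
#' @param model A [ram_model()].
#' @return A list with the sparse matrix `HM` (|maintenance| x (|C| + |P|),
#'   rownames the reaction ids) and `reactions`, the affected reaction ids.
#' @export
build_maintenance_matrix <- function(model) {
  bw <- biomass_weights(model)
  part <- bw$part
  rx <- model$reactions
  maint <- rx$id[rx$maintenance_scaling > 0]
  cols <- c(part$C, part$P)
  HM <- matrix(0, nrow = length(maint), ncol = length(cols),
               dimnames = list(maint, cols))
  for (m in maint) {
    psi <- rx$maintenance_scaling[match(m, rx$id)]
    HM[m, ] <- psi * c(bw$w_C, bw$b_P)
  }
  list(HM = Matrix(HM, sparse = TRUE), reactions = maint)
}

#' Objective and total biomass
#'
#' The objective biomass is the b-weighted mass of the macromolecules,
#' `B_o = b_P' p`; the total biomass additionally counts the w-weighted
#' storage, `B_t = B_o + w_C' c`. Storage is part of the total biomass (it
#' scales quota and maintenance constraints) but not of the optimization
#' objective.
#'
#' @param model A [ram_model()].
#' @param p Macromolecule amounts (mmol): a vector over the P species, either
#'   named or in partition order.
#' @param c_amounts Storage amounts (mmol) over the C species.
#' @return Biomass in grams.
#' @export
objective_biomass <- function(model, p) {
  bw <- biomass_weights(model)
  p <- resolve_amounts(p, bw$part$P, "p")
  sum(bw$b_P * p)
}

#' @rdname objective_biomass
#' @export
total_biomass <- function(model, c_amounts, p) {
  bw <- biomass_weights(model)
  c_amounts <- resolve_amounts(c_amounts, bw$part$C, "c_amounts")
  objective_biomass(model, p) + sum(bw$w_C * c_amounts)
}

resolve_amounts <- function(x, ids, what) {
  if (length(ids) == 0 && length(x) == 0) return(numeric(0))
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing) > 0) {
      abort(paste0("`", what, "` is missing amounts for: ",
                   paste(missing, collapse = ", ")))
    }
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    abort(paste0("`", what, "` must have length ", length(ids),
                 " (one per species), got ", length(x), "."))
  }
  if (any(x < 0)) abort(paste0("`", what, "` contains negative amounts."))
  unname(x)
}
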