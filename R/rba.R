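#' Balanced-growth (RBA) initializer
#'
#' Finds the maximal growth rate mu at which balanced exponential growth is
#' feasible, together with a consistent cell composition. At a fixed mu the
#' problem is a feasibility LP over fluxes v (direction-split), storage
#' amounts c, and macromolecule amounts p:
#' quasi-steady-state metabolite balances `S_X v = 0`; balanced production
#' `S_P v = mu p` and `S_C v = mu c`; the enzyme capacity, biomass
#' composition, and maintenance constraints; flux box bounds; and the
#' normalization `B_t = b_P' p + w_C' c = 1` g. The largest feasible mu in
#' the bracket is located by bisection. Uptake of external nutrients that
#' are absent from the environment (`y0` entry 0 for a non-boundary
#' species) is blocked.
#'
#' The returned composition is the feasibility point at `mu_max`, linearly
#' rescaled so that the total biomass equals `biomass` grams.
#'
#' @param model A [ram_model()].
#' @param y0 Named vector of available external amounts (mmol); defaults to
#'   the model's initial amounts. Only the zero/nonzero pattern matters.
#' @param mu_bracket Numeric `c(lo, hi)` bracket for mu (1/h). Default
#'   `c(0, max kcat over catalyzed reactions)`, since no enzyme-limited
#'   model can replicate its catalysts faster than its fastest catalyst.
#' @param tolerance Absolute bisection tolerance in mu (1/h).
#' @param biomass Total biomass (g) to which the returned amounts are
#'   scaled.
#' @return A `ram_rba` object with elements `mu_max` (1/h), `c0` and `p0`
#'   (named amount vectors, mmol), `fluxes` (named net fluxes at the
#'   returned composition, mmol/h), and `tolerance`.
#' @examples
#' \dontrun{
#' fit <- solve_rba_initial(toy_model())
#' glance(fit)
#' }
#' @export
solve_rba_initial <- function(model, y0 = NULL, mu_bracket = NULL,
                              tolerance = 1e-6, biomass = 1) {
  part <- partition_model(model)
  sp <- model$species
  rx <- model$reactions
  if (is.null(y0)) {
    y0 <- setNames(sp$initial_amount[match(part$Y, sp$id)], part$Y)
  } else {
    y0 <- setNames(resolve_amounts(y0, part$Y, "y0"), part$Y)
  }
  fc <- flux_columns(model)
  S <- stoichiometric_matrix(model)
  D <- split_map_matrix(model)
  S_split <- S %*% D
  cap <- build_capacity_matrices(model)
  HB <- build_biomass_composition_matrix(model)
  maint <- build_maintenance_matrix(model)

  nf <- nrow(fc); nC <- length(part$C); nP <- length(part$P)
  n_var <- nf + nC + nP
  c_col <- nf + seq_len(nC)
  p_col <- nf + nC + seq_len(nP)
  cp_col <- c(c_col, p_col)
  b_P <- sp$objective_weight[match(part$P, sp$id)]
  w_C <- sp$molecular_weight[match(part$C, sp$id)]

  # flux upper bounds per split column: box bounds plus environment blocking
  ub_var <- rep(Inf, n_var)
  boundary <- sp$id[sp$boundary]
  absent <- names(y0)[y0 == 0 & !(names(y0) %in% boundary)]
  if (length(absent) > 0) {
    for (j in seq_len(nf)) {
      srow <- S[absent, fc$reaction_id[j], drop = FALSE] * fc$sign[j]
      if (any(as.numeric(srow) < 0)) ub_var[j] <- 0
    }
  }

  # mu-independent pieces
  Sx <- S_split[match(part$X, rownames(S)), , drop = FALSE]
  Sc <- S_split[match(part$C, rownames(S)), , drop = FALSE]
  Sp <- S_split[match(part$P, rownames(S)), , drop = FALSE]

  feas_lp <- function(mu) {
    eq <- triplet_builder(); ub <- triplet_builder()
    for (xi in seq_along(part$X)) {
      nz <- which(Sx[xi, ] != 0)
      eq$add_row(nz, Sx[xi, nz], 0, paste0("qssa[", part$X[xi], "]"))
    }
    for (ci in seq_along(part$C)) {
      nz <- which(Sc[ci, ] != 0)
      eq$add_row(c(nz, c_col[ci]), c(Sc[ci, nz], -mu), 0,
                 paste0("bal[", part$C[ci], "]"))
    }
    for (pi in seq_along(part$P)) {
      nz <- which(Sp[pi, ] != 0)
      eq$add_row(c(nz, p_col[pi]), c(Sp[pi, nz], -mu), 0,
                 paste0("bal[", part$P[pi], "]"))
    }
    eq$add_row(cp_col, c(w_C, b_P), 1, "biomass_norm")
    for (e in seq_along(cap$enzymes)) {
      hrow <- cap$HC[e, ]
      nz <- which(hrow != 0)
      ub$add_row(c(nz, p_col[match(cap$enzymes[e], part$P)]),
                 c(hrow[nz], -1), 0, paste0("cap[", cap$enzymes[e], "]"))
    }
    if (nrow(HB) > 0) {
      for (q in seq_len(nrow(HB))) {
        hrow <- HB[q, ]
        nz <- which(hrow != 0)
        ub$add_row(cp_col[nz], hrow[nz], 0,
                   paste0("quota[", rownames(HB)[q], "]"))
      }
    }
    for (m in seq_along(maint$reactions)) {
      rid <- maint$reactions[m]
      cols <- fc$col[fc$reaction_id == rid]
      signs <- fc$sign[fc$reaction_id == rid]
      hrow <- maint$HM[m, ]
      nz <- which(hrow != 0)
      ub$add_row(c(cp_col[nz], cols), c(hrow[nz], -signs), 0,
                 paste0("maint[", rid, "]"))
    }
    for (j in seq_len(nrow(rx))) {
      cols <- fc$col[fc$reaction_id == rx$id[j]]
      signs <- fc$sign[fc$reaction_id == rx$id[j]]
      if (is.finite(rx$upper_bound[j])) {
        ub$add_row(cols, signs, rx$upper_bound[j],
                   paste0("vmax[", rx$id[j], "]"))
      }
      if (is.finite(rx$lower_bound[j]) &&
          (rx$lower_bound[j] != 0 || rx$reversible[j])) {
        ub$add_row(cols, -signs, -rx$lower_bound[j],
                   paste0("vmin[", rx$id[j], "]"))
      }
    }
    lp_solve(
      numeric(n_var), A_ub = ub$matrix(n_var), b_ub = ub$rhs(),
      A_eq = eq$matrix(n_var), b_eq = eq$rhs(),
      lb = 0, ub = ub_var
    )
  }

  if (is.null(mu_bracket)) {
    kcats <- c(rx$kcat_forward[!is.na(rx$gene_product)],
               rx$kcat_backward[!is.na(rx$gene_product) & rx$reversible])
    hi <- if (length(kcats) > 0) max(kcats) else 1
    mu_bracket <- c(0, hi)
  }
  lo <- mu_bracket[1]; hi <- mu_bracket[2]

  res_lo <- feas_lp(lo)
  if (!identical(res_lo$status, "optimal")) {
    abort(paste0(
      "Balanced growth infeasible even at mu = ", lo,
      "; the model cannot sustain itself (check quota and maintenance ",
      "parameters)."
    ))
  }
  best <- list(mu = lo, x = res_lo$x)
  res_hi <- feas_lp(hi)
  if (identical(res_hi$status, "optimal")) {
    best <- list(mu = hi, x = res_hi$x)
  } else {
    while (hi - best$mu > tolerance) {
      mid <- (best$mu + hi) / 2
      res <- feas_lp(mid)
      if (identical(res$status, "optimal")) {
        best <- list(mu = mid, x = res$x)
      } else {
        hi <- mid
      }
    }
  }

  x <- best$x * biomass
  v_split <- x[seq_len(nf)]
  net <- map_dbl(rx$id, function(rid) {
    sum(fc$sign[fc$reaction_id == rid] * v_split[fc$col[fc$reaction_id == rid]])
  })
  structure(
    list(
      mu_max = best$mu,
      c0 = setNames(x[c_col], part$C),
      p0 = setNames(x[p_col], part$P),
      fluxes = setNames(net, rx$id),
      biomass = biomass, tolerance = tolerance, model_id = model$id
    ),
    class = "ram_rba"
  )
}

#' @export
print.ram_rba <- function(x, ...) {
  cat("<ram_rba> mu_max = ", format(x$mu_max), " 1/h (tolerance ",
      format(x$tolerance), ")\n", sep = "")
  cat("  composition scaled to B_t = ", x$biomass, " g\n", sep = "")
  invisible(x)
}
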