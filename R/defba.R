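#' Discretization settings for the deFBA dynamic optimization
#'
#' The dynamic problem is discretized on a uniform time grid by collocation:
#' amounts live on the nodes, fluxes are piecewise constant on the
#' intervals. Under `implicit_euler` (default) the capacity, quota, and
#' maintenance constraints are enforced at the right node of each interval
#' and the objective uses right-endpoint quadrature; under `trapezoid` they
#' are enforced at both interval endpoints and the objective uses the
#' trapezoidal rule (exact for the piecewise-linear amounts).
#'
#' @param t_end Simulation end time T_end in hours (> 0).
#' @param n_steps Number of intervals (>= 1).
#' @param scheme `"implicit_euler"` or `"trapezoid"`.
#' @param lp_tolerance Residual tolerance used when checking the returned
#'   trajectory against the continuous constraints.
#' @return A `defba_config` object.
#' @export
defba_config <- function(t_end, n_steps, scheme = c("implicit_euler", "trapezoid"),
                         lp_tolerance = 1e-8) {
  scheme <- match.arg(scheme)
  if (!is.numeric(t_end) || t_end <= 0) abort("`t_end` must be positive.")
  if (!is.numeric(n_steps) || n_steps < 1 || n_steps != round(n_steps)) {
    abort("`n_steps` must be a positive integer.")
  }
  structure(
    list(t_end = t_end, n_steps = as.integer(n_steps), scheme = scheme,
         lp_tolerance = lp_tolerance),
    class = "defba_config"
  )
}

#' Initial amounts for a deFBA simulation
#'
#' Internal metabolites are at quasi-steady state and need no initial value;
#' the scenario fixes the initial amounts of the external species (y0),
#' storage (c0), and macromolecules (p0). Defaults are taken from the
#' model's `initial_amount` column. A good way to obtain c0 and p0 adapted
#' to a preculture medium is [solve_rba_initial()].
#'
#' @param model A [ram_model()].
#' @param y0,c0,p0 Optional named (or partition-ordered) nonnegative amount
#'   vectors in mmol.
#' @return A `defba_scenario` object with named vectors `y0`, `c0`, `p0`.
#' @export
defba_scenario <- function(model, y0 = NULL, c0 = NULL, p0 = NULL) {
  part <- partition_model(model)
  sp <- model$species
  default <- function(ids) setNames(sp$initial_amount[match(ids, sp$id)], ids)
  pick <- function(x, ids, what) {
    if (is.null(x)) return(default(ids))
    setNames(resolve_amounts(x, ids, what), ids)
  }
  structure(
    list(
      y0 = pick(y0, part$Y, "y0"),
      c0 = pick(c0, part$C, "c0"),
      p0 = pick(p0, part$P, "p0")
    ),
    class = "defba_scenario"
  )
}

# Shared index bookkeeping for the collocation LP.
defba_layout <- function(model, config) {
  part <- partition_model(model)
  fc <- flux_columns(model)
  dyn <- c(part$Y, part$C, part$P)
  nd <- length(dyn)
  nf <- nrow(fc)
  N <- config$n_steps
  list(
    part = part, fc = fc, dyn = dyn, nd = nd, nf = nf, N = N,
    dt = config$t_end / N,
    amount_col = function(sp_idx, node) node * nd + sp_idx,
    flux_col = function(fc_idx, interval) {
      nd * (N + 1) + (interval - 1) * nf + fc_idx
    },
    n_var = nd * (N + 1) + nf * N
  )
}

#' Cast the deFBA problem into a linear program
#'
#' Discretizes the dynamic optimization (biomass-integral objective; species
#' dynamics; quasi-steady-state metabolite balances; flux box bounds; enzyme
#' capacity; biomass composition; maintenance floors; initial values;
#' nonnegativity) into one LP over node amounts and interval fluxes, with
#' reversible fluxes split into nonnegative direction parts. Nonlimiting
#' (boundary) extracellular species are held constant instead of following
#' the reaction dynamics.
#'
#' @inheritParams defba_scenario
#' @param scenario A [defba_scenario()].
#' @param config A [defba_config()].
#' @return A `ram_lp` object: objective vector, sparse constraint matrices
#'   with symbolic row names, bounds, and a `var_info` tibble describing
#'   every variable (kind, species or reaction, node or interval).
#' @export
discretize_to_lp <- function(model, scenario, config) {
  stopifnot(inherits(config, "defba_config"))
  if (!inherits(scenario, "defba_scenario")) {
    abort("`scenario` must be a defba_scenario().")
  }
  lay <- defba_layout(model, config)
  part <- lay$part; fc <- lay$fc; N <- lay$N; dt <- lay$dt
  sp <- model$species
  S <- stoichiometric_matrix(model)
  D <- split_map_matrix(model)
  S_split <- S %*% D
  cap <- build_capacity_matrices(model)
  HB <- build_biomass_composition_matrix(model)
  maint <- build_maintenance_matrix(model)
  boundary_ids <- sp$id[sp$boundary]

  dyn_idx <- match(lay$dyn, rownames(S))
  x_idx <- match(part$X, rownames(S))
  c_pos <- match(part$C, lay$dyn)
  p_pos <- match(part$P, lay$dyn)
  cp_pos <- c(c_pos, p_pos) # [c; p] ordering used by HB/HM

  eq <- triplet_builder(); ub <- triplet_builder()

  # (19) initial values at node 0
  init <- c(scenario$y0, scenario$c0, scenario$p0)
  for (i in seq_len(lay$nd)) {
    eq$add_row(lay$amount_col(i, 0), 1, init[[i]],
               paste0("init[", lay$dyn[i], "]"))
  }

  # (13)/(14) dynamics and QSSA, interval by interval
  Sd <- S_split[dyn_idx, , drop = FALSE]
  Sx <- S_split[x_idx, , drop = FALSE]
  for (k in seq_len(N)) {
    vcols <- lay$flux_col(seq_len(lay$nf), k)
    for (i in seq_len(lay$nd)) {
      if (lay$dyn[i] %in% boundary_ids) {
        eq$add_row(
          c(lay$amount_col(i, k), lay$amount_col(i, k - 1)), c(1, -1), 0,
          paste0("const[", lay$dyn[i], ",k", k, "]")
        )
      } else {
        srow <- Sd[i, ]
        nz <- which(srow != 0)
        eq$add_row(
          c(lay$amount_col(i, k), lay$amount_col(i, k - 1), vcols[nz]),
          c(1, -1, -dt * srow[nz]), 0,
          paste0("dyn[", lay$dyn[i], ",k", k, "]")
        )
      }
    }
    for (xi in seq_along(part$X)) {
      srow <- Sx[xi, ]
      nz <- which(srow != 0)
      eq$add_row(vcols[nz], srow[nz], 0,
                 paste0("qssa[", part$X[xi], ",k", k, "]"))
    }
  }

  cap_nodes <- function(k) {
    if (config$scheme == "trapezoid") c(k - 1, k) else k
  }

  for (k in seq_len(N)) {
    vcols <- lay$flux_col(seq_len(lay$nf), k)
    for (node in cap_nodes(k)) {
      # (16) capacity: HC v_k - HE p_node <= 0
      for (e in seq_along(cap$enzymes)) {
        hrow <- cap$HC[e, ]
        nz <- which(hrow != 0)
        pcol <- lay$amount_col(p_pos[match(cap$enzymes[e], part$P)], node)
        ub$add_row(c(vcols[nz], pcol), c(hrow[nz], -1), 0,
                   paste0("cap[", cap$enzymes[e], ",k", k, ",t", node, "]"))
      }
      # (18) maintenance: HM [c;p]_node - v_m,k <= 0
      for (m in seq_along(maint$reactions)) {
        rid <- maint$reactions[m]
        mcols <- fc$col[fc$reaction_id == rid]
        msigns <- fc$sign[fc$reaction_id == rid]
        hrow <- maint$HM[m, ]
        nz <- which(hrow != 0)
        ub$add_row(
          c(lay$amount_col(cp_pos[nz], node), vcols[mcols]),
          c(hrow[nz], -msigns), 0,
          paste0("maint[", rid, ",k", k, ",t", node, "]")
        )
      }
    }
    # (15) box bounds on net fluxes
    rx <- model$reactions
    for (j in seq_len(nrow(rx))) {
      jcols <- fc$col[fc$reaction_id == rx$id[j]]
      jsigns <- fc$sign[fc$reaction_id == rx$id[j]]
      if (is.finite(rx$upper_bound[j])) {
        ub$add_row(vcols[jcols], jsigns, rx$upper_bound[j],
                   paste0("vmax[", rx$id[j], ",k", k, "]"))
      }
      if (is.finite(rx$lower_bound[j]) &&
          (rx$lower_bound[j] != 0 || rx$reversible[j])) {
        ub$add_row(vcols[jcols], -jsigns, -rx$lower_bound[j],
                   paste0("vmin[", rx$id[j], ",k", k, "]"))
      }
    }
  }

  # (17) quota at every node
  quota_ids <- rownames(HB)
  for (node in 0:N) {
    for (q in seq_along(quota_ids)) {
      hrow <- HB[q, ]
      nz <- which(hrow != 0)
      ub$add_row(lay$amount_col(cp_pos[nz], node), hrow[nz], 0,
                 paste0("quota[", quota_ids[q], ",t", node, "]"))
    }
  }

  # (12) objective: quadrature of B_o(t) = b_P' p(t)
  b_P <- sp$objective_weight[match(part$P, sp$id)]
  objective <- numeric(lay$n_var)
  node_weight <- function(node) {
    if (config$scheme == "trapezoid") {
      if (node == 0 || node == N) dt / 2 else dt
    } else {
      if (node == 0) 0 else dt
    }
  }
  for (node in 0:N) {
    w <- node_weight(node)
    if (w == 0) next
    objective[lay$amount_col(p_pos, node)] <-
      objective[lay$amount_col(p_pos, node)] + w * b_P
  }

  var_info <- bind_rows(
    tidyr::expand_grid(node = 0:N, species = lay$dyn) |>
      mutate(kind = "amount", col = lay$amount_col(
        match(.data$species, lay$dyn), .data$node
      )),
    tidyr::expand_grid(interval = seq_len(N), fc_idx = seq_len(lay$nf)) |>
      mutate(
        kind = "flux",
        reaction = fc$reaction_id[.data$fc_idx],
        direction = fc$direction[.data$fc_idx],
        col = lay$flux_col(.data$fc_idx, .data$interval)
      )
  ) |> arrange(.data$col)

  structure(
    list(
      objective = objective, maximize = TRUE,
      A_ub = ub$matrix(lay$n_var), b_ub = ub$rhs(), row_names_ub = ub$names(),
      A_eq = eq$matrix(lay$n_var), b_eq = eq$rhs(), row_names_eq = eq$names(),
      lb = rep(0, lay$n_var), ub = rep(Inf, lay$n_var),
      var_info = var_info, layout = lay,
      model = model, scenario = scenario, config = config
    ),
    class = "ram_lp"
  )
}

triplet_builder <- function() {
  ii <- list(); jj <- list(); xx <- list(); bb <- list(); nm <- list()
  row <- 0L
  list(
    add_row = function(cols, vals, rhs, name) {
      row <<- row + 1L
      ii[[row]] <<- rep.int(row, length(cols))
      jj[[row]] <<- cols
      xx[[row]] <<- vals
      bb[[row]] <<- rhs
      nm[[row]] <<- name
    },
    matrix = function(ncol) {
      if (row == 0L) return(NULL)
      sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                   dims = c(row, ncol))
    },
    rhs = function() if (row == 0L) NULL else unlist(bb),
    names = function() if (row == 0L) character(0) else unlist(nm)
  )
}

#' @export
print.ram_lp <- function(x, ...) {
  cat("<ram_lp> ", length(x$objective), " variables, ",
      NROW(x$A_eq), " equalities, ", NROW(x$A_ub), " inequalities\n",
      sep = "")
  invisible(x)
}

#' Solve the deFBA dynamic optimization
#'
#' Discretizes the problem via [discretize_to_lp()], solves the LP, and
#' reassembles the solution into a trajectory: amounts at the grid nodes,
#' piecewise-constant fluxes on the intervals, the biomass integral
#' objective, and residuals of all constraint families. Infeasible or
#' unbounded problems are surfaced through the `status` field, never
#' clamped.
#'
#' @inheritParams discretize_to_lp
#' @param scenario A [defba_scenario()]; defaults to the model's initial
#'   amounts.
#' @return A `ram_trajectory` object; see [tidy.ram_trajectory()],
#'   [glance.ram_trajectory()], [autoplot.ram_trajectory()],
#'   [instantaneous_growth_rate()], [defba_residuals()].
#' @examples
#' \dontrun{
#' traj <- solve_defba(toy_model(), config = defba_config(1, 20))
#' glance(traj)
#' }
#' @export
solve_defba <- function(model, scenario = defba_scenario(model), config) {
  lp <- discretize_to_lp(model, scenario, config)
  res <- lp_solve(
    lp$objective, A_ub = lp$A_ub, b_ub = lp$b_ub,
    A_eq = lp$A_eq, b_eq = lp$b_eq, lb = lp$lb, ub = lp$ub, maximize = TRUE
  )
  lay <- lp$layout
  times <- seq(0, config$t_end, length.out = lay$N + 1)
  out <- structure(
    list(
      status = res$status, objective = res$objective,
      times = times, model = model, scenario = scenario, config = config
    ),
    class = "ram_trajectory"
  )
  if (!identical(res$status, "optimal")) return(out)

  x <- res$x
  amounts <- matrix(
    x[seq_len(lay$nd * (lay$N + 1))],
    nrow = lay$N + 1, ncol = lay$nd, byrow = TRUE,
    dimnames = list(NULL, lay$dyn)
  )
  vsplit <- matrix(
    x[lay$nd * (lay$N + 1) + seq_len(lay$nf * lay$N)],
    nrow = lay$N, ncol = lay$nf, byrow = TRUE
  )
  fc <- lay$fc
  net <- vsplit %*% sparseMatrix(
    i = fc$col, j = match(fc$reaction_id, model$reactions$id), x = fc$sign,
    dims = c(lay$nf, nrow(model$reactions))
  )
  fluxes <- tidyr::expand_grid(
    interval = seq_len(lay$N), reaction = model$reactions$id
  ) |>
    mutate(
      t_start = times[.data$interval], t_end = times[.data$interval + 1],
      flux = as.numeric(Matrix::t(net))[
        (interval - 1) * nrow(model$reactions) +
          match(.data$reaction, model$reactions$id)
      ]
    )

  part <- lay$part
  sp <- model$species
  b_P <- sp$objective_weight[match(part$P, sp$id)]
  w_C <- sp$molecular_weight[match(part$C, sp$id)]
  p_mat <- amounts[, part$P, drop = FALSE]
  c_mat <- amounts[, part$C, drop = FALSE]
  biomass <- tibble(
    time = times,
    B_o = as.numeric(p_mat %*% b_P),
    B_t = as.numeric(p_mat %*% b_P) + as.numeric(c_mat %*% w_C)
  )

  out$amounts <- amounts
  out$flux_split <- vsplit
  out$fluxes <- fluxes
  out$biomass <- biomass
  out$residuals <- trajectory_residuals(model, lay, amounts, vsplit,
                                        lp, config)
  out
}

trajectory_residuals <- function(model, lay, amounts, vsplit, lp, config) {
  part <- lay$part
  S <- stoichiometric_matrix(model)
  D <- split_map_matrix(model)
  S_split <- S %*% D
  cap <- build_capacity_matrices(model)
  HB <- build_biomass_composition_matrix(model)
  maint <- build_maintenance_matrix(model)
  sp <- model$species
  dt <- lay$dt
  N <- lay$N
  boundary <- lay$dyn %in% sp$id[sp$boundary]

  qssa <- 0; dyn <- 0; capr <- -Inf; quota <- -Inf; maintr <- -Inf
  Sx <- S_split[match(part$X, rownames(S)), , drop = FALSE]
  Sd <- S_split[match(lay$dyn, rownames(S)), , drop = FALSE]
  cp_cols <- c(part$C, part$P)
  for (k in seq_len(N)) {
    v <- vsplit[k, ]
    if (length(part$X) > 0) qssa <- max(qssa, max(abs(Sx %*% v)))
    step <- amounts[k + 1, ] - amounts[k, ]
    pred <- dt * as.numeric(Sd %*% v)
    pred[boundary] <- 0
    dyn <- max(dyn, max(abs(step - pred)))
    nodes <- if (config$scheme == "trapezoid") c(k, k + 1) else k + 1
    for (nd in nodes) {
      p_node <- amounts[nd, part$P]
      cp_node <- amounts[nd, cp_cols]
      if (nrow(cap$HC) > 0) {
        capr <- max(capr, max(as.numeric(cap$HC %*% v - cap$HE %*% p_node)))
      }
      if (nrow(maint$HM) > 0) {
        v_net_m <- map_dbl(maint$reactions, function(rid) {
          cols <- lay$fc$col[lay$fc$reaction_id == rid]
          sum(lay$fc$sign[lay$fc$reaction_id == rid] * v[cols])
        })
        maintr <- max(maintr, max(as.numeric(maint$HM %*% cp_node) - v_net_m))
      }
    }
  }
  for (nd in seq_len(N + 1)) {
    if (nrow(HB) > 0) {
      quota <- max(quota, max(as.numeric(HB %*% amounts[nd, cp_cols])))
    }
  }
  list(
    qssa = qssa, dynamics = dyn,
    capacity = max(0, capr),
    quota = max(0, quota),
    maintenance = max(0, maintr),
    nonnegativity = -min(0, min(amounts))
  )
}

#' Constraint residuals of a solved trajectory
#'
#' @param trajectory A solved `ram_trajectory`.
#' @return A tibble with one row per constraint family (`qssa`, `dynamics`,
#'   `capacity`, `quota`, `maintenance`, `nonnegativity`) and its maximal
#'   violation (0 means satisfied everywhere).
#' @export
defba_residuals <- function(trajectory) {
  stopifnot(inherits(trajectory, "ram_trajectory"))
  if (is.null(trajectory$residuals)) {
    abort("Trajectory has no solution (status was not optimal).")
  }
  tibble(
    constraint = names(trajectory$residuals),
    residual = unlist(trajectory$residuals)
  )
}

#' Instantaneous growth rate of a trajectory
#'
#' On each interval, the model growth rate is the log-slope of the total
#' biomass: `mu_i = ln(B_t(t_{i+1}) / B_t(t_i)) / (t_{i+1} - t_i)`. Under
#' saturating nutrients the deFBA optimum grows balanced and mu is constant
#' up to the discretization error.
#'
#' @param trajectory A solved `ram_trajectory`.
#' @param interval Optional single interval index (1-based); default all.
#' @return A tibble with columns `interval`, `t_start`, `t_end`, `mu`
#'   (1/h), or a single numeric value when `interval` is given.
#' @export
instantaneous_growth_rate <- function(trajectory, interval = NULL) {
  stopifnot(inherits(trajectory, "ram_trajectory"))
  if (is.null(trajectory$biomass)) {
    abort("Trajectory has no solution (status was not optimal).")
  }
  Bt <- trajectory$biomass$B_t
  if (any(Bt <= 0)) {
    abort("Total biomass is zero on the trajectory; growth rate undefined.")
  }
  t <- trajectory$times
  mu <- diff(log(Bt)) / diff(t)
  out <- tibble(
    interval = seq_along(mu),
    t_start = head(t, -1), t_end = tail(t, -1), mu = mu
  )
  if (!is.null(interval)) {
    if (!interval %in% out$interval) abort("No such interval.")
    return(out$mu[out$interval == interval])
  }
  out
}

#' @export
print.ram_trajectory <- function(x, ...) {
  cat("<ram_trajectory> status: ", x$status, "\n", sep = "")
  cat("  t in [0, ", x$config$t_end, "] h, ", x$config$n_steps,
      " intervals (", x$config$scheme, ")\n", sep = "")
  if (!is.null(x$objective)) {
    cat("  biomass integral: ", format(x$objective), " g h\n", sep = "")
  }
  invisible(x)
}
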