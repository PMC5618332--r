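#' Fit a culture growth rate from optical-density measurements
#'
#' For an exponentially growing batch culture, the growth rate is the slope
#' of the logarithm of the optical density versus time, estimated by
#' ordinary least squares over all supplied points (no outlier trimming;
#' restriction to the exponential phase is up to the caller).
#'
#' @param series A data frame with columns `times` (h, strictly increasing)
#'   and `od` (optical density, positive, arbitrary units) — or two vectors.
#' @param od Optional OD vector when `series` is a time vector.
#' @return The growth rate mu_exp in 1/h.
#' @examples
#' fit_growth_rate_from_od(data.frame(times = 0:4, od = exp(0.3 * (0:4))))
#' @export
fit_growth_rate_from_od <- function(series, od = NULL) {
  if (!is.null(od)) series <- tibble(times = series, od = od)
  series <- as_tibble(series)
  if (!all(c("times", "od") %in% names(series))) {
    abort("`series` must have columns `times` and `od`.")
  }
  if (nrow(series) < 2) abort("Need at least two OD measurements.")
  if (any(series$od <= 0)) abort("OD values must be positive.")
  if (any(diff(series$times) <= 0)) {
    abort("`times` must be strictly increasing.")
  }
  unname(coef(lm(log(od) ~ times, data = series))[2])
}

# Whole-horizon model growth rate of a deFBA run under fixed psi.
defba_mu_model <- function(model, scenario, config) {
  traj <- solve_defba(model, scenario, config)
  if (!identical(traj$status, "optimal")) {
    abort(paste0("deFBA solve returned status '", traj$status, "'."))
  }
  Bt <- traj$biomass$B_t
  log(Bt[length(Bt)] / Bt[1]) / config$t_end
}

#' Tune the maintenance coefficient to match an experimental growth rate
#'
#' The model growth rate under constant saturating conditions is an upper
#' bound on the measured culture growth rate; the gap represents energy
#' expenditure not covered by the model and is absorbed by forcing a
#' biomass-proportional flux through a maintenance reaction. Because the
#' model growth rate decreases monotonically in the maintenance coefficient
#' psi, the matching psi is found by bisection on deFBA solves (the model
#' growth rate is measured as the whole-horizon log-slope of total
#' biomass).
#'
#' @param model A [ram_model()].
#' @param maintenance_reaction_id Id of the (spontaneous) reaction whose
#'   `maintenance_scaling` is tuned.
#' @param mu_exp Experimental growth rate (1/h), e.g. from
#'   [fit_growth_rate_from_od()].
#' @param scenario,config Passed to [solve_defba()]; the scenario should
#'   represent the saturating conditions of the experiment.
#' @param tolerance Absolute tolerance on `|mu_model - mu_exp|` (1/h).
#' @param psi_max Upper limit of the search (expanded automatically by
#'   doubling if the initial limit still overshoots `mu_exp`).
#' @return The tuned psi (mmol/(g h)), with attribute `mu_model`, the
#'   achieved growth rate.
#' @export
tune_maintenance <- function(model, maintenance_reaction_id, mu_exp,
                             scenario = defba_scenario(model), config,
                             tolerance = 1e-3, psi_max = 1) {
  rx_idx <- match(maintenance_reaction_id, model$reactions$id)
  if (is.na(rx_idx)) {
    abort(paste0("Unknown reaction: ", maintenance_reaction_id))
  }
  if (!is.na(model$reactions$gene_product[rx_idx])) {
    abort("The maintenance reaction must be spontaneous.")
  }
  with_psi <- function(psi) {
    model$reactions$maintenance_scaling[rx_idx] <- psi
    model
  }
  mu_at <- function(psi) defba_mu_model(with_psi(psi), scenario, config)

  mu0 <- mu_at(0)
  if (mu_exp > mu0 + tolerance) {
    abort(paste0(
      "Measured growth rate (", signif(mu_exp, 4), " 1/h) exceeds the ",
      "model optimum without maintenance (", signif(mu0, 4), " 1/h); the ",
      "turnover-rate (kcat) parameters are likely too small and should be ",
      "checked before tuning maintenance."
    ))
  }
  if (abs(mu0 - mu_exp) <= tolerance) {
    return(structure(0, mu_model = mu0))
  }

  lo <- 0; mu_lo <- mu0
  hi <- psi_max
  mu_hi <- mu_at(hi)
  while (mu_hi > mu_exp) {
    lo <- hi; mu_lo <- mu_hi
    hi <- hi * 2
    if (hi > 1e6) abort("Could not bracket mu_exp; check the model.")
    mu_hi <- mu_at(hi)
  }
  repeat {
    mid <- (lo + hi) / 2
    mu_mid <- mu_at(mid)
    if (abs(mu_mid - mu_exp) <= tolerance) {
      return(structure(mid, mu_model = mu_mid))
    }
    if (mu_mid > mu_exp) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) {
      return(structure(mid, mu_model = mu_mid))
    }
  }
}
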