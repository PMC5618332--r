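#' Tidy a deFBA trajectory
#'
#' @param x A `ram_trajectory` from [solve_defba()].
#' @param ... Unused.
#' @return A tibble with one row per (time, species): columns `time`,
#'   `species`, `type`, `amount`.
#' @method tidy ram_trajectory
#' @export
tidy.ram_trajectory <- function(x, ...) {
  if (is.null(x$amounts)) {
    abort("Trajectory has no solution (status was not optimal).")
  }
  sp <- x$model$species
  as_tibble(x$amounts) |>
    mutate(time = x$times) |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "amount") |>
    mutate(type = sp$type[match(.data$species, sp$id)]) |>
    select("time", "species", "type", "amount") |>
    arrange(.data$time, .data$species)
}

#' One-line summary of a deFBA trajectory
#'
#' @param x A `ram_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: `status`, `objective` (biomass integral, g h),
#'   `t_end`, `n_steps`, `scheme`, `mu_mean` (mean interval growth rate,
#'   1/h), `max_residual`.
#' @method glance ram_trajectory
#' @export
glance.ram_trajectory <- function(x, ...) {
  mu_mean <- if (is.null(x$biomass)) NA_real_ else {
    mean(instantaneous_growth_rate(x)$mu)
  }
  tibble(
    status = x$status,
    objective = x$objective %||% NA_real_,
    t_end = x$config$t_end,
    n_steps = x$config$n_steps,
    scheme = x$config$scheme,
    mu_mean = mu_mean,
    max_residual = if (is.null(x$residuals)) NA_real_ else {
      max(unlist(x$residuals))
    }
  )
}

#' Tidy a balanced-growth (RBA) fit
#'
#' @param x A `ram_rba` from [solve_rba_initial()].
#' @param ... Unused.
#' @return A tibble with one row per storage/macromolecule species:
#'   `species`, `pool` (`"storage"` or `"macromolecule"`), `amount` (mmol).
#' @method tidy ram_rba
#' @export
tidy.ram_rba <- function(x, ...) {
  bind_rows(
    tibble(species = names(x$c0), pool = "storage", amount = unname(x$c0)),
    tibble(species = names(x$p0), pool = "macromolecule",
           amount = unname(x$p0))
  )
}

#' @rdname tidy.ram_rba
#' @return `glance()`: a one-row tibble with `mu_max`, `biomass`,
#'   `tolerance`.
#' @method glance ram_rba
#' @export
glance.ram_rba <- function(x, ...) {
  tibble(mu_max = x$mu_max, biomass = x$biomass, tolerance = x$tolerance)
}

#' Plot a deFBA trajectory
#'
#' Amounts over time, faceted by species class (free scales); storage and
#' macromolecules show the allocation dynamics, external species the
#' nutrient consumption.
#'
#' @param object A `ram_trajectory`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot ram_trajectory
#' @export
autoplot.ram_trajectory <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$amount,
                                    colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$type), scales = "free_y") +
    ggplot2::labs(x = "time [h]", y = "amount [mmol]") +
    ggplot2::theme_minimal()
}

#' Plot the biomass composition of an RBA fit
#'
#' @param object A `ram_rba`.
#' @param ... Unused.
#' @return A `ggplot` bar chart of the balanced-growth amounts.
#' @method autoplot ram_rba
#' @export
autoplot.ram_rba <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$species, .data$amount,
                                    fill = .data$pool)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "amount [mmol]",
      title = paste0("Balanced growth at mu = ",
                     signif(object$mu_max, 4), " 1/h")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
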