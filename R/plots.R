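#' @export
autoplot.nutrient_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = 1,
                                       fill = .data$nutrient)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (arbitrary units)", y = NULL, fill = "nutrient") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pf_filter <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$probability,
                                     colour = .data$nutrient)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time step",
                  y = "posterior predictive probability",
                  colour = "nutrient") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.policy_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$policy, y = .data$mean_rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::labs(x = NULL, y = "mean growth rate (e-folds / step)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fold_change_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta_gg,
                                       y = .data$theta_galg,
                                       fill = .data$fold_change)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(theta["Glu" %->% "Glu"]),
                  y = expression(theta["Gal" %->% "Glu"]),
                  fill = "fold change") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.circuit_sim <- function(object, species = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"t",
                              names_to = "species", values_to = "concentration")
  if (!is.null(species)) long <- dplyr::filter(long, .data$species %in% !!species)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$concentration)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (arbitrary units)",
                  y = "concentration (arbitrary units)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.growth_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$pop)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time step", y = "population size (log scale)") +
    ggplot2::theme_minimal()
}
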