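# broom-style accessors for the package's fitted/derived objects

#' @export
tidy.pf_filter <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x), dplyr::starts_with("p_"),
    names_to = "nutrient", names_prefix = "p_", values_to = "probability"
  )
}

#' @export
glance.pf_filter <- function(x, ...) {
  ens <- attr(x, "ensemble")
  spec <- attr(x, "spec")
  tibble(
    n_steps = nrow(x),
    n_particles = ens$n,
    K = spec$K,
    J = spec$J,
    final_ess = tail(x$ess, 1)
  )
}

#' @export
tidy.policy_comparison <- function(x, ...) {
  rates <- attr(x, "rates")
  as_tibble(rates) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    tidyr::pivot_longer(-"replicate", names_to = "policy", values_to = "rate")
}

#' @export
glance.policy_comparison <- function(x, ...) {
  tibble(
    n_policies = nrow(x),
    n_sims = x$n_sims[1],
    horizon = attr(x, "horizon") %||% NA_integer_,
    best_policy = x$policy[which.max(x$mean_rate)],
    best_mean_rate = max(x$mean_rate)
  )
}

#' @export
tidy.circuit_sim <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"t", names_to = "species",
                      values_to = "concentration")
}
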