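#' Inputs for closed-form policy analysis of two-sugar Markov environments
#'
#' The two-nutrient Markov environment is parameterized by
#' \eqn{\theta_{Glu \to Glu}} and \eqn{\theta_{Gal \to Glu}}; matched growth
#' rates are `v11` (tuned to glucose in glucose) and `v22` (tuned to
#' galactose in galactose). Mismatched growth rates are fixed at 0.
#'
#' @param theta_gg,theta_galg Environment transition probabilities.
#' @param v11,v22 Matched growth rates (defaults 0.6 and 0.3, glucose twice
#'   galactose).
#' @return A `markov_policy_inputs` object.
#' @export
markov_policy_inputs <- function(theta_gg, theta_galg, v11 = 0.6, v22 = 0.3) {
  check_probability(theta_gg, "theta_gg")
  check_probability(theta_galg, "theta_galg")
  if (v11 < 0 || v22 < 0) abort("Growth rates must be nonnegative.")
  structure(list(theta_gg = theta_gg, theta_galg = theta_galg,
                 v11 = v11, v22 = v22),
            class = "markov_policy_inputs")
}

#' Expected growth rate of the constitutive glucose-only policy
#'
#' \eqn{R(\pi_1) = V_{11}[\theta_{Glu \to Glu} + \theta_{Gal \to Glu}]}:
#' the conditional growth rates given each possible previous environment
#' state, summed (unweighted) over the two previous states.
#'
#' @param inp A [markov_policy_inputs()].
#' @return The expected growth rate.
#' @examples
#' expected_rate_glucose_only(markov_policy_inputs(0.9, 0.9, v11 = 1))  # 1.8
#' @export
expected_rate_glucose_only <- function(inp) {
  stopifnot(inherits(inp, "markov_policy_inputs"))
  # summed per previous state (matching the adaptive policy's
  # floating-point evaluation order, so coinciding cases are bit-identical)
  inp$v11 * inp$theta_gg + inp$v11 * inp$theta_galg
}

#' Expected growth rate of the constitutive galactose-only policy
#'
#' \eqn{R(\pi_2) = V_{22}[(1 - \theta_{Glu \to Glu}) +
#' (1 - \theta_{Gal \to Glu})]}.
#'
#' @inheritParams expected_rate_glucose_only
#' @return The expected growth rate.
#' @export
expected_rate_galactose_only <- function(inp) {
  stopifnot(inherits(inp, "markov_policy_inputs"))
  inp$v22 * (1 - inp$theta_gg) + inp$v22 * (1 - inp$theta_galg)
}

#' Expected growth rate of the posterior predictive policy
#'
#' With known transition probabilities the posterior predictive policy tunes,
#' from each previous state, to that state's most probable successor; its
#' expected rate is the per-state maximum of the two constitutive policies'
#' conditional rates, summed over the previous states. The four cases split
#' on whether each of \eqn{\theta_{Glu \to Glu}} and
#' \eqn{\theta_{Gal \to Glu}} is at least 0.5 (boundary values fall in the
#' glucose-choosing case).
#'
#' @inheritParams expected_rate_glucose_only
#' @return The expected growth rate.
#' @examples
#' expected_rate_posterior_predictive(
#'   markov_policy_inputs(0.2, 0.9, v11 = 2, v22 = 1))  # 2.6
#' @export
expected_rate_posterior_predictive <- function(inp) {
  stopifnot(inherits(inp, "markov_policy_inputs"))
  from_glu <- if (inp$theta_gg >= 0.5) inp$v11 * inp$theta_gg else
    inp$v22 * (1 - inp$theta_gg)
  from_gal <- if (inp$theta_galg >= 0.5) inp$v11 * inp$theta_galg else
    inp$v22 * (1 - inp$theta_galg)
  from_glu + from_gal
}

#' Fold-change grid of posterior predictive over glucose-only growth
#'
#' Evaluates \eqn{R(\pi_3) / R(\pi_1)} over a grid of environment transition
#' probabilities. In the quadrant where both probabilities are at least 0.5
#' the two policies coincide and the ratio is exactly 1; below it, the
#' adaptive policy harvests galactose stretches the constitutive policy
#' wastes. Cells where \eqn{R(\pi_1) = 0} (only the corner
#' \eqn{\theta = (0, 0)}) are flagged `NA` rather than infinite.
#'
#' An optional stationary-distribution weighting of the two previous states
#' is available (`stationary = TRUE`); the default unweighted sum matches
#' the closed forms above.
#'
#' @param resolution Grid points per axis (at least 2; default 101).
#' @param v11,v22 Matched growth rates.
#' @param theta_min Lower grid bound (default 0.02, excluding the degenerate
#'   corner).
#' @param stationary Weight previous states by the chain's stationary
#'   distribution instead of summing unweighted.
#'
#' @return A `fold_change_grid` tibble: `theta_gg`, `theta_galg`,
#'   `rate_pp`, `rate_glu`, `fold_change`.
#' @examples
#' g <- fold_change_grid(resolution = 21, v11 = 2, v22 = 1)
#' all(g$fold_change[g$theta_gg >= 0.5 & g$theta_galg >= 0.5] == 1)
#' @export
fold_change_grid <- function(resolution = 101, v11 = 0.6, v22 = 0.3,
                             theta_min = 0.02, stationary = FALSE) {
  if (!is_count(resolution) || resolution < 2) {
    abort("`resolution` must be an integer >= 2.")
  }
  if (v11 <= 0) abort("`v11` must be positive.")
  th <- seq(theta_min, 1, length.out = resolution)
  grid <- tidyr::expand_grid(theta_gg = th, theta_galg = th)
  rate_pair <- function(tgg, tgalg) {
    inp <- markov_policy_inputs(tgg, tgalg, v11, v22)
    r1 <- expected_rate_glucose_only(inp)
    r3 <- expected_rate_posterior_predictive(inp)
    if (stationary) {
      w <- stationary_glu_gal(tgg, tgalg)
      cond1 <- c(inp$v11 * tgg, inp$v11 * tgalg)
      cond3 <- c(if (tgg >= 0.5) inp$v11 * tgg else inp$v22 * (1 - tgg),
                 if (tgalg >= 0.5) inp$v11 * tgalg else inp$v22 * (1 - tgalg))
      r1 <- sum(w * cond1)
      r3 <- sum(w * cond3)
    }
    c(r3, r1)
  }
  rr <- mapply(rate_pair, grid$theta_gg, grid$theta_galg)
  grid$rate_pp <- rr[1, ]
  grid$rate_glu <- rr[2, ]
  grid$fold_change <- ifelse(grid$rate_glu > 0, grid$rate_pp / grid$rate_glu,
                             NA_real_)
  class(grid) <- c("fold_change_grid", class(grid))
  grid
}

# Stationary distribution over (Glu, Gal) for a two-state chain.
stationary_glu_gal <- function(theta_gg, theta_galg) {
  denom <- 1 - theta_gg + theta_galg
  if (denom == 0) return(c(0.5, 0.5))  # degenerate periodic-free chain
  p_glu <- theta_galg / denom
  c(p_glu, 1 - p_glu)
}
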