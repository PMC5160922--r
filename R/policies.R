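#' Specify a growth policy
#'
#' Policies map what a population can observe (the last nutrient, or its
#' belief about the next one) to an action. Winner-take-all policies tune the
#' whole population to a single nutrient; bet-hedging (`_bh`) policies split
#' the population into fractions.
#'
#' * `posterior_predictive` - tune to the most probable next nutrient under
#'   the supplied belief (ties go to the preferred nutrient).
#' * `plastic` - tune to the nutrient experienced last.
#' * `random` - tune uniformly at random.
#' * `constant` - always tune to `target` (glucose-only by default).
#' * `posterior_predictive_bh` - bet-hedge with fractions equal to the belief.
#' * `random_bh` - bet-hedge with uniform fractions.
#'
#' @param name Policy name (see above).
#' @param target Nutrient for the constant policy (default 1, the preferred
#'   nutrient).
#' @param tie_break Nutrient chosen at exact belief ties (default 1).
#' @return A `policy_spec` object.
#' @examples
#' policy_spec("posterior_predictive")
#' policy_spec("constant", target = "Glu")
#' @export
policy_spec <- function(name = c("posterior_predictive", "plastic", "random",
                                 "constant", "posterior_predictive_bh",
                                 "random_bh"),
                        target = 1L, tie_break = 1L) {
  name <- match.arg(name)
  structure(list(name = name, target = target, tie_break = tie_break),
            class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  cat("<policy_spec> ", x$name, "\n", sep = "")
  invisible(x)
}

policy_uses_belief <- function(policy) {
  policy$name %in% c("posterior_predictive", "posterior_predictive_bh")
}

#' Choose an action under a policy
#'
#' @param policy A [policy_spec()].
#' @param belief Predictive distribution over the next nutrient (required for
#'   the posterior-predictive policies).
#' @param last_observed Most recently observed nutrient index (required for
#'   the plastic policy).
#' @param n_nutrients Number of nutrients (required for random policies when
#'   no belief is given).
#'
#' @return An `action`: a list with `kind` (`"tune"` or `"hedge"`) and either
#'   `nutrient` (an index) or `fractions` (a probability vector).
#' @examples
#' act(policy_spec("posterior_predictive"), belief = c(Glu = 0.7, Gal = 0.3))
#' @export
act <- function(policy, belief = NULL, last_observed = NULL,
                n_nutrients = length(belief)) {
  stopifnot(inherits(policy, "policy_spec"))
  tune <- function(i) structure(list(kind = "tune", nutrient = as.integer(i)),
                                class = "action")
  hedge <- function(f) structure(list(kind = "hedge",
                                      fractions = as.numeric(f) / sum(f)),
                                 class = "action")
  switch(
    policy$name,
    posterior_predictive = {
      if (is.null(belief)) abort("The posterior predictive policy needs a `belief`.")
      m <- max(belief)
      winners <- which(belief == m)
      i <- if (policy$tie_break %in% winners) policy$tie_break else winners[1]
      tune(i)
    },
    plastic = {
      if (is.null(last_observed)) abort("The plastic policy needs `last_observed`.")
      tune(last_observed)
    },
    random = {
      if (is.null(n_nutrients) || n_nutrients < 1) {
        abort("The random policy needs `n_nutrients` (or a `belief`).")
      }
      tune(sample.int(n_nutrients, 1))
    },
    constant = tune(policy$target),
    posterior_predictive_bh = {
      if (is.null(belief)) abort("Bet-hedging on the posterior predictive needs a `belief`.")
      hedge(belief)
    },
    random_bh = {
      if (is.null(n_nutrients) || n_nutrients < 1) {
        abort("Random bet-hedging needs `n_nutrients` (or a `belief`).")
      }
      hedge(rep(1 / n_nutrients, n_nutrients))
    }
  )
}

#' Closed-form posterior predictive action for known two-sugar environments
#'
#' When the transition probabilities of a two-nutrient Markov environment are
#' known, the posterior predictive policy reduces to choosing the most
#' probable successor of the previous nutrient: from glucose, tune to glucose
#' iff \eqn{\theta_{Glu \to Glu} > 0.5}; from galactose, tune to glucose iff
#' \eqn{\theta_{Gal \to Glu} > 0.5} (at exactly 0.5 the alternative nutrient
#' is chosen, per the strict inequality).
#'
#' @param theta_gg \eqn{\theta_{Glu \to Glu}}.
#' @param theta_galg \eqn{\theta_{Gal \to Glu}}.
#' @param c_prev Previous nutrient (1/"Glu" or 2/"Gal").
#' @return The chosen nutrient index (1 = Glu, 2 = Gal).
#' @examples
#' analytic_pp_action(0.9, 0.2, "Glu")  # stay tuned to glucose
#' @export
analytic_pp_action <- function(theta_gg, theta_galg, c_prev) {
  check_probability(theta_gg, "theta_gg")
  check_probability(theta_galg, "theta_galg")
  c_prev <- nutrient_index(c_prev, nutrient_alphabet(c("Glu", "Gal")))
  p_glu <- if (c_prev == 1) theta_gg else theta_galg
  if (p_glu > 0.5) 1L else 2L
}
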