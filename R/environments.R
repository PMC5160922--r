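#' Define a nutrient alphabet
#'
#' A nutrient alphabet is an ordered set of nutrient names. The first label is
#' the designated "preferred" nutrient (glucose in the canonical two-sugar
#' setting): tie-breaking policies and the glucose-only constant policy default
#' to it.
#'
#' @param labels Character vector of unique nutrient names, length at least 2.
#'
#' @return A `nutrient_alphabet` object (a character vector).
#' @examples
#' nutrient_alphabet(c("Glu", "Gal"))
#' @export
nutrient_alphabet <- function(labels = c("Glu", "Gal")) {
  labels <- as.character(labels)
  if (length(labels) < 2) abort("A nutrient alphabet needs at least 2 labels.")
  if (anyDuplicated(labels)) abort("Nutrient labels must be unique.")
  structure(labels, class = "nutrient_alphabet")
}

#' @export
print.nutrient_alphabet <- function(x, ...) {
  cat("<nutrient_alphabet> ", paste(unclass(x), collapse = ", "),
      " (preferred: ", x[1], ")\n", sep = "")
  invisible(x)
}

#' Specify a Markov nutrient environment
#'
#' A discrete environment in which the nutrient at each time step is drawn
#' from a row-stochastic transition matrix conditioned on the previous
#' nutrient. In the two-sugar case the matrix is fully determined by
#' \eqn{\theta_{Glu \to Glu}} and \eqn{\theta_{Gal \to Glu}}.
#'
#' @param transition_matrix J x J row-stochastic matrix; rows index the
#'   previous nutrient, columns the next.
#' @param alphabet A [nutrient_alphabet()]; defaults to the matrix dimnames or
#'   Glu/Gal(/Mal...) labels.
#' @param initial Index (or label) of the nutrient at time 0.
#'
#' @return A `markov_env_spec` object.
#' @examples
#' markov_env_spec(matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE))
#' @export
markov_env_spec <- function(transition_matrix, alphabet = NULL, initial = 1L) {
  transition_matrix <- as.matrix(transition_matrix)
  if (is.null(alphabet)) {
    alphabet <- if (!is.null(rownames(transition_matrix))) {
      nutrient_alphabet(rownames(transition_matrix))
    } else if (nrow(transition_matrix) == 2) {
      nutrient_alphabet(c("Glu", "Gal"))
    } else if (nrow(transition_matrix) == 3) {
      nutrient_alphabet(c("Glu", "Gal", "Mal"))
    } else {
      nutrient_alphabet(paste0("N", seq_len(nrow(transition_matrix))))
    }
  }
  J <- length(alphabet)
  if (!all(dim(transition_matrix) == c(J, J))) {
    abort("`transition_matrix` must be square with one row per nutrient.")
  }
  check_row_stochastic(transition_matrix, "transition_matrix")
  dimnames(transition_matrix) <- list(unclass(alphabet), unclass(alphabet))
  initial <- nutrient_index(initial, alphabet)
  structure(
    list(alphabet = alphabet, transition_matrix = transition_matrix,
         initial = initial),
    class = "markov_env_spec"
  )
}

#' Convenience constructor for two-sugar Markov environments
#'
#' @param theta_gg Probability of staying in glucose,
#'   \eqn{\theta_{Glu \to Glu}}.
#' @param theta_galg Probability of switching from galactose to glucose,
#'   \eqn{\theta_{Gal \to Glu}}.
#' @param initial Initial nutrient (index or label).
#' @return A `markov_env_spec` over Glu/Gal.
#' @examples
#' glu_gal_env_spec(0.9, 0.5)
#' @export
glu_gal_env_spec <- function(theta_gg, theta_galg, initial = "Glu") {
  check_probability(theta_gg, "theta_gg")
  check_probability(theta_galg, "theta_galg")
  m <- matrix(c(theta_gg, 1 - theta_gg, theta_galg, 1 - theta_galg),
              nrow = 2, byrow = TRUE)
  markov_env_spec(m, nutrient_alphabet(c("Glu", "Gal")), initial)
}

#' Specify a meta-changing environment
#'
#' A meta-changing environment layers a hidden Markov chain of "switch states"
#' (regimes) on top of nutrient transitions: the regime at time t selects
#' which nutrient transition matrix generates the next nutrient. The regime
#' chain itself is unobservable to cells.
#'
#' @param switch_matrix K x K row-stochastic matrix over hidden regimes.
#' @param state_matrices List of K row-stochastic J x J nutrient transition
#'   matrices, one per regime.
#' @param alphabet A [nutrient_alphabet()] (defaulting as in
#'   [markov_env_spec()]).
#' @param initial_switch Index of the regime at time 1.
#' @param initial_nutrient Index (or label) of the nutrient at time 0.
#'
#' @return A `meta_env_spec` object.
#' @seealso [two_state_glu_gal_spec()] for the canonical periodic/constant
#'   two-regime environment.
#' @export
meta_env_spec <- function(switch_matrix, state_matrices, alphabet = NULL,
                          initial_switch = 1L, initial_nutrient = 1L) {
  switch_matrix <- as.matrix(switch_matrix)
  K <- nrow(switch_matrix)
  if (K < 1 || ncol(switch_matrix) != K) {
    abort("`switch_matrix` must be a square matrix with K >= 1.")
  }
  check_row_stochastic(switch_matrix, "switch_matrix")
  if (!is.list(state_matrices) || length(state_matrices) != K) {
    abort("`state_matrices` must be a list with one matrix per switch state.")
  }
  state_matrices <- lapply(state_matrices, as.matrix)
  if (is.null(alphabet)) {
    probe <- markov_env_spec(state_matrices[[1]])
    alphabet <- probe$alphabet
  }
  J <- length(alphabet)
  for (k in seq_len(K)) {
    if (!all(dim(state_matrices[[k]]) == c(J, J))) {
      abort(sprintf("`state_matrices[[%d]]` must be %d x %d.", k, J, J))
    }
    check_row_stochastic(state_matrices[[k]], sprintf("state_matrices[[%d]]", k))
    dimnames(state_matrices[[k]]) <- list(unclass(alphabet), unclass(alphabet))
  }
  if (!is_count(initial_switch) || initial_switch > K) {
    abort("`initial_switch` must be a switch-state index in 1..K.")
  }
  initial_nutrient <- nutrient_index(initial_nutrient, alphabet)
  structure(
    list(alphabet = alphabet, K = K, switch_matrix = switch_matrix,
         state_matrices = state_matrices,
         initial_switch = as.integer(initial_switch),
         initial_nutrient = initial_nutrient),
    class = "meta_env_spec"
  )
}

#' Two-regime periodic/constant glucose-galactose environment
#'
#' The canonical meta-changing environment: regime 1 alternates
#' (near-deterministically) between glucose and galactose, regime 2 holds the
#' environment (near-deterministically) in glucose. The hidden regime chain is
#' parameterized by `p1`, the probability that the periodic regime transitions
#' to itself, and `p2`, the probability that the constant regime transitions
#' to the periodic one.
#'
#' The regimes are made near-deterministic rather than exactly deterministic
#' (off-pattern probability `eps`) so that generated traces stay inside the
#' support of the inference model; set `eps = 0` for strict alternation.
#'
#' @param p1 P(periodic regime -> periodic regime).
#' @param p2 P(constant regime -> periodic regime).
#' @param eps Off-pattern slack probability per transition (default 0.02).
#' @param initial_switch Starting regime (1 = periodic, 2 = constant).
#'
#' @return A `meta_env_spec` with K = 2 over Glu/Gal.
#' @examples
#' two_state_glu_gal_spec(0.95, 0.05)
#' @export
two_state_glu_gal_spec <- function(p1, p2, eps = 0.02, initial_switch = 1L) {
  check_probability(p1, "p1")
  check_probability(p2, "p2")
  check_probability(eps, "eps")
  periodic <- matrix(c(eps, 1 - eps, 1 - eps, eps), nrow = 2, byrow = TRUE)
  constant <- matrix(c(1 - eps, eps, 1 - eps, eps), nrow = 2, byrow = TRUE)
  switch_matrix <- matrix(c(p1, 1 - p1, p2, 1 - p2), nrow = 2, byrow = TRUE)
  meta_env_spec(switch_matrix, list(periodic, constant),
                nutrient_alphabet(c("Glu", "Gal")),
                initial_switch = initial_switch, initial_nutrient = "Glu")
}

#' Three-nutrient Markov environment archetypes
#'
#' Constructs three qualitatively distinct glucose/galactose/maltose Markov
#' environments: (1) "persistent" stretches of each nutrient; (2) a mixture of
#' periodic glucose-galactose switching with persistent maltose stretches;
#' (3) a "chained" environment where glucose signals upcoming galactose and
#' galactose signals an upcoming persistent maltose stretch. Exact transition
#' values are parameterized by a single `persistence` level; the archetypes
#' are qualitative constructions, not fitted matrices.
#'
#' @param persistence Dominant transition probability, in (0.5, 1).
#' @return Named list of three `markov_env_spec` objects
#'   (`persistent`, `periodic_persistent`, `chained`).
#' @examples
#' make_multinutrient_archetypes(0.9)
#' @export
make_multinutrient_archetypes <- function(persistence = 0.9) {
  if (!is.numeric(persistence) || length(persistence) != 1 ||
      persistence <= 0.5 || persistence >= 1) {
    abort("`persistence` must lie in (0.5, 1).")
  }
  p <- persistence
  q <- (1 - p) / 2
  ab <- nutrient_alphabet(c("Glu", "Gal", "Mal"))
  persistent <- matrix(c(p, q, q,
                         q, p, q,
                         q, q, p), nrow = 3, byrow = TRUE)
  # Glu<->Gal periodic; Mal self-persistent; rare escapes into/out of Mal.
  periodic_persistent <- matrix(c(1 - p, p - q, q,
                                  p - q, 1 - p, q,
                                  q, q, p), nrow = 3, byrow = TRUE)
  # Glu -> Gal -> Mal chain, Mal persistent.
  chained <- matrix(c(1 - p, p, 0,
                      q, q, p,
                      q, q, p), nrow = 3, byrow = TRUE)
  list(
    persistent = markov_env_spec(persistent, ab, "Glu"),
    periodic_persistent = markov_env_spec(periodic_persistent, ab, "Glu"),
    chained = markov_env_spec(chained, ab, "Glu")
  )
}

#' Sample nutrients along a fixed regime schedule
#'
#' Instead of letting the hidden regime chain evolve stochastically, follow a
#' prescribed per-step regime index vector and draw each nutrient from the
#' scheduled regime's transition matrix. This is how fixed-boundary
#' illustration environments are built (e.g. periodic for 20 steps, constant
#' for 20, periodic again, constant again); with exactly deterministic regime
#' matrices the resulting trace is deterministic.
#'
#' @param spec A `meta_env_spec` (its switch matrix is ignored).
#' @param regimes Integer vector of regime indices, one per transition.
#' @param seed Integer seed.
#' @return A `nutrient_trace` tibble with the scheduled regimes recorded in
#'   `switch_state`.
#' @examples
#' me <- two_state_glu_gal_spec(0.5, 0.5, eps = 0)
#' sample_regime_schedule(me, rep(c(1, 2), each = 20), seed = 1)
#' @export
sample_regime_schedule <- function(spec, regimes, seed = NULL) {
  stopifnot(inherits(spec, "meta_env_spec"))
  regimes <- as.integer(regimes)
  if (length(regimes) < 1 || any(regimes < 1 | regimes > spec$K)) {
    abort("`regimes` must be a nonempty vector of regime indices in 1..K.")
  }
  if (!is.null(seed)) set.seed(seed)
  horizon <- length(regimes)
  obs <- integer(horizon + 1)
  obs[1] <- spec$initial_nutrient
  for (t in seq_len(horizon)) {
    obs[t + 1] <- sample_categorical(spec$state_matrices[[regimes[t]]][obs[t], ])
  }
  new_nutrient_trace(0:horizon, obs, spec$alphabet,
                     switch_state = c(NA_integer_, regimes))
}

#' Three-nutrient meta-changing environment
#'
#' A hidden two-regime environment over glucose, galactose and maltose that
#' switches between the periodic-plus-persistent-maltose archetype and the
#' chained (Glu signals Gal, Gal signals persistent Mal) archetype of
#' [make_multinutrient_archetypes()]. Regime switching is parameterized by
#' `p1` and `p2` exactly as in [two_state_glu_gal_spec()].
#'
#' @inheritParams two_state_glu_gal_spec
#' @param persistence Dominant transition probability of the archetypes.
#' @return A `meta_env_spec` with K = 2, J = 3.
#' @export
multinutrient_meta_spec <- function(p1, p2, persistence = 0.9,
                                    initial_switch = 1L) {
  arch <- make_multinutrient_archetypes(persistence)
  meta_env_spec(
    matrix(c(p1, 1 - p1, p2, 1 - p2), nrow = 2, byrow = TRUE),
    list(arch$periodic_persistent$transition_matrix,
         arch$chained$transition_matrix),
    arch$persistent$alphabet,
    initial_switch = initial_switch, initial_nutrient = "Glu"
  )
}

new_nutrient_trace <- function(t, nutrient_idx, alphabet, switch_state = NULL) {
  nutrient <- factor(unclass(alphabet)[nutrient_idx],
                     levels = unclass(alphabet))
  out <- tibble(t = as.integer(t), nutrient = nutrient)
  if (!is.null(switch_state)) out$switch_state <- as.integer(switch_state)
  class(out) <- c("nutrient_trace", class(out))
  out
}

#' Sample a trace from a Markov nutrient environment
#'
#' @param spec A `markov_env_spec`.
#' @param horizon Number of transitions T; the trace has T + 1 observations
#'   (times 0..T) with the initial nutrient fixed by the spec.
#' @param seed Integer seed; identical seeds give identical traces.
#'
#' @return A `nutrient_trace` tibble with columns `t` and `nutrient`.
#' @examples
#' sample_markov_env(glu_gal_env_spec(0.9, 0.5), horizon = 10, seed = 1)
#' @export
sample_markov_env <- function(spec, horizon, seed = NULL) {
  stopifnot(inherits(spec, "markov_env_spec"))
  if (!is_count(horizon)) abort("`horizon` must be a positive integer.")
  if (!is.null(seed)) set.seed(seed)
  J <- length(spec$alphabet)
  obs <- integer(horizon + 1)
  obs[1] <- spec$initial
  for (t in seq_len(horizon)) {
    obs[t + 1] <- sample_categorical(spec$transition_matrix[obs[t], ])
  }
  new_nutrient_trace(0:horizon, obs, spec$alphabet)
}

#' Sample a trace from a meta-changing environment
#'
#' The hidden regime chain S_1..S_T evolves by the switch matrix (S_1 is the
#' spec's initial regime); the nutrient at time t is drawn from regime S_t's
#' transition matrix conditioned on the previous nutrient. True regimes are
#' recorded in the trace for downstream evaluation; they are never visible to
#' the inference model.
#'
#' @inheritParams sample_markov_env
#' @param spec A `meta_env_spec`.
#' @return A `nutrient_trace` tibble with columns `t`, `nutrient`,
#'   `switch_state` (NA at t = 0, where no regime applies).
#' @examples
#' sample_meta_env(two_state_glu_gal_spec(0.9, 0.1), horizon = 20, seed = 1)
#' @export
sample_meta_env <- function(spec, horizon, seed = NULL) {
  stopifnot(inherits(spec, "meta_env_spec"))
  if (!is_count(horizon)) abort("`horizon` must be a positive integer.")
  if (!is.null(seed)) set.seed(seed)
  obs <- integer(horizon + 1)
  sw <- integer(horizon)
  obs[1] <- spec$initial_nutrient
  s <- spec$initial_switch
  for (t in seq_len(horizon)) {
    sw[t] <- s
    obs[t + 1] <- sample_categorical(spec$state_matrices[[s]][obs[t], ])
    if (t < horizon) s <- sample_categorical(spec$switch_matrix[s, ])
  }
  new_nutrient_trace(0:horizon, obs, spec$alphabet,
                     switch_state = c(NA_integer_, sw))
}

# Resolve a nutrient given as index, label or factor to a 1-based index.
nutrient_index <- function(x, alphabet) {
  labels <- unclass(alphabet)
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    idx <- match(x, labels)
    if (anyNA(idx)) {
      abort(sprintf("Unknown nutrient name(s): %s (alphabet: %s).",
                    paste(x[is.na(idx)], collapse = ", "),
                    paste(labels, collapse = ", ")))
    }
    return(as.integer(idx))
  }
  x <- as.integer(x)
  if (any(is.na(x) | x < 1 | x > length(labels))) {
    abort("Nutrient index out of range for the alphabet.")
  }
  x
}

# Extract 1-based nutrient indices from a trace tibble, factor, character or
# integer vector.
trace_indices <- function(history, alphabet = NULL) {
  if (is.data.frame(history)) {
    if (!"nutrient" %in% names(history)) {
      abort("A trace data frame must have a `nutrient` column.")
    }
    nut <- history$nutrient
    if (is.factor(nut)) {
      if (is.null(alphabet)) alphabet <- nutrient_alphabet(levels(nut))
      return(list(idx = as.integer(nut), alphabet = alphabet))
    }
    history <- nut
  }
  if (is.null(alphabet)) {
    if (is.factor(history)) {
      alphabet <- nutrient_alphabet(levels(history))
    } else if (is.character(history)) {
      abort("Supply `alphabet` when the history is a bare character vector.")
    } else {
      alphabet <- nutrient_alphabet(c("Glu", "Gal"))
      if (max(history) > 2) {
        alphabet <- nutrient_alphabet(c("Glu", "Gal", "Mal")[seq_len(max(history))])
      }
    }
  }
  list(idx = nutrient_index(history, alphabet), alphabet = alphabet)
}
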