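#' Specify the switching-state model of a meta-changing environment
#'
#' The inference model assumes K hidden regimes ("switch states") and J
#' nutrients. The initial regime, initial nutrient, regime transitions and
#' per-regime nutrient transitions all carry Dirichlet priors, so all
#' transition probabilities are integrated out analytically (collapsed
#' Dirichlet-multinomial inference) and inference only tracks transition
#' counts.
#'
#' Default hyperparameters: all-ones vectors for the initial regime, initial
#' nutrient and nutrient transitions; the regime-transition prior is weakly
#' "sticky", giving self-transitions pseudo-count 2 and all others 1.
#'
#' @param K Number of hidden switch states (default 2).
#' @param J Number of nutrients (default 2).
#' @param alpha_s1 K-vector, Dirichlet prior on the initial switch state.
#' @param alpha_c0 J-vector, Dirichlet prior on the initial nutrient.
#' @param alpha_s_self,alpha_s_other Pseudo-counts for regime self- and
#'   cross-transitions (defaults 2 and 1).
#' @param alpha_c Scalar pseudo-count for nutrient transitions (default 1).
#' @param labels Optional nutrient labels (defaults to Glu/Gal/Mal prefixes).
#'
#' @return A `model_spec` object.
#' @examples
#' model_spec()           # the default two-regime, two-sugar model
#' model_spec(K = 2, J = 3)
#' @export
model_spec <- function(K = 2, J = 2, alpha_s1 = rep(1, K),
                       alpha_c0 = rep(1, J), alpha_s_self = 2,
                       alpha_s_other = 1, alpha_c = 1, labels = NULL) {
  if (!is_count(K)) abort("`K` must be a positive integer.")
  if (!is_count(J) || J < 2) abort("`J` must be an integer >= 2.")
  if (length(alpha_s1) != K || any(alpha_s1 <= 0)) {
    abort("`alpha_s1` must be a strictly positive K-vector.")
  }
  if (length(alpha_c0) != J || any(alpha_c0 <= 0)) {
    abort("`alpha_c0` must be a strictly positive J-vector.")
  }
  if (any(c(alpha_s_self, alpha_s_other, alpha_c) <= 0)) {
    abort("All hyperparameters must be strictly positive.")
  }
  if (is.null(labels)) {
    labels <- if (J <= 3) c("Glu", "Gal", "Mal")[seq_len(J)] else
      paste0("N", seq_len(J))
  }
  structure(
    list(K = as.integer(K), J = as.integer(J),
         alpha_s1 = as.numeric(alpha_s1), alpha_c0 = as.numeric(alpha_c0),
         alpha_s_self = as.numeric(alpha_s_self),
         alpha_s_other = as.numeric(alpha_s_other),
         alpha_c = as.numeric(alpha_c),
         alphabet = nutrient_alphabet(labels)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> K = %d switch states, J = %d nutrients (%s)\n", x$K, x$J,
    paste(unclass(x$alphabet), collapse = ", ")))
  cat(sprintf("  alpha_s: self %g / other %g; alpha_c: %g\n",
              x$alpha_s_self, x$alpha_s_other, x$alpha_c))
  invisible(x)
}

# Dirichlet pseudo-count row for switch transitions out of state i.
alpha_s_row <- function(spec, i) {
  a <- rep(spec$alpha_s_other, spec$K)
  a[i] <- spec$alpha_s_self
  a
}

#' Empty transition-count sufficient statistics
#'
#' Counts are the only state collapsed inference needs: `S[i, j]` is the
#' number of observed (or hypothesized) regime transitions i -> j and
#' `C[i, j, k]` the number of nutrient transitions i -> j under regime k.
#'
#' @param spec A [model_spec()].
#' @return A `count_stats` list with zero matrices `S` (K x K) and `C`
#'   (J x J x K).
#' @export
count_stats <- function(spec) {
  structure(
    list(S = matrix(0, spec$K, spec$K),
         C = array(0, dim = c(spec$J, spec$J, spec$K))),
    class = "count_stats"
  )
}

#' Collapsed predictive probability of a switch-state transition
#'
#' With the regime transition probabilities integrated out against their
#' Dirichlet prior, the predictive probability of moving from regime `from`
#' to regime `to` given accumulated counts S is the Dirichlet-multinomial
#' ratio \deqn{P(j | i) = \frac{\alpha_s^{(j)} + S^{(i,j)}}
#'   {\sum_k (\alpha_s^{(k)} + S^{(i,k)})}.}
#'
#' @param stats A [count_stats()] object.
#' @param spec A [model_spec()].
#' @param from Current switch-state index.
#' @param to Optional next-state index; if `NULL` the full predictive row is
#'   returned.
#' @return A probability, or a K-vector summing to 1 when `to` is `NULL`.
#' @examples
#' sp <- model_spec()
#' collapsed_switch_prob(count_stats(sp), sp, from = 1)  # sticky prior: 2/3, 1/3
#' @export
collapsed_switch_prob <- function(stats, spec, from, to = NULL) {
  a <- alpha_s_row(spec, from) + stats$S[from, ]
  p <- a / sum(a)
  if (is.null(to)) p else p[to]
}

#' Collapsed predictive probability of a nutrient transition
#'
#' The Dirichlet-multinomial predictive for the next nutrient given the
#' current nutrient and a hypothesized regime `s`:
#' \deqn{P(c' | c, s) = \frac{\alpha_c + C^{(c, c', s)}}
#'   {\sum_k (\alpha_c + C^{(c, k, s)})}.}
#'
#' @inheritParams collapsed_switch_prob
#' @param c_prev Current nutrient index.
#' @param c_next Optional next-nutrient index; if `NULL` the full row is
#'   returned.
#' @param s Switch-state index conditioning the transition.
#' @return A probability, or a J-vector summing to 1 when `c_next` is `NULL`.
#' @export
collapsed_nutrient_prob <- function(stats, spec, c_prev, c_next = NULL, s = 1) {
  a <- spec$alpha_c + stats$C[c_prev, , s]
  p <- a / sum(a)
  if (is.null(c_next)) p else p[c_next]
}

#' Sample an environment trace from the model prior
#'
#' Draws one set of transition parameter vectors from their Dirichlet priors,
#' then simulates the regime chain and nutrient chain forward. Useful for
#' prior predictive checks and for generating environments that are exactly
#' within the inference model's family.
#'
#' @param spec A [model_spec()].
#' @param horizon Number of transitions T (trace has T + 1 observations).
#' @param seed Integer seed.
#' @return A `nutrient_trace` tibble (`t`, `nutrient`, `switch_state`) with
#'   the drawn parameters attached as attribute `"params"`.
#' @export
sample_from_prior <- function(spec, horizon, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is_count(horizon)) abort("`horizon` must be a positive integer.")
  if (!is.null(seed)) set.seed(seed)
  K <- spec$K; J <- spec$J
  pi_s1 <- rdirichlet1(spec$alpha_s1)
  pi_c0 <- rdirichlet1(spec$alpha_c0)
  pi_s <- t(vapply(seq_len(K), function(i) rdirichlet1(alpha_s_row(spec, i)),
                   numeric(K)))
  pi_c <- array(0, dim = c(J, J, K))
  for (k in seq_len(K)) for (i in seq_len(J)) {
    pi_c[i, , k] <- rdirichlet1(rep(spec$alpha_c, J))
  }
  obs <- integer(horizon + 1)
  sw <- integer(horizon)
  obs[1] <- sample_categorical(pi_c0)
  s <- sample_categorical(pi_s1)
  for (t in seq_len(horizon)) {
    sw[t] <- s
    obs[t + 1] <- sample_categorical(pi_c[obs[t], , s])
    if (t < horizon) s <- sample_categorical(pi_s[s, ])
  }
  out <- new_nutrient_trace(0:horizon, obs, spec$alphabet,
                            switch_state = c(NA_integer_, sw))
  attr(out, "params") <- list(pi_s1 = pi_s1, pi_c0 = pi_c0, pi_s = pi_s,
                              pi_c = pi_c)
  out
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Exact posterior predictive distribution by regime-path enumeration
#'
#' Computes \eqn{P(C_{t+1} | C_{0:t})} exactly by summing over all K^T hidden
#' regime trajectories, with transition parameters integrated out analytically
#' along each trajectory (sequential Polya-urn factorization of the collapsed
#' joint). Exponential in the history length, so it is capped at K^T <= 4096
#' trajectories; beyond that the particle filter is the only estimator. This
#' function is the ground-truth oracle used to validate the particle filter.
#'
#' @param history A `nutrient_trace` tibble, factor, or integer index vector
#'   of observations \eqn{C_0..C_T}.
#' @param spec A [model_spec()].
#' @return A named probability vector over the next nutrient (class
#'   `predictive_dist`).
#' @examples
#' exact_posterior_predictive(c(1, 2, 1, 2), model_spec())
#' @export
exact_posterior_predictive <- function(history, spec) {
  stopifnot(inherits(spec, "model_spec"))
  h <- trace_indices(history, spec$alphabet)$idx
  n_trans <- length(h) - 1
  K <- spec$K; J <- spec$J
  if (n_trans >= 1 && K^n_trans > 4096) {
    abort(sprintf(
      "Enumeration infeasible: K^T = %d^%d trajectories exceeds the 4096 cap.",
      K, n_trans))
  }
  if (length(h) == 0) {
    # Prior predictive for the initial nutrient.
    p <- spec$alpha_c0 / sum(spec$alpha_c0)
    return(new_predictive(p, spec$alphabet))
  }
  if (n_trans == 0) {
    # One observation: average the zero-count nutrient predictive over the
    # prior on S_1 (uniform in c by symmetry of the collapsed counts).
    stats <- count_stats(spec)
    prior_s1 <- spec$alpha_s1 / sum(spec$alpha_s1)
    p <- numeric(J)
    for (s1 in seq_len(K)) {
      p <- p + prior_s1[s1] * collapsed_nutrient_prob(stats, spec, h[1], s = s1)
    }
    return(new_predictive(p, spec$alphabet))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n_trans)))
  log_w <- numeric(nrow(paths))
  pred <- matrix(0, nrow(paths), J)
  prior_s1 <- spec$alpha_s1 / sum(spec$alpha_s1)
  for (r in seq_len(nrow(paths))) {
    s_path <- paths[r, ]
    stats <- count_stats(spec)
    lw <- log(prior_s1[s_path[1]])
    for (t in seq_len(n_trans)) {
      if (t > 1) {
        lw <- lw + log(collapsed_switch_prob(stats, spec, s_path[t - 1],
                                             s_path[t]))
        stats$S[s_path[t - 1], s_path[t]] <- stats$S[s_path[t - 1], s_path[t]] + 1
      }
      lw <- lw + log(collapsed_nutrient_prob(stats, spec, h[t], h[t + 1],
                                             s_path[t]))
      stats$C[h[t], h[t + 1], s_path[t]] <- stats$C[h[t], h[t + 1], s_path[t]] + 1
    }
    log_w[r] <- lw
    # Predictive for C_{T+1} under this trajectory's counts.
    s_T <- s_path[n_trans]
    p <- numeric(J)
    for (s_next in seq_len(K)) {
      p <- p + collapsed_switch_prob(stats, spec, s_T, s_next) *
        collapsed_nutrient_prob(stats, spec, h[n_trans + 1], s = s_next)
    }
    pred[r, ] <- p
  }
  w <- exp(log_w - max(log_w))
  w <- w / sum(w)
  new_predictive(colSums(pred * w), spec$alphabet)
}

#' Posterior predictive of a flat (single-regime) Markov model
#'
#' The baseline model with no hidden states: a single Dirichlet-multinomial
#' transition matrix over nutrients. The predictive for the next nutrient is
#' the pseudo-count-smoothed empirical transition row of the current nutrient,
#' \eqn{(\alpha + n(c_t, \cdot)) / \sum_k (\alpha + n(c_t, k))}.
#'
#' @param history Observations \eqn{C_0..C_T} (trace tibble, factor, or index
#'   vector); length at least 1.
#' @param alpha Dirichlet pseudo-count, scalar or J-vector (default 1).
#' @param alphabet Optional [nutrient_alphabet()] when `history` is a bare
#'   index vector with fewer symbols than nutrients.
#' @return A named probability vector over the next nutrient.
#' @examples
#' flat_markov_posterior_predictive(c("Glu", "Glu", "Gal", "Glu"),
#'                                  alphabet = nutrient_alphabet())
#' @export
flat_markov_posterior_predictive <- function(history, alpha = 1,
                                             alphabet = NULL) {
  tr <- trace_indices(history, alphabet)
  h <- tr$idx
  J <- length(tr$alphabet)
  if (length(h) < 1) abort("`history` must contain at least one observation.")
  if (length(alpha) == 1) alpha <- rep(alpha, J)
  if (length(alpha) != J || any(alpha <= 0)) {
    abort("`alpha` must be positive, scalar or one value per nutrient.")
  }
  n <- matrix(0, J, J)
  if (length(h) > 1) {
    for (t in seq_len(length(h) - 1)) n[h[t], h[t + 1]] <- n[h[t], h[t + 1]] + 1
  }
  a <- alpha + n[h[length(h)], ]
  new_predictive(a / sum(a), tr$alphabet)
}

new_predictive <- function(p, alphabet) {
  p <- as.numeric(p)
  structure(setNames(p, unclass(alphabet)), class = "predictive_dist")
}

#' @export
print.predictive_dist <- function(x, ...) {
  cat("<predictive_dist>\n")
  print(round(unclass(x), 4))
  invisible(x)
}
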