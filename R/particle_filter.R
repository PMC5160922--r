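#' Initialize a particle ensemble
#'
#' Each particle is a hidden-regime hypothesis `{s, S, C}`: a current switch
#' state plus private transition-count matrices accumulated along the
#' particle's own trajectory. Transition probabilities never appear explicitly
#' (they are integrated out analytically), so the counts are the complete
#' sufficient statistics. Particles start with regimes drawn from the prior on
#' the initial switch state, zero counts, and uniform weights.
#'
#' @param spec A [model_spec()].
#' @param n_particles Number of particles (default 200).
#' @param seed Optional integer seed.
#' @return A `pf_ensemble` object.
#' @examples
#' init_ensemble(model_spec(), n_particles = 100, seed = 1)
#' @export
init_ensemble <- function(spec, n_particles = 200, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is_count(n_particles)) abort("`n_particles` must be a positive integer.")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_particles)
  prior <- spec$alpha_s1 / sum(spec$alpha_s1)
  structure(
    list(
      spec = spec, n = n,
      s = sample_rows(matrix(prior, n, spec$K, byrow = TRUE)),
      S = array(0, dim = c(n, spec$K, spec$K)),
      C = array(0, dim = c(n, spec$J, spec$J, spec$K)),
      w = rep(1 / n, n),
      t = 0L
    ),
    class = "pf_ensemble"
  )
}

#' @export
print.pf_ensemble <- function(x, ...) {
  cat(sprintf("<pf_ensemble> %d particles, t = %d, ESS = %.1f\n",
              x$n, x$t, effective_sample_size(x)))
  invisible(x)
}

#' Effective sample size of a particle ensemble
#'
#' `1 / sum(w^2)`: ranges from 1 (fully degenerate) to N (uniform weights).
#' Used as the default resampling trigger.
#'
#' @param ensemble A `pf_ensemble`.
#' @return A number in `[1, N]`.
#' @export
effective_sample_size <- function(ensemble) 1 / sum(ensemble$w^2)

# N x K matrix of collapsed switch-transition predictive rows, one per
# particle, each conditioned on the particle's own current state and counts.
switch_prob_matrix <- function(ens) {
  spec <- ens$spec
  n <- ens$n
  a <- matrix(spec$alpha_s_other, n, spec$K)
  a[cbind(seq_len(n), ens$s)] <- spec$alpha_s_self
  for (j in seq_len(spec$K)) {
    a[, j] <- a[, j] + ens$S[cbind(seq_len(n), ens$s, j)]
  }
  a / rowSums(a)
}

# N x J matrix of collapsed nutrient predictive rows P(. | c_prev, s_vec[i]).
nutrient_prob_matrix <- function(ens, c_prev, s_vec = ens$s) {
  spec <- ens$spec
  n <- ens$n
  a <- matrix(spec$alpha_c, n, spec$J)
  for (j in seq_len(spec$J)) {
    a[, j] <- a[, j] + ens$C[cbind(seq_len(n), c_prev, j, s_vec)]
  }
  a / rowSums(a)
}

#' Particle-filter prediction step
#'
#' Advances every particle's hidden regime one step: a new switch state is
#' drawn from the particle's own collapsed regime-transition predictive, and
#' the sampled transition is then recorded into the particle's S counts (so
#' each draw conditions only on strictly past events). Weights are unchanged.
#'
#' @param ensemble A `pf_ensemble`.
#' @return The advanced ensemble.
#' @export
predict_step <- function(ensemble) {
  probs <- switch_prob_matrix(ensemble)
  s_new <- sample_rows(probs)
  idx <- cbind(seq_len(ensemble$n), ensemble$s, s_new)
  ensemble$S[idx] <- ensemble$S[idx] + 1
  ensemble$s <- s_new
  ensemble
}

#' Particle-filter updating step
#'
#' Reweights each particle by the collapsed likelihood of the observed
#' nutrient transition under the particle's current regime,
#' \eqn{w \propto P(C_{t+1} = c_{obs} | C_t = c_{prev}, S_{t+1} = s)},
#' renormalizes, and then records the observed transition into the particle's
#' C counts under its regime.
#'
#' @param ensemble A `pf_ensemble` (after the prediction step for this time
#'   step).
#' @param c_prev,c_obs Previous and observed nutrient (index or label).
#' @return The reweighted ensemble.
#' @export
update_step <- function(ensemble, c_prev, c_obs) {
  spec <- ensemble$spec
  c_prev <- nutrient_index(c_prev, spec$alphabet)
  c_obs <- nutrient_index(c_obs, spec$alphabet)
  lik <- nutrient_prob_matrix(ensemble, c_prev)[, c_obs]
  w <- ensemble$w * lik
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    abort("Internal error: all particle weights vanished during the update.")
  }
  ensemble$w <- w / total
  idx <- cbind(seq_len(ensemble$n), c_prev, c_obs, ensemble$s)
  ensemble$C[idx] <- ensemble$C[idx] + 1
  ensemble$t <- ensemble$t + 1L
  ensemble
}

#' Systematic resampling
#'
#' Draws N offspring particles in proportion to the weights using a single
#' uniform offset (systematic scheme, so each particle's copy count is the
#' floor or ceiling of N times its weight), copies their sufficient
#' statistics, and resets the weights to uniform.
#'
#' @param ensemble A `pf_ensemble` with normalized weights.
#' @return The resampled ensemble.
#' @export
resample <- function(ensemble) {
  n <- ensemble$n
  anc <- systematic_ancestors(ensemble$w, n)
  ensemble$s <- ensemble$s[anc]
  ensemble$S <- ensemble$S[anc, , , drop = FALSE]
  ensemble$C <- ensemble$C[anc, , , , drop = FALSE]
  ensemble$w <- rep(1 / n, n)
  ensemble
}

systematic_ancestors <- function(w, n) {
  u <- (runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(w) / sum(w)) + 1L
}

#' Posterior predictive estimate from a particle ensemble
#'
#' The weighted particle average of
#' \eqn{\sum_{s'} P(S_{t+1} = s' | s_t) P(C_{t+1} = c | C_t = c_{prev}, s')},
#' with both factors given by the particle's own collapsed counts. This
#' marginalizes the next regime analytically rather than using the sampled
#' one, which lowers Monte-Carlo variance.
#'
#' @param ensemble A `pf_ensemble`.
#' @param c_prev The current (most recently observed) nutrient.
#' @return A named probability vector over the next nutrient.
#' @export
predictive_estimate <- function(ensemble, c_prev) {
  spec <- ensemble$spec
  c_prev <- nutrient_index(c_prev, spec$alphabet)
  sw <- switch_prob_matrix(ensemble)
  p <- matrix(0, ensemble$n, spec$J)
  for (s_next in seq_len(spec$K)) {
    p <- p + sw[, s_next] * nutrient_prob_matrix(ensemble, c_prev,
                                                 s_vec = rep(s_next, ensemble$n))
  }
  new_predictive(colSums(p * ensemble$w), spec$alphabet)
}

#' Run the particle filter along a nutrient history
#'
#' Sequentially processes the observations \eqn{C_1..C_T} (given \eqn{C_0}):
#' before each observation the one-step-ahead posterior predictive estimate is
#' emitted, then particles are advanced (prediction step), reweighted against
#' the observation (updating step), and resampled when the effective sample
#' size falls below `ess_frac * N` (or after every step with
#' `resample_mode = "always"`). The initial regime draw from the prior serves
#' as \eqn{S_1}, paired with the first transition \eqn{C_0 \to C_1}, so no
#' regime transition is sampled for the first observation.
#'
#' @param history Observations \eqn{C_0..C_T} (trace tibble, factor, or index
#'   vector), length at least 2.
#' @param spec A [model_spec()].
#' @param n_particles Number of particles (default 200).
#' @param seed Integer seed; (spec, history, n_particles, seed) fully
#'   determine the output.
#' @param resample_mode `"ess"` (default) or `"always"`.
#' @param ess_frac Resampling threshold as a fraction of N (default 0.5).
#'
#' @return A `pf_filter` object: a tibble with one row per observation
#'   (`t`, one `p_<nutrient>` column per nutrient holding the predictive
#'   probability emitted before seeing that observation, and `ess` measured
#'   after the update), with the final ensemble attached as attribute
#'   `"ensemble"`.
#' @examples
#' env <- sample_meta_env(two_state_glu_gal_spec(0.9, 0.1), 30, seed = 1)
#' filter_sequence(env, model_spec(), n_particles = 100, seed = 2)
#' @export
filter_sequence <- function(history, spec, n_particles = 200, seed = NULL,
                            resample_mode = c("ess", "always"),
                            ess_frac = 0.5) {
  stopifnot(inherits(spec, "model_spec"))
  resample_mode <- match.arg(resample_mode)
  h <- trace_indices(history, spec$alphabet)$idx
  if (length(h) < 2) abort("`history` must contain at least two observations.")
  if (!is.null(seed)) set.seed(seed)
  ens <- init_ensemble(spec, n_particles)
  n_obs <- length(h) - 1
  pred <- matrix(0, n_obs, spec$J)
  ess_out <- numeric(n_obs)
  for (t in seq_len(n_obs)) {
    pred[t, ] <- predictive_estimate(ens, h[t])
    if (t > 1) ens <- predict_step(ens)
    ens <- update_step(ens, h[t], h[t + 1])
    ess_out[t] <- effective_sample_size(ens)
    if (resample_mode == "always" || ess_out[t] < ess_frac * ens$n) {
      ens <- resample(ens)
    }
  }
  out <- tibble(t = seq_len(n_obs))
  for (j in seq_len(spec$J)) {
    out[[paste0("p_", unclass(spec$alphabet)[j])]] <- pred[, j]
  }
  out$ess <- ess_out
  class(out) <- c("pf_filter", class(out))
  attr(out, "ensemble") <- ens
  attr(out, "spec") <- spec
  out
}
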