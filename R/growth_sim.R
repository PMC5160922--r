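#' Growth-model parameters
#'
#' Populations grow exponentially when tuned to the nutrient actually present
#' and not at all when mismatched (mismatched growth rate 0). Actions take
#' effect with a lag of `lag_k` steps: a commitment made at time t changes
#' growth at time t + k. Rates are e-fold rates per unit time (the population
#' multiplies by `exp(rate * dt)` per matched step); use
#' [doublings_to_efolds()] to convert doublings-per-hour measurements.
#'
#' Default rates encode the empirical regularity that glucose supports roughly
#' twice the galactose growth rate, with galactose and maltose comparable.
#'
#' @param rates Named per-nutrient matched growth rates.
#' @param lag_k Action lag in steps (default 1).
#' @param initial_pop Initial population size (default 1).
#' @param dt Step duration in arbitrary time units (default 1).
#' @return A `growth_params` object.
#' @export
growth_params <- function(rates = c(Glu = 0.6, Gal = 0.3, Mal = 0.3),
                          lag_k = 1, initial_pop = 1, dt = 1) {
  if (any(rates < 0)) abort("Growth rates must be nonnegative.")
  if (!is_count(lag_k)) abort("`lag_k` must be a positive integer.")
  if (initial_pop <= 0) abort("`initial_pop` must be positive.")
  structure(list(rates = rates, lag_k = as.integer(lag_k),
                 initial_pop = initial_pop, dt = dt),
            class = "growth_params")
}

#' Convert doublings per unit time to e-fold rates
#'
#' @param x Rate in doublings per unit time.
#' @return Rate in e-folds per unit time (`x * log(2)`).
#' @export
doublings_to_efolds <- function(x) x * log(2)

# Match the parameter rate vector to an alphabet, by name where available.
match_rates <- function(params, alphabet) {
  labels <- unclass(alphabet)
  r <- params$rates
  if (!is.null(names(r)) && all(labels %in% names(r))) {
    return(as.numeric(r[labels]))
  }
  if (length(r) < length(labels)) {
    abort("`rates` must provide a growth rate for every nutrient.")
  }
  as.numeric(r[seq_along(labels)])
}

#' Simulate population growth under a policy
#'
#' Walks a nutrient trace forward: at each time t the policy commits an
#' action using only information available at t (the last observed nutrient,
#' or for posterior-predictive policies the particle filter's online
#' predictive estimate), and the population's growth at t + k reflects that
#' commitment. Winner-take-all populations multiply by `exp(rate * dt)` when
#' matched and by 1 when mismatched; bet-hedging populations grow as the
#' fraction-weighted sum, with fractions re-allocated every step
#' (infinite-population limit).
#'
#' @param env A `nutrient_trace` (the realized environment).
#' @param policy A [policy_spec()] or a policy name.
#' @param params A [growth_params()].
#' @param spec Optional [model_spec()] for posterior-predictive policies
#'   (defaults to a K = 2 model over the trace's alphabet).
#' @param n_particles Particle count for online inference (default 200).
#' @param seed Integer seed driving both inference and any policy randomness.
#' @param beliefs Optional precomputed T x J matrix of one-step-ahead
#'   predictive probabilities (row t = belief about the nutrient at time t);
#'   supplying it lets several policies share one filter run.
#'
#' @return A `growth_trace` tibble: `t`, `nutrient`, `action`, `pop`.
#' @examples
#' env <- sample_meta_env(two_state_glu_gal_spec(0.9, 0.1), 50, seed = 1)
#' tr <- simulate_growth(env, policy_spec("plastic"), growth_params(), seed = 1)
#' estimate_growth_rate(tr)
#' @export
simulate_growth <- function(env, policy, params = growth_params(),
                            spec = NULL, n_particles = 200, seed = NULL,
                            beliefs = NULL) {
  if (is.character(policy)) policy <- policy_spec(policy)
  stopifnot(inherits(policy, "policy_spec"), inherits(params, "growth_params"))
  tr <- trace_indices(env)
  h <- tr$idx
  alphabet <- tr$alphabet
  J <- length(alphabet)
  k <- params$lag_k
  n_steps <- length(h) - 1
  if (n_steps <= k) abort("`env` must be longer than the action lag.")
  rates <- match_rates(params, alphabet)
  if (policy_uses_belief(policy) && k != 1) {
    abort("Posterior-predictive policies are defined for lag_k = 1 only.")
  }
  if (policy_uses_belief(policy) && is.null(beliefs)) {
    if (is.null(spec)) {
      spec <- model_spec(K = 2, J = J, labels = unclass(alphabet))
    }
    pf <- filter_sequence(h, spec, n_particles = n_particles,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
    beliefs <- as.matrix(pf[, paste0("p_", unclass(alphabet))])
  }
  if (!is.null(seed)) set.seed(derive_seed(seed, 2))
  pop <- numeric(n_steps + 1)
  pop[1] <- params$initial_pop
  action_lab <- rep(NA_character_, n_steps + 1)
  grow <- exp(rates * params$dt)
  for (u in seq_len(n_steps)) {
    if (u < k) {          # no commitment has matured yet
      pop[u + 1] <- pop[u]
      next
    }
    t_commit <- u - k     # decision time (0-based)
    a <- act(policy,
             belief = if (policy_uses_belief(policy)) beliefs[u, ] else NULL,
             last_observed = h[t_commit + 1],
             n_nutrients = J)
    c_u <- h[u + 1]
    if (a$kind == "tune") {
      action_lab[u + 1] <- unclass(alphabet)[a$nutrient]
      pop[u + 1] <- pop[u] * if (a$nutrient == c_u) grow[c_u] else 1
    } else {
      action_lab[u + 1] <- "hedge"
      f <- a$fractions
      mult <- sum(f * ifelse(seq_len(J) == c_u, grow, 1))
      pop[u + 1] <- pop[u] * mult
    }
  }
  out <- tibble(
    t = 0:n_steps,
    nutrient = factor(unclass(alphabet)[h], levels = unclass(alphabet)),
    action = action_lab,
    pop = pop
  )
  class(out) <- c("growth_trace", class(out))
  attr(out, "policy") <- policy$name
  attr(out, "dt") <- params$dt
  out
}

#' Estimate the realized growth rate of a population trace
#'
#' Fits a smoothing spline to log population size over time and summarizes
#' its first derivative. `method = "max"` (the default) returns the maximum
#' fitted derivative - the "exponential phase" rate, the readout used for
#' optical-density growth curves with a single exponential phase.
#' `method = "mean"` returns the derivative averaged over the run, the
#' realized long-run rate; this is the appropriate fitness summary in
#' changing environments, where growth alternates between matched bursts and
#' mismatched stalls and the maximum would reward burstiness rather than
#' overall performance. With fewer than 8 time points, falls back to the
#' least-squares slope of log population with a warning.
#'
#' @param trace A `growth_trace` tibble (or any data frame with `t` and
#'   `pop` columns).
#' @param method `"max"` or `"mean"` (see above).
#' @return The estimated growth rate (e-folds per unit time).
#' @export
estimate_growth_rate <- function(trace, method = c("max", "mean")) {
  stopifnot(is.data.frame(trace), all(c("t", "pop") %in% names(trace)))
  method <- match.arg(method)
  x <- as.numeric(trace$t)
  y <- log(as.numeric(trace$pop))
  if (any(!is.finite(y))) abort("Population sizes must be positive.")
  slope <- function() unname(coef(lm(y ~ x))[2])
  if (length(x) < 8) {
    warn("Fewer than 8 time points: using the least-squares slope of log population.")
    return(slope())
  }
  fit <- tryCatch(smooth.spline(x, y), error = function(e) NULL)
  if (is.null(fit)) return(slope())
  d <- predict(fit, x = x, deriv = 1)$y
  if (method == "max") max(d) else mean(d)
}

#' Compare growth policies in a meta-changing environment
#'
#' Simulates `n_sims` independent environment realizations and runs every
#' policy on each realization (environments are shared across policies within
#' a replicate, a common-random-numbers design that tightens the comparison).
#' Posterior-predictive and bet-hedging posterior-predictive policies share
#' one particle-filter run per replicate. Per policy, reports the mean
#' realized growth rate and a percentile bootstrap confidence interval over
#' the replicate rates.
#'
#' @param meta_spec A `meta_env_spec`.
#' @param policies Character vector of policy names or list of
#'   [policy_spec()]s.
#' @param params A [growth_params()].
#' @param n_sims Number of replicate environments (default 20).
#' @param horizon Environment length in steps (default 200).
#' @param seed Integer root seed; all replicate and policy randomness derives
#'   from it.
#' @param spec Optional inference [model_spec()].
#' @param n_particles Particle count (default 200).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param rate_method Growth-rate readout per replicate (see
#'   [estimate_growth_rate()]); defaults to `"mean"`, the realized long-run
#'   rate, which is the fitness quantity policies compete on.
#'
#' @return A `policy_comparison`: a tibble with `policy`, `mean_rate`,
#'   `ci_lo`, `ci_hi`, `n_sims`, with the per-replicate rate matrix attached
#'   as attribute `"rates"`.
#' @examples
#' \donttest{
#' cmp <- compare_policies(two_state_glu_gal_spec(0.9, 0.1),
#'                         c("posterior_predictive", "plastic", "constant"),
#'                         n_sims = 5, horizon = 60, seed = 1)
#' cmp
#' }
#' @export
compare_policies <- function(meta_spec, policies = c("posterior_predictive",
                                                     "plastic", "random",
                                                     "constant"),
                             params = growth_params(), n_sims = 20,
                             horizon = 200, seed = NULL, spec = NULL,
                             n_particles = 200, n_boot = 10000, conf = 0.95,
                             rate_method = c("mean", "max")) {
  rate_method <- match.arg(rate_method)
  stopifnot(inherits(meta_spec, "meta_env_spec"))
  if (n_sims < 2) abort("`n_sims` must be at least 2.")
  if (is.character(policies)) {
    policies <- setNames(lapply(policies, policy_spec), policies)
  }
  if (is.null(names(policies))) {
    names(policies) <- vapply(policies, function(p) p$name, character(1))
  }
  J <- length(meta_spec$alphabet)
  if (is.null(spec)) {
    spec <- model_spec(K = 2, J = J, labels = unclass(meta_spec$alphabet))
  }
  need_beliefs <- any(vapply(policies, policy_uses_belief, logical(1)))
  rates <- matrix(0, n_sims, length(policies),
                  dimnames = list(NULL, names(policies)))
  for (i in seq_len(n_sims)) {
    env <- sample_meta_env(meta_spec, horizon,
                           seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    beliefs <- NULL
    if (need_beliefs) {
      pf <- filter_sequence(env, spec, n_particles = n_particles,
                            seed = if (is.null(seed)) NULL else
                              derive_seed(seed, 10000 + i))
      beliefs <- as.matrix(pf[, paste0("p_", unclass(meta_spec$alphabet))])
    }
    for (p in seq_along(policies)) {
      # per-policy stream keyed by name, so ordering never matters
      key <- sum(utf8ToInt(names(policies)[p]))
      tr <- simulate_growth(env, policies[[p]], params, spec = spec,
                            beliefs = beliefs,
                            seed = if (is.null(seed)) NULL else
                              derive_seed(seed, 20000 + i * 1000 + key))
      rates[i, p] <- estimate_growth_rate(tr, method = rate_method)
    }
  }
  if (!is.null(seed)) set.seed(derive_seed(seed, 999))
  lo <- (1 - conf) / 2
  boot_idx <- matrix(sample.int(n_sims, n_sims * n_boot, replace = TRUE),
                     nrow = n_boot)
  ci <- apply(rates, 2, function(r) {
    boot_means <- rowMeans(matrix(r[boot_idx], nrow = n_boot))
    quantile(boot_means, c(lo, 1 - lo), names = FALSE)
  })
  out <- tibble(
    policy = names(policies),
    mean_rate = colMeans(rates),
    ci_lo = ci[1, ],
    ci_hi = ci[2, ],
    n_sims = as.integer(n_sims)
  )
  class(out) <- c("policy_comparison", class(out))
  attr(out, "rates") <- rates
  attr(out, "horizon") <- horizon
  out
}
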