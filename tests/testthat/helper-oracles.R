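# Independent oracles, coded along different routes than the package:
# marginal likelihoods via log-gamma functions instead of sequential
# Polya-urn products, Dirichlet posteriors via direct Monte-Carlo.

# log Dirichlet-multinomial marginal likelihood of a count vector n under
# prior alpha: log [ Gamma(sum a) / Gamma(sum a + sum n) * prod Gamma(a+n)/Gamma(a) ]
ldirmult <- function(n, alpha) {
  lgamma(sum(alpha)) - lgamma(sum(alpha) + sum(n)) +
    sum(lgamma(alpha + n) - lgamma(alpha))
}

# Exact posterior predictive by brute-force enumeration of switch-state
# trajectories, scoring each trajectory by closed-form marginal likelihoods
# of its count tables (not by sequential predictive products).
oracle_posterior_predictive <- function(h, spec) {
  K <- spec$K; J <- spec$J
  n_trans <- length(h) - 1
  a_s_row <- function(i) {
    a <- rep(spec$alpha_s_other, K); a[i] <- spec$alpha_s_self; a
  }
  score <- function(s_path, h_ext) {
    # joint marginal likelihood of (s_path, transitions of h_ext)
    nt <- length(h_ext) - 1
    S <- matrix(0, K, K); C <- array(0, c(J, J, K))
    for (t in seq_len(nt)) {
      if (t > 1) S[s_path[t - 1], s_path[t]] <- S[s_path[t - 1], s_path[t]] + 1
      C[h_ext[t], h_ext[t + 1], s_path[t]] <- C[h_ext[t], h_ext[t + 1], s_path[t]] + 1
    }
    lp <- log(spec$alpha_s1[s_path[1]] / sum(spec$alpha_s1))
    for (i in seq_len(K)) lp <- lp + ldirmult(S[i, ], a_s_row(i))
    for (k in seq_len(K)) for (i in seq_len(J)) {
      lp <- lp + ldirmult(C[i, , k], rep(spec$alpha_c, J))
    }
    lp
  }
  # unnormalized P(h, c_next) = sum over extended trajectories
  paths_ext <- as.matrix(expand.grid(rep(list(seq_len(K)), n_trans + 1)))
  joint_next <- vapply(seq_len(J), function(c_next) {
    tot <- -Inf
    for (r in seq_len(nrow(paths_ext))) {
      lp <- score(paths_ext[r, ], c(h, c_next))
      tot <- max(tot, lp) + log1p(exp(min(tot, lp) - max(tot, lp)))
    }
    tot
  }, numeric(1))
  p <- exp(joint_next - max(joint_next))
  p / sum(p)
}

# Monte-Carlo estimate of the Dirichlet-posterior mean of one component:
# the predictive probability of outcome j after counts n under prior alpha.
mc_dirichlet_predictive <- function(n, alpha, j, n_draws = 20000) {
  a <- alpha + n
  draws <- matrix(rgamma(n_draws * length(a), shape = rep(a, each = n_draws)),
                  nrow = n_draws)
  draws <- draws / rowSums(draws)
  est <- mean(draws[, j])
  se <- sd(draws[, j]) / sqrt(n_draws)
  list(est = est, se = se)
}

# Stationary distribution of a row-stochastic matrix via eigen-decomposition.
stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Mean run lengths of each symbol in an integer sequence.
mean_run_length <- function(x, value) {
  r <- rle(x)
  mean(r$lengths[r$values == value])
}
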