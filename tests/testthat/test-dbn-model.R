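test_that("collapsed switch predictive matches the Dirichlet-multinomial ratio", {
  sp <- model_spec()
  st <- count_stats(sp)
  # zero counts, flat prior: uniform
  sp_flat <- model_spec(alpha_s_self = 1)
  expect_equal(collapsed_switch_prob(st, sp_flat, 1), c(0.5, 0.5))
  # zero counts, sticky prior (self 2, other 1): 2/3 stay
  expect_equal(collapsed_switch_prob(st, sp, 1, 1), 2 / 3)
  expect_equal(collapsed_switch_prob(st, sp, 2, 2), 2 / 3)
  # S = [[3, 1], [0, 0]], flat prior: P(1 -> 1) = 4/6
  st$S[1, ] <- c(3, 1)
  expect_equal(collapsed_switch_prob(st, sp_flat, 1, 1), 4 / 6)
  expect_equal(sum(collapsed_switch_prob(st, sp, 1)), 1)
})

test_that("collapsed nutrient predictive matches the ratio and normalizes", {
  sp <- model_spec()
  st <- count_stats(sp)
  expect_equal(collapsed_nutrient_prob(st, sp, 1, 1, 1), 0.5)
  st$C[1, 2, 1] <- 2
  expect_equal(collapsed_nutrient_prob(st, sp, 1, 2, 1), 3 / 4)
  # random counts: rows always sum to 1
  set.seed(1)
  for (r in 1:10) {
    st$C[, , ] <- rpois(length(st$C), 3)
    expect_equal(sum(collapsed_nutrient_prob(st, sp, sample(2, 1),
                                             s = sample(2, 1))), 1)
  }
})

test_that("collapsed predictives equal Monte-Carlo Dirichlet posterior integrals", {
  sp <- model_spec()
  set.seed(20)
  for (r in 1:10) {
    st <- count_stats(sp)
    st$S[, ] <- rpois(4, 4)
    st$C[, , ] <- rpois(8, 4)
    i <- sample(2, 1); j <- sample(2, 1); s <- sample(2, 1)
    a_s <- c(1, 1); a_s[i] <- 2
    mc <- mc_dirichlet_predictive(st$S[i, ], a_s, j)
    expect_lt(abs(collapsed_switch_prob(st, sp, i, j) - mc$est), 3 * mc$se + 1e-12)
    mc2 <- mc_dirichlet_predictive(st$C[i, , s], c(1, 1), j)
    expect_lt(abs(collapsed_nutrient_prob(st, sp, i, j, s) - mc2$est),
              3 * mc2$se + 1e-12)
  }
})

test_that("prior sampling is reproducible and matches its drawn parameters", {
  sp <- model_spec()
  a <- sample_from_prior(sp, 50, seed = 4)
  b <- sample_from_prior(sp, 50, seed = 4)
  expect_identical(a, b)

  # long trace: empirical nutrient transitions under each regime match the
  # drawn parameter vectors within binomial error
  tr <- sample_from_prior(sp, 8000, seed = 5)
  pars <- attr(tr, "params")
  h <- as.integer(tr$nutrient)
  sw <- tr$switch_state[-1]
  for (k in 1:2) for (i in 1:2) {
    idx <- which(h[-length(h)] == i & sw == k)
    if (length(idx) < 100) next
    phat <- mean(h[idx + 1] == 1)
    p <- pars$pi_c[i, 1, k]
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / length(idx)) + 0.01)
  }

  # K = 1, symmetric priors: marginal initial nutrient is uniform over seeds
  first <- vapply(1:400, function(sd) {
    as.integer(sample_from_prior(model_spec(K = 1), 1, seed = sd)$nutrient)[1]
  }, integer(1))
  expect_lt(abs(mean(first == 1) - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("exact enumeration agrees with an independent marginal-likelihood oracle", {
  sp <- model_spec()
  for (h in list(c(1, 2, 1, 2), c(1, 1, 2, 1, 1, 2), c(2, 2, 2), c(2, 1))) {
    expect_equal(as.numeric(exact_posterior_predictive(h, sp)),
                 oracle_posterior_predictive(h, sp), tolerance = 1e-10)
  }
  sp3 <- model_spec(K = 3, J = 3)
  expect_equal(as.numeric(exact_posterior_predictive(c(1, 2, 3, 1), sp3)),
               oracle_posterior_predictive(c(1, 2, 3, 1), sp3),
               tolerance = 1e-10)
})

test_that("exact predictive handles trivial histories and enforces the cap", {
  sp <- model_spec()
  # empty history: prior predictive over the initial nutrient
  expect_equal(as.numeric(exact_posterior_predictive(integer(0), sp)),
               c(0.5, 0.5))
  # single observation, no transitions observed yet
  expect_equal(as.numeric(exact_posterior_predictive(1, model_spec(K = 1))),
               c(0.5, 0.5))
  expect_error(exact_posterior_predictive(rep(1, 14), sp), "nfeasible")
})

test_that("the hidden state degenerates: K = 1 exact equals the flat model", {
  sp1 <- model_spec(K = 1)
  set.seed(2)
  for (r in 1:5) {
    h <- sample(2, 9, replace = TRUE)
    expect_equal(as.numeric(exact_posterior_predictive(h, sp1)),
                 as.numeric(flat_markov_posterior_predictive(h)))
  }
})

test_that("flat-model predictive counts transitions correctly", {
  # no transitions observed: uniform
  expect_equal(as.numeric(flat_markov_posterior_predictive(c(1))), c(0.5, 0.5))
  # [Glu, Glu, Gal, Glu]: n(Glu -> Glu) = 1, n(Glu -> Gal) = 1
  expect_equal(as.numeric(flat_markov_posterior_predictive(c(1, 1, 2, 1))),
               c(0.5, 0.5))
  # constant glucose of n transitions: P(Glu) = (n + 1) / (n + 2), increasing
  p <- vapply(1:8, function(n) {
    as.numeric(flat_markov_posterior_predictive(rep(1, n + 1)))[1]
  }, numeric(1))
  expect_equal(p, (1:8 + 1) / (1:8 + 2))
  expect_true(all(diff(p) > 0))
})

test_that("relabeling nutrients permutes the predictive identically", {
  sp <- model_spec()
  h <- c(1, 2, 2, 1, 2)
  swapped <- 3 - h
  p <- as.numeric(exact_posterior_predictive(h, sp))
  q <- as.numeric(exact_posterior_predictive(swapped, sp))
  expect_equal(p, rev(q), tolerance = 1e-12)
})

test_that("model and environment specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  sp <- model_spec(K = 2, J = 3, alpha_s_self = 2.5)
  write_model_spec(sp, path)
  sp2 <- read_model_spec(path)
  expect_equal(sp2$alpha_s_self, 2.5)
  expect_equal(sp2$J, 3L)

  write_env_spec(glu_gal_env_spec(0.7, 0.4), path)
  e <- read_env_spec(path)
  expect_s3_class(e, "markov_env_spec")
  expect_equal(unname(e$transition_matrix[1, 1]), 0.7)

  write_env_spec(two_state_glu_gal_spec(0.9, 0.1), path)
  m <- read_env_spec(path)
  expect_s3_class(m, "meta_env_spec")
  expect_equal(unname(m$switch_matrix[2, 1]), 0.1)
})
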