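test_that("degenerate Markov environments produce the forced sequences", {
  # absorbing glucose state
  tr <- sample_markov_env(glu_gal_env_spec(1, 1), horizon = 5, seed = 1)
  expect_equal(as.character(tr$nutrient), rep("Glu", 6))
  # deterministic alternation
  tr2 <- sample_markov_env(glu_gal_env_spec(0, 1), horizon = 4, seed = 1)
  expect_equal(as.character(tr2$nutrient), c("Glu", "Gal", "Glu", "Gal", "Glu"))
  expect_equal(tr2$t, 0:4)
})

test_that("non-stochastic matrices are rejected naming the offending row", {
  m <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, byrow = TRUE)
  expect_error(markov_env_spec(m), "row 1")
  expect_error(meta_env_spec(matrix(c(0.2, 0.9, 0.5, 0.5), 2, byrow = TRUE),
                             list(diag(2), diag(2))),
               "row 1")
})

test_that("sampling is reproducible and follows the transition matrix", {
  spec <- glu_gal_env_spec(0.5, 0.5)
  a <- sample_markov_env(spec, 100, seed = 42)
  b <- sample_markov_env(spec, 100, seed = 42)
  expect_identical(a, b)

  # empirical Glu->Glu frequency within 3 binomial SEs of 0.5 at T = 10000
  tr <- sample_markov_env(spec, 10000, seed = 7)
  h <- as.integer(tr$nutrient)
  from_glu <- which(h[-length(h)] == 1)
  phat <- mean(h[from_glu + 1] == 1)
  se <- sqrt(0.25 / length(from_glu))
  expect_lt(abs(phat - 0.5), 3 * se)
})

test_that("long-run transition frequencies pass a chi-square fit check", {
  spec <- glu_gal_env_spec(0.7, 0.4)
  reject <- vapply(1:10, function(sd) {
    tr <- sample_markov_env(spec, 5000, seed = sd)
    h <- as.integer(tr$nutrient)
    p <- vapply(1:2, function(i) {
      idx <- which(h[-length(h)] == i)
      obs <- tabulate(h[idx + 1], 2)
      suppressWarnings(
        stats::chisq.test(obs, p = spec$transition_matrix[i, ])$p.value)
    }, numeric(1))
    any(p < 0.001)
  }, logical(1))
  expect_lte(mean(reject), 0.05 + 1e-9)  # >= 95% of seeds not rejected
})

test_that("hidden regimes occupy time per the stationary distribution", {
  spec <- two_state_glu_gal_spec(0.8, 0.3)
  tr <- sample_meta_env(spec, 20000, seed = 3)
  sw <- tr$switch_state[-1]
  pi_hat <- mean(sw == 1)
  pi_exact <- stationary_dist(spec$switch_matrix)[1]
  expect_lt(abs(pi_hat - pi_exact), 0.02)

  # p1 = 0 (always leave periodic), p2 = 1 (always re-enter it):
  # the hidden regime alternates deterministically every step
  alt <- sample_meta_env(two_state_glu_gal_spec(0, 1), 10, seed = 1)
  expect_equal(alt$switch_state[-1], rep(c(1, 2), 5))
  # p2 = 0 makes the constant regime absorbing
  ab <- sample_meta_env(two_state_glu_gal_spec(0, 0), 10, seed = 1)
  expect_equal(ab$switch_state[-1], c(1, rep(2, 9)))

  # p1 = 1 from the periodic regime with exact alternation: pure periodic trace
  pure <- sample_meta_env(two_state_glu_gal_spec(1, 1, eps = 0), 8, seed = 1)
  expect_equal(as.character(pure$nutrient), rep(c("Glu", "Gal"), length.out = 9))
})

test_that("regime sojourn lengths are geometric with the specified means", {
  spec <- two_state_glu_gal_spec(0.95, 0.05)
  tr <- sample_meta_env(spec, 30000, seed = 11)
  sw <- tr$switch_state[-1]
  # mean sojourns 1/(1-p1) = 20 in periodic, 1/p2 = 20 in constant
  expect_lt(abs(mean_run_length(sw, 1) - 20) / 20, 0.15)
  expect_lt(abs(mean_run_length(sw, 2) - 20) / 20, 0.15)

  spec2 <- two_state_glu_gal_spec(0.5, 0.5)
  sw2 <- sample_meta_env(spec2, 30000, seed = 12)$switch_state[-1]
  expect_lt(abs(mean_run_length(sw2, 1) - 2), 0.1)
  expect_lt(abs(mean_run_length(sw2, 2) - 2), 0.1)
})

test_that("a single-regime meta environment behaves like its Markov spec", {
  m <- matrix(c(0.8, 0.2, 0.35, 0.65), 2, byrow = TRUE)
  meta <- meta_env_spec(matrix(1), list(m))
  markov <- markov_env_spec(m)
  run_stats <- function(h) c(mean_run_length(h, 1), mean_run_length(h, 2),
                             mean(h == 1))
  a <- run_stats(as.integer(sample_meta_env(meta, 20000, seed = 5)$nutrient))
  b <- run_stats(as.integer(sample_markov_env(markov, 20000, seed = 6)$nutrient))
  expect_lt(max(abs(a - b) / b), 0.05)
})

test_that("multinutrient archetypes realize their qualitative structure", {
  arch <- make_multinutrient_archetypes(0.9)
  expect_equal(unname(diag(arch$persistent$transition_matrix)), rep(0.9, 3))
  ch <- arch$chained$transition_matrix
  expect_gte(ch["Glu", "Gal"], 0.9)   # glucose signals upcoming galactose
  expect_gte(ch["Gal", "Mal"], 0.9)   # galactose signals persistent maltose
  expect_gte(ch["Mal", "Mal"], 0.9)

  # maltose run lengths in archetype 2 are geometric with mean 1/(1-persistence)
  tr <- sample_markov_env(arch$periodic_persistent, 30000, seed = 9)
  h <- as.integer(tr$nutrient)
  expect_lt(abs(mean_run_length(h, 3) - 10) / 10, 0.15)

  expect_error(make_multinutrient_archetypes(0.4), "0.5")
})

test_that("regime-schedule sampling follows the prescribed regimes", {
  me <- two_state_glu_gal_spec(0.5, 0.5, eps = 0)
  regimes <- rep(c(1, 2), each = 5)
  tr <- sample_regime_schedule(me, regimes, seed = 1)
  expect_equal(tr$switch_state[-1], regimes)
  # deterministic regimes: alternation then constant glucose
  expect_equal(as.character(tr$nutrient),
               c("Glu", "Gal", "Glu", "Gal", "Glu", "Gal",
                 rep("Glu", 5)))
})
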