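test_that("ensembles initialize from the prior with uniform weights", {
  sp <- model_spec()
  ens <- init_ensemble(sp, 200, seed = 1)
  expect_equal(ens$w, rep(1 / 200, 200))
  expect_true(all(ens$S == 0) && all(ens$C == 0))
  # prior over S_1 is symmetric: about half the particles start in regime 1
  frac <- mean(ens$s == 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 200))
  expect_identical(init_ensemble(sp, 200, seed = 1)$s, ens$s)
})

test_that("the prediction step samples from each particle's collapsed counts", {
  sp <- model_spec()
  # K = 1: state can never change
  e1 <- init_ensemble(model_spec(K = 1), 50, seed = 2)
  expect_equal(predict_step(e1)$s, rep(1L, 50))

  # fresh particles, sticky prior: P(stay) = 2/3
  set.seed(3)
  ens <- init_ensemble(sp, 4000, seed = 3)
  adv <- predict_step(ens)
  stay <- mean(adv$s == ens$s)
  expect_lt(abs(stay - 2 / 3), 3 * sqrt(2 / 9 / 4000))

  # S = [[10, 0], [0, 0]], s = 1, flat alpha: P(stay) = 11/12
  spf <- model_spec(alpha_s_self = 1)
  ens2 <- init_ensemble(spf, 4000, seed = 4)
  ens2$s <- rep(1L, ens2$n)
  ens2$S[, 1, 1] <- 10
  stay2 <- mean(predict_step(ens2)$s == 1)
  expect_lt(abs(stay2 - 11 / 12), 3 * sqrt(11 / 144 / 4000))

  # the sampled transition is recorded into S
  adv3 <- predict_step(init_ensemble(sp, 10, seed = 5))
  expect_equal(apply(adv3$S, 1, sum), rep(1, 10))
})

test_that("the updating step reweights by the collapsed nutrient likelihood", {
  sp <- model_spec()
  ens <- init_ensemble(sp, 20, seed = 6)
  # identical particles keep uniform weights
  upd <- update_step(ens, 1, 2)
  expect_equal(upd$w, rep(1 / 20, 20))
  expect_equal(sum(upd$w), 1)

  # counts favoring the observation under regime 1 pull weight toward it
  ens2 <- init_ensemble(sp, 2, seed = 7)
  ens2$s <- c(1L, 2L)
  ens2$C[1, 1, 2, 1] <- 5          # particle 1, Glu -> Gal seen 5x under s = 1
  upd2 <- update_step(ens2, 1, 2)
  expect_gt(upd2$w[1], upd2$w[2])
  # unnormalized weights equal collapsed_nutrient_prob outputs
  st <- count_stats(sp); st$C[1, 2, 1] <- 5
  w1 <- collapsed_nutrient_prob(st, sp, 1, 2, 1)
  w2 <- collapsed_nutrient_prob(count_stats(sp), sp, 1, 2, 2)
  expect_equal(upd2$w, c(w1, w2) / (w1 + w2))
  # the observed transition is recorded under each particle's regime
  expect_equal(upd2$C[1, 1, 2, 1], 6)
  expect_equal(upd2$C[2, 1, 2, 2], 1)
})

test_that("systematic resampling copies by value with floor/ceiling counts", {
  sp <- model_spec()
  # one weight = 1: all offspring copy that particle
  ens <- init_ensemble(sp, 8, seed = 8)
  ens$C[3, 1, 2, 1] <- 7
  ens$w <- c(0, 0, 1, 0, 0, 0, 0, 0)
  rs <- resample(ens)
  expect_equal(rs$w, rep(1 / 8, 8))
  expect_true(all(rs$C[, 1, 2, 1] == 7))
  # deep copy: mutating one offspring leaves its siblings untouched
  rs$C[1, 1, 2, 1] <- 99
  expect_equal(rs$C[2, 1, 2, 1], 7)

  # copy counts are floor(N w) or ceiling(N w) for every weight vector
  set.seed(9)
  for (r in 1:20) {
    n <- sample(2:8, 1)
    w <- rgamma(n, 1); w <- w / sum(w)
    ens2 <- init_ensemble(sp, n)
    ens2$s <- seq_len(n)  # tag particles by state index
    ens2$w <- w
    copies <- tabulate(resample(ens2)$s, n)
    expect_true(all(copies >= floor(n * w) & copies <= ceiling(n * w)))
  }
})

test_that("predictive estimates are exchangeable, normalized and degenerate correctly", {
  sp <- model_spec()
  ens <- init_ensemble(sp, 100, seed = 10)
  # fresh ensemble, symmetric priors: uniform
  expect_equal(as.numeric(predictive_estimate(ens, 1)), c(0.5, 0.5))

  # permuting particle order never changes the estimate
  h <- c(1, 2, 2, 1, 2, 2, 1)
  pf <- filter_sequence(h, sp, n_particles = 50, seed = 11)
  ens2 <- attr(pf, "ensemble")
  perm <- sample(ens2$n)
  ens3 <- ens2
  ens3$s <- ens2$s[perm]; ens3$w <- ens2$w[perm]
  ens3$S <- ens2$S[perm, , , drop = FALSE]
  ens3$C <- ens2$C[perm, , , , drop = FALSE]
  expect_equal(predictive_estimate(ens3, 2), predictive_estimate(ens2, 2))
  expect_equal(sum(predictive_estimate(ens2, 2)), 1)
})

test_that("with K = 1 the filter reproduces the flat Markov model exactly", {
  sp1 <- model_spec(K = 1)
  set.seed(12)
  h <- sample(2, 12, replace = TRUE)
  pf <- filter_sequence(h, sp1, n_particles = 5, seed = 13)
  for (t in 2:length(h)) {
    expect_equal(
      unname(as.matrix(pf[t - 1, c("p_Glu", "p_Gal")])[1, ]),
      as.numeric(flat_markov_posterior_predictive(h[1:(t - 1)])),
      tolerance = 1e-12
    )
  }
})

test_that("the filter is deterministic given (spec, history, N, seed)", {
  sp <- model_spec()
  h <- sample_meta_env(two_state_glu_gal_spec(0.9, 0.1), 40, seed = 14)
  a <- filter_sequence(h, sp, n_particles = 100, seed = 15)
  b <- filter_sequence(h, sp, n_particles = 100, seed = 15)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # weights normalized after every step (ESS is finite and <= N)
  expect_true(all(is.finite(a$ess) & a$ess <= 100 + 1e-9 & a$ess >= 1))
})

test_that("particle estimates converge to the exact enumeration oracle", {
  sp <- model_spec()
  tv <- function(N, sd) {
    h <- sample_markov_env(glu_gal_env_spec(0.3, 0.7), 6, seed = 1000 + sd)
    ex <- exact_posterior_predictive(h, sp)
    pf <- filter_sequence(h, sp, n_particles = N, seed = sd)
    est <- predictive_estimate(attr(pf, "ensemble"),
                               tail(as.integer(h$nutrient), 1))
    0.5 * sum(abs(est - ex))
  }
  med <- vapply(c(50, 500, 2000), function(N) {
    median(vapply(1:10, function(sd) tv(N, sd), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))  # strictly decreasing in N
  expect_lt(med[3], 0.02)
})

test_that("constant-glucose histories drive P(Glu) up monotonically", {
  sp <- model_spec()
  h <- rep(1, 25)
  pf <- filter_sequence(h, sp, n_particles = 400, seed = 16)
  p <- pf$p_Glu
  burn <- 3
  expect_true(all(diff(p[burn:length(p)]) > -0.05))
  expect_gt(tail(p, 1), 0.85)
})

test_that("always-resample mode runs and stays normalized", {
  sp <- model_spec()
  h <- sample_meta_env(two_state_glu_gal_spec(0.9, 0.1), 30, seed = 17)
  pf <- filter_sequence(h, sp, n_particles = 50, seed = 18,
                        resample_mode = "always")
  expect_equal(nrow(pf), 30)
  expect_true(all(abs(rowSums(as.matrix(pf[, c("p_Glu", "p_Gal")])) - 1) < 1e-9))
})
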