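statics <- static_params(v0 = 0, b_tau = 0.15, beta = 0.5)
state <- latent_state(b_v = 4, a = 1.5, tau0 = 0.3)

test_that("static log-likelihood is the plain sum of trial densities", {
  rec <- cached_session()
  expect_equal(static_loglik(rec[0, ], statics, state), 0)
  expect_equal(static_loglik(rec[1, , drop = FALSE], statics, state),
               dwfpt(rec$rt[1], rec$choice[1],
                     trial_drift(0, 4, validity_regressor(rec$bits[1], canon)),
                     1.5, trial_ndt(0.3, 0.15, rec$n_cues[1]), 0.5))
  # brute-force re-summation, one trial at a time
  brute <- 0
  for (i in seq_len(nrow(rec))) {
    v <- trial_drift(0, 4, validity_regressor(rec$bits[i], canon))
    tau <- trial_ndt(0.3, 0.15, rec$n_cues[i])
    brute <- brute + dwfpt(rec$rt[i], rec$choice[i], v, 1.5, tau, 0.5)
  }
  expect_equal(static_loglik(rec, statics, state), brute, tolerance = 1e-10)
})

test_that("particle filter collapses exactly to the static oracle at zero scales", {
  rec <- cached_session()
  pf <- particle_filter(rec, statics, noise_scales(0, 0, 0), state,
                        n_particles = 64, summaries = FALSE, seed = 2)
  expect_equal(pf$loglik, static_loglik(rec, statics, state),
               tolerance = 1e-10)
  expect_false(pf$degenerate)
  expect_true(all(pf$ess >= 1 & pf$ess <= 64))
})

test_that("filter runs are reproducible and report per-trial summaries", {
  rec <- cached_session()
  sc <- noise_scales(0.15, 0.02, 0.005)
  pf1 <- particle_filter(rec, statics, sc, init_prior(), 128, seed = 6)
  pf2 <- particle_filter(rec, statics, sc, init_prior(), 128, seed = 6)
  expect_identical(pf1$loglik, pf2$loglik)
  expect_identical(pf1$filtered, pf2$filtered)
  expect_equal(nrow(pf1$filtered), nrow(rec))
  expect_equal(nrow(pf1$path), nrow(rec))
  expect_true(all(pf1$filtered$b_v_q05 <= pf1$filtered$b_v_median &
                    pf1$filtered$b_v_median <= pf1$filtered$b_v_q95))
  expect_true(all(pf1$filtered$a_q05 >= latent_bounds()$a_min))
})

test_that("likelihood estimate matches quadrature over a diffuse initial state", {
  # scales zero, only b_v,1 uncertain: the marginal likelihood reduces to a
  # one-dimensional integral over the initial sensitivity
  rec <- cached_session()[1:50, ]
  init <- init_prior(b_v = c(2, 1), a = c(1.5, 0), tau0 = c(0.3, 0))
  ll_of_bv <- vapply(seq(-3, 9, by = 0.01), function(b) {
    static_loglik(rec, statics, latent_state(b, 1.5, 0.3))
  }, numeric(1))
  m <- max(ll_of_bv)
  quad <- m + log(sum(exp(ll_of_bv - m) *
                        dnorm(seq(-3, 9, by = 0.01), 2, 1)) * 0.01)
  lls <- vapply(1:20, function(i) {
    particle_filter(rec, statics, noise_scales(0, 0, 0), init,
                    2048, summaries = FALSE, seed = 100 + i)$loglik
  }, numeric(1))
  expect_lt(sd(lls), 1.0)
  expect_lt(abs(mean(lls) - quad), 3 * sd(lls) / sqrt(20) + 0.05)
})

test_that("likelihood estimator variance shrinks with more particles", {
  rec <- cached_session()
  sc <- noise_scales(0.15, 0.02, 0.005)
  v_small <- var(vapply(1:15, function(i) {
    particle_filter(rec, statics, sc, init_prior(), 512,
                    summaries = FALSE, seed = 200 + i)$loglik
  }, numeric(1)))
  v_big <- var(vapply(1:15, function(i) {
    particle_filter(rec, statics, sc, init_prior(), 4096,
                    summaries = FALSE, seed = 300 + i)$loglik
  }, numeric(1)))
  expect_lt(v_big, v_small)
})

test_that("the likelihood prefers the generating sensitivity over its sign flip", {
  agree <- vapply(1:20, function(i) {
    rec <- simulate_participant(canon, statics,
                                trajectory = flat_trajectory(246, 5, 1.5, 0.3),
                                seed = 700 + i)
    good <- particle_filter(rec, statics, noise_scales(0, 0, 0),
                            latent_state(5, 1.5, 0.3), 64,
                            summaries = FALSE, seed = 1)$loglik
    bad <- particle_filter(rec, statics, noise_scales(0, 0, 0),
                           latent_state(-5, 1.5, 0.3), 64,
                           summaries = FALSE, seed = 1)$loglik
    good > bad
  }, logical(1))
  expect_gte(sum(agree), 18)
})

test_that("filtered trajectories track a known rising sensitivity", {
  tr <- preset_trajectory("congruent", 246)
  rec <- simulate_participant(canon, statics, trajectory = tr, seed = 31)
  pf <- particle_filter(rec, statics, noise_scales(0.2, 0.02, 0.005),
                        init_prior(), 512, seed = 8)
  r <- cor(pf$filtered$b_v_mean, tr$b_v)
  expect_gt(r, 0.5)
  # and beats a prior-only (no-data) baseline in RMSE
  rmse_filter <- sqrt(mean((pf$filtered$b_v_median - tr$b_v)^2))
  rmse_prior <- sqrt(mean((0 - tr$b_v)^2))  # prior location for b_v
  expect_lt(rmse_filter, rmse_prior)
})

test_that("PMMH chains are seed-reproducible and fail loudly on impossible data", {
  rec <- cached_session()[1:60, ]
  cfg <- fit_config(n_particles = 64, n_iter = 80, burn_in = 30, seed = 5)
  f1 <- pmmh(rec, config = cfg)
  f2 <- pmmh(rec, config = cfg)
  expect_identical(f1$samples, f2$samples)
  expect_equal(nrow(f1$samples), 50)
  expect_length(f1$trajectories, sum(seq_len(50) %% cfg$traj_thin == 0))
  # rts far below any feasible non-decision time: initialization must error
  bad <- rec[1:5, ]
  bad$rt <- 0.001
  expect_error(pmmh(bad, config = cfg), "initialization failed")
})

test_that("posterior summaries aggregate medians per participant and condition", {
  samples <- data.frame(v0 = c(0.1, 0.2, 0.3), beta = c(0.4, 0.5, 0.6),
                        b_tau = c(0.1, 0.15, 0.2), sigma_v = c(0.1, 0.1, 0.4),
                        sigma_a = c(0, 0, 0), sigma_tau = c(0, 0, 0),
                        loglik = c(-1, -2, -3))
  trajs <- list(flat_trajectory(4, 1, 1.5, 0.3),
                flat_trajectory(4, 2, 1.4, 0.2),
                flat_trajectory(4, 6, 1.3, 0.1))
  rec <- data.frame(participant = 1, condition = "congruent")
  fits <- list(fake_fit(rec, samples, trajs),
               fake_fit(rec, samples, trajs),
               fake_fit(transform(rec, condition = "incongruent"),
                        samples, trajs))
  out <- posterior_summaries(fits)
  expect_equal(out$statics$b_tau, rep(0.15, 3))  # median of each column
  expect_equal(out$statics$v0, rep(0.2, 3))
  # per-trial medians over the three stored trajectories
  expect_equal(out$trajectory$b_v[out$trajectory$participant == 1],
               rep(2, 4))
  cong <- out$trajectory_by_condition
  expect_equal(cong$b_v_mean[cong$condition == "congruent"], rep(2, 4))
  expect_equal(nrow(cong), 8)  # 2 conditions x 4 trials
  # degenerate case: all samples identical reproduces that sample
  one <- samples[c(1, 1, 1), ]
  fit1 <- fake_fit(rec, one, list(trajs[[1]], trajs[[1]], trajs[[1]]))
  out1 <- posterior_summaries(list(fit1))
  expect_equal(out1$statics$v0, 0.1)
  expect_equal(out1$trajectory$b_v, rep(1, 4))
  expect_error(posterior_summaries(list()), "non-empty")
})
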