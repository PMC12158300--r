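# Transition estimation, the covariance loss, the fuzzy update and the
# session fit / alignment procedures.

test_that("estimate_transition solves the stated linear relation", {
  x <- random_obs(1)
  A_id <- estimate_transition(x, x)
  expect_lt(rel_frob(A_id, identity_trans()), 1e-10)
  A_2 <- estimate_transition(x, obs_scale(x, 2))
  expect_lt(rel_frob(A_2, transition_matrix(2 * diag(3), 2 * diag(4),
                                            2 * diag(3), 2 * diag(3))), 1e-10)
  for (seed in 1:10) {
    xp <- random_obs(seed)
    At <- random_trans(seed + 100)
    xc <- apply_transition(At, xp)
    expect_lt(rel_frob(estimate_transition(xp, xc), At), 1e-10)
  }
  z <- random_obs(2); z$mc[] <- 0
  expect_error(estimate_transition(z, random_obs(3)), "all-zero")
})

test_that("linearization has the documented fixed layout", {
  v <- linearize(identity_trans())
  expect_length(v, 43)
  expect_equal(sum(v), 3 + 4 + 3 + 3)
  expect_equal(unname(v[1:9]), as.vector(t(diag(3))))
  A <- random_trans(5)
  expect_lt(rel_frob(delinearize(linearize(A)), A), 1e-15)
  expect_equal(names(v)[1], "mc:C3:C3")
  expect_equal(names(v)[10], "loc:P7:P7")
})

test_that("f1 covariance loss is the mean element-wise variance", {
  A <- random_trans(1)
  expect_equal(f1_loss(list(A, A, A)), 0)
  B <- A; B$mc[1, 1] <- B$mc[1, 1] + 0.3
  expect_equal(f1_loss(list(A, B)), 0.3^2 / 2 / 43)
  C <- random_trans(2)
  expect_equal(f1_loss(list(A, B, C)), f1_loss(list(C, A, B)))
  # brute-force oracle on a larger set
  set.seed(3)
  ts <- lapply(1:6, function(i) random_trans(i + 10))
  V <- sapply(ts, linearize)
  expect_equal(f1_loss(ts), mean(apply(V, 1, var)), tolerance = 1e-14)
  expect_error(f1_loss(list(A)), "2 transitions")
})

test_that("fuzzy gain interpolates the rule table and respects bounds", {
  cfg <- pnda_config()
  expect_equal(fuzzy_gain(0, cfg), 1.0)
  expect_equal(fuzzy_gain(-10, cfg), 1.2)
  expect_equal(fuzzy_gain(10, cfg), 0.7)
  # at half the membership width the gain is the membership-weighted
  # mean of the adjacent categories
  w <- cfg$delta_width
  expect_equal(fuzzy_gain(w / 2, cfg), (0.5 * 1.0 + 0.5 * 0.7) / 1)
  expect_equal(fuzzy_gain(-w / 2, cfg), (0.5 * 1.0 + 0.5 * 1.2) / 1)
  cfg2 <- pnda_config(theta_gains = c(improving = 1.9, flat = 1, worsening = 0.1),
                      theta_bounds = c(0.6, 1.4))
  expect_equal(fuzzy_gain(-10, cfg2), 1.4)
  expect_equal(fuzzy_gain(10, cfg2), 0.6)
  expect_error(fuzzy_gain(NaN, cfg), "non-finite")
})

test_that("process-noise update follows the stated rule", {
  w <- random_obs(4)
  cfg1 <- pnda_config(theta_gains = c(improving = 1, flat = 1, worsening = 1))
  up <- update_process_noise(w, 0.5, cfg1)
  for (b in c("mc", "loc", "mc_loc", "mnet"))
    expect_equal(up[[b]], w[[b]])
  # scalar check of w_new = theta * w + b0
  w2 <- zero_observation(); w2$mc[1, 1] <- 0.1
  b0 <- zero_observation(); b0$mc[1, 1] <- 0.01
  cfg2 <- pnda_config(theta_gains = c(improving = 0.9, flat = 0.9, worsening = 0.9),
                      theta_bounds = c(0.8, 1.2))
  up2 <- update_process_noise(w2, 0, cfg2, b0)
  expect_equal(up2$mc[1, 1], 0.9 * 0.1 + 0.01)
})

test_that("a noiseless consistent chain converges immediately", {
  cfg <- sim_config(process_noise_sd = 0)
  for (seed in 1:5) {
    ch <- simulate_network_chain(cfg, "resting", seed = seed)
    fit <- pnda_fit_session(ch)
    expect_true(fit$converged)
    expect_lte(fit$iterations_used, 2)
    expect_lt(fit$f1_final, 1e-20)
    expect_lt(rel_frob(fit$consensus_A, ch$truth$A), 1e-8)
  }
})

test_that("noisy chains improve f1 and recover the generating transition", {
  cfg <- sim_config(process_noise_sd = 0.01)
  for (seed in 1:8) {
    ch <- simulate_network_chain(cfg, "resting", seed = seed)
    fit <- pnda_fit_session(ch)
    expect_lt(fit$f1_final, fit$f1_initial)
    expect_true(all(diff(fit$per_iteration_f1) <= 0))
    expect_lt(rel_frob(fit$consensus_A, ch$truth$A), 0.1)
  }
})

test_that("median recovery error decreases with the noise level", {
  errs <- sapply(c(0.02, 0.01, 0.005), function(sd) {
    cfg <- sim_config(process_noise_sd = sd)
    median(sapply(1:10, function(s) {
      ch <- simulate_network_chain(cfg, "resting", seed = s)
      rel_frob(pnda_fit_session(ch)$consensus_A, ch$truth$A)
    }))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("alignment reduces f2 for bias-offset session groups", {
  cfg <- sim_config(process_noise_sd = 0.01)
  off <- zero_observation()
  for (b in c("mc", "loc", "mc_loc", "mnet")) off[[b]][] <- 0.15
  cfgb <- sim_config(process_noise_sd = 0.01, state_offset = off)
  fits <- c(lapply(1:3, function(s)
              pnda_fit_session(simulate_network_chain(cfg, "resting", seed = 100 + s))),
            lapply(1:3, function(s)
              pnda_fit_session(simulate_network_chain(cfgb, "resting", seed = 200 + s))))
  f2_pre <- f2_loss(fits)
  aligned <- align_sessions(fits)
  expect_lt(f2_loss(aligned), f2_pre)
  # f2 is order-invariant
  expect_equal(f2_loss(fits[c(4, 2, 6, 1, 3, 5)]), f2_pre)
})

test_that("alignment of identical sessions is a fixed point", {
  ch <- simulate_network_chain(sim_config(process_noise_sd = 0.01), "NFT", seed = 3)
  fits <- list(pnda_fit_session(ch), pnda_fit_session(ch))
  expect_equal(f2_loss(fits), 0)
  aligned <- align_sessions(fits)
  expect_equal(f2_loss(aligned), 0)
  expect_equal(max(abs(unlist(unclass(aligned[[1]]$b0_final)))), 0)
  expect_warning(align_sessions(fits[1]), ">= 2 sessions")
})

test_that("fit serialization round-trips", {
  ch <- simulate_network_chain(sim_config(process_noise_sd = 0.01), "NFT", seed = 5)
  ch$session_id <- "S042"
  fit <- pnda_fit_session(ch)
  path <- file.path(tempdir(), "fits.json")
  write_fits_json(list(fit), path)
  back <- read_fits_json(path)[[1]]
  expect_identical(back$session_id, "S042")
  expect_identical(back$condition, "NFT")
  expect_lt(rel_frob(back$consensus_A, fit$consensus_A), 1e-15)
  expect_equal(back$per_iteration_f1, fit$per_iteration_f1)
})
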