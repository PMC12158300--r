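# Network- and signal-level generator contracts.

test_that("noiseless identity dynamics are a fixed point and composition holds", {
  idA <- list(NFT = identity_trans(), resting = identity_trans())
  cfg <- sim_config(process_noise_sd = 0, ground_truth_A = idA)
  ch <- simulate_network_chain(cfg, "resting", seed = 1)
  for (k in 2:10)
    for (b in c("mc", "loc", "mc_loc", "mnet"))
      expect_equal(ch$states[[k]][[b]], ch$states[[1]][[b]], tolerance = 0)

  # arbitrary full-rank A: x_3 == A (A x_1) to machine precision
  A <- random_trans(4, scale = 0.4)
  cfg2 <- sim_config(process_noise_sd = 0,
                     ground_truth_A = list(NFT = A, resting = A))
  ch2 <- simulate_network_chain(cfg2, "NFT", seed = 2)
  x3 <- apply_transition(A, apply_transition(A, ch2$truth$pre_clip_states[[1]]))
  for (b in c("mc", "loc", "mc_loc", "mnet"))
    expect_lt(max(abs(ch2$truth$pre_clip_states[[3]][[b]] - x3[[b]])), 1e-12)
})

test_that("noiseless chains satisfy the dynamics exactly", {
  cfg <- sim_config(process_noise_sd = 0)
  for (seed in 1:5) {
    ch <- simulate_network_chain(cfg, "NFT", seed = seed)
    A <- ch$truth$A
    for (k in 2:10) {
      pred <- apply_transition(A, ch$truth$pre_clip_states[[k - 1]])
      resid <- sqrt(sum(sapply(c("mc", "loc", "mc_loc", "mnet"), function(b)
        sum((ch$truth$pre_clip_states[[k]][[b]] - pred[[b]])^2))))
      expect_lt(resid, 1e-12)
    }
  }
})

test_that("chains are seed-deterministic and stored states stay in [-1, 1]", {
  cfg <- sim_config(process_noise_sd = 0.05)
  a <- simulate_network_chain(cfg, "NFT", seed = 9)
  b <- simulate_network_chain(cfg, "NFT", seed = 9)
  expect_identical(a, b)
  c <- simulate_network_chain(cfg, "NFT", seed = 10)
  expect_false(identical(a$states, c$states))
  rng <- range(unlist(lapply(a$states, function(s) unlist(unclass(s)))))
  expect_gte(rng[1], -1)
  expect_lte(rng[2], 1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(runs_per_session = 1), "runs_per_session")
  expect_error(sim_config(process_noise_sd = -1), "non-negative")
  expect_error(sim_config(alpha_threshold_fraction = 0), "alpha_threshold_fraction")
  A <- identity_trans(); A$mc[1, 1] <- NA_real_
  expect_error(sim_config(ground_truth_A = list(NFT = A, resting = identity_trans())),
               "non-finite|finite")
  cfg <- sim_config()
  expect_error(simulate_network_chain(cfg, "unknown-cond"), "condition")
})

test_that("signal generator matches a null target and suppresses alpha during NFT", {
  cfg <- sim_config(run_duration = 134, seed = 5)
  tgt <- diag(7); dimnames(tgt) <- list(CHANNELS7, CHANNELS7)
  rec <- simulate_eeg_run(cfg, "resting", tgt, seed = 5)
  expect_equal(dim(rec$data), c(7L, 134L * 250L))
  net <- spearman_network(make_run(rec$data))
  expect_lt(max(abs(net[upper.tri(net)])), 0.1)

  nft <- simulate_eeg_run(cfg, "NFT", tgt, seed = 6)
  rest <- simulate_eeg_run(cfg, "resting", tgt, seed = 6)
  ratio <- band_power(nft, "Pz", c(8, 12)) / band_power(rest, "Pz", c(8, 12))
  expect_lt(ratio, cfg$alpha_threshold_fraction)
})

test_that("degenerate or unstable signal configurations error", {
  tgt <- diag(7); dimnames(tgt) <- list(CHANNELS7, CHANNELS7)
  expect_error(simulate_eeg_run(sim_config(amplitude_uv = 0), "NFT", tgt),
               "zero-amplitude|undefined")
  expect_error(simulate_eeg_run(sim_config(ar_phi = 1), "NFT", tgt),
               "unstable|spectral")
})

test_that("empirical Spearman network converges toward the target with duration", {
  set.seed(1)
  W <- matrix(rnorm(70), 7)
  S <- cov2cor(0.6 * cov2cor(tcrossprod(W) / 10) + 0.4 * diag(7))
  dimnames(S) <- list(CHANNELS7, CHANNELS7)
  mads <- sapply(c(33.5, 67, 134), function(dur) {
    mean(sapply(1:20, function(s) {
      cfg <- sim_config(run_duration = dur)
      rec <- simulate_eeg_run(cfg, "resting", S, seed = s)
      net <- spearman_network(make_run(rec$data))
      mean(abs(net[upper.tri(net)] - S[upper.tri(S)]))
    }))
  })
  expect_true(all(diff(mads) < 0))
})

test_that("two-class dataset has the stated cardinality and warns on identical classes", {
  cfg <- sim_config(n_sessions = 6, seed = 2)
  sessions <- make_two_class_dataset(cfg)
  expect_length(sessions, 6)
  for (s in sessions) {
    expect_named(s$chains, c("NFT", "resting"))
    expect_length(s$chains$NFT$states, cfg$runs_per_session)
    expect_length(s$chains$resting$states, cfg$runs_per_session)
  }
  expect_warning(make_two_class_dataset(sim_config(n_sessions = 2, separation = 0)),
                 "not separable")
})

test_that("session archives round-trip through JSON bit-exactly", {
  cfg <- sim_config(n_sessions = 2, seed = 3)
  sessions <- make_two_class_dataset(cfg)
  path <- file.path(tempdir(), "sessions.json")
  write_sessions_json(sessions, path)
  back <- read_sessions_json(path)
  expect_length(back, 2)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$session_id, sessions[[i]]$session_id)
    for (cond in c("NFT", "resting")) {
      expect_identical(back[[i]]$chains[[cond]]$condition, cond)
      for (k in 1:10)
        for (b in c("mc", "loc", "mc_loc", "mnet"))
          expect_identical(unname(back[[i]]$chains[[cond]]$states[[k]][[b]]),
                           unname(sessions[[i]]$chains[[cond]]$states[[k]][[b]]))
    }
  }
})
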