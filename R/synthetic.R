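# Synthetic NFT session generator.
#
# Two levels:
#  * network level: chains of observation matrices evolved exactly by
#    x_k = A x_(k-1) + w_(k-1), for testing the dynamics estimator in
#    isolation;
#  * signal level: 7-channel VAR-coupled EEG whose empirical Spearman
#    network approaches a target, with a condition-dependent alpha-band
#    component emulating the neurofeedback paradigm (alpha suppression
#    during NFT runs relative to eyes-open resting).

#' Simulation configuration
#'
#' Collects the stated conditions of the emulated paradigm: 10 runs per
#' session, 134-s runs at 250 Hz, a 10 Hz alpha rhythm and the 60%%
#' alpha-power feedback threshold, plus generator noise levels.
#'
#' @param n_sessions number of sessions to generate.
#' @param runs_per_session states per chain (>= 2; default 10).
#' @param run_duration run length in seconds (default 134).
#' @param sampling_rate Hz (default 250).
#' @param ground_truth_A named list of `transition_matrix` per condition
#'   (`NFT`, `resting`); defaults from [default_ground_truth()].
#' @param process_noise_sd sd of the i.i.d. Gaussian process noise added
#'   to every block entry at each step (default 0.01).
#' @param measurement_noise_sd sd in microvolts of white sensor noise
#'   added to signal-level runs (default 1).
#' @param alpha_freq alpha rhythm frequency in Hz (default 10).
#' @param alpha_threshold_fraction feedback threshold: NFT alpha power
#'   must fall below this fraction of the resting reference (default 0.6).
#' @param separation scales how strongly the NFT condition suppresses the
#'   default ground-truth transition weights; 0 makes both conditions
#'   identical (see [default_ground_truth()]).
#' @param state_offset optional `observation_matrix`-shaped constant added
#'   to every stored state (models a session-level feature-space bias).
#' @param amplitude_uv signal scale of generated EEG in microvolts
#'   (default 10).
#' @param ar_phi lag-1 coefficient of the broadband component (default 0.9).
#' @param alpha_pole_r pole radius of the resonant alpha component
#'   (default 0.97). Both must be < 1 for stability.
#' @param alpha_fraction_rest,alpha_fraction_nft fraction of signal
#'   variance carried by the alpha component in each condition (defaults
#'   0.5 and 0.15; chosen so that the NFT/resting alpha-power ratio sits
#'   well below the 60%% feedback threshold).
#' @param seed base integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sessions = 1L,
                       runs_per_session = 10L,
                       run_duration = 134,
                       sampling_rate = 250,
                       ground_truth_A = NULL,
                       process_noise_sd = 0.01,
                       measurement_noise_sd = 1,
                       alpha_freq = 10,
                       alpha_threshold_fraction = 0.6,
                       separation = 1,
                       state_offset = NULL,
                       amplitude_uv = 10,
                       ar_phi = 0.9,
                       alpha_pole_r = 0.97,
                       alpha_fraction_rest = 0.5,
                       alpha_fraction_nft = 0.15,
                       seed = 1L) {
  if (runs_per_session < 2) stopf("runs_per_session must be >= 2 (a chain needs a transition)")
  if (process_noise_sd < 0 || measurement_noise_sd < 0)
    stopf("noise standard deviations must be non-negative")
  if (alpha_threshold_fraction <= 0 || alpha_threshold_fraction > 1)
    stopf("alpha_threshold_fraction must be in (0, 1]")
  if (run_duration <= 0 || sampling_rate <= 0)
    stopf("run_duration and sampling_rate must be positive")
  if (is.null(ground_truth_A))
    ground_truth_A <- list(NFT = default_ground_truth("NFT", separation),
                           resting = default_ground_truth("resting", separation))
  for (cond in names(ground_truth_A)) {
    A <- ground_truth_A[[cond]]
    if (!inherits(A, "transition_matrix"))
      stopf("ground_truth_A[['%s']] must be a transition_matrix", cond)
    if (!all(vapply(A, function(m) all(is.finite(m)), logical(1))))
      stopf("ground_truth_A[['%s']] has non-finite entries", cond)
  }
  structure(list(
    n_sessions = as.integer(n_sessions),
    runs_per_session = as.integer(runs_per_session),
    run_duration = run_duration,
    sampling_rate = sampling_rate,
    ground_truth_A = ground_truth_A,
    process_noise_sd = process_noise_sd,
    measurement_noise_sd = measurement_noise_sd,
    alpha_freq = alpha_freq,
    alpha_threshold_fraction = alpha_threshold_fraction,
    separation = separation,
    state_offset = state_offset,
    amplitude_uv = amplitude_uv,
    ar_phi = ar_phi,
    alpha_pole_r = alpha_pole_r,
    alpha_fraction_rest = alpha_fraction_rest,
    alpha_fraction_nft = alpha_fraction_nft,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Fixed small mixing patterns, hard-coded so the ground truth is a stated
# constant of the generator rather than a random draw.
.mix3 <- matrix(c(0,    0.04, -0.03,
                  0.02, 0,     0.04,
                  -0.04, 0.03, 0), 3, 3, byrow = TRUE)
.mix4 <- matrix(c(0,    0.03, -0.02, 0.04,
                  0.02, 0,     0.03, -0.03,
                  -0.03, 0.04, 0,    0.02,
                  0.04, -0.02, 0.03, 0), 4, 4, byrow = TRUE)

#' Default condition-dependent ground-truth transitions
#'
#' The resting transition is a near-identity contraction (diagonal 0.95
#' plus a fixed small non-symmetric mixing), so resting chains decay
#' slowly and stay well conditioned over 10 states. The NFT transition
#' applies the suppression the paradigm targets: motor-cortex diagonal
#' weights scaled by `1 - 0.5 * separation` (i.e. exactly half of the
#' resting weights at separation 1), occipital diagonals by
#' `1 - 0.3 * separation`, and mesoscale diagonals by condition-specific
#' factors (RMC suppressed most). The cross MC-LOC block is identical
#' across conditions, mirroring the absence of an NFT effect there.
#'
#' @param condition `"NFT"` or `"resting"`.
#' @param separation effect-size knob in `[0, 1]`; 0 gives identical
#'   transitions for both conditions.
#' @return a `transition_matrix`.
#' @export
default_ground_truth <- function(condition = c("resting", "NFT"), separation = 1) {
  condition <- match.arg(condition)
  mc <- 0.95 * diag(3) + .mix3
  loc <- 0.95 * diag(4) + .mix4
  mc_loc <- 0.90 * diag(3) + 0.5 * .mix3
  mnet <- 0.95 * diag(3) + t(.mix3)
  if (condition == "NFT") {
    s <- clamp(separation, 0, 1)
    diag(mc) <- diag(mc) * (1 - 0.5 * s)
    diag(loc) <- diag(loc) * (1 - 0.3 * s)
    # mesoscale suppression: LMC, RMC, LOC with RMC strongest
    diag(mnet) <- diag(mnet) * (1 - c(0.40, 0.50, 0.30) * s)
  }
  transition_matrix(mc, loc, mc_loc, mnet)
}

# Random correlation matrix: shrunk Wishart-style construction,
# guaranteed symmetric positive definite with unit diagonal.
random_correlation <- function(n, df = n + 3L, shrink = 0.4) {
  W <- matrix(stats::rnorm(n * df), n, df)
  S <- tcrossprod(W) / df
  S <- (1 - shrink) * S + shrink * diag(n)
  d <- 1 / sqrt(diag(S))
  S * tcrossprod(d)
}

# Initial state x_1: random correlation blocks. The cross block comes
# from one 7x7 correlation over the canonical montage so that mc, loc and
# mc_loc are mutually consistent; mnet is a separate 3x3 correlation.
random_initial_state <- function() {
  full <- random_correlation(7L)
  dimnames(full) <- list(CANONICAL_CHANNELS, CANONICAL_CHANNELS)
  observation_matrix(full[MC_CHANNELS, MC_CHANNELS],
                     full[LOC_CHANNELS, LOC_CHANNELS],
                     full[MC_CHANNELS, LOC_CHANNELS],
                     random_correlation(3L))
}

random_noise_state <- function(sd) {
  structure(lapply(OBS_BLOCK_DIMS, function(d)
    matrix(stats::rnorm(d[1] * d[2], sd = sd), d[1], d[2])),
    class = "observation_matrix")
}

#' Simulate a network-level session chain
#'
#' Evolves the exact linear dynamics x_k = A x_(k-1) + w_(k-1) over the
#' four observation blocks, starting from a random correlation-structured
#' initial state. Stored states are clipped to [-1, 1] after noise
#' injection (correlation semantics); the pre-clip truth, the noise
#' realizations and the generating transition are recorded.
#'
#' @param config a [sim_config()].
#' @param condition `"NFT"` or `"resting"` (must have a ground-truth A).
#' @param seed integer seed for this chain.
#' @return a `synthetic_session_chain` list with elements `condition`,
#'   `states` (list of `observation_matrix`), and `truth` (ground-truth
#'   transition, noise draws, pre-clip states, offset).
#' @export
simulate_network_chain <- function(config, condition, seed = config$seed) {
  A <- config$ground_truth_A[[condition]]
  if (is.null(A)) stopf("no ground_truth_A configured for condition '%s'", condition)
  set.seed(seed)
  K <- config$runs_per_session
  offset <- config$state_offset
  states <- vector("list", K)
  raw <- vector("list", K)
  noise <- vector("list", K - 1L)
  x <- random_initial_state()
  raw[[1]] <- x
  for (k in 2:K) {
    w <- random_noise_state(config$process_noise_sd)
    noise[[k - 1L]] <- w
    x <- obs_add(apply_transition(A, raw[[k - 1L]]), w)
    raw[[k]] <- x
  }
  for (k in 1:K) {
    s <- raw[[k]]
    if (!is.null(offset)) s <- obs_add(s, offset)
    states[[k]] <- obs_clip(s)
  }
  structure(list(condition = condition,
                 states = states,
                 truth = list(A = A, noise = noise, pre_clip_states = raw,
                              offset = offset),
                 seed = seed),
            class = "session_chain")
}

# --- signal-level generator ------------------------------------------------

# Stationary-variance-normalized AR(1) innovations-driven series.
ar1_series <- function(n, phi) {
  e <- stats::rnorm(n)
  x <- stats::filter(e, phi, method = "recursive")
  as.numeric(x) * sqrt(1 - phi^2)
}

# Resonant AR(2) with complex poles r*exp(+-i*2*pi*f0/fs), normalized to
# unit stationary variance (closed-form Yule-Walker variance).
ar2_alpha_series <- function(n, f0, fs, r) {
  a1 <- 2 * r * cos(2 * pi * f0 / fs)
  a2 <- -r^2
  e <- stats::rnorm(n)
  x <- as.numeric(stats::filter(e, c(a1, a2), method = "recursive"))
  v <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  x / sqrt(v)
}

#' Simulate one signal-level EEG run
#'
#' Generates a 7-channel run whose cross-channel dependence matches a
#' target Spearman network: seven independent unit-variance temporal
#' processes (a broadband AR(1) plus a resonant alpha-band AR(2), in a
#' condition-dependent variance mix) are coupled through the Cholesky
#' factor of the Pearson-warped target. Because all channels share the
#' same spectrum, the instantaneous correlation equals the target
#' regardless of the alpha mix, and the rank-correlation bias of the
#' Gaussian copula is removed by the 2*sin(pi*rho/6) pre-warp. During NFT
#' the alpha variance fraction drops from `alpha_fraction_rest` to
#' `alpha_fraction_nft`, emulating successful alpha down-regulation below
#' the feedback threshold.
#'
#' @param config a [sim_config()].
#' @param condition `"NFT"` or `"resting"`.
#' @param target_network 7x7 symmetric correlation matrix (canonical
#'   channel order) the empirical Spearman network should approach.
#' @param seed integer seed.
#' @return an [eeg_recording()] with device `"synthetic"` and one run
#'   annotation covering the whole segment.
#' @export
simulate_eeg_run <- function(config, condition, target_network, seed = config$seed) {
  if (config$amplitude_uv <= 0)
    stopf("amplitude_uv must be > 0: a zero-amplitude run is all zeros and its correlation network is undefined")
  if (abs(config$ar_phi) >= 1 || config$alpha_pole_r >= 1)
    stopf("unstable generator: AR spectral radius must be < 1 (ar_phi = %g, alpha_pole_r = %g)",
          config$ar_phi, config$alpha_pole_r)
  tn <- as.matrix(target_network)
  if (!identical(dim(tn), c(7L, 7L)) || max(abs(tn - t(tn))) > 1e-8)
    stopf("target_network must be a symmetric 7x7 correlation matrix")
  gamma <- if (condition == "NFT") config$alpha_fraction_nft else config$alpha_fraction_rest
  n <- round(config$run_duration * config$sampling_rate)
  set.seed(seed)
  # Pearson pre-warp so the *Spearman* correlation converges to target.
  P <- 2 * sin(pi * tn / 6)
  diag(P) <- 1
  eg <- eigen(P, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-8)
  L <- eg$vectors %*% diag(sqrt(vals))
  U <- vapply(1:7, function(i) {
    sqrt(1 - gamma) * ar1_series(n, config$ar_phi) +
      sqrt(gamma) * ar2_alpha_series(n, config$alpha_freq,
                                     config$sampling_rate, config$alpha_pole_r)
  }, numeric(n))
  S <- L %*% t(U) * config$amplitude_uv            # 7 x n
  if (config$measurement_noise_sd > 0)
    S <- S + matrix(stats::rnorm(length(S), sd = config$measurement_noise_sd),
                    nrow(S), ncol(S))
  eeg_recording(S, CANONICAL_CHANNELS, config$sampling_rate,
                device = "synthetic",
                annotations = data.frame(onset = 0,
                                         duration = config$run_duration,
                                         label = condition,
                                         valid = TRUE,
                                         stringsAsFactors = FALSE))
}

#' Band power of one channel
#'
#' Mean periodogram power inside a frequency band; used to verify the
#' alpha-suppression contract of the paradigm emulation.
#'
#' @param rec an [eeg_recording()].
#' @param channel channel label.
#' @param band numeric length-2, Hz (default the 8-12 Hz alpha band).
#' @return scalar mean power in the band.
#' @export
band_power <- function(rec, channel, band = c(8, 12)) {
  x <- rec$data[match(channel, rec$channel_names), ]
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * rec$sampling_rate / n
  sel <- freqs >= band[1] & freqs <= band[2]
  mean(sp[sel])
}

#' Generate a balanced two-class synthetic dataset
#'
#' Produces `n_sessions` sessions, each holding one NFT chain and one
#' resting chain of `runs_per_session` network states, with deterministic
#' per-session seeds derived from the config seed.
#'
#' @param config a [sim_config()]; both conditions must have a
#'   ground-truth transition. If the two are identical a warning is
#'   raised (classes are not separable by construction).
#' @return list of sessions, each `list(session_id, chains = list(NFT, resting))`.
#' @export
make_two_class_dataset <- function(config) {
  gt <- config$ground_truth_A
  if (is.null(gt$NFT) || is.null(gt$resting))
    stopf("config must define ground_truth_A for both 'NFT' and 'resting'")
  same <- all(vapply(BLOCK_NAMES, function(b)
    isTRUE(all.equal(gt$NFT[[b]], gt$resting[[b]])), logical(1)))
  if (same)
    warnf("NFT and resting ground-truth transitions are identical: classes are not separable by construction")
  lapply(seq_len(config$n_sessions), function(i) {
    list(session_id = sprintf("S%03d", i),
         chains = list(
           NFT = simulate_network_chain(config, "NFT",
                                        derive_seed(config$seed, 2L * i)),
           resting = simulate_network_chain(config, "resting",
                                            derive_seed(config$seed, 2L * i + 1L))))
  })
}

# --- serialization ---------------------------------------------------------

obs_to_list <- function(x) lapply(unclass(x), function(m) unname(m))

obs_from_list <- function(l) observation_matrix(
  do.call(rbind, lapply(seq_len(3), function(i) unlist(l$mc[[i]]))),
  do.call(rbind, lapply(seq_len(4), function(i) unlist(l$loc[[i]]))),
  do.call(rbind, lapply(seq_len(3), function(i) unlist(l$mc_loc[[i]]))),
  do.call(rbind, lapply(seq_len(3), function(i) unlist(l$mnet[[i]]))))

#' Write a synthetic dataset to JSON
#'
#' Plain-text archive of session chains (blocks, labels, truth
#' transitions) at full double precision.
#'
#' @param sessions output of [make_two_class_dataset()].
#' @param path output file.
#' @export
write_sessions_json <- function(sessions, path) {
  ser <- lapply(sessions, function(s) list(
    session_id = s$session_id,
    chains = lapply(s$chains, function(ch) list(
      condition = ch$condition,
      seed = ch$seed,
      states = lapply(ch$states, obs_to_list),
      truth_A = lapply(unclass(ch$truth$A), unname)))))
  jsonlite::write_json(ser, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a synthetic dataset from JSON
#'
#' @param path file written by [write_sessions_json()].
#' @return list of sessions mirroring the writer's input (truth reduced
#'   to the generating transition).
#' @export
read_sessions_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(s) list(
    session_id = s$session_id,
    chains = lapply(s$chains, function(ch) {
      tA <- ch$truth_A
      structure(list(
        condition = ch$condition,
        seed = ch$seed,
        states = lapply(ch$states, obs_from_list),
        truth = list(A = transition_matrix(
          do.call(rbind, lapply(tA$mc, unlist)),
          do.call(rbind, lapply(tA$loc, unlist)),
          do.call(rbind, lapply(tA$mc_loc, unlist)),
          do.call(rbind, lapply(tA$mnet, unlist))))),
        class = "session_chain")
    })))
}
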