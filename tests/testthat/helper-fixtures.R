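# Shared fixtures, built in code.

CHANNELS7 <- c("C3", "Cz", "C4", "P7", "Pz", "PO3", "Oz")

rel_frob <- function(a, b) {
  va <- linearize(a); vb <- linearize(b)
  sqrt(sum((va - vb)^2)) / sqrt(sum(vb^2))
}

# random full-rank observation with all blocks drawn freely
random_obs <- function(seed) {
  set.seed(seed)
  observation_matrix(matrix(rnorm(9), 3), matrix(rnorm(16), 4),
                     matrix(rnorm(12), 3, 4), matrix(rnorm(9), 3))
}

random_trans <- function(seed, scale = 0.5) {
  set.seed(seed)
  transition_matrix(matrix(rnorm(9, sd = scale), 3),
                    matrix(rnorm(16, sd = scale), 4),
                    matrix(rnorm(9, sd = scale), 3),
                    matrix(rnorm(9, sd = scale), 3))
}

identity_trans <- function() transition_matrix(diag(3), diag(4), diag(3), diag(3))

make_run <- function(data, fs = 250, condition = "NFT") {
  aligned_run(data, fs, condition)
}

random_run <- function(seed, n = 500, fs = 250) {
  set.seed(seed)
  make_run(matrix(rnorm(7 * n), 7, n), fs)
}

# brute-force Spearman oracle: rank transform (average ranks), then Pearson
spearman_oracle <- function(m) {
  r <- t(apply(m, 1, rank, ties.method = "average"))
  stats::cor(t(r))
}

# fit all chains of a two-class dataset
fit_dataset <- function(sessions, config = pnda_config()) {
  unlist(lapply(sessions, function(s) lapply(s$chains, function(ch) {
    ch$session_id <- s$session_id
    pnda_fit_session(ch, config)
  })), recursive = FALSE)
}
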