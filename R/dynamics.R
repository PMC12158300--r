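# Core dynamics estimation: per-transition least-squares estimates of
# the block-structured transition matrix along a session's Markov chain,
# adaptive removal of process noise by minimizing the cross-transition
# covariance loss f1 with a fuzzy-gain update, and cross-session
# alignment of feature spaces through a learned bias driven by the
# pairwise-distance loss f2.

#' PNDA fitting configuration
#'
#' @param theta_gains named gains of the three fuzzy categories applied
#'   to the loss change: `improving` (loss decreased), `flat`
#'   (essentially unchanged), `worsening` (loss increased). Defaults
#'   1.2 / 1.0 / 0.7.
#' @param theta_bounds admissible gain interval (subset of (0, 2)).
#' @param delta_width half-width of the triangular `flat` membership on
#'   the *relative* loss-change axis.
#' @param tol_f1 convergence tolerance on the relative change of f1.
#' @param max_iter maximum noise-update iterations per session.
#' @param max_iter_align maximum bias-update iterations across sessions.
#' @param b0 optional initial session bias (observation-shaped); zero
#'   blocks by default.
#' @return a `pnda_config` list. The control-input matrix B and input u
#'   of the general state-space form are fixed to zero (the emulated
#'   protocol never changes within a session) and are not configurable.
#' @export
pnda_config <- function(theta_gains = c(improving = 1.2, flat = 1.0, worsening = 0.7),
                        theta_bounds = c(0.5, 1.5),
                        delta_width = 1e-3,
                        tol_f1 = 1e-8,
                        max_iter = 50L,
                        max_iter_align = 10L,
                        b0 = NULL) {
  if (tol_f1 <= 0) stopf("tol_f1 must be positive")
  if (max_iter < 1) stopf("max_iter must be >= 1")
  if (!(theta_bounds[1] > 0 && theta_bounds[2] < 2 && theta_bounds[1] < theta_bounds[2]))
    stopf("theta_bounds must be an interval inside (0, 2)")
  stopifnot(all(c("improving", "flat", "worsening") %in% names(theta_gains)))
  list(theta_gains = theta_gains, theta_bounds = theta_bounds,
       delta_width = delta_width, tol_f1 = tol_f1,
       max_iter = as.integer(max_iter),
       max_iter_align = as.integer(max_iter_align),
       b0 = b0)
}

#' Fuzzy update gain
#'
#' Triangular-membership three-category fuzzy rule mapping a loss change
#' to a multiplicative gain: `improving` for negative changes, `flat`
#' near zero, `worsening` for positive changes, defuzzified by the
#' membership-weighted mean of the category gains and clamped to the
#' configured bounds.
#'
#' @param delta loss change (relative scale).
#' @param config a [pnda_config()].
#' @return scalar gain.
#' @export
fuzzy_gain <- function(delta, config = pnda_config()) {
  if (!is.finite(delta)) stopf("fuzzy_gain: non-finite loss change")
  w <- config$delta_width
  s <- delta / w
  mu_imp <- clamp(-s, 0, 1)
  mu_wor <- clamp(s, 0, 1)
  mu_flat <- clamp(1 - abs(s), 0, 1)
  g <- config$theta_gains
  theta <- (mu_imp * g[["improving"]] + mu_flat * g[["flat"]] +
            mu_wor * g[["worsening"]]) / (mu_imp + mu_flat + mu_wor)
  clamp(theta, config$theta_bounds[1], config$theta_bounds[2])
}

#' Estimate the transition between two states
#'
#' Per block, the minimum-Frobenius-norm least-squares solution
#' `A = x_curr %*% pinv(x_prev)`; the rectangular MC-LOC block yields a
#' 3x3 left-multiplying map.
#'
#' @param x_prev,x_curr [observation_matrix()]s.
#' @return a [transition_matrix()].
#' @export
estimate_transition <- function(x_prev, x_curr) {
  blocks <- lapply(BLOCK_NAMES, function(b) {
    xp <- x_prev[[b]]
    if (all(xp == 0))
      stopf("estimate_transition: all-zero previous state in block '%s' (transition unidentifiable)", b)
    x_curr[[b]] %*% pinv(xp)
  })
  names(blocks) <- BLOCK_NAMES
  transition_matrix(blocks$mc, blocks$loc, blocks$mc_loc, blocks$mnet)
}

# Joint least squares over the whole chain: per block,
# argmin_A sum_k ||x_k - A x_(k-1)||_F^2.
consensus_transition <- function(states) {
  K <- length(states)
  blocks <- lapply(BLOCK_NAMES, function(b) {
    Sxy <- 0
    Sxx <- 0
    for (k in 2:K) {
      xp <- states[[k - 1]][[b]]
      xc <- states[[k]][[b]]
      Sxy <- Sxy + xc %*% t(xp)
      Sxx <- Sxx + xp %*% t(xp)
    }
    Sxy %*% pinv(Sxx)
  })
  names(blocks) <- BLOCK_NAMES
  transition_matrix(blocks$mc, blocks$loc, blocks$mc_loc, blocks$mnet)
}

#' Covariance loss f1 over a set of transitions
#'
#' Scalar summary of the across-transition covariance of the linearized
#' transition matrices: the mean over the 43 weight positions of the
#' across-k sample variance (equivalently, trace of the 43x43 covariance
#' divided by 43). Zero iff all transitions are identical.
#'
#' @param transitions list of [transition_matrix()]s (>= 2).
#' @return non-negative scalar.
#' @export
f1_loss <- function(transitions) {
  if (length(transitions) < 2) stopf("f1_loss needs at least 2 transitions")
  V <- vapply(transitions, linearize, numeric(43))
  mean(apply(V, 1, stats::var))
}

#' Process-noise fuzzy update
#'
#' Element-wise `w_new = theta1(delta_f1) * w + b0` over the four noise
#' blocks.
#'
#' @param w observation-shaped noise blocks.
#' @param delta_f1 relative f1 change driving the gain.
#' @param config a [pnda_config()].
#' @param b0 observation-shaped bias (defaults to zero blocks).
#' @return updated noise blocks.
#' @export
update_process_noise <- function(w, delta_f1, config = pnda_config(), b0 = NULL) {
  theta <- fuzzy_gain(delta_f1, config)
  if (is.null(b0)) b0 <- zero_observation()
  obs_add(obs_scale(w, theta), b0)
}

denoise_states <- function(states, noise, b0) {
  K <- length(states)
  out <- vector("list", K)
  out[[1]] <- obs_sub(states[[1]], b0)
  for (k in 2:K)
    out[[k]] <- obs_sub(obs_sub(states[[k]], b0), noise[[k - 1]])
  out
}

transitions_of <- function(states) {
  K <- length(states)
  lapply(2:K, function(k) estimate_transition(states[[k - 1]], states[[k]]))
}

#' Fit the noise-adapted dynamics of one session
#'
#' Iteratively removes process noise from a session's Markov chain so
#' that the per-transition estimates A_1..A_(K-1) become as similar as
#' possible. Each iteration (a) denoises the states with the current
#' noise estimates and session bias, (b) re-estimates all transitions,
#' (c) evaluates the covariance loss f1 and its change, and (d) proposes
#' the fuzzy-gain update of each noise state along the candidate
#' direction given by the residual from the joint (consensus)
#' least-squares transition. An update is accepted only if f1 does not
#' increase; on rejection the gain's deviation from 1 is halved and the
#' step retried once, after which the previous noise is kept and
#' iteration stops. Iteration also stops when the relative f1 change
#' falls below `tol_f1` or after `max_iter` rounds. If f1 ever exceeds
#' ten times its initial value the fit aborts with a diagnostic.
#'
#' @param chain a `session_chain` (>= 2 states).
#' @param config a [pnda_config()].
#' @param b0 optional observation-shaped session bias overriding
#'   `config$b0`.
#' @return a `pnda_fit`: `consensus_A`, `per_iteration_f1` (accepted
#'   values, non-increasing), `final_noise`, `final_transitions`,
#'   `b0_final`, `iterations_used`, `converged`, plus the input chain.
#' @export
pnda_fit_session <- function(chain, config = pnda_config(), b0 = NULL) {
  states <- chain$states
  K <- length(states)
  if (K < 2) stopf("a session chain needs at least 2 states")
  b0 <- b0 %||% config$b0 %||% zero_observation()
  noise <- replicate(K - 1, zero_observation(), simplify = FALSE)

  xt <- denoise_states(states, noise, b0)
  trans <- transitions_of(xt)
  f1 <- f1_loss(trans)
  f1_init <- f1
  traj <- f1
  delta_rel <- 0
  converged <- FALSE
  iters <- 0L
  # numerical floor: a chain already consistent to round-off has nothing
  # left to adapt
  f1_floor <- 1e-24

  if (f1 <= f1_floor) converged <- TRUE
  for (j in if (converged) integer(0) else seq_len(config$max_iter)) {
    iters <- j
    A_cons <- consensus_transition(xt)
    # candidate noise: current noise plus the residual left after the
    # consensus dynamics explain the denoised chain. Residuals are
    # propagated sequentially (each state is compared against the
    # consensus prediction from the *corrected* previous state) so that
    # a full step makes the denoised chain exactly consistent with the
    # consensus transition.
    cand <- vector("list", K - 1)
    xprev <- xt[[1]]
    for (k in 2:K) {
      pred <- apply_transition(A_cons, xprev)
      resid <- obs_sub(xt[[k]], pred)
      cand[[k - 1]] <- obs_add(noise[[k - 1]], resid)
      xprev <- pred
    }
    theta <- fuzzy_gain(delta_rel, config)
    accepted <- FALSE
    for (attempt in 1:2) {
      prop_noise <- lapply(cand, obs_scale, s = theta)
      prop_xt <- denoise_states(states, prop_noise, b0)
      prop_trans <- transitions_of(prop_xt)
      f1_new <- f1_loss(prop_trans)
      if (f1_new > 10 * f1_init + 1e-15)
        stopf("pnda_fit_session diverged: f1 = %g exceeds 10x initial (%g) at iteration %d",
              f1_new, f1_init, j)
      if (f1_new <= f1) {
        delta_rel <- (f1_new - f1) / max(f1, .Machine$double.xmin)
        noise <- prop_noise
        xt <- prop_xt
        trans <- prop_trans
        f1 <- f1_new
        traj <- c(traj, f1)
        accepted <- TRUE
        break
      }
      theta <- theta / 2   # damp the step and retry once
    }
    if (!accepted) break
    if (abs(delta_rel) < config$tol_f1 || f1 <= f1_floor) {
      converged <- TRUE
      break
    }
  }

  structure(list(session_id = chain$session_id %||% NA_character_,
                 condition = chain$condition,
                 consensus_A = consensus_transition(xt),
                 per_iteration_f1 = traj,
                 final_noise = noise,
                 final_transitions = trans,
                 b0_final = b0,
                 iterations_used = iters,
                 converged = converged,
                 f1_initial = f1_init,
                 f1_final = f1,
                 chain = chain),
            class = "pnda_fit")
}

# Mean linearized transition of one fit.
fit_mean_weights <- function(fit) {
  rowMeans(vapply(fit$final_transitions, linearize, numeric(43)))
}

#' Pairwise feature-space distance f2 across sessions
#'
#' Mean pairwise Euclidean (Frobenius) distance between the per-session
#' mean linearized transition vectors.
#'
#' @param fits list of `pnda_fit`s (>= 2).
#' @return non-negative scalar, invariant to session order.
#' @export
f2_loss <- function(fits) {
  if (length(fits) < 2) stopf("f2_loss needs at least 2 fits")
  M <- vapply(fits, fit_mean_weights, numeric(43))
  n <- ncol(M)
  tot <- 0
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sqrt(sum((M[, i] - M[, j])^2))
    cnt <- cnt + 1
  }
  tot / cnt
}

# Session bias direction: deviation of the session's mean state from the
# grand mean state across sessions, reshaped into observation blocks.
session_state_means <- function(fits) {
  lapply(fits, function(f) {
    ms <- lapply(BLOCK_NAMES, function(b) {
      Reduce(`+`, lapply(f$chain$states, `[[`, b)) / length(f$chain$states)
    })
    names(ms) <- BLOCK_NAMES
    structure(ms, class = "observation_matrix")
  })
}

#' Align feature spaces across sessions
#'
#' Estimates a per-session bias b0 that reduces the pairwise
#' feature-space distance f2 between sessions. A shared additive offset
#' between session groups appears as the dominant mode of the
#' per-session mean-state deviations from the grand mean, so the initial
#' bias of each session is the projection of its deviation onto the
#' leading singular vector of the deviation matrix (session-specific
#' random structure, which must not be removed, is left in the
#' orthogonal complement). Subsequent iterations rescale each bias by
#' the fuzzy gain of the f2 change and refit the session, keeping an
#' update only when f2 does not increase.
#'
#' @param fits list of `pnda_fit`s (each carrying its chain).
#' @param config a [pnda_config()].
#' @return list of refitted `pnda_fit`s with aligned `b0_final`; a single
#'   fit is returned unchanged with a warning.
#' @export
align_sessions <- function(fits, config = pnda_config()) {
  if (length(fits) < 2) {
    warnf("align_sessions needs >= 2 sessions; returning input unchanged")
    return(fits)
  }
  f2_cur <- f2_loss(fits)
  means <- session_state_means(fits)
  grand <- structure(lapply(BLOCK_NAMES, function(b)
    Reduce(`+`, lapply(means, `[[`, b)) / length(means)),
    class = "observation_matrix")
  names(grand) <- BLOCK_NAMES
  devs <- lapply(means, function(m) obs_sub(m, grand))
  D <- vapply(devs, linearize_observation, numeric(46))
  # cluster sessions by the sign of their score on the dominant
  # deviation mode; the candidate bias direction of a session is its
  # cluster's mean deviation (the shared offset estimate), leaving the
  # session-specific random structure untouched
  u1 <- svd(D)$u[, 1]
  scores <- as.numeric(t(u1) %*% D)
  cl <- scores >= 0
  dirs <- lapply(seq_along(devs), function(i)
    delinearize_observation(rowMeans(D[, cl == cl[i], drop = FALSE])))

  # greedy coordinate sweep: per session, backtracking line search on
  # the bias scale (the bias-to-f2 map is nonlinear and steep, so the
  # full-scale correction can overshoot even when a small step along
  # the same direction helps); a step is kept only if f2 decreases
  best <- fits
  b0s <- replicate(length(fits), zero_observation(), simplify = FALSE)
  for (i in seq_along(fits)) {
    for (scale in c(1, 0.5, 0.25, 0.1)) {
      cand <- obs_scale(dirs[[i]], scale)
      prop <- best
      prop[[i]] <- pnda_fit_session(fits[[i]]$chain, config, b0 = cand)
      f2_new <- f2_loss(prop)
      if (f2_new < f2_cur) {
        best <- prop
        b0s[[i]] <- cand
        f2_cur <- f2_new
        break
      }
    }
  }
  any_bias <- any(vapply(b0s, function(b) any(unlist(unclass(b)) != 0), TRUE))
  if (!any_bias) return(best)

  # joint fuzzy rescaling of the accepted biases, Eq.-style b0 update
  delta_rel <- -1
  for (j in seq_len(config$max_iter_align)) {
    theta <- fuzzy_gain(delta_rel, config)
    cand_b0s <- lapply(b0s, obs_scale, s = theta)
    prop <- mapply(function(f, b0) pnda_fit_session(f$chain, config, b0 = b0),
                   fits, cand_b0s, SIMPLIFY = FALSE)
    f2_new <- f2_loss(prop)
    if (f2_new <= f2_cur) {
      delta_rel <- (f2_new - f2_cur) / max(f2_cur, .Machine$double.xmin)
      best <- prop
      b0s <- cand_b0s
      f2_cur <- f2_new
      if (abs(delta_rel) < config$tol_f1) break
    } else {
      break
    }
  }
  best
}
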