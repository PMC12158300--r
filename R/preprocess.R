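# Harmonization of heterogeneous-device EEG into aligned 7-channel,
# 134-s, quality-controlled runs. Stage order is fixed:
# resample -> bandpass -> CAR -> ICA -> channel alignment -> segmentation
# -> baseline correction -> session z-scoring.

#' EEG recording container
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param channel_names ordered labels, one per row of `data`.
#' @param sampling_rate Hz, positive.
#' @param device one of `"gtec32"`, `"flex8"`, `"neusenw32"`, `"synthetic"`.
#' @param annotations data.frame with columns `onset` (s), `duration`
#'   (s), `label` (condition) and optional `valid` (logical); half-open
#'   intervals `[onset, onset + duration)`.
#' @param provenance character vector of applied processing steps.
#' @return an `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names, sampling_rate,
                          device = c("synthetic", "gtec32", "flex8", "neusenw32"),
                          annotations = NULL, provenance = character()) {
  device <- match.arg(device)
  data <- as.matrix(data)
  if (length(channel_names) != nrow(data))
    stopf("channel_names length (%d) must equal number of data rows (%d)",
          length(channel_names), nrow(data))
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (!all(is.finite(data))) stopf("data contains non-finite samples")
  if (is.null(annotations))
    annotations <- data.frame(onset = numeric(), duration = numeric(),
                              label = character(), valid = logical(),
                              stringsAsFactors = FALSE)
  if (is.null(annotations$valid)) annotations$valid <- TRUE
  rownames(data) <- channel_names
  structure(list(data = data, channel_names = as.character(channel_names),
                 sampling_rate = sampling_rate, device = device,
                 annotations = annotations, provenance = provenance),
            class = "eeg_recording")
}

add_provenance <- function(rec, step) {
  rec$provenance <- c(rec$provenance, step)
  rec
}

#' Resample a recording
#'
#' Polyphase resampling with Kaiser-windowed sinc anti-alias filtering.
#' Annotations are stored in seconds and are therefore unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param target_rate Hz.
#' @return resampled recording.
#' @export
resample_to <- function(rec, target_rate) {
  if (target_rate <= 0) stopf("target_rate must be positive")
  if (target_rate == rec$sampling_rate)
    return(add_provenance(rec, sprintf("resample:%g", target_rate)))
  if (target_rate > 4 * rec$sampling_rate)
    warnf("upsampling from %g to %g Hz exceeds 4x the original rate",
          rec$sampling_rate, target_rate)
  pq <- rational_ratio(target_rate, rec$sampling_rate)
  out <- t(apply(rec$data, 1, resample_poly, p = pq[1], q = pq[2]))
  rec$data <- out
  rownames(rec$data) <- rec$channel_names
  rec$sampling_rate <- target_rate
  add_provenance(rec, sprintf("resample:%g", target_rate))
}

#' Zero-phase Butterworth bandpass
#'
#' Forward-backward (zero-phase) application of an 8th-order Butterworth
#' bandpass, defaulting to the 0.5-38 Hz harmonization band.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz.
#' @param order prototype order.
#' @return filtered recording.
#' @export
bandpass_zero_phase <- function(rec, low = 0.5, high = 38, order = 8L) {
  if (high >= rec$sampling_rate / 2)
    stopf("high edge (%g Hz) must be below Nyquist (%g Hz)", high,
          rec$sampling_rate / 2)
  filt <- butter_bandpass(low, high, rec$sampling_rate, order)
  rec$data <- t(apply(rec$data, 1, sos_filtfilt, filt = filt))
  rownames(rec$data) <- rec$channel_names
  add_provenance(rec, sprintf("bandpass:%g-%g:order%d", low, high, order))
}

#' Common average reference
#'
#' Subtracts the cross-channel mean at every sample. With
#' `keep_original_reference` an explicit all-zero reference channel
#' (labelled `REF`) is appended before averaging, which preserves the
#' rank of the data matrix under re-referencing.
#'
#' @param rec an [eeg_recording()].
#' @param keep_original_reference logical.
#' @return re-referenced recording (including the `REF` row if kept).
#' @export
common_average_reference <- function(rec, keep_original_reference = FALSE) {
  if (nrow(rec$data) < 2) stopf("CAR requires at least 2 channels")
  d <- rec$data
  if (keep_original_reference && !("REF" %in% rec$channel_names)) {
    d <- rbind(d, REF = 0)
    rec$channel_names <- c(rec$channel_names, "REF")
  }
  d <- sweep(d, 2, colMeans(d))
  rec$data <- d
  rownames(rec$data) <- rec$channel_names
  add_provenance(rec, "car")
}

#' ICA rejection criteria
#'
#' @param enabled apply rejection at all.
#' @param ocular_lowfreq_fraction reject a component as ocular when its
#'   power fraction below `lowfreq_hz` exceeds this threshold.
#' @param muscular_highfreq_fraction reject as muscular when the power
#'   fraction above `highfreq_hz` exceeds this threshold.
#' @param lowfreq_hz,highfreq_hz band edges (defaults 4 and 20 Hz).
#' @param n_components `"full"` (one component per channel; errors on a
#'   rank-deficient input), `"auto"` (reduce to the numerical rank, as
#'   needed after common average referencing), or an integer.
#' @param seed seed for the ICA initialization (determinism).
#' @return criteria list.
#' @export
ica_criteria <- function(enabled = TRUE,
                         ocular_lowfreq_fraction = 0.6,
                         muscular_highfreq_fraction = 0.6,
                         lowfreq_hz = 4, highfreq_hz = 20,
                         n_components = "full",
                         seed = 42L) {
  list(enabled = enabled,
       ocular_lowfreq_fraction = ocular_lowfreq_fraction,
       muscular_highfreq_fraction = muscular_highfreq_fraction,
       lowfreq_hz = lowfreq_hz, highfreq_hz = highfreq_hz,
       n_components = n_components,
       seed = as.integer(seed))
}

# FastICA with symmetric decorrelation and tanh contrast; deterministic
# for a fixed init seed.
fastica_decompose <- function(X, seed, n_components = "full",
                              max_iter = 500, tol = 1e-8) {
  nch <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  rel <- eg$values / max(eg$values)
  rk <- sum(rel >= 1e-10)
  ncomp <- if (identical(n_components, "full")) nch
           else if (identical(n_components, "auto")) rk
           else as.integer(n_components)
  if (ncomp > rk)
    stopf("ICA decomposition failed: %d components requested but input is rank deficient (rank %d of %d channels)",
          ncomp, rk, nch)
  if (ncomp < 2) stopf("ICA needs at least 2 usable components (rank %d)", rk)
  vals <- eg$values[seq_len(ncomp)]
  vecs <- eg$vectors[, seq_len(ncomp), drop = FALSE]
  K <- diag(1 / sqrt(vals), ncomp) %*% t(vecs)        # whitening
  Z <- K %*% Xc
  set.seed(seed)
  W <- matrix(stats::rnorm(ncomp * ncomp), ncomp, ncomp)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- (G %*% t(Z)) / ncol(Z) - diag(rowMeans(Gp)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  mixing <- vecs %*% diag(sqrt(vals), ncomp) %*% t(W)  # X ~ mixing %*% S + mu
  list(mixing = mixing, sources = S, mean = mu)
}

component_band_fractions <- function(s, fs, low_hz, high_hz) {
  n <- length(s)
  sp <- Mod(stats::fft(s - mean(s)))^2
  half <- 2:(floor(n / 2) + 1)
  freqs <- (half - 1) * fs / n
  p <- sp[half]
  tot <- sum(p)
  c(low = sum(p[freqs < low_hz]) / tot,
    high = sum(p[freqs > high_hz]) / tot)
}

#' ICA-based artifact removal
#'
#' Decomposes the recording into independent components, flags components
#' whose spectra look ocular (dominant power below 4 Hz) or muscular
#' (dominant power above 20 Hz), and reconstructs the signal without the
#' flagged components.
#'
#' @param rec an [eeg_recording()] (filtered, >= 2 channels).
#' @param criteria an [ica_criteria()] list.
#' @return list with elements `recording` (cleaned) and `decomposition`
#'   (mixing, sources, rejected indices, reason codes).
#' @export
remove_artifacts_ica <- function(rec, criteria = ica_criteria()) {
  if (nrow(rec$data) < 2) stopf("ICA requires at least 2 channels")
  dec <- fastica_decompose(rec$data, criteria$seed,
                           criteria$n_components %||% "full")
  ncomp <- nrow(dec$sources)
  rejected <- integer(0)
  reasons <- character(0)
  if (isTRUE(criteria$enabled)) {
    for (i in seq_len(ncomp)) {
      fr <- component_band_fractions(dec$sources[i, ], rec$sampling_rate,
                                     criteria$lowfreq_hz, criteria$highfreq_hz)
      if (fr["low"] > criteria$ocular_lowfreq_fraction) {
        rejected <- c(rejected, i); reasons <- c(reasons, "ocular")
      } else if (fr["high"] > criteria$muscular_highfreq_fraction) {
        rejected <- c(rejected, i); reasons <- c(reasons, "muscular")
      }
    }
  }
  keep <- setdiff(seq_len(ncomp), rejected)
  if (length(keep) == 0) {
    warnf("all %d ICA components rejected: cleaned signal is zero", ncomp)
    clean <- matrix(0, nrow(rec$data), ncol(rec$data))
  } else {
    clean <- dec$mixing[, keep, drop = FALSE] %*%
      dec$sources[keep, , drop = FALSE] + dec$mean
  }
  rec$data <- clean
  rownames(rec$data) <- rec$channel_names
  rec <- add_provenance(rec, sprintf("ica:rejected=%d", length(rejected)))
  list(recording = rec,
       decomposition = list(mixing = dec$mixing, sources = dec$sources,
                            mean = dec$mean, rejected = rejected,
                            reasons = reasons))
}

#' Align device channels to the canonical 7-channel montage
#'
#' 32-channel devices contribute C3, Cz, C4, P7, Pz, PO3, Oz directly;
#' the 8-channel montage has no PO3, so PO3 is synthesized as the mean of
#' P3 and O1. Output channels are always in canonical order.
#'
#' @param rec an [eeg_recording()] with a known device.
#' @return recording with exactly the 7 canonical channels.
#' @export
align_channels <- function(rec) {
  need <- switch(rec$device,
                 flex8 = c("C3", "Cz", "C4", "P7", "Pz", "P3", "O1", "Oz"),
                 CANONICAL_CHANNELS)
  missing <- setdiff(need, rec$channel_names)
  if (length(missing) > 0)
    stopf("device '%s' is missing required channel(s): %s", rec$device,
          paste(missing, collapse = ", "))
  if (rec$device == "flex8") {
    po3 <- (rec$data["P3", ] + rec$data["O1", ]) / 2
    d <- rbind(rec$data[c("C3", "Cz", "C4", "P7", "Pz"), , drop = FALSE],
               PO3 = po3,
               Oz = rec$data["Oz", ])
  } else {
    d <- rec$data[CANONICAL_CHANNELS, , drop = FALSE]
  }
  rec$data <- d[CANONICAL_CHANNELS, , drop = FALSE]
  rec$channel_names <- CANONICAL_CHANNELS
  add_provenance(rec, "align_channels")
}

#' Aligned 7-channel run
#'
#' @param data 7 x samples matrix (canonical channel order).
#' @param sampling_rate Hz.
#' @param condition `"NFT"` or `"resting"`.
#' @param session_id,run_index identifiers.
#' @param partial flag set when the segment is shorter than the nominal
#'   run length.
#' @return an `aligned_run`.
#' @export
aligned_run <- function(data, sampling_rate, condition,
                        session_id = "S001", run_index = 1L, partial = FALSE) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == 7)
  rownames(data) <- CANONICAL_CHANNELS
  structure(list(data = data, channel_names = CANONICAL_CHANNELS,
                 sampling_rate = sampling_rate, condition = condition,
                 session_id = session_id, run_index = as.integer(run_index),
                 partial = partial),
            class = "aligned_run")
}

#' Extract annotated runs as aligned segments
#'
#' One [aligned_run()] per valid annotation; invalid annotations are
#' dropped, overlapping annotations are an error, and segments shorter
#' than `run_length_s` are flagged partial.
#'
#' @param rec an [eeg_recording()] already aligned to the 7 canonical
#'   channels.
#' @param run_length_s nominal run length in seconds (default 134).
#' @param session_id identifier stamped into every run.
#' @return list of `aligned_run`s.
#' @export
segment_runs <- function(rec, run_length_s = 134, session_id = "S001") {
  ann <- rec$annotations
  if (nrow(ann) == 0) {
    warnf("no annotations: returning an empty run list")
    return(list())
  }
  ann <- ann[order(ann$onset), , drop = FALSE]
  ends <- ann$onset + ann$duration
  if (nrow(ann) > 1 && any(ann$onset[-1] < ends[-nrow(ann)] - 1e-9))
    stopf("overlapping annotations")
  ann <- ann[ann$valid %in% TRUE, , drop = FALSE]
  fs <- rec$sampling_rate
  n_target <- round(run_length_s * fs)
  runs <- list()
  idx <- 0L
  for (i in seq_len(nrow(ann))) {
    start <- round(ann$onset[i] * fs) + 1L
    avail <- min(round((ann$onset[i] + ann$duration[i]) * fs), ncol(rec$data))
    take <- min(n_target, avail - start + 1L)
    if (take < 1) next
    idx <- idx + 1L
    runs[[idx]] <- aligned_run(rec$data[, start:(start + take - 1L), drop = FALSE],
                               fs, ann$label[i], session_id = session_id,
                               run_index = idx, partial = take < n_target)
  }
  runs
}

#' Baseline correction
#'
#' Subtracts the per-channel mean of the initial `baseline` seconds.
#'
#' @param run an [aligned_run()].
#' @param baseline seconds (default 0.5); must be positive and no longer
#'   than the run.
#' @return corrected run.
#' @export
baseline_correct <- function(run, baseline = 0.5) {
  if (baseline <= 0) stopf("baseline must be positive")
  nb <- round(baseline * run$sampling_rate)
  if (nb > ncol(run$data)) stopf("baseline window exceeds run duration")
  run$data <- run$data - rowMeans(run$data[, seq_len(nb), drop = FALSE])
  run
}

#' Session-level z-scoring
#'
#' Per channel, pools all runs of a session and standardizes to mean 0
#' and sd 1 over the pooled samples.
#'
#' @param runs list of [aligned_run()]s from one session.
#' @return list of standardized runs.
#' @export
zscore_session <- function(runs) {
  if (length(runs) < 1) stopf("zscore_session needs at least one run")
  pooled <- do.call(cbind, lapply(runs, function(r) r$data))
  mu <- rowMeans(pooled)
  centered <- pooled - mu
  sdv <- sqrt(rowSums(centered^2) / (ncol(pooled) - 1))
  if (any(sdv == 0))
    stopf("zero-variance channel(s) in session: %s",
          paste(CANONICAL_CHANNELS[sdv == 0], collapse = ", "))
  lapply(runs, function(r) {
    r$data <- (r$data - mu) / sdv
    r
  })
}

#' Full harmonization pipeline for one recording
#'
#' Applies the fixed stage order resample -> bandpass -> CAR -> ICA ->
#' align -> segment -> baseline -> z-score and records the applied steps
#' in the recording provenance.
#'
#' @param rec raw [eeg_recording()].
#' @param target_rate Hz (default 250).
#' @param band bandpass edges (default `c(0.5, 38)`).
#' @param order filter order (default 8).
#' @param car_keep_reference passed to [common_average_reference()].
#' @param criteria [ica_criteria()].
#' @param run_length_s segment length (default 134).
#' @param baseline_s baseline window (default 0.5).
#' @param session_id identifier.
#' @return list with `runs` (z-scored aligned runs) and `provenance`.
#' @export
preprocess_pipeline <- function(rec, target_rate = 250, band = c(0.5, 38),
                                order = 8L, car_keep_reference = TRUE,
                                criteria = ica_criteria(n_components = "auto"),
                                run_length_s = 134, baseline_s = 0.5,
                                session_id = "S001") {
  rec <- resample_to(rec, target_rate)
  rec <- bandpass_zero_phase(rec, band[1], band[2], order)
  rec <- common_average_reference(rec, car_keep_reference)
  rec <- remove_artifacts_ica(rec, criteria)$recording
  rec <- align_channels(rec)
  runs <- segment_runs(rec, run_length_s, session_id)
  runs <- lapply(runs, baseline_correct, baseline = baseline_s)
  runs <- zscore_session(runs)
  list(runs = runs, provenance = rec$provenance)
}
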