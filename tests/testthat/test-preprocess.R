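# Harmonization pipeline contracts.

analytic_butter_gain <- function(f, low, high, fs, order) {
  # prewarped analog Butterworth bandpass magnitude (exact for a
  # bilinear-transform design)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs); w2 <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  W <- fs2 * tan(pi * f / fs)
  1 / sqrt(1 + ((W^2 - w0^2) / (W * bw))^(2 * order))
}

test_that("resampling preserves rate-invariant content", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(7 * 500), 7), CHANNELS7, 250)
  same <- resample_to(rec, 250)
  expect_identical(same$data, rec$data)

  # 10 Hz sinusoid at 500 Hz downsampled to 250 Hz: amplitude error < 1%
  t <- seq(0, 4, by = 1 / 500)
  x <- matrix(rep(sin(2 * pi * 10 * t), each = 7), 7, byrow = FALSE)
  rec2 <- eeg_recording(x, CHANNELS7, 500,
                        annotations = data.frame(onset = 10, duration = 1,
                                                 label = "NFT", valid = TRUE))
  down <- resample_to(rec2, 250)
  expect_equal(down$sampling_rate, 250)
  expect_equal(ncol(down$data), ceiling(ncol(x) / 2))
  mid <- down$data[5, 200:800]
  expect_lt(abs(max(abs(mid)) - 1), 0.01)
  # annotations are stored in seconds: unchanged
  expect_equal(down$annotations$onset, 10)
  expect_warning(resample_to(rec, 2000), "upsampling")
})

test_that("bandpass filter matches the analytic Butterworth response", {
  fs <- 250
  filt <- butter_bandpass(0.5, 38, fs, 8)
  for (f in c(0.5, 5, 10, 38, 60)) {
    expect_equal(filter_gain(filt, f),
                 analytic_butter_gain(f, 0.5, 38, fs, 8), tolerance = 1e-9)
  }
  # zero in, zero out
  rec0 <- eeg_recording(matrix(0, 7, 1000), CHANNELS7, fs)
  expect_equal(max(abs(bandpass_zero_phase(rec0)$data)), 0)

  # 10 Hz passband sinusoid: zero-phase gain = |H|^2 within 1%
  t <- seq(0, 20, by = 1 / fs)
  rec10 <- eeg_recording(matrix(rep(sin(2 * pi * 10 * t), each = 7), 7),
                         CHANNELS7, fs)
  y <- bandpass_zero_phase(rec10)$data[1, ]
  amp <- max(abs(y[1000:4000]))
  expect_gte(amp, 0.99)
  expect_lte(amp, 1.01)

  # 60 Hz stopband sinusoid strongly attenuated
  rec60 <- eeg_recording(matrix(rep(sin(2 * pi * 60 * t), each = 7), 7),
                         CHANNELS7, fs)
  y60 <- bandpass_zero_phase(rec60)$data[1, ]
  expect_lt(max(abs(y60[1000:4000])), 0.01)
  expect_error(bandpass_zero_phase(eeg_recording(matrix(0, 2, 10), c("C3", "Cz"), 100),
                                   low = 0.5, high = 60), "Nyquist")
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  filt <- butter_bandpass(0.5, 38, 250, 8)
  n <- 8001
  pulse <- exp(-((seq_len(n) - 4001)^2) / (2 * 10^2))
  y <- sos_filtfilt(pulse, filt)
  expect_lt(max(abs(y - rev(y))) / max(abs(y)), 1e-6)
})

test_that("common average reference has its defining properties", {
  rec <- eeg_recording(matrix(c(1, 3), 2, 10), c("C3", "Cz"), 250)
  car <- common_average_reference(rec)
  expect_equal(unname(car$data[, 1]), c(-1, 1))
  set.seed(2)
  rec2 <- eeg_recording(matrix(rnorm(7 * 100), 7), CHANNELS7, 250)
  car2 <- common_average_reference(rec2)
  expect_lt(max(abs(colMeans(car2$data))), 1e-12)
  twice <- common_average_reference(car2)
  expect_equal(twice$data, car2$data)
  # retained reference: zero REF channel appended before averaging
  kept <- common_average_reference(rec2, keep_original_reference = TRUE)
  expect_true("REF" %in% kept$channel_names)
  expect_lt(max(abs(colMeans(kept$data))), 1e-12)
  expect_equal(qr(kept$data)$rank, 7)
  expect_error(common_average_reference(eeg_recording(matrix(0, 1, 5), "C3", 250)),
               "2 channels")
})

test_that("ICA reconstructs the input when no component is rejected", {
  set.seed(4)
  x <- matrix(rnorm(7 * 2000), 7)
  rec <- eeg_recording(x, CHANNELS7, 250)
  out <- remove_artifacts_ica(rec, ica_criteria(enabled = FALSE))
  expect_lt(max(abs(out$recording$data - x)) / max(abs(x)), 1e-6)
  expect_length(out$decomposition$rejected, 0)
})

test_that("ICA removes an injected low-frequency shared artifact", {
  set.seed(7)
  fs <- 250; ns <- 5000
  neural <- t(sapply(1:7, function(i)
    as.numeric(stats::filter(rnorm(ns), 0.5, method = "recursive"))))
  artifact <- 25 * sin(2 * pi * 1 * seq_len(ns) / fs)
  mix <- runif(7, 0.5, 1.5)
  noisy <- neural + outer(mix, artifact)
  out <- remove_artifacts_ica(eeg_recording(noisy, CHANNELS7, fs), ica_criteria())
  expect_gte(length(out$decomposition$rejected), 1)
  expect_true("ocular" %in% out$decomposition$reasons)
  rmse_in <- sqrt(mean((noisy - neural)^2))
  rmse_out <- sqrt(mean((out$recording$data - neural)^2))
  expect_lt(rmse_out, rmse_in)
})

test_that("ICA boundary cases: reject-all warning and rank-deficiency error", {
  set.seed(8)
  fs <- 250; ns <- 3000
  # every channel dominated by < 4 Hz power: all components ocular
  slow <- t(sapply(1:7, function(i)
    as.numeric(stats::filter(rnorm(ns), 0.99, method = "recursive"))))
  expect_warning(out <- remove_artifacts_ica(eeg_recording(slow, CHANNELS7, fs),
                                             ica_criteria()),
                 "all .* rejected")
  expect_equal(max(abs(out$recording$data)), 0)

  x <- matrix(rnorm(6 * 1000), 6)
  x <- rbind(x, colSums(x))   # rank 6 of 7
  expect_error(remove_artifacts_ica(eeg_recording(x, CHANNELS7, 250),
                                    ica_criteria(n_components = "full")),
               "rank 6 of 7")
})

test_that("channel alignment produces the canonical montage per device", {
  set.seed(5)
  n <- 100
  s <- sin(2 * pi * seq_len(n) / 25)
  flex_names <- c("C3", "Cz", "C4", "P3", "O1", "P7", "Oz", "Pz")
  d <- matrix(rnorm(8 * n), 8); rownames(d) <- flex_names
  d["P3", ] <- s; d["O1", ] <- s
  rec <- eeg_recording(d, flex_names, 250, device = "flex8")
  al <- align_channels(rec)
  expect_identical(al$channel_names, CHANNELS7)
  expect_equal(unname(al$data["PO3", ]), s)

  d["P3", ] <- 2; d["O1", ] <- 4
  al2 <- align_channels(eeg_recording(d, flex_names, 250, device = "flex8"))
  expect_equal(unname(al2$data["PO3", ]), rep(3, n))

  g <- matrix(rnorm(32 * n), 32)
  gnames <- c(CHANNELS7, paste0("X", 1:25))
  rec32 <- eeg_recording(g[sample(32), ], sample(gnames), 250, device = "gtec32")
  expect_identical(align_channels(rec32)$channel_names, CHANNELS7)
  expect_error(align_channels(eeg_recording(g[1:5, ], gnames[1:5], 250,
                                            device = "gtec32")),
               "missing required channel")
})

test_that("segmentation honours annotations, validity and run length", {
  fs <- 100
  n <- fs * 60
  rec <- eeg_recording(matrix(rnorm(7 * n), 7), CHANNELS7, fs,
                       annotations = data.frame(
                         onset = c(0, 12, 24, 36),
                         duration = c(10, 10, 10, 10),
                         label = c("NFT", "resting", "NFT", "NFT"),
                         valid = c(TRUE, TRUE, FALSE, TRUE)))
  runs <- segment_runs(rec, run_length_s = 10)
  expect_length(runs, 3)   # invalid annotation dropped
  expect_true(all(vapply(runs, function(r) ncol(r$data), 0L) == fs * 10))
  expect_false(any(vapply(runs, `[[`, TRUE, "partial")))
  # short annotation flagged partial
  rec2 <- eeg_recording(matrix(rnorm(7 * n), 7), CHANNELS7, fs,
                        annotations = data.frame(onset = 0, duration = 5,
                                                 label = "NFT", valid = TRUE))
  expect_true(segment_runs(rec2, run_length_s = 10)[[1]]$partial)
  # overlap error, empty warning
  rec3 <- eeg_recording(matrix(rnorm(7 * n), 7), CHANNELS7, fs,
                        annotations = data.frame(onset = c(0, 5), duration = c(10, 10),
                                                 label = c("NFT", "NFT"), valid = TRUE))
  expect_error(segment_runs(rec3, run_length_s = 10), "overlap")
  rec4 <- eeg_recording(matrix(rnorm(7 * 100), 7), CHANNELS7, fs)
  expect_warning(expect_length(segment_runs(rec4), 0), "no annotations")
})

test_that("baseline correction and z-scoring have their defining properties", {
  fs <- 250
  run <- make_run(matrix(5, 7, fs * 2), fs)
  expect_equal(max(abs(baseline_correct(run)$data)), 0)
  set.seed(6)
  run2 <- make_run(matrix(rnorm(7 * fs * 2), 7), fs)
  bc <- baseline_correct(run2, baseline = 0.5)
  expect_lt(max(abs(rowMeans(bc$data[, 1:(fs / 2)]))), 1e-12)
  expect_equal(baseline_correct(bc, 0.5)$data, bc$data)
  expect_error(baseline_correct(run2, 0), "positive")

  runs <- list(run2, make_run(matrix(rnorm(7 * fs), 7), fs))
  z <- zscore_session(runs)
  pooled <- do.call(cbind, lapply(z, `[[`, "data"))
  expect_lt(max(abs(rowMeans(pooled))), 1e-9)
  expect_lt(max(abs(apply(pooled, 1, sd) - 1)), 1e-9)
  # scale invariance
  z10 <- zscore_session(lapply(runs, function(r) { r$data <- r$data * 10; r }))
  expect_equal(z10[[1]]$data, z[[1]]$data, tolerance = 1e-12)
  # idempotence
  z2 <- zscore_session(z)
  expect_equal(z2[[1]]$data, z[[1]]$data, tolerance = 1e-9)
  flat <- make_run(matrix(0, 7, 100), fs)
  expect_error(zscore_session(list(flat)), "zero-variance")
})

test_that("the full pipeline is deterministic and records stage order", {
  set.seed(11)
  fs <- 250
  n <- fs * 30
  rec <- eeg_recording(matrix(rnorm(7 * n), 7), CHANNELS7, fs,
                       device = "synthetic",
                       annotations = data.frame(onset = c(1, 15),
                                                duration = c(10, 10),
                                                label = c("NFT", "resting"),
                                                valid = TRUE))
  a <- preprocess_pipeline(rec, run_length_s = 10)
  b <- preprocess_pipeline(rec, run_length_s = 10)
  expect_identical(a$runs, b$runs)
  expect_identical(a$provenance,
                   c("resample:250", "bandpass:0.5-38:order8", "car",
                     "ica:rejected=0", "align_channels"))
})

test_that("recordings round-trip through the CSV + sidecar format", {
  set.seed(12)
  rec <- eeg_recording(matrix(rnorm(7 * 50), 7), CHANNELS7, 250,
                       device = "gtec32",
                       annotations = data.frame(onset = 1, duration = 2,
                                                label = "NFT", valid = TRUE))
  path <- file.path(tempdir(), "rec.csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(unname(back$data), unname(rec$data), tolerance = 1e-12)
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$device, "gtec32")
  expect_equal(back$annotations$onset, 1)
})
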