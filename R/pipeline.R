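# End-to-end orchestration: simulate -> fit -> classify -> stats on
# synthetic data (plus file-based preprocess/networks stages), with a
# single JSON config, config-hash provenance and an artifact manifest.

trans_to_list <- function(A) lapply(unclass(A), unname)

trans_from_list <- function(l) transition_matrix(
  do.call(rbind, lapply(l$mc, unlist)),
  do.call(rbind, lapply(l$loc, unlist)),
  do.call(rbind, lapply(l$mc_loc, unlist)),
  do.call(rbind, lapply(l$mnet, unlist)))

#' Serialize fits to JSON
#'
#' Stores, per session fit: ids, consensus transition, final
#' per-transition estimates, the f1 trajectory and convergence state.
#'
#' @param fits list of `pnda_fit`s.
#' @param path output file.
#' @export
write_fits_json <- function(fits, path) {
  ser <- lapply(fits, function(f) list(
    session_id = f$session_id, condition = f$condition,
    consensus_A = trans_to_list(f$consensus_A),
    final_transitions = lapply(f$final_transitions, trans_to_list),
    per_iteration_f1 = f$per_iteration_f1,
    f1_initial = f$f1_initial, f1_final = f$f1_final,
    iterations_used = f$iterations_used, converged = f$converged))
  jsonlite::write_json(ser, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read fits written by [write_fits_json()]
#'
#' @param path JSON file.
#' @return list of reduced `pnda_fit`s (no chains attached).
#' @export
read_fits_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(f) structure(list(
    session_id = f$session_id, condition = f$condition,
    consensus_A = trans_from_list(f$consensus_A),
    final_transitions = lapply(f$final_transitions, trans_from_list),
    per_iteration_f1 = unlist(f$per_iteration_f1),
    f1_initial = f$f1_initial, f1_final = f$f1_final,
    iterations_used = f$iterations_used, converged = f$converged),
    class = "pnda_fit"))
}

#' Write / read a multichannel recording as CSV with a JSON sidecar
#'
#' The CSV holds one row per channel (no header); the sidecar stores
#' channel names, sampling rate, device and annotations.
#'
#' @param rec an [eeg_recording()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @export
write_recording_csv <- function(rec, path) {
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(channel_names = rec$channel_names,
               sampling_rate = rec$sampling_rate,
               device = rec$device,
               annotations = rec$annotations)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = I(17),
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_recording_csv
#' @return for the reader, an [eeg_recording()].
#' @export
read_recording_csv <- function(path) {
  d <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ann <- meta$annotations
  if (length(ann) == 0) ann <- NULL else ann <- as.data.frame(ann)
  eeg_recording(unname(d), meta$channel_names, meta$sampling_rate,
                device = meta$device, annotations = ann)
}

config_hash <- function(config) {
  # hash only the scientific configuration, not artifact locations
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, digits = I(17), auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Pipeline configuration
#'
#' @param seed global seed.
#' @param out_dir artifact directory.
#' @param n_sessions synthetic sessions (default 40).
#' @param sim extra arguments for [sim_config()].
#' @param pnda arguments for [pnda_config()].
#' @param cnn arguments for [cnn_spec()].
#' @param split_seed session-split seed (defaults to `seed`).
#' @param alpha FDR level for the stats stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "pnda_out",
                            n_sessions = 40L, sim = list(),
                            pnda = list(), cnn = list(),
                            split_seed = NULL, alpha = 0.05) {
  list(seed = as.integer(seed), out_dir = out_dir,
       n_sessions = as.integer(n_sessions), sim = sim, pnda = pnda,
       cnn = cnn, split_seed = split_seed %||% as.integer(seed),
       alpha = alpha)
}

stage_done <- function(dir, stage, hash) {
  marker <- file.path(dir, paste0(stage, ".stamp.json"))
  if (!file.exists(marker)) return(FALSE)
  st <- jsonlite::read_json(marker)
  identical(st$config_hash, hash)
}

stamp_stage <- function(dir, stage, hash, files) {
  jsonlite::write_json(list(stage = stage, config_hash = hash,
                            files = files,
                            time = format(Sys.time(), tz = "UTC")),
                       file.path(dir, paste0(stage, ".stamp.json")),
                       auto_unbox = TRUE)
}

#' Run the synthetic end-to-end pipeline
#'
#' Stages: `simulate` (two-class network-level dataset), `fit`
#' (per-chain noise-adapted dynamics), `classify` (session-split CNN on
#' transition tensors) and `stats` (weight-wise tests with BH-FDR).
#' Stages whose outputs exist with a matching config hash are skipped
#' unless `force`. Every artifact is listed in the returned manifest
#' with its md5 hash; the manifest is also written to
#' `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (in canonical order).
#' @param force rerun stages even when their stamps match.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "fit", "classify", "stats"),
                         force = FALSE) {
  stages <- match.arg(stages, c("simulate", "fit", "classify", "stats"),
                      several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  paths <- list(sessions = file.path(config$out_dir, "sessions.json"),
                fits = file.path(config$out_dir, "fits.json"),
                report = file.path(config$out_dir, "classification.json"),
                stats = file.path(config$out_dir, "weight_stats.csv"))

  if ("simulate" %in% stages && (force || !stage_done(config$out_dir, "simulate", hash))) {
    sc <- do.call(sim_config, c(list(n_sessions = config$n_sessions,
                                     seed = config$seed), config$sim))
    sessions <- make_two_class_dataset(sc)
    write_sessions_json(sessions, paths$sessions)
    stamp_stage(config$out_dir, "simulate", hash, paths$sessions)
  }

  if ("fit" %in% stages && (force || !stage_done(config$out_dir, "fit", hash))) {
    if (!file.exists(paths$sessions))
      stopf("fit stage: missing input %s (run the simulate stage first)", paths$sessions)
    sessions <- read_sessions_json(paths$sessions)
    pc <- do.call(pnda_config, config$pnda)
    fits <- unlist(lapply(sessions, function(s) lapply(s$chains, function(ch) {
      ch$session_id <- s$session_id
      pnda_fit_session(ch, pc)
    })), recursive = FALSE)
    write_fits_json(fits, paths$fits)
    stamp_stage(config$out_dir, "fit", hash, paths$fits)
  }

  if ("classify" %in% stages && (force || !stage_done(config$out_dir, "classify", hash))) {
    if (!file.exists(paths$fits))
      stopf("classify stage: missing input %s (run the fit stage first)", paths$fits)
    fits <- read_fits_json(paths$fits)
    res <- classify_fits(fits, split_seed = config$split_seed,
                         cnn = do.call(cnn_spec, config$cnn),
                         train_seed = config$seed)
    jsonlite::write_json(list(
      metrics = unclass(res$report)[c("accuracy", "f1_score", "tpr", "tnr", "auc")],
      confusion = as.list(res$report$confusion),
      split = res$split, config_hash = hash),
      paths$report, digits = I(17), auto_unbox = TRUE)
    stamp_stage(config$out_dir, "classify", hash, paths$report)
  }

  if ("stats" %in% stages && (force || !stage_done(config$out_dir, "stats", hash))) {
    if (!file.exists(paths$fits))
      stopf("stats stage: missing input %s (run the fit stage first)", paths$fits)
    fits <- read_fits_json(paths$fits)
    rep <- weight_stats_report(fits[vapply(fits, `[[`, "", "condition") == "NFT"],
                               fits[vapply(fits, `[[`, "", "condition") == "resting"],
                               alpha = config$alpha, seed = config$seed)
    utils::write.csv(rep, paths$stats, row.names = FALSE)
    stamp_stage(config$out_dir, "stats", hash, paths$stats)
  }

  files <- unlist(paths)[file.exists(unlist(paths))]
  manifest <- list(config_hash = hash,
                   artifacts = lapply(files, function(f)
                     list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Session-split CNN classification of a set of fits
#'
#' Splits sessions 7:1:2 (leakage-free), trains the transition-tensor
#' CNN and evaluates on the held-out sessions.
#'
#' @param fits list of `pnda_fit`s (both conditions).
#' @param split_seed seed of the session shuffle.
#' @param cnn a [cnn_spec()].
#' @param train_seed training seed.
#' @return list with `report` ([evaluate_classifier()] output), `split`,
#'   `model`, and the test tensor set.
#' @export
classify_fits <- function(fits, split_seed = 1L, cnn = cnn_spec(),
                          train_seed = 1L) {
  ids <- unique(vapply(fits, `[[`, "", "session_id"))
  split <- split_sessions(ids, split_spec(seed = split_seed))
  pick <- function(part) {
    sel <- fits[vapply(fits, `[[`, "", "session_id") %in% split[[part]]]
    sets <- lapply(sel, tensorize_transitions)
    list(tensors = do.call(c, lapply(sets, `[[`, "tensors")),
         labels = do.call(c, lapply(sets, `[[`, "labels")),
         session_ids = do.call(c, lapply(sets, `[[`, "session_ids")))
  }
  train <- pick("train"); val <- pick("val"); test <- pick("test")
  model <- train_classifier(train, val, cnn, seed = train_seed)
  list(report = evaluate_classifier(model, test), split = split,
       model = model, test = test)
}

#' Permutation (shuffled-label) control
#'
#' Permutes the condition labels across all chains' fits before the
#' session split, trains the CNN on the permuted labels and evaluates
#' against the permuted test labels. Under this global permutation the
#' test accuracy is binomially distributed around 0.5 whatever the
#' classifier does, which is the correct chance null for a dataset whose
#' feature space is strongly clustered.
#'
#' @param fits list of `pnda_fit`s.
#' @param split_seed,train_seed seeds as in [classify_fits()].
#' @param perm_seed seed of the label permutation.
#' @param cnn a [cnn_spec()].
#' @return as [classify_fits()].
#' @export
shuffled_label_control <- function(fits, split_seed = 1L, train_seed = 1L,
                                   perm_seed = 1L, cnn = cnn_spec()) {
  set.seed(perm_seed)
  labs <- vapply(fits, `[[`, "", "condition")
  perm <- sample(labs)
  fits <- mapply(function(f, l) { f$condition <- l; f }, fits, perm,
                 SIMPLIFY = FALSE)
  classify_fits(fits, split_seed = split_seed, cnn = cnn,
                train_seed = train_seed)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit`, `classify`, `stats`, `run`; common
#' options `--seed`, `--out`, `--config` (JSON file of
#' [pipeline_config()] overrides), `--stages`, `--force`. Installed as
#' `inst/scripts/pnda_cli.R`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
pnda_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: pnda <simulate|fit|classify|stats|run> [--seed N] [--out DIR] [--config FILE] [--stages a,b] [--force]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(seed = 1L, out = "pnda_out", config = NULL,
              stages = NULL, force = FALSE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--force") { opt$force <- TRUE; i <- i + 1; next }
    if (i + 1 > length(args)) stopf("missing value for option %s", a)
    v <- args[i + 1]
    switch(a,
           "--seed" = { opt$seed <- as.integer(v) },
           "--out" = { opt$out <- v },
           "--config" = { opt$config <- v },
           "--stages" = { opt$stages <- strsplit(v, ",")[[1]] },
           stopf("unknown option %s", a))
    i <- i + 2
  }
  overrides <- if (!is.null(opt$config)) jsonlite::read_json(opt$config, simplifyVector = TRUE) else list()
  cfg <- do.call(pipeline_config,
                 utils::modifyList(list(seed = opt$seed, out_dir = opt$out),
                                   overrides))
  stages <- switch(cmd,
                   simulate = "simulate", fit = "fit",
                   classify = "classify", stats = "stats",
                   run = opt$stages %||% c("simulate", "fit", "classify", "stats"),
                   stopf("unknown subcommand '%s'", cmd))
  run_pipeline(cfg, stages = stages, force = opt$force)
  invisible(0L)
}
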