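#' Default pipeline configuration
#'
#' Nested list validated against a fixed schema; unknown keys are
#' rejected. `synthesis$n_per_type = NULL` means the published per-type
#' sample sizes.
#'
#' @return named list
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthesis = list(
      rate = 11025,
      n_per_type = NULL,
      gap = 0.25,
      n_degraded = 0L,
      n_moan = 0L
    ),
    features = list(
      smooth_hz = 30
    ),
    rf = list(
      n_trees = 500L
    ),
    soundscape = list(
      time_bin = 5,
      freq_bin = 5,
      psd_window = 1,
      bb_band = c(20, 5500),
      octave_centers = c(125, 500, 2000)
    ),
    calibration = NULL
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- paste0(path, k)
    if (!k %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[k]]) && is.list(user[[k]]) && k != "n_per_type") {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(full, "$"))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file, or NULL for defaults
#' @return validated config list (attribute `hash`: md5 of the file)
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  hash <- "default"
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    # calibration block is all-or-nothing
    if (!is.null(user$calibration)) {
      cal <- user$calibration
      extra <- setdiff(names(cal), c("sensitivity", "gain", "adc_full_scale"))
      if (length(extra)) stop("unknown config key: calibration$", extra[1])
      cfg$calibration <- do.call(hydrophone_cal, cal)
      user$calibration <- NULL
    }
    cfg <- merge_config(cfg, user)
    hash <- unname(tools::md5sum(path))
  }
  attr(cfg, "hash") <- hash
  cfg
}

write_run_log <- function(out_dir, stage, config, t0) {
  log_path <- file.path(out_dir, paste0(stage, "_run_log.txt"))
  writeLines(c(
    sprintf("stage: %s", stage),
    sprintf("package: sealscape %s", as.character(utils::packageVersion("sealscape"))),
    sprintf("R: %s", R.version.string),
    sprintf("config_hash: %s", attr(config, "hash") %||% "default"),
    sprintf("seed: %s", config$seed),
    sprintf("wall_time_s: %.2f", as.numeric(Sys.time()) - t0),
    sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), log_path)
  invisible(log_path)
}

#' Generate the synthetic call corpus
#'
#' Writes, per call category, one WAV with the calls laid out sequentially
#' (fixed silent gap between calls), an annotation track, a pooled
#' ground-truth CSV, and a manifest with md5 checksums of every artifact.
#' Deterministic for a fixed seed.
#'
#' @param config pipeline config ([read_pipeline_config()])
#' @param out_dir output directory (created)
#' @return manifest list, invisibly
#' @export
run_synth <- function(config = default_config(), out_dir) {
  t0 <- as.numeric(Sys.time())
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  set.seed(config$seed)
  rate <- config$synthesis$rate
  gap <- config$synthesis$gap
  p <- repertoire_params()
  n_per_type <- config$synthesis$n_per_type
  if (is.null(n_per_type)) n_per_type <- stats::setNames(p$n, p$name)
  n_per_type <- unlist(n_per_type)
  if (config$synthesis$n_moan > 0) n_per_type <- c(n_per_type, moan = config$synthesis$n_moan)

  files <- character(0)
  truth_all <- NULL
  k_deg <- config$synthesis$n_degraded
  for (cat in c("harmonic", "noisy", "pulsative")) {
    types <- p$name[p$category == cat]
    if (cat == "harmonic" && "moan" %in% names(n_per_type)) types <- c(types, "moan")
    types <- intersect(types, names(n_per_type))
    waves <- list()
    labels <- NULL
    truth <- NULL
    n_gap <- round(gap * rate)
    cursor <- n_gap                          # sample-exact placement
    for (ty in types) {
      spec <- type_spec(ty)
      for (i in seq_len(n_per_type[[ty]])) {
        out <- retry_synth(spec, rate)
        w <- as.numeric(out$wave)
        lab <- ty
        if (k_deg > 0 && i == n_per_type[[ty]]) {  # flag the type's last call
          lab <- paste0(ty, "|degraded")
          k_deg <- k_deg - 1L
        }
        labels <- rbind(labels, data.frame(
          start = cursor / rate, end = (cursor + length(w)) / rate, label = lab,
          stringsAsFactors = FALSE))
        tr <- out$truth
        tr$start <- cursor / rate
        waves[[length(waves) + 1L]] <- w
        truth <- rbind(truth, tr)
        cursor <- cursor + length(w) + n_gap
      }
    }
    if (!length(waves)) next                 # category absent from config
    xs <- lapply(waves, function(w) c(w, numeric(n_gap)))
    x <- c(numeric(n_gap), unlist(xs))
    wav_path <- file.path(out_dir, paste0("corpus_", cat, ".wav"))
    lab_path <- file.path(out_dir, paste0("corpus_", cat, "_labels.txt"))
    write_wav(audio_segment(x, rate = rate), wav_path, bits = 16L)
    write_label_track(labels, lab_path)
    truth$file <- basename(wav_path)
    truth_all <- rbind(truth_all, truth)
    files <- c(files, wav_path, lab_path)
  }
  gt_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(truth_all, gt_path, row.names = FALSE)
  files <- c(files, gt_path)

  manifest <- list(
    seed = config$seed, rate = rate,
    n_calls = nrow(truth_all),
    config_hash = attr(config, "hash") %||% "default",
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_run_log(out_dir, "synth", config, t0)
  invisible(manifest)
}

# a sampled spec draw can be degenerate (e.g. a pulsative duration too
# short for two pulses); redraw within the truncated world
retry_synth <- function(spec, rate, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    out <- tryCatch(synth_call(spec, seed = NULL, rate = rate),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("synthesis failed repeatedly for type ", spec$call_type)
}

#' Extract features from a generated dataset
#'
#' Reads each category WAV and its label track, measures every
#' good-quality call, and writes `features.csv` (all internally computed
#' variables), `features_report.csv` (per-type availability mask applied)
#' and `skipped.csv` (call id + reason for moans, degraded calls and
#' failed measurements).
#'
#' @param config pipeline config
#' @param dataset_dir directory produced by [run_synth()]
#' @param out_dir output directory
#' @return the internal feature data.frame, invisibly
#' @export
run_features <- function(config = default_config(), dataset_dir, out_dir) {
  t0 <- as.numeric(Sys.time())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lab_files <- list.files(dataset_dir, pattern = "_labels\\.txt$", full.names = TRUE)
  if (!length(lab_files)) stop("no label tracks found in ", dataset_dir)
  feats <- NULL
  report <- NULL
  skipped <- NULL
  for (lf in lab_files) {
    wav <- sub("_labels\\.txt$", ".wav", lf)
    if (!file.exists(wav)) stop("missing audio file referenced by labels: ", wav)
    wave <- read_wav(wav)
    labels <- read_label_track(lf)
    ft <- extract_feature_table(wave, labels, report = FALSE)
    rp <- extract_feature_table(wave, labels, report = TRUE)
    if (nrow(ft)) {
      ft$file <- basename(wav)
      rp$file <- basename(wav)
    }
    sk <- attr(ft, "skipped")
    if (nrow(sk)) sk$file <- basename(wav)
    feats <- rbind(feats, ft)
    report <- rbind(report, rp)
    skipped <- rbind(skipped, sk)
  }
  utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(report, file.path(out_dir, "features_report.csv"), row.names = FALSE)
  utils::write.csv(skipped, file.path(out_dir, "skipped.csv"), row.names = FALSE)
  for (i in seq_len(nrow(skipped))) {
    message(sprintf("skipped call %s (%s): %s", skipped$call_id[i],
                    skipped$type[i], skipped$reason[i]))
  }
  write_run_log(out_dir, "features", config, t0)
  invisible(feats)
}

#' Random-Forest repertoire validation per category
#'
#' Runs the category-specific forest on a feature table and serializes a
#' confusion matrix CSV per category plus a JSON summary (overall error,
#' accuracy, Gini ranking, per-class errors). Categories with fewer than
#' two types are skipped with a warning.
#'
#' @param config pipeline config
#' @param features feature data.frame or path to `features.csv`
#' @param out_dir output directory
#' @return named list of [rf_validate()] results, invisibly
#' @export
run_repertoire <- function(config = default_config(), features, out_dir) {
  t0 <- as.numeric(Sys.time())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(features)) features <- utils::read.csv(features)
  set.seed(config$seed)
  results <- list()
  summary <- list()
  for (cat in unique(features$category)) {
    sub <- features[features$category == cat, , drop = FALSE]
    if (length(unique(sub$type)) < 2L) {
      warning("category '", cat, "' has fewer than 2 types; skipped")
      next
    }
    cfg <- rf_config(cat, n_trees = config$rf$n_trees)
    sub <- sub[stats::complete.cases(sub[, cfg$variables, drop = FALSE]), ,
               drop = FALSE]
    res <- rf_validate(sub, cfg)
    results[[cat]] <- res
    utils::write.csv(cbind(data.frame(type = rownames(res$confusion)),
                           as.data.frame(res$confusion),
                           error = round(res$per_class_error, 3)),
                     file.path(out_dir, paste0("confusion_", cat, ".csv")),
                     row.names = FALSE)
    summary[[cat]] <- list(
      n_calls = sum(res$confusion),
      oob_error_pct = round(100 * res$oob_error, 2),
      accuracy_pct = round(100 * res$accuracy, 2),
      gini_importance = as.list(round(res$importance, 2)),
      per_class_error = as.list(round(res$per_class_error, 3))
    )
  }
  jsonlite::write_json(summary, file.path(out_dir, "rf_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_run_log(out_dir, "repertoire", config, t0)
  invisible(results)
}

#' Soundscape metrics for a recording
#'
#' Computes the LTSA, PSD percentile curves and broadband/octave level
#' series, optionally with hourly/daily noise-budget outputs when a noise
#' label track is supplied. Without a calibration block, levels are in dB
#' relative to digital full scale and flagged as such.
#'
#' @param config pipeline config
#' @param recording an [audio_segment()] or WAV path
#' @param out_dir output directory
#' @param noise_labels optional label track path or data.frame
#'   (`noise:`-tagged rows are used); combined with `n_days = 1`
#' @return list of computed metrics, invisibly
#' @export
run_soundscape <- function(config = default_config(), recording, out_dir,
                           noise_labels = NULL) {
  t0 <- as.numeric(Sys.time())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(recording)) recording <- read_wav(recording)
  calibrated <- !is.null(config$calibration)
  seg <- if (calibrated) calibrate(recording, config$calibration) else recording
  ref <- if (calibrated) "dB re 1 uPa" else "dB re full scale"
  sc <- config$soundscape

  lt <- ltsa(seg, time_bin = sc$time_bin, freq_bin = sc$freq_bin)
  utils::write.csv(
    cbind(data.frame(time = lt$times),
          stats::setNames(as.data.frame(lt$db),
                          sprintf("f%g", lt$freq))),
    file.path(out_dir, "ltsa.csv"), row.names = FALSE)

  psd <- psd_percentiles(seg, window = sc$psd_window)
  utils::write.csv(
    cbind(data.frame(freq = psd$freq),
          stats::setNames(as.data.frame(t(psd$db)),
                          rownames(psd$db))),
    file.path(out_dir, "psd_percentiles.csv"), row.names = FALSE)

  bands <- c(list(BB = sc$bb_band),
             stats::setNames(lapply(sc$octave_centers, octave_band),
                             sprintf("OL%g", sc$octave_centers)))
  bl <- band_levels(seg, bands = bands, time_bin = sc$time_bin,
                    window = sc$psd_window)
  utils::write.csv(bl, file.path(out_dir, "band_levels.csv"), row.names = FALSE)

  budget <- NULL
  if (!is.null(noise_labels)) {
    if (is.character(noise_labels)) noise_labels <- read_label_track(noise_labels)
    noise <- noise_labels[startsWith(noise_labels$label, "noise:"), , drop = FALSE]
    if (nrow(noise)) {
      ev <- noise_events(day = rep(1L, nrow(noise)),
                         start = noise$start, end = noise$end,
                         source = sub("^noise:", "", noise$label))
      hp <- hourly_presence(ev, n_days = 1)
      dt <- daily_totals(ev)
      utils::write.csv(data.frame(hour = 0:23, mean_hours = hp),
                       file.path(out_dir, "noise_hourly.csv"), row.names = FALSE)
      utils::write.csv(dt, file.path(out_dir, "noise_daily.csv"), row.names = FALSE)
      budget <- list(hourly = hp, daily = dt)
    }
  }
  writeLines(c(sprintf("reference: %s", ref),
               sprintf("calibrated: %s", calibrated)),
             file.path(out_dir, "level_reference.txt"))
  write_run_log(out_dir, "soundscape", config, t0)
  invisible(list(ltsa = lt, psd = psd, band_levels = bl, budget = budget,
                 reference = ref))
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `features`, `repertoire`, `soundscape`, `all`.
#' Flags: `--config FILE`, `--seed N`, `--out DIR`, `--in DIR` (dataset or
#' features input), `--wav FILE`, `--log-level LEVEL`.
#'
#' @param args character vector (default: command line)
#' @return exit status, invisibly
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: sealscape <synth|features|repertoire|soundscape|all> [--config FILE] [--seed N] [--out DIR] [--in DIR] [--wav FILE]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(config = NULL, seed = NULL, out = "sealscape_out",
              `in` = NULL, wav = NULL, `log-level` = "info")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  config <- read_pipeline_config(opt$config)
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)

  switch(cmd,
    synth = run_synth(config, opt$out),
    features = run_features(config, opt$`in` %||% opt$out, opt$out),
    repertoire = run_repertoire(config,
                                file.path(opt$`in` %||% opt$out, "features.csv"),
                                opt$out),
    soundscape = run_soundscape(config, opt$wav, opt$out,
                                noise_labels = opt$`in`),
    all = {
      run_synth(config, opt$out)
      feats <- run_features(config, opt$out, opt$out)
      run_repertoire(config, feats, opt$out)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
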