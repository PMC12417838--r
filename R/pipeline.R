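# End-to-end orchestration: synth -> preprocess -> spectra -> features ->
# PLV -> group stats -> classification, as a configured, seeded, logged run.

#' Default pipeline configuration
#'
#' A single nested list driving [run_pipeline()]; every stage parameter the
#' analysis depends on surfaces here with its default (filter band, Welch
#' window, line-noise half-width, band tables, fit ranges, artifact
#' thresholds, split/CV settings). `stages` toggles individual stages.
#'
#' @param seed Integer master seed.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(preprocess = TRUE, spectra = TRUE, plv = TRUE,
                  stats = TRUE, classify = TRUE),
    synth = list(sampling_rate = 500, duration = 20,
                 channels_per_compartment = c(
                   tumoral = 30, close_peritumoral = 30,
                   far_peritumoral = 30, healthy = 30),
                 n_patients = 4),
    preprocess = list(low_hz = 0.1, high_hz = NA, resample_hz = NA,
                      amplitude_z_threshold = 8, flatline_epsilon = 1e-12),
    spectra = list(window_seconds = 2, overlap_fraction = 0.5,
                   mains_hz = 50, line_half_width_hz = 1,
                   normalization = "per_feature"),
    aperiodic = list(max_peaks = 6, min_peak_height = 0.1),
    plv = list(trim_seconds = 1),
    stats = list(adjust = "holm"),
    infiltration = list(n_biopsies = 26, effect_feature = "abs_beta",
                        effect_size = -0.5),
    classify = list(train_fraction = 0.7, cv_folds = 5,
                    n_learners = 30, subspace_dim = 19,
                    two_class = "tumoral_vs_rest")
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  modifyList(default_pipeline_config(), user)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a synthetic recording (or accepts one), applies artifact
#' rejection and optional filtering/resampling, computes Welch spectra with
#' line-noise exclusion, band-power and aperiodic feature blocks, per-band
#' PLV compartment summaries, compartment group statistics, infiltration
#' correlations, and both classifiers under the 4-class and 2-class
#' schemes. All artifacts are written under `out_dir` together with a
#' manifest (package version, config, seed, per-stage counts).
#'
#' @param config Configuration list, see [default_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param recording Optional [ecog_recording()] (with `label` and
#'   `patient_id` metadata) to analyze instead of generating one.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("ecogmap_run_"),
                         recording = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  counts <- list()

  if (is.null(recording)) {
    sc <- do.call(synth_config, c(config$synth, list(seed = config$seed)))
    gen <- generate_recording(sc)
    rec <- gen$recording
    truth <- gen$ground_truth
    say("synth: %d channels @ %g Hz, %g s", nrow(rec$samples),
        rec$sampling_rate, ncol(rec$samples) / rec$sampling_rate)
  } else {
    rec <- recording
    truth <- NULL
  }
  counts$channels <- nrow(rec$samples)

  if (isTRUE(config$stages$preprocess)) {
    pp <- config$preprocess
    if (!is.null(pp$resample_hz) && !is.na(pp$resample_hz) &&
        pp$resample_hz < rec$sampling_rate) {
      rec <- resample_recording(rec, pp$resample_hz)
      say("preprocess: resampled to %g Hz", rec$sampling_rate)
    }
    if (!is.null(pp$high_hz) && !is.na(pp$high_hz)) {
      rec <- bandpass_zero_phase(rec, pp$low_hz, pp$high_hz)
      say("preprocess: bandpass %g-%g Hz", pp$low_hz, pp$high_hz)
    }
    mask <- reject_artifacts(rec, pp$amplitude_z_threshold,
                             pp$flatline_epsilon)
    say("preprocess: %d/%d channels retained, %.1f s median duration",
        sum(!mask$removed), length(mask$removed),
        median(mask$retained_seconds))
  } else {
    mask <- full_mask(rec)
  }
  counts$channels_retained <- sum(!mask$removed)

  results <- list(config = config, recording_meta = rec$channel_meta,
                  ground_truth = truth)

  sp <- config$spectra
  psd <- welch_psd(rec, mask, sp$window_seconds, sp$overlap_fraction)
  psd <- remove_line_noise(psd, sp$mains_hz, sp$line_half_width_hz)
  bp <- band_powers(psd)
  ap <- aperiodic_feature_block(psd,
                                max_peaks = config$aperiodic$max_peaks,
                                min_peak_height = config$aperiodic$min_peak_height)
  features <- assemble_features(bp, ap, rec$channel_meta,
                                normalization = sp$normalization)
  write_tsv(features, file.path(out_dir, "features.tsv"))
  say("spectra: %d features x %d channels (%d complete)",
      length(feature_columns()), nrow(features), sum(features$complete))
  counts$feature_rows_complete <- sum(features$complete)
  results$features <- features

  if (isTRUE(config$stages$plv)) {
    plv_sum <- lapply(names(plv_bands()), function(bn) {
      pm <- plv_matrix(rec, plv_bands()[[bn]], band_name = bn,
                       trim_seconds = config$plv$trim_seconds)
      write_tsv(as.data.frame(pm$values),
                file.path(out_dir, sprintf("plv_%s.tsv", bn)))
      compartment_plv_summary(pm, rec$channel_meta$label)
    })
    names(plv_sum) <- names(plv_bands())
    jsonlite::write_json(
      lapply(plv_sum, function(s) as.data.frame(s$means)),
      file.path(out_dir, "plv_summary.json"))
    say("plv: %d bands summarized", length(plv_sum))
    results$plv <- plv_sum
  }

  if (isTRUE(config$stages$stats)) {
    gs <- compartment_feature_stats(features[features$complete, ],
                                    adjust = config$stats$adjust)
    write_tsv(gs$summary, file.path(out_dir, "group_summary.tsv"))
    write_tsv(gs$pairwise, file.path(out_dir, "group_pairwise.tsv"))
    inf_cfg <- config$infiltration
    n_peri <- sum(features$label %in% c("close_peritumoral",
                                        "far_peritumoral") &
                  is.finite(features[[inf_cfg$effect_feature]]))
    n_bx <- min(inf_cfg$n_biopsies, n_peri)
    if (n_bx < inf_cfg$n_biopsies)
      say("stats: capping biopsies at %d (peritumoral channels available)",
          n_bx)
    if (n_bx >= 4) {
      biopsies <- generate_infiltration_table(
        features, effect_feature = inf_cfg$effect_feature,
        effect_size = inf_cfg$effect_size, n_biopsies = n_bx,
        seed = config$seed)
      write_tsv(biopsies, file.path(out_dir, "biopsies.tsv"))
      infc <- stratify_and_correlate(biopsies, features,
                                     feature_cols = feature_columns()[1:19])
      write_tsv(infc, file.path(out_dir, "infiltration_correlations.tsv"))
      say("stats: %d features tested; %d biopsies correlated",
          nrow(gs$summary), nrow(biopsies))
      results$biopsies <- biopsies
      results$infiltration <- infc
    } else {
      say("stats: %d features tested; too few peritumoral channels for biopsies",
          nrow(gs$summary))
    }
    results$group_stats <- gs
  }

  if (isTRUE(config$stages$classify)) {
    cl <- config$classify
    runs <- list()
    for (scheme in c("4class", "2class")) {
      for (model in c("knn_ensemble", "svm")) {
        extra <- if (model == "knn_ensemble")
          list(n_learners = cl$n_learners, subspace_dim = cl$subspace_dim)
        else list()
        r <- do.call(run_classification,
                     c(list(features = features, scheme = scheme,
                            model = model,
                            train_fraction = cl$train_fraction,
                            cv_folds = cl$cv_folds, seed = config$seed,
                            two_class = cl$two_class), extra))
        key <- paste(model, scheme, sep = "_")
        runs[[key]] <- r
        write_tsv(as.data.frame.matrix(r$report$confusion),
                  file.path(out_dir, sprintf("confusion_%s.tsv", key)))
        say("classify: %s %s macro-F1 %.3f (train %d / test %d)",
            model, scheme, r$report$macro["f1"], r$n_train, r$n_test)
      }
    }
    jsonlite::write_json(
      lapply(runs, function(r) list(
        scheme = r$report$scheme, accuracy = r$report$accuracy,
        macro = as.list(r$report$macro), per_class = r$report$per_class,
        best_hyperparameter = r$cv$best,
        n_train = r$n_train, n_test = r$n_test)),
      file.path(out_dir, "classification_reports.json"), auto_unbox = TRUE)
    results$classification <- runs
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, null = "null")
  manifest <- list(
    package = "ecogmap",
    version = as.character(packageVersion("ecogmap")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    counts = counts,
    log = log_lines,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}
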