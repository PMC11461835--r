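#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end flow: cohort simulation (or EDF
#' input), preprocessing, layer-1 (MCSA) augmentation, feature extraction,
#' layer-2 (CTGAN) augmentation and classifier evaluation. Serializable to
#' YAML via [write_pipeline_config()] / [read_pipeline_config()]; unknown
#' keys are rejected on read.
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Global seed (stage seeds default to it).
#' @return Nested named list of class `sleepaug_config`.
#' @export
default_config <- function(out_dir = tempfile("sleepaug_run_"), seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    layers = "both",                 # none | mcsa_only | ctgan_only | both
    edf_dir = NULL,                  # read recordings instead of simulating
    cohort = list(n_insomnia = 6, n_healthy = 6, fs = 512, duration_s = 60,
                  subject_sd = 0.1, planted_gap_sd = NULL,
                  powerline_amp = 0, drift_amp = 0),
    preprocess = list(lo_hz = 0.5, hi_hz = 45, order = 4, epoch_s = 30,
                      denoise_level = 5),
    mcsa = list(scale_factor = 1.5, snr_db = 10),
    ctgan = list(epochs = 2000, batch = NULL, n_samples = 10000,
                 latent_dim = 128, max_modes = 10),
    eval = list(bands = c(BAND_NAMES, "combined"),
                models = c("DT", "EBDT", "GB", "RF", "SC"),
                random_state = 22, kfold = 5, subject_folds = 6)),
    class = c("sleepaug_config", "list"))
}

check_config_keys <- function(cfg, ref = default_config(), path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad)) {
    abort(sprintf("Unknown config key%s: %s",
                  if (length(bad) > 1) "s" else "",
                  paste0(path, bad, collapse = ", ")),
          class = "sleepaug_config_error")
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @param cfg A `sleepaug_config`.
#' @return `read_pipeline_config()` a validated `sleepaug_config` (missing
#'   keys filled from [default_config()]); `write_pipeline_config()` the path
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_config_keys(raw)
  cfg <- utils::modifyList(default_config(), raw, keep.null = TRUE)
  class(cfg) <- c("sleepaug_config", "list")
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_spec <- function(cfg) {
  co <- cfg$cohort
  if (!is.null(co$planted_gap_sd)) {
    planted_alpha_spec(gap_sd = co$planted_gap_sd, fs = co$fs,
                       duration_s = co$duration_s, subject_sd = co$subject_sd,
                       n_insomnia = co$n_insomnia, n_healthy = co$n_healthy,
                       powerline_amp = co$powerline_amp,
                       drift_amp = co$drift_amp, seed = cfg$seed)
  } else {
    cohort_spec(n_insomnia = co$n_insomnia, n_healthy = co$n_healthy,
                fs = co$fs, duration_s = co$duration_s,
                subject_sd = co$subject_sd, powerline_amp = co$powerline_amp,
                drift_amp = co$drift_amp, seed = cfg$seed)
  }
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "sleepaug_stage_error", parent = e)
  })
}

#' Run the full detection pipeline
#'
#' Generate (or load) a cohort, preprocess, augment at signal level (MCSA),
#' extract band-wise features, augment at feature level (CTGAN), evaluate
#' the classifiers on each requested band subset, and write all artifacts
#' (feature CSVs, GAN validation JSON, per-band evaluation reports, run
#' metadata with the config hash) into the run directory.
#'
#' @param cfg A `sleepaug_config` (see [default_config()]).
#' @return Invisibly, a list with the cohort, feature tables, GAN model and
#'   validation, evaluation reports and the run directory.
#' @export
run_pipeline <- function(cfg = default_config()) {
  check_config_keys(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  layers <- match.arg(cfg$layers, c("none", "mcsa_only", "ctgan_only", "both"))

  cohort <- run_stage("simulate", {
    if (!is.null(cfg$edf_dir)) read_edf(cfg$edf_dir)
    else simulate_cohort(config_spec(cfg))
  })
  stage_log("simulate", "%d recordings (%d insomnia / %d healthy)",
            nrow(cohort), sum(cohort$group == "insomnia"),
            sum(cohort$group == "healthy"))

  pp <- cfg$preprocess
  cohort <- run_stage("preprocess", preprocess_cohort(
    cohort, lo = pp$lo_hz, hi = pp$hi_hz, order = pp$order,
    denoise_level = pp$denoise_level, epoch_s = pp$epoch_s))
  stage_log("preprocess", "bands segmented into %d epochs of %gs",
            cohort$segments[[1]]$n_segments, pp$epoch_s)

  feats_real <- run_stage("features", extract_features(cohort))
  aug <- NULL
  feats_mcsa <- NULL
  if (layers %in% c("mcsa_only", "both")) {
    aug <- run_stage("augment", run_mcsa(cohort, mcsa_config(
      scale_factor = cfg$mcsa$scale_factor, snr_db = cfg$mcsa$snr_db,
      seed = cfg$seed)))
    stage_log("augment", "%d synthetic signals (4 x %d subjects x 5 bands x %d epochs)",
              nrow(aug), nrow(cohort), cohort$segments[[1]]$n_segments)
    feats_mcsa <- run_stage("features", extract_features(aug))
  }
  train_feats <- dplyr::bind_rows(feats_real, feats_mcsa)
  stage_log("features", "%d rows x %d feature columns",
            nrow(train_feats), length(feature_columns()))

  gan <- NULL; feats_ctgan <- NULL; gan_val <- NULL
  if (layers %in% c("ctgan_only", "both")) {
    gan <- run_stage("ctgan", ctgan_fit(
      train_feats, epochs = cfg$ctgan$epochs,
      batch = cfg$ctgan$batch, seed = cfg$seed,
      latent_dim = cfg$ctgan$latent_dim, max_modes = cfg$ctgan$max_modes))
    feats_ctgan <- run_stage("ctgan", ctgan_sample(
      gan, n = cfg$ctgan$n_samples, seed = cfg$seed))
    gan_val <- validate_synthetic(train_feats, feats_ctgan)
    stage_log("ctgan", "%d synthetic rows; %d/%d columns within tolerance",
              nrow(feats_ctgan), sum(gan_val$columns$pass),
              nrow(gan_val$columns))
  }
  all_feats <- dplyr::bind_rows(train_feats, feats_ctgan)

  ev <- cfg$eval
  reports <- list()
  for (b in ev$bands) {
    reports[[b]] <- run_stage("evaluate", holdout_eval(
      band_subset(all_feats, b), models = ev$models,
      random_state = ev$random_state))
  }
  stage_log("evaluate", "%d band subsets x %d models",
            length(ev$bands), length(ev$models))

  # artifacts
  info <- list(config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
               layers = layers, n_rows = nrow(all_feats))
  utils::write.csv(feats_real, file.path(cfg$out_dir, "features_real.csv"),
                   row.names = FALSE)
  if (!is.null(feats_mcsa)) {
    utils::write.csv(feats_mcsa, file.path(cfg$out_dir, "features_mcsa.csv"),
                     row.names = FALSE)
  }
  if (!is.null(feats_ctgan)) {
    utils::write.csv(feats_ctgan, file.path(cfg$out_dir, "features_ctgan.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(columns = gan_val$columns, corr_frobenius = gan_val$corr_frobenius,
           pass = gan_val$pass),
      file.path(cfg$out_dir, "gan_validation.json"),
      auto_unbox = TRUE, digits = NA)
  }
  for (b in names(reports)) {
    jsonlite::write_json(
      c(info, list(report = reports[[b]])),
      file.path(cfg$out_dir, paste0("eval_", b, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(info, file.path(cfg$out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, features_real = feats_real,
                 features_mcsa = feats_mcsa, features_ctgan = feats_ctgan,
                 gan = gan, gan_validation = gan_val, reports = reports,
                 out_dir = cfg$out_dir))
}

#' Compare augmentation arms on one cohort
#'
#' Runs the pipeline four times on the same base cohort and seed - no
#' augmentation, layer 1 only (MCSA), layer 2 only (CTGAN), both - and
#' reports one holdout accuracy per arm, the comparison used to judge what
#' each augmentation layer contributes.
#'
#' @param cfg A `sleepaug_config`.
#' @param model Model evaluated in each arm (default `"EBDT"`).
#' @return Tibble: `arm`, `n_train_rows`, `accuracy`.
#' @export
ablate_layers <- function(cfg = default_config(), model = "EBDT") {
  check_config_keys(cfg)
  arms <- c("none", "mcsa_only", "ctgan_only", "both")
  purrr::map_dfr(arms, function(arm) {
    acfg <- cfg
    acfg$layers <- arm
    acfg$out_dir <- file.path(cfg$out_dir, paste0("arm_", arm))
    acfg$eval$bands <- "combined"
    acfg$eval$models <- model
    res <- run_pipeline(acfg)
    n_rows <- nrow(res$features_real) +
      (if (is.null(res$features_mcsa)) 0 else nrow(res$features_mcsa)) +
      (if (is.null(res$features_ctgan)) 0 else nrow(res$features_ctgan))
    tibble::tibble(arm = arm, n_train_rows = n_rows,
                   accuracy = res$reports$combined$accuracy[
                     res$reports$combined$model == model])
  })
}
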