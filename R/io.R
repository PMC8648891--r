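# File formats (BIDS events.tsv, signal CSV/binary + JSON sidecar, burst
# TSV, NIfTI maps), run configuration, and the end-to-end pipeline.

KNOWN_TRIAL_TYPES <- c("rest", "0back", "1back", "2back",
                       "stim_target", "stim_nontarget", "response")

#' Flatten a schedule (and responses) into a BIDS-style event table
#'
#' Produces the `events.tsv` dialect used throughout the package: columns
#' `onset` (s), `duration` (s), `trial_type`, with rows for rest intervals
#' (`rest`), task sub-blocks (`0back`/`1back`/`2back`), stimuli
#' (`stim_target`/`stim_nontarget`, zero duration) and button presses
#' (`response`, zero duration). Sub-block and stimulus rows overlap in
#' time by design.
#'
#' @param schedule A `bb_schedule`.
#' @param responses Optional response tibble from [simulate_behavior()].
#' @return A tibble `onset`, `duration`, `trial_type`, sorted by onset.
#' @export
schedule_events <- function(schedule, responses = NULL) {
  stopifnot(inherits(schedule, "bb_schedule"))
  ev <- dplyr::bind_rows(
    schedule$rests |>
      dplyr::transmute(onset = .data$onset, duration = .data$duration,
                       trial_type = "rest"),
    schedule$subblocks |>
      dplyr::transmute(onset = .data$onset, duration = .data$duration,
                       trial_type = .data$condition),
    schedule$stimuli |>
      dplyr::transmute(
        onset = .data$onset, duration = 0,
        trial_type = ifelse(.data$is_target, "stim_target", "stim_nontarget")
      )
  )
  if (!is.null(responses) && nrow(responses)) {
    ev <- dplyr::bind_rows(
      ev,
      responses |>
        dplyr::transmute(onset = .data$onset, duration = 0,
                         trial_type = "response")
    )
  }
  dplyr::arrange(ev, .data$onset, .data$trial_type)
}

#' Read and write BIDS-style event tables
#'
#' `read_events()` reads a tab-separated events file with at least `onset`,
#' `duration` and `trial_type` columns (seconds, time origin at recording
#' start). Rows are returned sorted by onset (with a warning if the file
#' was out of order); unknown `trial_type` values are preserved and
#' reported in the `unknown_trial_types` attribute (with a warning).
#' `write_events()` writes the complementary format.
#'
#' @param path File path.
#' @return `read_events()`: a tibble sorted by onset; `write_events()`: the
#'   input, invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols)) {
    abort(sprintf("Events file is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "bb_format_error")
  }
  if (is.unsorted(ev$onset)) {
    warn("Event onsets were out of order; returning them sorted.")
    ev <- dplyr::arrange(ev, .data$onset)
  }
  unknown <- setdiff(unique(ev$trial_type), KNOWN_TRIAL_TYPES)
  if (length(unknown)) {
    warn(sprintf("Unknown trial_type value(s) preserved: %s",
                 paste(unknown, collapse = ", ")))
  }
  attr(ev, "unknown_trial_types") <- unknown
  ev
}

#' @rdname read_events
#' @param events Event tibble with `onset`, `duration`, `trial_type`.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  readr::write_tsv(events, path, progress = FALSE)
  invisible(events)
}

signal_sidecar_path <- function(path) paste0(path, ".json")

#' Read and write continuous signals
#'
#' Signals are stored either as a single-column CSV (column `sample`) or as
#' raw little-endian float64 binary (`.bin`/`.dat`), in both cases with a
#' JSON sidecar `<path>.json` holding `fs`, `start_time` and `n`. An
#' explicit `fs` argument overrides the sidecar; raw input without either
#' is an error, as are non-finite samples.
#'
#' @param path Signal file path (`.csv`, or `.bin`/`.dat` raw float64).
#' @param fs Sampling rate in Hz; optional if a sidecar is present.
#' @return `read_signal()`: a [continuous_signal()]; `write_signal()`: the
#'   signal, invisibly.
#' @export
read_signal <- function(path, fs = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  sidecar <- signal_sidecar_path(path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs)) {
    abort("No sampling rate: supply `fs` or provide a JSON sidecar.",
          class = "bb_format_error")
  }
  start_time <- if (!is.null(meta$start_time)) meta$start_time else 0
  ext <- tolower(tools::file_ext(path))
  samples <- if (ext == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    as.numeric(df[[if ("sample" %in% names(df)) "sample" else 1L]])
  } else {
    n <- file.info(path)$size / 8
    readBin(path, what = "double", n = n, size = 8, endian = "little")
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    abort("Signal contains non-finite samples (NA/NaN/Inf).",
          class = "bb_data_error")
  }
  continuous_signal(samples, fs = fs, start_time = start_time)
}

#' @rdname read_signal
#' @param signal A [continuous_signal()].
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "bb_signal"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(tibble(sample = signal$samples), path, progress = FALSE)
  } else {
    writeBin(signal$samples, path, size = 8, endian = "little")
  }
  jsonlite::write_json(
    list(fs = signal$fs, start_time = signal$start_time,
         n = length(signal$samples)),
    signal_sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(signal)
}

#' Read and write burst event tables
#'
#' Tab-separated burst tables with columns `time`, `freq`, `peak_power`,
#' `median_ratio` (ground-truth tables from the generator use `time`,
#' `freq`, `amplitude`, `duration` and round-trip through the same
#' functions).
#'
#' @param path File path.
#' @return A tibble (`read_bursts()`) or the input invisibly
#'   (`write_bursts()`).
#' @export
read_bursts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time" %in% names(out)) {
    abort("Burst file must have a `time` column.", class = "bb_format_error")
  }
  out
}

#' @rdname read_bursts
#' @param bursts Burst tibble.
#' @export
write_bursts <- function(bursts, path) {
  readr::write_tsv(as_tibble(bursts), path, progress = FALSE)
  invisible(bursts)
}

#' Read and write 3D/4D volumes as NIfTI
#'
#' Thin wrappers over RNifti for the coefficient/t/p maps and synthetic
#' BOLD series the pipeline produces.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: a numeric array with an `affine` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = c(4L, 4L))
  attr(arr, "affine") <- aff
  arr
}

#' @rdname read_volume
#' @param volume Numeric array (3D or 4D).
#' @param affine Optional 4x4 voxel-to-mm affine (default identity).
#' @export
write_volume <- function(volume, path, affine = NULL) {
  img <- RNifti::asNifti(volume)
  if (!is.null(affine)) {
    # voxel sizes first: RNifti scales the stored rotation by pixdim
    RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
    RNifti::qform(img) <- structure(affine, code = 2L)
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the simulate-detect-quantify
#' pipeline with its default, validating types and ranges. Configurations
#' round-trip losslessly through YAML via [read_config()] /
#' [write_config()].
#'
#' @param runs Number of task runs to simulate.
#' @param seed Base integer seed for all pipeline randomness.
#' @param fs EEG sampling rate in Hz.
#' @param noise_alpha,noise_amp 1/f noise exponent and SD.
#' @param attenuation Group PMBR attenuation factor in \[0, 1\].
#' @param beta_band,threshold_factor,n_cycles,sd_f,sd_t,min_separation
#'   Detection parameters; see [detection_config()].
#' @param pmbr_post,pmbr_baseline PMBR windows in seconds relative to the
#'   response.
#' @param glm Run the synthetic BOLD + GLM stage (default TRUE).
#' @param tr Repetition time for the BOLD stage in seconds.
#' @param n_voxels Number of synthetic voxels in the BOLD stage.
#' @param bold_noise_sd BOLD noise SD.
#' @param burst_beta True burst coefficient of the synthetic BOLD.
#' @return A list of class `bb_config`.
#' @export
run_config <- function(runs = 1, seed = 1, fs = 250, noise_alpha = 1,
                       noise_amp = 1, attenuation = 1,
                       beta_band = c(13, 30), threshold_factor = 6,
                       n_cycles = 5, sd_f = 1, sd_t = 0.006,
                       min_separation = 0,
                       pmbr_post = c(0.5, 1.0), pmbr_baseline = c(-3, -1.5),
                       glm = TRUE, tr = 2, n_voxels = 20,
                       bold_noise_sd = 1, burst_beta = 0.5) {
  cfg <- list(
    runs = as.integer(runs), seed = as.integer(seed), fs = fs,
    noise_alpha = noise_alpha, noise_amp = noise_amp,
    attenuation = attenuation,
    beta_band = as.numeric(beta_band), threshold_factor = threshold_factor,
    n_cycles = n_cycles, sd_f = sd_f, sd_t = sd_t,
    min_separation = min_separation,
    pmbr_post = as.numeric(pmbr_post),
    pmbr_baseline = as.numeric(pmbr_baseline),
    glm = isTRUE(glm), tr = tr, n_voxels = as.integer(n_voxels),
    bold_noise_sd = bold_noise_sd, burst_beta = burst_beta
  )
  if (cfg$runs < 1) abort("`runs` must be >= 1.")
  if (cfg$attenuation < 0 || cfg$attenuation > 1) {
    abort("`attenuation` must be in [0, 1].")
  }
  detection_config(beta_band = cfg$beta_band,
                   threshold_factor = cfg$threshold_factor,
                   n_cycles = cfg$n_cycles, sd_f = cfg$sd_f, sd_t = cfg$sd_t,
                   min_separation = cfg$min_separation) # validates
  structure(cfg, class = "bb_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `bb_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bb_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' Run the full synthetic pipeline
#'
#' End-to-end composition: simulate an n-back schedule, behavioural
#' responses and burst-structured EEG; detect bursts; compute condition
#' rates, the event-locked rate curve and PMBR; optionally synthesize BOLD
#' driven by the true burst times and fit the first-level GLM. All
#' artifacts are written under `out_dir` (events.tsv, signal CSV + sidecar,
#' ground-truth and detected burst TSVs, rate/PMBR/GLM CSVs) together with
#' a provenance JSON recording the package version, the configuration and
#' a hash of the signal, so a re-run with the same configuration
#' reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed results and file paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "bb_config"))
  if (missing(out_dir)) abort("`out_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  model <- burst_model(group_attenuation = config$attenuation)
  sched <- stage("simulate",
                 make_nback_schedule(config$runs,
                                     seed = child_seed(config$seed, 1L)))
  responses <- stage("simulate",
                     simulate_behavior(sched,
                                       seed = child_seed(config$seed, 2L)))
  synth <- stage("simulate", synthesize_eeg(
    sched, model, fs = config$fs, noise_alpha = config$noise_alpha,
    noise_amp = config$noise_amp, responses = responses,
    seed = child_seed(config$seed, 3L)
  ))
  events <- schedule_events(sched, responses)
  det_cfg <- detection_config(
    beta_band = config$beta_band, threshold_factor = config$threshold_factor,
    n_cycles = config$n_cycles, sd_f = config$sd_f, sd_t = config$sd_t,
    min_separation = config$min_separation
  )
  bursts <- stage("detect", detect_bursts(synth$signal, det_cfg))
  rates <- stage("rates", condition_rates(bursts, events))
  curve <- stage("rates", event_locked_rate(bursts, responses$onset))
  pm <- stage("pmbr", pmbr(bursts, responses$onset,
                           post = config$pmbr_post,
                           baseline = config$pmbr_baseline,
                           t_range = c(0, sched$duration)))
  paths <- list(
    events = file.path(out_dir, "events.tsv"),
    signal = file.path(out_dir, "signal.csv"),
    truth = file.path(out_dir, "bursts_truth.tsv"),
    bursts = file.path(out_dir, "bursts_detected.tsv"),
    rates = file.path(out_dir, "condition_rates.csv"),
    curve = file.path(out_dir, "response_locked_rate.csv"),
    pmbr = file.path(out_dir, "pmbr.csv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_events(events, paths$events)
  write_signal(synth$signal, paths$signal)
  write_bursts(synth$truth, paths$truth)
  write_bursts(bursts, paths$bursts)
  readr::write_csv(rates, paths$rates, progress = FALSE)
  readr::write_csv(as_tibble(curve), paths$curve, progress = FALSE)
  readr::write_csv(pm, paths$pmbr, progress = FALSE)
  glm_fit <- NULL
  if (config$glm) {
    bold <- stage("glm", synthesize_bold(
      synth$truth$time, events, tr = config$tr,
      n_scans = ceiling(sched$duration / config$tr),
      n_voxels = config$n_voxels,
      true_betas = c(0.2, 0.2, 0.2, 0.3, config$burst_beta, 100),
      noise_sd = config$bold_noise_sd, seed = child_seed(config$seed, 4L)
    ))
    glm_fit <- stage("glm", fit_glm(bold$bold, bold$design))
    paths$glm <- file.path(out_dir, "glm_burst_contrast.csv")
    readr::write_csv(tidy(glm_fit), paths$glm, progress = FALSE)
  }
  provenance <- list(
    package = "betaburst",
    version = as.character(utils::packageVersion("betaburst")),
    config = unclass(config),
    signal_sha = digest_vector(synth$signal$samples),
    n_bursts_true = nrow(synth$truth),
    n_bursts_detected = nrow(bursts)
  )
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    schedule = sched, responses = responses, events = events,
    truth = synth$truth, bursts = bursts, rates = rates, curve = curve,
    pmbr = pm, glm = glm_fit, paths = paths
  ))
}

# Cheap content fingerprint of a numeric vector (polynomial rolling hash
# over a subsample of the serialized bytes), for provenance records only.
digest_vector <- function(x) {
  s <- serialize(round(x, 10), connection = NULL)
  step <- max(1L, length(s) %/% 4096L)
  h <- 17
  for (b in as.integer(s[seq(1L, length(s), by = step)])) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
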