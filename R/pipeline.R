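#' Pipeline run configuration
#'
#' Desk-scale defaults: 64 x 64 voxels per slice, a handful of coronal
#' slices, 34 frequencies, 21 sectors. Every threshold of the chain is
#' reachable here; a persisted config plus seed reproduces every output.
#'
#' @param phantoms list of phantom specs ([make_phantom()] `spec` lists),
#'   optionally with `$id`.
#' @param ring_radius probe ring radius in mm.
#' @param n_xy in-plane voxel count.
#' @param n_freq frequency points over 0.8-4.1 GHz.
#' @param z_range vertical extent `c(z_low, z_high)` of the imaged slices
#'   (mm, negative below the table).
#' @param ranges pc_fib search ranges (percent pairs).
#' @param pc_step candidate step within a range (percent points).
#' @param mode `"auto"` or an explicit mode name.
#' @param noise_level relative measurement-noise level.
#' @param use_artifacts logical; inject coupling and skin terms.
#' @param roi list of ROI thresholds (`min_volume`, `min_solidity`,
#'   `min_contrast`, `quorum`, `r_match`).
#' @param analysis_volume which composite drives ROI extraction
#'   (`"GLOBAL"`, `"LOW"` or `"HIGH"`).
#' @param pad time-domain zero-padding factor.
#' @param max_rank TR-MUSIC signal-subspace rank cap.
#' @param seed master seed; per-stage substreams are derived from it.
#' @param output_dir optional directory for exported volumes and tables.
#' @return classed list `run_config`.
#' @export
run_config <- function(phantoms = list(), ring_radius = 120, n_xy = 64,
                       n_freq = 34, z_range = c(-48, -28),
                       ranges = pcfib_ranges(), pc_step = 5, mode = "auto",
                       noise_level = 0.01, use_artifacts = TRUE,
                       roi = list(min_volume = 0.25, min_solidity = 0.3,
                                  min_contrast = 2, quorum = NULL,
                                  r_match = 5, threshold = 0.90,
                                  threshold_quantile = TRUE),
                       analysis_volume = "GLOBAL", pad = 4, max_rank = 4,
                       seed = 1L, output_dir = NULL) {
  structure(list(phantoms = phantoms, ring_radius = ring_radius, n_xy = n_xy,
                 n_freq = n_freq, z_range = z_range, ranges = ranges,
                 pc_step = pc_step, mode = mode, noise_level = noise_level,
                 use_artifacts = use_artifacts, roi = roi,
                 analysis_volume = analysis_volume, pad = pad,
                 max_rank = max_rank, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

# Scan heights (array z positions) covered by the configured z range.
config_slices <- function(array, z_range) {
  which(array$z_positions >= min(z_range) - 1e-9 &
        array$z_positions <= max(z_range) + 1e-9)
}

#' Run the full imaging and analysis chain on a synthetic cohort
#'
#' For every phantom: simulate the multistatic scan, attribute the operating
#' mode, reconstruct one volume per pc_fib search range, average the
#' composites, extract/validate/label ROIs against the phantom ground truth
#' and compute the 25-feature vector per ROI. The pooled feature table feeds
#' the malignant-vs-benign separability analysis and, when lesion-free
#' phantoms are present, the unspecified-findings false-positive workflow.
#'
#' @param config a [run_config()].
#' @param progress print per-stage progress lines.
#' @return list: `features` (pooled table), `separability`, `fp_report` (or
#'   `NULL`), `volumes` (per-phantom composites), `rois`, `modes`, `log`.
#' @export
run_pipeline <- function(config, progress = interactive()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  array <- probe_array(config$ring_radius, z_min = -120)
  freq <- scan_frequencies(config$n_freq)
  media <- medium_model()
  slices <- config_slices(array, config$z_range)
  artifacts <- artifact_config(coupling = config$use_artifacts,
                               skin = config$use_artifacts)
  calib <- calibration_scan(array, freq, media, artifacts,
                            seed = config$seed + 880L)
  calib_ref <- calibration_reference(calib, pad = config$pad)
  all_feats <- NULL; all_rois <- list(); vols_out <- list(); modes <- list()
  log <- list()
  n_healthy <- 0
  for (pi in seq_along(config$phantoms)) {
    sp <- config$phantoms[[pi]]
    id <- sp$id %||% sprintf("P%03d", pi)
    sp$id <- NULL
    ph <- make_phantom(sp, seed = config$seed + 13L * pi)
    if (length(ph$lesions) == 0) n_healthy <- n_healthy + 1
    t1 <- Sys.time()
    grid <- voxel_grid(config$n_xy, z = array$z_positions)
    scan <- synthesize_scan(ph, array, freq, media, grid = grid,
                            noise_level = config$noise_level,
                            artifacts = artifacts,
                            seed = config$seed + 13L * pi + 1L)
    mode <- if (identical(config$mode, "auto")) {
      select_mode(envelope_volume(ph$envelope), fold = !is.null(ph$fold))
    } else imaging_mode(config$mode)
    modes[[id]] <- mode
    rec <- reconstruct_volume(scan, ph$envelope, mode,
                              ranges = config$ranges,
                              pc_step = config$pc_step, slices = slices,
                              media = media, calib_ref = calib_ref,
                              max_rank = config$max_rank, pad = config$pad,
                              chest_intrusion = ph$chest_intrusion)
    comp <- composite_images(rec$volumes, rec$ranges)
    analysis <- comp[[config$analysis_volume]] %||% comp$GLOBAL
    res <- extract_rois(analysis, rec$volumes,
                        quorum = config$roi$quorum,
                        r_match = config$roi$r_match,
                        threshold = config$roi$threshold,
                        threshold_quantile =
                          isTRUE(config$roi$threshold_quantile),
                        min_volume = config$roi$min_volume,
                        min_solidity = config$roi$min_solidity,
                        min_contrast = config$roi$min_contrast)
    rois <- label_rois(res$rois, ph)
    ft <- feature_table(rois, analysis, breast_id = id)
    if (!is.null(ft)) all_feats <- rbind(all_feats, ft)
    all_rois[[id]] <- rois
    vols_out[[id]] <- comp
    log[[id]] <- list(mode = mode$name, rule = attr(mode, "rule"),
                      n_candidates = length(res$rois) + nrow(res$rejects),
                      n_rois = length(rois), rejects = res$rejects,
                      seconds = as.numeric(Sys.time() - t1, units = "secs"))
    if (progress)
      message(sprintf("[%s] mode %s, %d ROI(s), %.1f s", id, mode$name,
                      length(rois), log[[id]]$seconds))
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in names(comp))
        write_volume_nifti(comp[[nm]],
                           file.path(config$output_dir,
                                     sprintf("%s_%s.nii.gz", id, nm)))
    }
  }
  sep <- NULL
  if (!is.null(all_feats) &&
      length(intersect(c("malignant", "benign"), all_feats$class)) == 2)
    sep <- separability_table(all_feats)
  fp <- NULL
  if (!is.null(all_feats) && n_healthy > 0 &&
      any(all_feats$label == "UNSPECIFIED") &&
      all(c("malignant", "benign") %in% all_feats$class)) {
    fp <- fp_workflow(all_feats, n_healthy)
  }
  if (!is.null(config$output_dir) && !is.null(all_feats)) {
    write_feature_table(all_feats,
                        file.path(config$output_dir, "features.csv"))
    if (!is.null(sep))
      write_separability_table(sep,
                               file.path(config$output_dir, "separability.csv"))
  }
  list(features = all_feats, separability = sep, fp_report = fp,
       volumes = vols_out, rois = all_rois, modes = modes, log = log,
       seconds = as.numeric(Sys.time() - t0, units = "secs"))
}

#' Canonical test fixtures
#'
#' Small seeded inputs used across the validation experiments:
#' `point-scatterer` (a single compact lesion at a fixed location),
#' `two-lesion` (two compact lesions 12 mm apart), `cohort` (n
#' heterogeneous-spiculated "malignant-like" plus n homogeneous-smooth
#' "benign-like" breasts), `healthy-batch` (lesion-free breasts).
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param n cohort size per class / batch size.
#' @return list of phantom spec lists (fields as [run_config()] `phantoms`).
#' @export
generate_fixtures <- function(kind = c("point-scatterer", "two-lesion",
                                       "cohort", "healthy-batch"),
                              seed = 1L, n = 10L) {
  kind <- match.arg(kind)
  env_spec <- function(r_max = 55, depth = 75) list(r_max = r_max, depth = depth)
  if (kind == "point-scatterer") {
    return(list(list(id = "POINT", envelope = env_spec(), pc_fib = 0.35,
                     lesions = list(lesion_spec(c(18, 6, -38),
                                                axes = c(2, 2, 2),
                                                contrast = 3)))))
  }
  if (kind == "two-lesion") {
    return(list(list(id = "TWOLES", envelope = env_spec(), pc_fib = 0.35,
                     lesions = list(
                       lesion_spec(c(14, 6, -38), axes = c(2, 2, 2), contrast = 3),
                       lesion_spec(c(26, 6, -38), axes = c(2, 2, 2), contrast = 3)))))
  }
  specs <- list()
  local_rng(seed, {
    if (kind == "cohort") {
      # per-class lesion sizes are drawn from the detected-lesion maximal
      # linear dimensions reported for the clinical malignant and benign
      # cases (invasive carcinomas trend larger than the fibroadenomas and
      # cysts); position and breast composition vary freely
      size_mal <- c(29.4, 28.4, 23.0, 15.6)
      size_ben <- c(15.2, 15.6, 23.3)
      for (i in seq_len(n)) {
        ang <- stats::runif(1, 0, 2 * pi)
        r <- stats::runif(1, 10, 18)
        ctr <- c(r * cos(ang), r * sin(ang), stats::runif(1, -40, -36))
        specs[[length(specs) + 1]] <- list(
          id = sprintf("MAL%02d", i), envelope = env_spec(),
          pc_fib = stats::runif(1, 0.25, 0.5),
          lesions = list(lesion_malignant(ctr, size = sample(size_mal, 1))))
      }
      for (i in seq_len(n)) {
        ang <- stats::runif(1, 0, 2 * pi)
        r <- stats::runif(1, 10, 18)
        ctr <- c(r * cos(ang), r * sin(ang), stats::runif(1, -40, -36))
        specs[[length(specs) + 1]] <- list(
          id = sprintf("BEN%02d", i), envelope = env_spec(),
          pc_fib = stats::runif(1, 0.25, 0.5),
          lesions = list(lesion_benign(ctr, size = sample(size_ben, 1))))
      }
    } else {                                   # healthy-batch
      for (i in seq_len(n)) {
        fold <- if (i %% 4 == 0)
          list(azimuth = stats::runif(1, 0, 2 * pi), z = -36, amplitude = 1)
        else NULL
        specs[[length(specs) + 1]] <- list(
          id = sprintf("HLT%02d", i),
          envelope = env_spec(r_max = stats::runif(1, 45, 60)),
          pc_fib = stats::runif(1, 0.2, 0.6), lesions = list(), fold = fold)
      }
    }
  })
  specs
}
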