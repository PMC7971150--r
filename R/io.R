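# EEG containers, preprocessing, file formats and the end-to-end phantom
# pipeline.

#' EEG recording container
#'
#' Channels x samples matrix (microvolts) with sampling rate, channel
#' names, bad-channel bookkeeping and the spike-peak sample index.
#'
#' @param data channels x samples numeric matrix (uV).
#' @param fs sampling rate (Hz).
#' @param channel_names channel names (default E001...).
#' @param bad_channels names of channels flagged bad.
#' @param spike_peak sample index of the averaged spike peak.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          bad_channels = character(), spike_peak = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("EEG data contains NA/NaN")
  if (is.null(channel_names))
    channel_names <- sprintf("E%03d", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data), fs > 0)
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 bad_channels = bad_channels,
                 spike_peak = spike_peak), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples @ %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (length(x$bad_channels))
                sprintf(" (%d bad)", length(x$bad_channels)) else ""))
  invisible(x)
}

#' Preprocess raw averaged-spike EEG
#'
#' Zero-phase 4th-order Butterworth band-pass (default 0.1-30 Hz,
#' applied forward-backward), removal of bad channels, and re-referencing
#' to the average of the retained channels. Remove the same channels from
#' the lead-field rows downstream.
#'
#' @param raw channels x samples matrix (uV), or an [eeg_recording()].
#' @param fs sampling rate (Hz); taken from the recording if given one.
#' @param bad_channels channel names (or indices) to drop.
#' @param band band-pass edges (Hz); use `NULL` to skip filtering.
#' @param channel_names channel names for a bare matrix.
#' @param spike_peak spike-peak sample index to carry along.
#' @return An [eeg_recording()], average-referenced.
#' @export
preprocess <- function(raw, fs = NULL, bad_channels = NULL,
                       band = c(0.1, 30), channel_names = NULL,
                       spike_peak = NULL) {
  if (inherits(raw, "eeg_recording")) {
    fs <- fs %||% raw$fs
    channel_names <- channel_names %||% raw$channel_names
    spike_peak <- spike_peak %||% raw$spike_peak
    raw <- raw$data
  }
  if (is.null(fs)) stop("sampling rate fs is required")
  raw <- as.matrix(raw)
  if (is.null(channel_names))
    channel_names <- sprintf("E%03d", seq_len(nrow(raw)))
  if (is.numeric(bad_channels)) bad_channels <- channel_names[bad_channels]
  keep <- !(channel_names %in% (bad_channels %||% character()))
  x <- raw[keep, , drop = FALSE]
  if (!is.null(band)) {
    ny <- fs / 2
    # cascaded high-pass + low-pass: numerically stable where a single
    # band-pass polynomial with a 0.1 Hz edge at EEG rates is not
    bh <- signal::butter(4, band[1] / ny, type = "high")
    bl <- signal::butter(4, min(band[2] / ny, 0.999), type = "low")
    x <- x - rowMeans(x)
    x <- t(apply(x, 1, function(ch)
      signal::filtfilt(bl, signal::filtfilt(bh, ch))))
  }
  x <- sweep(x, 2, colMeans(x))  # average reference over retained channels
  eeg_recording(x, fs = fs, channel_names = channel_names[keep],
                bad_channels = channel_names[!keep],
                spike_peak = spike_peak)
}

#' Extract the analysis snapshot from a recording
#'
#' Returns the scalp topography at `time_ms` relative to the spike peak
#' (e.g. -12 ms on the rising slope).
#'
#' @param rec an [eeg_recording()] with a `spike_peak`.
#' @param time_ms offset in ms relative to the spike peak (negative =
#'   before the peak).
#' @return Length-L numeric snapshot.
#' @export
snapshot_at <- function(rec, time_ms = 0) {
  stopifnot(inherits(rec, "eeg_recording"), !is.null(rec$spike_peak))
  idx <- rec$spike_peak + round(time_ms * rec$fs / 1000)
  if (idx < 1 || idx > ncol(rec$data)) stop("time point outside recording")
  rec$data[, idx]
}

#' Read an .sfp-style electrode file
#'
#' Whitespace-delimited `name x y z` rows (mm).
#'
#' @param path file path.
#' @param reference reference electrode (index or name).
#' @return An [electrode_montage()].
#' @export
read_electrodes_sfp <- function(path, reference = 1L) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  electrode_montage(tab$name, as.matrix(tab[, c("x", "y", "z")]),
                    reference = reference)
}

#' Write an .sfp-style electrode file
#' @param montage an [electrode_montage()].
#' @param path output path.
#' @export
write_electrodes_sfp <- function(montage, path) {
  utils::write.table(
    data.frame(montage$names, montage$positions_mm),
    path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-matrix EEG file
#'
#' Whitespace-delimited channels x samples matrix (uV).
#'
#' @param path file path.
#' @param fs sampling rate (Hz).
#' @param ... passed to [eeg_recording()].
#' @return An [eeg_recording()].
#' @export
read_eeg_matrix <- function(path, fs, ...) {
  eeg_recording(as.matrix(utils::read.table(path, header = FALSE)),
                fs = fs, ...)
}

#' Write a segmentation or VOI to NIfTI
#' @param x a [voxel_segmentation()] or [voi_mask()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "voxel_segmentation")) x$labels else x$mask * 1L
  aff <- if (inherits(x, "voxel_segmentation")) x$affine else x$affine
  img <- RNifti::asNifti(arr * 1L)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI segmentation
#' @param path NIfTI file.
#' @param label_names named integer vector mapping tissue name -> label.
#' @return A [voxel_segmentation()].
#' @export
read_nifti_segmentation <- function(path, label_names) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- array(as.integer(round(img)), dim(img))
  seg <- voxel_segmentation(arr, abs(diag(aff)[1:3]), label_names,
                            origin_mm = aff[1:3, 4])
  seg$affine <- unclass(aff)[1:4, 1:4]
  seg
}

#' Read a NIfTI VOI mask
#' @param path NIfTI file.
#' @return A [voi_mask()].
#' @export
read_nifti_voi <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  voi_mask(array(img != 0, dim(img)), aff)
}

#' Persist a lead field as TSV + JSON provenance
#' @param lf a `lead_field`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @export
write_lead_field <- function(lf, path) {
  utils::write.table(lf$matrix, paste0(path, ".tsv"), row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  jsonlite::write_json(
    list(electrodes = lf$electrodes, avg_ref = lf$avg_ref,
         provenance = lf$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a lead field persisted by [write_lead_field()]
#' @param path base path used at write time.
#' @return A `lead_field`.
#' @export
read_lead_field <- function(path) {
  m <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dimnames(m) <- NULL
  structure(list(matrix = m, electrodes = meta$electrodes,
                 avg_ref = meta$avg_ref, provenance = meta$provenance),
            class = "lead_field")
}

# simple content-addressed .rds cache
cache_fetch <- function(cache_dir, key, compute) {
  if (is.null(cache_dir)) return(compute())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

#' Default phantom pipeline configuration
#'
#' Study-scale defaults for the sphere-phantom end-to-end run; override
#' any entry through `modifyList()`-style arguments of [run_pipeline()].
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    phantom = list(radii_mm = c(80, 85, 92), voxel_mm = 4,
                   source_radius_mm = 72, n_dipoles = 500,
                   n_electrodes = 64, seed = 7L),
    spike = list(active_patch = 1L, moment_nAm = 20, snr_db = Inf,
                 fs = 500, T_samples = 501L, seed = 7L),
    analysis = list(time_point_ms = 0, window_ms = c(-200, 0)),
    solver = list(method = "sloreta", alphas = default_alpha_grid(),
                  n_priors = 100L, sigma = 0.6, order = 8L, seed = 7L),
    voi = list(radius_mm = 10)
  )
}

#' Run the end-to-end phantom pipeline
#'
#' Segmentation -> lead field -> inverse solver(s) -> candidate selection
#' -> VOI metrics, with optional on-disk caching of the stage outputs
#' keyed by a content hash of the relevant configuration, so an unchanged
#' rerun reproduces the report bit-identically from cache.
#'
#' @param config nested list as in [default_pipeline_config()]; partial
#'   configs are filled with the defaults. May also be a path to a YAML
#'   file with the same structure. Set `voi = FALSE` to skip the VOI and
#'   its metrics (solver and selection outputs are still produced).
#' @param cache_dir optional directory for stage caches.
#' @param verbose print stage progress.
#' @return A list of class `pipeline_report`: `lead_field`, `recording`,
#'   `maps`, `best` (winning candidate), `voi`, `metrics`
#'   (a [metrics_report()], or `NULL` without a VOI) and `report` (a
#'   one-row data frame: solver, polarity, alpha, NRDM, LE, SD, Foc).
#' @export
run_pipeline <- function(config = list(), cache_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  say <- function(...) if (verbose) message(sprintf(...))
  ph <- cfg$phantom
  seed_forward <- rlang::hash(ph)
  say("phantom + lead field")
  fwd <- cache_fetch(cache_dir, paste0("fwd_", seed_forward), function() {
    seg <- make_sphere_segmentation(ph$radii_mm, ph$voxel_mm)
    src <- make_sphere_source_space(ph$source_radius_mm, ph$n_dipoles,
                                    seed = ph$seed)
    montage <- make_sphere_montage(ph$n_electrodes, ph$radii_mm[3],
                                   seed = NULL)
    cond <- conductivity_table()
    lf <- compute_leadfield_reciprocity(seg, cond, montage, src$source_space)
    list(seg = seg, ss = src$source_space, A = src$adjacency,
         montage = montage, cond = cond, lf = lf)
  })
  sp <- cfg$spike
  say("spike simulation")
  rec <- cache_fetch(cache_dir, rlang::hash(list("spike", seed_forward, sp)),
                     function() {
    simulate_spike(fwd$lf, patches = sp$active_patch,
                   moments_nAm = sp$moment_nAm, snr_db = sp$snr_db,
                   T_samples = sp$T_samples, fs = sp$fs, seed = sp$seed)
  })
  y <- snapshot_at(rec, cfg$analysis$time_point_ms)
  sv <- cfg$solver
  say("inverse solve (%s)", sv$method)
  maps <- cache_fetch(cache_dir,
                      rlang::hash(list("maps", seed_forward, sp, cfg$analysis, sv)),
                      function() {
    if (sv$method == "sloreta") {
      sloreta_sweep(y, fwd$lf, sv$alphas)
    } else {
      G <- build_smoothing_matrix(fwd$A, sigma = sv$sigma, order = sv$order)
      centers <- select_prior_centers(fwd$ss, n_priors = sv$n_priors,
                                      seed = sv$seed)
      win <- cfg$analysis$window_ms
      idx <- rec$spike_peak + round(seq(win[1], win[2]) * rec$fs / 1000)
      idx <- unique(pmax(1, pmin(ncol(rec$data), idx)))
      res <- msp_invert(rec$data[, idx, drop = FALSE], fwd$lf,
                        prior_set(G, centers))
      tsel <- which(idx == rec$spike_peak +
                      round(cfg$analysis$time_point_ms * rec$fs / 1000))[1]
      list(msp_snapshot(res, if (is.na(tsel)) length(idx) else tsel))
    }
  })
  best <- select_best(y, maps, fwd$lf)
  voi <- NULL
  metrics <- NULL
  if (!is.null(cfg$voi) && !identical(cfg$voi, FALSE)) {
    center <- cfg$voi$center_patch %||% sp$active_patch[1]
    voi <- make_voi(fwd$ss, fwd$seg, center, cfg$voi$radius_mm)
    # metrics use the map the winning candidate came from
    winner_map <- Filter(function(m) {
      identical(m$solver, best$solver) &&
        (is.na(best$alpha) || identical(m$alpha, best$alpha))
    }, maps)[[1]]
    metrics <- metrics_report(best, winner_map, voi, fwd$ss)
  }
  report <- data.frame(
    solver = best$solver, polarity = best$mode,
    alpha = if (is.na(best$alpha)) NA else best$alpha,
    nrdm = best$nrdm,
    LE = if (is.null(metrics)) NA else metrics$LE,
    SD = if (is.null(metrics)) NA else metrics$SD,
    Foc = if (is.null(metrics)) NA else metrics$Foc)
  structure(list(lead_field = fwd$lf, source_space = fwd$ss,
                 adjacency = fwd$A, segmentation = fwd$seg,
                 montage = fwd$montage, recording = rec, snapshot = y,
                 maps = maps, best = best, voi = voi, metrics = metrics,
                 report = report, config = cfg),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
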