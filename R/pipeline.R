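## Pipeline orchestration and file formats -----------------------------------
##
## Configuration with the protocol defaults pinned, an end-to-end runner
## over the synthetic generator, and plain-format IO: multi-page TIFF for
## movies, CSV for stimulus/descriptor/response tables and distances, JSON
## for reports and provenance sidecars, Newick for cluster trees.

#' Pipeline configuration with protocol defaults
#'
#' Builds a validated configuration list. All stage parameters default to
#' the protocol values: 8x8 spatial / 12-frame temporal binning, bandpass
#' sigmas 10 and 1 px, downsampling factor 2, 150 components at
#' smoothness 2 for IOS (20 at smoothness 5 for SpH), trial-correlation
#' threshold 0.6, reference-ligand criterion 2e-4 (0.2 per-mille on the
#' fractional scale), 50 bootstraps, 10000 shuffles. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults (named).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # synthetic data
    n_animals = 3L, n_glomeruli = 6L, grid = c(32L, 42L),
    overlap_level = 0.2, chemotopy_strength = 0.8,
    n_odorants = 16L, n_descriptors = 60L, informative_fraction = 0.4,
    amplitude_noise_sd = 0.02, n_trials = 2L, n_blanks = 2L,
    frames_per_recording = 5L, frame_rate = 5 / 12,
    stimulus_onset_frame = 2L, pixel_noise_sd = 0.5, global_signal_sd = 0,
    baseline = 1000, response_scale = 0.01, bleach_rate = 0,
    # preprocessing (raw-scale stages; protocol values)
    spatial_bin = c(8L, 8L), temporal_bin = 12L, baseline_seconds = 2,
    sigma_low = 10, sigma_high = 1, downsample_factor = 2L,
    lowpass_sigma = 1.5,
    # factorization
    K = NULL, alpha_sm = 2, alpha_sp = 0.5, nonneg_activations = TRUE,
    max_iter = 300L, tol = 1e-7,
    ios_defaults = list(K = 150L, alpha_sm = 2),
    sph_defaults = list(K = 20L, alpha_sm = 5),
    # spectra
    trial_corr_threshold = 0.6, reference_overlap = 0.5,
    min_ref = 2e-4,
    # models
    bootstrap_B = 25L, eva_sigma = 5,
    # topography
    n_shuffles = 1000L, cut_height = 0.4, min_animals = 3L,
    nearfar_thresholds_um = c(100, 180, 300),
    reference_axis = c(1, 0),
    # bookkeeping
    seed = 1L, pixel_um = 19.4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Generates a ground-truth ensemble, descriptor table and movies at the
#' configured (preprocessed) scale, converts the movies to a measurement
#' matrix via Delta R/R, segments them with rNMF, extracts and filters
#' response spectra, labels the planted reference glomerulus, fits an SVR
#' activation model with bootstrap q^2, and runs the tunotopic and
#' chemotopic analyses. With `out_dir` given, result tables are written
#' as CSV/JSON with a provenance sidecar; reruns with the same
#' configuration reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `spectra` (per animal), `positions`, `responses`,
#'   `amplitudes` (planted truth), `model_report`, `tunotopy`
#'   (`tree`, `clusters`, `proximity`), `chemotopy` (sweep table),
#'   `matches`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 10L)

  ens <- gen_ensemble(cfg$n_animals, cfg$n_glomeruli, cfg$grid,
                      cfg$overlap_level, cfg$chemotopy_strength,
                      seed = seeds[1])
  desc <- gen_descriptor_table(ens, cfg$n_odorants, cfg$n_descriptors,
                               cfg$informative_fraction, seed = seeds[2])
  amp <- gen_response_amplitudes(ens, desc$latent,
                                 noise_sd = cfg$amplitude_noise_sd,
                                 seed = seeds[3])
  stim <- gen_stimulus_table(rownames(desc$latent), cfg$n_trials,
                             cfg$n_blanks, seed = seeds[4])

  n_gl <- cfg$n_glomeruli
  per_animal <- vector("list", cfg$n_animals)
  matches <- vector("list", cfg$n_animals)
  for (a in seq_len(cfg$n_animals)) {
    movies <- gen_movie(ens, amp, stim, animal = a,
                        frames_per_recording = cfg$frames_per_recording,
                        frame_rate = cfg$frame_rate,
                        baseline = cfg$baseline,
                        response_scale = cfg$response_scale,
                        global_signal_sd = cfg$global_signal_sd,
                        pixel_noise_sd = cfg$pixel_noise_sd,
                        bleach_rate = cfg$bleach_rate,
                        stimulus_onset_frame = cfg$stimulus_onset_frame,
                        seed = seeds[5] + a)
    pre <- lapply(movies, function(m)
      ios_delta_r(m, baseline_seconds = 1 / cfg$frame_rate))
    mm <- assemble_measurement_matrix(pre, stim, pixel_um = cfg$pixel_um,
                                      frame_rate = cfg$frame_rate)
    K <- cfg$K %||% n_gl
    fit <- fit_rnmf(mm, K = K, alpha_sm = cfg$alpha_sm,
                    alpha_sp = cfg$alpha_sp,
                    nonneg_activations = cfg$nonneg_activations,
                    seed = seeds[6] + a, max_iter = cfg$max_iter,
                    tol = cfg$tol)
    resp <- extract_responses(fit, modality = "ios",
                              frame_rate = cfg$frame_rate)
    tsp <- trial_spectra(resp)
    kept <- trial_filter(tsp, cfg$trial_corr_threshold)
    idx_a <- which(ens$animal_ids == a)
    mask <- ens$footprints[[idx_a[which(ens$reference_flag[idx_a])[1]]]] > 0
    ref_comp <- assign_reference(fit, mask, cfg$reference_overlap)
    spec <- t(vapply(tsp, colMeans, colMeans(tsp[[1]])))
    per_animal[[a]] <- list(fit = fit, spectra = spec, kept = kept,
                            reference_components = ref_comp,
                            frame_map = mm$frame_map)
    matches[[a]] <- match_footprints(fit, ens$footprints[idx_a])
  }

  ## glomerulus records: matched fitted components <-> planted glomeruli
  odorants <- colnames(amp)
  records <- list()
  for (a in seq_len(cfg$n_animals)) {
    pa <- per_animal[[a]]
    idx_a <- which(ens$animal_ids == a)
    for (g in seq_len(n_gl)) {
      comp <- matches[[a]]$component[g]
      if (is.na(comp) || !comp %in% pa$kept) next
      spec <- pa$spectra[comp, odorants]
      if (any(spec < 0)) spec <- pmax(spec, 0)
      if (sum(spec) == 0) next
      records[[length(records) + 1L]] <- list(
        animal = a, identity = ens$shared_identity[idx_a[g]],
        reference = ens$reference_flag[idx_a[g]],
        position = ens$positions[idx_a[g], ],
        spectrum = spec)
    }
  }
  if (length(records) < 4L) stop("too few repeatable glomeruli recovered")
  spectra_mat <- t(vapply(records, `[[`, numeric(length(odorants)),
                          "spectrum"))
  positions <- t(vapply(records, `[[`, numeric(2L), "position"))
  animals <- vapply(records, `[[`, numeric(1L), "animal")
  is_ref <- vapply(records, `[[`, logical(1L), "reference")

  ## tunotopy: correlation distances, UPGMA, cluster filter, proximity
  dr <- correlation_distance_matrix(spectra_mat)
  tree <- upgma(dr)
  assign <- cut_tree(tree, cfg$cut_height)
  vassign <- valid_clusters(assign, animals,
                            min(cfg$min_animals, cfg$n_animals))
  ref_dist <- distance_to_reference(positions, which(is_ref))
  ref_cluster <- names(which.max(table(assign[is_ref])))
  member <- assign == as.integer(ref_cluster)
  proximity <- if (any(member) && any(!member)) {
    patch_proximity_test(ref_dist, member, cfg$n_shuffles, seed = seeds[7])
  } else NULL

  ## chemotopy: barycentres in the z-scored informative space
  zdesc <- z_normalize(desc$table)
  bary <- t(apply(spectra_mat, 1L, function(s)
    barycentre(unit_norm(s), zdesc$values[odorants, , drop = FALSE])))
  ref_bary <- colMeans(bary[is_ref, , drop = FALSE])
  chem_dist <- apply(bary, 1L, function(b) cosine_distance(b, ref_bary))
  sweep_tab <- nearfar_chemotopy_sweep(ref_dist, chem_dist,
                                       cfg$nearfar_thresholds_um,
                                       n_shuffles = cfg$n_shuffles,
                                       seed = seeds[8])

  ## receptive-range model of the reference glomerulus, on the relative
  ## scale (responses normalized to the strongest ligand, as a_rel)
  ref_spec <- colMeans(spectra_mat[is_ref, , drop = FALSE])
  ref_spec <- ref_spec / max(ref_spec)
  model_report <- q_squared_bootstrap(model_factory("svr"),
                                      zdesc$values[odorants, , drop = FALSE],
                                      ref_spec, B = cfg$bootstrap_B,
                                      seed = seeds[9])

  out <- list(spectra = spectra_mat, positions = positions,
              animals = animals, is_reference = is_ref,
              amplitudes = amp, matches = matches,
              model_report = model_report,
              tunotopy = list(tree = tree, clusters = vassign,
                              proximity = proximity),
              chemotopy = sweep_tab, config = cfg)
  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  out
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(animal = res$animals,
                              reference = res$is_reference,
                              x_um = res$positions[, 2],
                              y_um = res$positions[, 1],
                              res$spectra, check.names = FALSE),
                   file.path(out_dir, "glomerulus_spectra.csv"),
                   row.names = FALSE)
  utils::write.csv(res$chemotopy, file.path(out_dir, "chemotopy_sweep.csv"),
                   row.names = FALSE)
  tree_newick(res$tunotopy$tree, file.path(out_dir, "tunotopy_tree.nwk"))
  report <- list(
    q_squared = res$model_report$q_squared,
    r_squared = res$model_report$r_squared,
    B = res$model_report$B,
    proximity = if (!is.null(res$tunotopy$proximity)) {
      unclass(res$tunotopy$proximity)
    }
  )
  jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(package = "glomtopo",
               version = as.character(utils::packageVersion("glomtopo")),
               r_version = R.version.string,
               seed = res$config$seed,
               config = unclass(res$config),
               timestamp_utc = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

## -- plain-format IO ---------------------------------------------------------

#' Write a movie as a multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages; metadata (frame rate,
#' odorant, trial, blank flag) goes to a JSON sidecar next to the file.
#'
#' @param movie height x width x frames array.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  movie <- as_stack(movie)
  pages <- lapply(seq_len(dim(movie)[3]), function(f) movie[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(frame_rate = attr(movie, "frame_rate"),
               odorant = attr(movie, "odorant"),
               trial = attr(movie, "trial"),
               is_blank = attr(movie, "is_blank"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF movie written by [write_movie_tiff()]
#'
#' @param path `.tif` path.
#' @return height x width x frames array with metadata attributes
#'   restored from the sidecar when present.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) out[, , f] <- pages[[f]]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  }
  out
}

#' Write a descriptor table as CSV with a block-label header row
#'
#' The first data row holds the block label of each column; molecule ids
#' are the first column.
#'
#' @param table a [descriptor_table()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(table, path) {
  df <- rbind(c("block", table$blocks),
              cbind(rownames(table$values),
                    matrix(as.character(table$values),
                           nrow(table$values))))
  colnames(df) <- c("molecule", colnames(table$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor table written by [write_descriptor_csv()]
#'
#' @param path `.csv` path.
#' @return A [descriptor_table()].
#' @export
read_descriptor_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  blocks <- as.character(raw[1, -1])
  body <- raw[-1, , drop = FALSE]
  vals <- as.matrix(body[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- body[[1]]
  descriptor_table(vals, blocks)
}

#' Write vibrational line spectra as CSV
#'
#' Long format: one row per (molecule, frequency).
#'
#' @param spectra named list of frequency vectors.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_line_spectra_csv <- function(spectra, path) {
  df <- data.frame(
    molecule = rep(names(spectra), lengths(spectra)),
    frequency = unlist(spectra, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read line spectra written by [write_line_spectra_csv()]
#'
#' @param path `.csv` path.
#' @return Named list of sorted frequency vectors.
#' @export
read_line_spectra_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df$frequency, df$molecule), sort)
}
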