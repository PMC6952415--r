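## Synthetic ground-truth generator -----------------------------------------
##
## Emulates the statistical structure the downstream analysis assumes: smooth,
## partially overlapping glomerular footprints on a pixel grid; per-odorant
## activation amplitudes drawn from latent Gaussian tuning curves; a broad
## low-frequency global signal, pixel noise and slow bleaching; several
## "animals" sharing glomerulus identities; and a descriptor table whose
## informative columns carry the planted tuning structure.

#' Generate a multi-animal glomerular ground-truth ensemble
#'
#' Each synthetic animal carries one glomerulus per shared identity. A
#' glomerulus has a truncated 2-D Gaussian footprint (truncation at 3
#' standard deviations), a 2-D position on the imaging grid, and a tuning
#' centre in a latent chemical space of dimension `d_lat`.
#'
#' `chemotopy_strength` interpolates between chemotopic and unordered maps:
#' a fraction of the tuning variance lies in a 2-D plane that is carried
#' onto spatial positions by a similarity transform (which preserves
#' distance ranks), the residual latent dimensions being scaled by
#' `sqrt(1 - chemotopy_strength)`. At strength 1 (and zero positional
#' noise) spatial and tuning distances are therefore perfectly rank
#' correlated within each animal; at strength 0 positions are drawn on a
#' jittered lattice independent of tuning.
#'
#' @param n_animals number of synthetic animals.
#' @param n_glomeruli_per_animal glomeruli (= shared identities) per animal;
#'   at least 3.
#' @param grid `c(height, width)` of the pixel grid at the preprocessed
#'   scale.
#' @param overlap_level in `[0, 1]`; 0 yields spatially disjoint footprints,
#'   larger values shrink the enforced separation and enlarge footprints.
#' @param chemotopy_strength in `[0, 1]`, see Details.
#' @param seed integer seed; output is deterministic given the seed.
#' @param d_lat latent chemical dimension (default 3).
#' @param pixel_um pixel pitch in micrometres (default 19.4).
#' @param identity_jitter_sd standard deviation of per-animal jitter applied
#'   to shared tuning centres (default 0: identical tuning across animals).
#' @return An object of class `gt_ensemble`: list with per-glomerulus
#'   `footprints` (list of height x width matrices), `positions` (n x 2, µm),
#'   `positions_px`, `tuning_centres` (n x d_lat), `tuning_widths`, `scales`,
#'   `animal_ids`, `shared_identity`, `reference_flag`, plus `grid`,
#'   `pixel_um` and the generating parameters.
#' @export
gen_ensemble <- function(n_animals, n_glomeruli_per_animal,
                         grid = c(64L, 84L),
                         overlap_level = 0.3, chemotopy_strength = 0.5,
                         seed = 1L, d_lat = 3L, pixel_um = 19.4,
                         identity_jitter_sd = 0) {
  if (n_animals < 1L || n_glomeruli_per_animal < 3L) {
    stop("need at least 1 animal and 3 glomeruli per animal")
  }
  if (overlap_level < 0 || overlap_level > 1) stop("overlap_level must be in [0,1]")
  if (chemotopy_strength < 0 || chemotopy_strength > 1) {
    stop("chemotopy_strength must be in [0,1]")
  }
  h <- as.integer(grid[1]); w <- as.integer(grid[2])
  G <- as.integer(n_glomeruli_per_animal)
  s <- chemotopy_strength

  with_seed(seed, {
    sigma <- 1 + overlap_level + stats::runif(G, -0.15, 0.15) # footprint sd, px
    sig_max <- max(sigma)
    margin <- ceiling(3 * sig_max) + 1

    ## shared latent structure per identity
    u <- matrix(stats::rnorm(G * 2L), G, 2L)          # plane mapped to space
    v <- if (d_lat > 2L) matrix(stats::rnorm(G * (d_lat - 2L)), G) else
      matrix(0, G, 0L)
    tuning_base <- cbind(u, sqrt(max(0, 1 - s)) * v)
    if (ncol(tuning_base) < d_lat) {
      tuning_base <- cbind(tuning_base,
                           matrix(0, G, d_lat - ncol(tuning_base)))
    }
    widths <- stats::runif(G, 0.9, 1.4)
    scales <- stats::runif(G, 0.6, 1.0)

    if (h - 2 * margin < 1 || w - 2 * margin < 1) {
      stop("grid too small to place footprints with the requested size")
    }

    place_animal <- function() {
      if (s == 0) {
        ## jittered lattice with enforced separation
        d_sep <- (1 - overlap_level) * 6 * sig_max + overlap_level * 2 * sig_max
        nr <- max(1L, floor((h - 2 * margin) / d_sep) + 1L)
        nc <- max(1L, floor((w - 2 * margin) / d_sep) + 1L)
        if (nr * nc < G) stop("grid too small for ", G,
                              " footprints at overlap_level ", overlap_level)
        ys <- seq(margin, h - margin, length.out = nr)
        xs <- seq(margin, w - margin, length.out = nc)
        cells <- expand.grid(y = ys, x = xs)
        pick <- sample.int(nrow(cells), G)
        jit <- min(1, d_sep / 6)
        cbind(cells$y[pick] + stats::runif(G, -jit, jit),
              cells$x[pick] + stats::runif(G, -jit, jit))
      } else {
        r <- matrix(stats::rnorm(G * 2L), G, 2L)
        base <- s * u + (1 - s) * r
        ## isotropic similarity map into the grid (rank preserving)
        ctr <- colMeans(base)
        cen <- sweep(base, 2L, ctr)
        span <- max(abs(cen))
        if (span == 0) span <- 1
        scl <- min((h - 2 * margin) / 2, (w - 2 * margin) / 2) / span
        cbind(cen[, 1] * scl + (h + 1) / 2, cen[, 2] * scl + (w + 1) / 2)
      }
    }

    n_tot <- n_animals * G
    footprints <- vector("list", n_tot)
    positions_px <- matrix(0, n_tot, 2L)
    tuning <- matrix(0, n_tot, d_lat)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (a in seq_len(n_animals)) {
      pos <- place_animal()
      idx <- (a - 1L) * G + seq_len(G)
      positions_px[idx, ] <- pos
      jit <- if (identity_jitter_sd > 0) {
        matrix(stats::rnorm(G * d_lat, sd = identity_jitter_sd), G, d_lat)
      } else 0
      tuning[idx, ] <- tuning_base + jit
      for (g in seq_len(G)) {
        d2 <- (yy - pos[g, 1])^2 + (xx - pos[g, 2])^2
        fp <- exp(-d2 / (2 * sigma[g]^2))
        fp[d2 > (3 * sigma[g])^2] <- 0 # truncate at 3 sd
        footprints[[idx[g]]] <- fp
      }
    }

    structure(list(
      footprints = footprints,
      positions = positions_px * pixel_um,
      positions_px = positions_px,
      tuning_centres = tuning,
      tuning_widths = rep(widths, n_animals),
      scales = rep(scales, n_animals),
      animal_ids = rep(seq_len(n_animals), each = G),
      shared_identity = rep(seq_len(G), n_animals),
      reference_flag = rep(seq_len(G) == 1L, n_animals),
      grid = c(h, w), pixel_um = pixel_um, d_lat = d_lat,
      chemotopy_strength = s, overlap_level = overlap_level,
      footprint_sigma = rep(sigma, n_animals), seed = seed
    ), class = "gt_ensemble")
  })
}

#' @export
print.gt_ensemble <- function(x, ...) {
  cat(sprintf(
    "Ground-truth ensemble: %d animals x %d glomeruli on a %dx%d grid\n",
    max(x$animal_ids), sum(x$animal_ids == 1L), x$grid[1], x$grid[2]))
  cat(sprintf("  chemotopy_strength = %.2f, overlap_level = %.2f, d_lat = %d\n",
              x$chemotopy_strength, x$overlap_level, x$d_lat))
  invisible(x)
}

#' Generate a pseudo-randomized stimulus table
#'
#' @param odorant_ids character vector of odorant identifiers.
#' @param n_trials repetitions per odorant (at least 2).
#' @param n_blanks number of blank (no-odour) recordings, used downstream
#'   for bleaching correction.
#' @param seed integer seed for the presentation order.
#' @return data.frame with columns `recording`, `odorant`, `trial`,
#'   `is_blank`; blank rows carry the reserved odorant id `"blank"`.
#' @export
gen_stimulus_table <- function(odorant_ids, n_trials = 2L, n_blanks = 2L,
                               seed = 1L) {
  if (n_trials < 2L) stop("every odorant must be presented at least twice")
  stim <- data.frame(
    odorant = c(rep(odorant_ids, each = n_trials), rep("blank", n_blanks)),
    trial = c(rep(seq_len(n_trials), length(odorant_ids)),
              seq_len(n_blanks)),
    is_blank = c(rep(FALSE, length(odorant_ids) * n_trials),
                 rep(TRUE, n_blanks)),
    stringsAsFactors = FALSE
  )
  ord <- with_seed(seed, sample.int(nrow(stim)))
  stim <- stim[ord, , drop = FALSE]
  stim$recording <- seq_len(nrow(stim))
  rownames(stim) <- NULL
  stim[, c("recording", "odorant", "trial", "is_blank")]
}

#' Generate a descriptor table with planted latent structure
#'
#' Latent odorant coordinates are drawn i.i.d. standard normal in the
#' ensemble's latent space; an `informative_fraction` of descriptor columns
#' are noisy random linear images of those coordinates, the remainder pure
#' noise. Columns carry block labels so block-wise benchmarking is
#' exercisable.
#'
#' @param ensemble a [gen_ensemble()] result (fixes the latent dimension).
#' @param n_odorants number of odorants (at least 2).
#' @param n_descriptors number of descriptor columns (at least `d_lat`).
#' @param informative_fraction fraction of informative columns, in `(0, 1]`.
#' @param seed integer seed.
#' @param noise_sd noise added to informative columns (default 0.1).
#' @return list with `table` (a [descriptor_table()]) and `latent`
#'   (n_odorants x d_lat matrix of the planted coordinates).
#' @export
gen_descriptor_table <- function(ensemble, n_odorants, n_descriptors,
                                 informative_fraction, seed = 1L,
                                 noise_sd = 0.1) {
  if (n_odorants < 2L) stop("need at least 2 odorants")
  d <- ensemble$d_lat
  if (n_descriptors < d) stop("n_descriptors must be at least d_lat = ", d)
  if (informative_fraction <= 0 || informative_fraction > 1) {
    stop("informative_fraction must be in (0, 1]")
  }
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_odorants * d), n_odorants, d)
    n_inf <- max(d, round(informative_fraction * n_descriptors))
    n_inf <- min(n_inf, n_descriptors)
    wmat <- matrix(stats::rnorm(d * n_inf), d, n_inf)
    inf <- z %*% wmat
    if (noise_sd > 0) {
      inf <- inf + matrix(stats::rnorm(length(inf), sd = noise_sd),
                          nrow(inf))
    }
    n_noise <- n_descriptors - n_inf
    noise <- matrix(stats::rnorm(n_odorants * n_noise), n_odorants, n_noise)
    values <- cbind(inf, noise)
    rownames(z) <- rownames(values) <-
      sprintf("odorant_%03d", seq_len(n_odorants))
    colnames(values) <- c(sprintf("INF%04d", seq_len(n_inf)),
                          if (n_noise > 0) sprintf("RND%04d", seq_len(n_noise)))
    n_blocks <- min(4L, n_inf)
    blocks <- c(sprintf("INFO%d", rep_len(seq_len(n_blocks), n_inf)),
                rep("NOISE", n_noise))
    list(table = descriptor_table(values, blocks), latent = z)
  })
}

#' Generate planted response amplitudes from Gaussian tuning curves
#'
#' The true amplitude of glomerulus k for odorant o is
#' `scale_k * exp(-||z_o - c_k||^2 / (2 w_k^2))` plus optional Gaussian
#' noise, clipped at zero. Glomeruli sharing an identity (and hence tuning
#' centre) receive near-identical spectra across animals.
#'
#' @param ensemble a [gen_ensemble()] result.
#' @param latent n_odorants x d_lat matrix of odorant coordinates (e.g. from
#'   [gen_descriptor_table()]).
#' @param noise_sd amplitude noise standard deviation (default 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return glomeruli x odorants amplitude matrix with dimnames.
#' @export
gen_response_amplitudes <- function(ensemble, latent, noise_sd = 0,
                                    seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  n_g <- length(ensemble$footprints)
  n_o <- nrow(latent)
  amp <- matrix(0, n_g, n_o)
  for (k in seq_len(n_g)) {
    d2 <- rowSums(sweep(latent, 2L, ensemble$tuning_centres[k, ])^2)
    amp[k, ] <- ensemble$scales[k] *
      exp(-d2 / (2 * ensemble$tuning_widths[k]^2))
  }
  if (noise_sd > 0) {
    amp <- amp + with_seed(seed, matrix(stats::rnorm(n_g * n_o, sd = noise_sd),
                                        n_g, n_o))
    amp[amp < 0] <- 0
  }
  dimnames(amp) <- list(sprintf("glom_%03d", seq_len(n_g)),
                        rownames(latent) %||%
                          sprintf("odorant_%03d", seq_len(n_o)))
  amp
}

#' Generate synthetic imaging movies for one animal
#'
#' Produces one grayscale movie per stimulus-table row at the ensemble's
#' grid scale. Pre-onset frames contain baseline, noise and bleaching only;
#' from `stimulus_onset_frame` on, the amplitude-weighted sum of the
#' animal's footprints is added with a linear 2-frame onset ramp followed
#' by a plateau. A single spatially broad (sigma >= 20 px blur) global
#' component with its own smooth time course emulates the unspecific
#' signal that the difference-of-Gaussians bandpass removes. Blank rows
#' carry no stimulus term. IOS movies encode activation as a reflectance
#' decrease, SpH movies as a fluorescence increase.
#'
#' @param ensemble a [gen_ensemble()] result.
#' @param amplitudes glomeruli x odorants matrix from
#'   [gen_response_amplitudes()]; rows for other animals are ignored.
#' @param stim data.frame from [gen_stimulus_table()].
#' @param animal which animal's footprints to image (default 1).
#' @param frames_per_recording,frame_rate temporal layout (defaults 60
#'   frames at 5 Hz, i.e. a 12-s recording).
#' @param baseline mean pre-stimulus pixel value (arbitrary camera units).
#' @param response_scale peak fractional signal change for an amplitude of
#'   1 (default 0.01).
#' @param global_signal_sd,pixel_noise_sd,bleach_rate nuisance-signal
#'   levels: fractional sd of the global component, i.i.d. pixel noise sd
#'   (camera units), and per-frame exponential bleaching rate.
#' @param stimulus_onset_frame first stimulated frame (default 13, i.e.
#'   2.5 s gas arrival at 5 Hz).
#' @param modality `"ios"` (signal decreases reflectance) or `"sph"`.
#' @param seed integer seed; movies are bit-identical given the seed.
#' @return list of height x width x frames arrays, one per recording, each
#'   with attributes `frame_rate`, `odorant`, `trial`, `is_blank`.
#' @export
gen_movie <- function(ensemble, amplitudes, stim, animal = 1L,
                      frames_per_recording = 60L, frame_rate = 5,
                      baseline = 1000, response_scale = 0.01,
                      global_signal_sd = 0, pixel_noise_sd = 0,
                      bleach_rate = 0, stimulus_onset_frame = 13L,
                      modality = c("ios", "sph"), seed = 1L) {
  modality <- match.arg(modality)
  if (nrow(stim) == 0L) stop("empty stimulus table")
  if (stimulus_onset_frame >= frames_per_recording) {
    stop("stimulus_onset_frame must lie before the end of the recording")
  }
  h <- ensemble$grid[1]; w <- ensemble$grid[2]
  idx <- which(ensemble$animal_ids == animal)
  if (length(idx) == 0L) stop("no glomeruli for animal ", animal)
  fps <- ensemble$footprints[idx]
  sgn <- if (modality == "ios") -1 else 1

  ## temporal ramp: 0 before onset, linear over 2 frames, then plateau
  tramp <- pmin(1, pmax(0, (seq_len(frames_per_recording) -
                              stimulus_onset_frame + 1L) / 2))
  decay <- exp(-bleach_rate * (seq_len(frames_per_recording) - 1L))

  with_seed(seed, {
    gmap <- if (global_signal_sd > 0) {
      m <- gauss_blur(matrix(stats::rnorm(h * w), h, w), 20)
      m / max(abs(m))
    } else matrix(0, h, w)
    lapply(seq_len(nrow(stim)), function(i) {
      gcourse <- if (global_signal_sd > 0) {
        tc <- cumsum(stats::rnorm(frames_per_recording))
        global_signal_sd * (tc - mean(tc)) / max(stats::sd(tc), 1e-12)
      } else numeric(frames_per_recording)
      actmap <- matrix(0, h, w)
      if (!stim$is_blank[i]) {
        o <- match(stim$odorant[i], colnames(amplitudes))
        if (is.na(o)) stop("odorant ", stim$odorant[i],
                           " missing from amplitude table")
        for (k in seq_along(fps)) {
          actmap <- actmap + amplitudes[idx[k], o] * fps[[k]]
        }
      }
      mv <- array(0, c(h, w, frames_per_recording))
      for (f in seq_len(frames_per_recording)) {
        frame <- baseline * decay[f] *
          (1 + gmap * gcourse[f] + sgn * response_scale * tramp[f] * actmap)
        if (pixel_noise_sd > 0) {
          frame <- frame + matrix(stats::rnorm(h * w, sd = pixel_noise_sd),
                                  h, w)
        }
        mv[, , f] <- frame
      }
      attr(mv, "frame_rate") <- frame_rate
      attr(mv, "odorant") <- stim$odorant[i]
      attr(mv, "trial") <- stim$trial[i]
      attr(mv, "is_blank") <- stim$is_blank[i]
      mv
    })
  })
}

#' Generate synthetic vibrational line spectra
#'
#' Stand-in for quantum-chemical vibrational frequencies: each molecule
#' receives a sorted list of mode frequencies drawn uniformly within the
#' requested range, which must lie inside `[0, 4000]` cm^-1.
#'
#' @param n_molecules number of molecules.
#' @param modes_range `c(min, max)` number of modes per molecule.
#' @param freq_range frequency range in cm^-1, within `[0, 4000]`.
#' @param seed integer seed.
#' @return named list of sorted numeric frequency vectors.
#' @export
gen_line_spectra <- function(n_molecules, modes_range = c(20L, 60L),
                             freq_range = c(100, 3800), seed = 1L) {
  if (freq_range[1] < 0 || freq_range[2] > 4000) {
    stop("requested frequencies outside [0, 4000] cm^-1")
  }
  with_seed(seed, {
    out <- lapply(seq_len(n_molecules), function(i) {
      n <- if (modes_range[1] == modes_range[2]) modes_range[1] else
        sample(seq(modes_range[1], modes_range[2]), 1L)
      sort(stats::runif(n, freq_range[1], freq_range[2]))
    })
    names(out) <- sprintf("molecule_%03d", seq_len(n_molecules))
    out
  })
}
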