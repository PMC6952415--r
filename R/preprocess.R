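## Movie preprocessing -------------------------------------------------------
##
## IOS: spatial 8x8 / temporal 12-frame binning, Delta R/R against the first
## 2 s, difference-of-Gaussians spatial bandpass (sigma 10 / 1 px), factor-2
## downsampling -> 64 x 84 px at 0.42 Hz for a 1024 x 1344 px, 12-s, 5-Hz
## recording. SpH: F - F0, mean-blank bleaching correction, 1.5-px Gaussian
## lowpass, factor-2 downsampling -> 64 x 64 px for 128 x 128 frames.

#' Spatial block binning of an image stack
#'
#' Non-overlapping window means. The spatial shape must be divisible by the
#' window; anything else is an error rather than a silent crop.
#'
#' @param stack height x width x frames array (a single matrix is treated
#'   as one frame).
#' @param window `c(rows, cols)` bin size, default `c(8, 8)`.
#' @return Binned array of shape `dim/window` (frames unchanged).
#' @export
bin_spatial <- function(stack, window = c(8L, 8L)) {
  stack <- as_stack(stack)
  d <- dim(stack)
  out <- array(0, c(d[1] %/% window[1], d[2] %/% window[2], d[3]))
  if (d[1] %% window[1] != 0L || d[2] %% window[2] != 0L) {
    stop(sprintf("spatial shape %dx%d not divisible by window %dx%d (no silent cropping)",
                 d[1], d[2], window[1], window[2]))
  }
  for (f in seq_len(d[3])) {
    out[, , f] <- block_mean(stack[, , f], window[1], window[2])
  }
  copy_movie_attrs(out, stack)
}

#' Temporal binning of an image stack
#'
#' @param stack height x width x frames array.
#' @param window number of consecutive frames per bin (default 12).
#' @return Array with `frames / window` frames of window means; the
#'   `frame_rate` attribute, if present, is divided accordingly.
#' @export
bin_temporal <- function(stack, window = 12L) {
  stack <- as_stack(stack)
  d <- dim(stack)
  if (d[3] %% window != 0L) {
    stop(sprintf("frame count %d not divisible by temporal window %d (no silent cropping)",
                 d[3], window))
  }
  nf <- d[3] %/% window
  out <- array(0, c(d[1], d[2], nf))
  for (f in seq_len(nf)) {
    sel <- (f - 1L) * window + seq_len(window)
    out[, , f] <- apply_frames_mean(stack, sel)
  }
  out <- copy_movie_attrs(out, stack)
  if (!is.null(attr(stack, "frame_rate"))) {
    attr(out, "frame_rate") <- attr(stack, "frame_rate") / window
  }
  out
}

#' Relative reflectance decrease for IOS recordings
#'
#' Computes `Delta R / R = -(R - R0) / R` per pixel and frame, where `R0`
#' is the per-pixel mean over the first `baseline_seconds` of the
#' recording (frames strictly before odorant arrival). Positive output
#' means the reflectance decreased, i.e. the tissue was activated.
#'
#' @param stack height x width x frames array of strictly positive
#'   reflectance values, with a `frame_rate` attribute or explicit
#'   `frame_rate` argument (Hz).
#' @param baseline_seconds length of the baseline window (default 2).
#' @param frame_rate frames per second; taken from the stack attribute if
#'   missing.
#' @return Array of the same shape containing Delta R / R.
#' @export
ios_delta_r <- function(stack, baseline_seconds = 2.0, frame_rate = NULL) {
  stack <- as_stack(stack)
  frame_rate <- frame_rate %||% attr(stack, "frame_rate")
  if (is.null(frame_rate)) stop("frame_rate not given and not on the stack")
  n_base <- max(1L, floor(baseline_seconds * frame_rate))
  d <- dim(stack)
  if (n_base > d[3]) stop("baseline window longer than the recording")
  if (any(stack <= 0)) {
    bad <- which(stack <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive reflectance at pixel (%d, %d), frame %d",
                 bad[1], bad[2], bad[3]))
  }
  r0 <- apply_frames_mean(stack, seq_len(n_base))
  out <- array(0, d)
  for (f in seq_len(d[3])) {
    out[, , f] <- -(stack[, , f] - r0) / stack[, , f]
  }
  copy_movie_attrs(out, stack)
}

#' Fluorescence increase for SpH recordings
#'
#' `F - F0` with `F0` the per-pixel mean of the first `baseline_seconds`.
#'
#' @inheritParams ios_delta_r
#' @return Array of the same shape containing `F - F0`.
#' @export
sph_delta_f <- function(stack, baseline_seconds = 2.0, frame_rate = NULL) {
  stack <- as_stack(stack)
  frame_rate <- frame_rate %||% attr(stack, "frame_rate")
  if (is.null(frame_rate)) stop("frame_rate not given and not on the stack")
  n_base <- max(1L, floor(baseline_seconds * frame_rate))
  d <- dim(stack)
  if (n_base > d[3]) stop("baseline window longer than the recording")
  f0 <- apply_frames_mean(stack, seq_len(n_base))
  out <- array(0, d)
  for (f in seq_len(d[3])) out[, , f] <- stack[, , f] - f0
  copy_movie_attrs(out, stack)
}

#' Difference-of-Gaussians spatial bandpass
#'
#' Per frame, `G(sigma_high) * frame - G(sigma_low) * frame` with reflective
#' border padding. Spatially broad components (including any constant
#' offset) are removed exactly: a constant frame maps to zero.
#'
#' @param stack height x width x frames array.
#' @param sigma_low broad Gaussian sd in pixels (default 10).
#' @param sigma_high narrow Gaussian sd in pixels (default 1).
#' @return Filtered array of the same shape.
#' @export
bandpass <- function(stack, sigma_low = 10, sigma_high = 1) {
  if (sigma_low <= sigma_high || sigma_high <= 0) {
    stop("need sigma_low > sigma_high > 0")
  }
  stack <- as_stack(stack)
  d <- dim(stack)
  out <- array(0, d)
  for (f in seq_len(d[3])) {
    fr <- stack[, , f]
    out[, , f] <- gauss_blur(fr, sigma_high) - gauss_blur(fr, sigma_low)
  }
  copy_movie_attrs(out, stack)
}

#' Gaussian spatial lowpass
#'
#' @param stack height x width x frames array.
#' @param sigma Gaussian sd in pixels (default 1.5, the SpH setting).
#' @return Filtered array of the same shape.
#' @export
lowpass <- function(stack, sigma = 1.5) {
  stack <- as_stack(stack)
  d <- dim(stack)
  out <- array(0, d)
  for (f in seq_len(d[3])) out[, , f] <- gauss_blur(stack[, , f], sigma)
  copy_movie_attrs(out, stack)
}

#' Spatial downsampling by block mean
#'
#' @param stack height x width x frames array.
#' @param factor integer reduction factor (default 2); 1 is the identity.
#' @return Downsampled array.
#' @export
downsample <- function(stack, factor = 2L) {
  if (factor < 1L) stop("factor must be at least 1")
  if (factor == 1L) return(as_stack(stack))
  bin_spatial(stack, c(factor, factor))
}

#' Full IOS preprocessing for one recording
#'
#' Applies, in the order of the acquisition protocol: 8x8 spatial and
#' 12-frame temporal binning, Delta R/R against the first 2 s, the
#' 10/1-px difference-of-Gaussians bandpass and factor-2 downsampling.
#' `delta_r_first = TRUE` swaps the binning and Delta R/R stages for
#' sensitivity checks.
#'
#' @param movie height x width x frames array with a `frame_rate`
#'   attribute (or `frame_rate` argument).
#' @param spatial_bin,temporal_bin,baseline_seconds,sigma_low,sigma_high,downsample_factor
#'   stage parameters; defaults are the protocol values.
#' @param frame_rate raw frame rate in Hz if not on the movie.
#' @param delta_r_first compute Delta R/R before binning (default FALSE).
#' @return Preprocessed stack with updated `frame_rate` attribute.
#' @export
ios_preprocess <- function(movie, spatial_bin = c(8L, 8L), temporal_bin = 12L,
                           baseline_seconds = 2.0, sigma_low = 10,
                           sigma_high = 1, downsample_factor = 2L,
                           frame_rate = NULL, delta_r_first = FALSE) {
  movie <- as_stack(movie)
  if (!is.null(frame_rate)) attr(movie, "frame_rate") <- frame_rate
  x <- movie
  if (delta_r_first) {
    x <- ios_delta_r(x, baseline_seconds)
    x <- bin_spatial(x, spatial_bin)
    x <- bin_temporal(x, temporal_bin)
  } else {
    x <- bin_spatial(x, spatial_bin)
    x <- bin_temporal(x, temporal_bin)
    x <- ios_delta_r(x, baseline_seconds)
  }
  x <- bandpass(x, sigma_low, sigma_high)
  downsample(x, downsample_factor)
}

#' Full SpH preprocessing with bleaching correction
#'
#' Each odour recording is converted to `F - F0`, the per-pixel mean blank
#' (bleaching) time course computed from the blank recordings is
#' subtracted, and the result is lowpass filtered and downsampled. At
#' least one blank recording is required; without blanks the bleaching
#' correction is refused, never silently skipped.
#'
#' @param movies list of odour recordings (height x width x frames arrays).
#' @param blank_movies list of blank recordings of the same shape.
#' @param baseline_seconds baseline window for `F0` (default 2).
#' @param lowpass_sigma Gaussian sd in px (default 1.5).
#' @param downsample_factor spatial reduction (default 2).
#' @param temporal_bin optional temporal bin width in frames.
#' @param frame_rate frames per second if not on the movies.
#' @return list of preprocessed stacks, one per odour recording.
#' @export
sph_preprocess <- function(movies, blank_movies, baseline_seconds = 2.0,
                           lowpass_sigma = 1.5, downsample_factor = 2L,
                           temporal_bin = NULL, frame_rate = NULL) {
  if (length(blank_movies) == 0L) {
    stop("bleaching correction requires at least one blank recording")
  }
  prep1 <- function(m) {
    m <- as_stack(m)
    if (!is.null(frame_rate)) attr(m, "frame_rate") <- frame_rate
    if (!is.null(temporal_bin)) m <- bin_temporal(m, temporal_bin)
    sph_delta_f(m, baseline_seconds)
  }
  blanks <- lapply(blank_movies, prep1)
  bleach <- blanks[[1]]
  if (length(blanks) > 1L) {
    for (b in blanks[-1]) bleach <- bleach + b
    bleach <- bleach / length(blanks)
  }
  lapply(movies, function(m) {
    x <- prep1(m)
    if (!all(dim(x) == dim(bleach))) {
      stop("odour and blank recordings differ in shape")
    }
    x <- copy_movie_attrs(x - bleach, x)
    x <- lowpass(x, lowpass_sigma)
    downsample(x, downsample_factor)
  })
}

#' Assemble preprocessed recordings into a measurement matrix
#'
#' Concatenates the frames of all recordings, in recording order, into the
#' frames x pixels matrix `Y`; pixels are stored column-major (column `p`
#' is pixel `(row, col)` with `p = (col-1)*height + row`). The frame map
#' makes every row invertible back to (recording, odorant, trial, frame).
#'
#' @param stacks list of preprocessed height x width x frames arrays, all
#'   the same spatial shape.
#' @param stim stimulus table with one row per recording (columns
#'   `odorant`, `trial`, `is_blank`); defaults to the movie attributes.
#' @param pixel_um pixel pitch of the preprocessed grid in micrometres.
#' @param frame_rate effective frame rate of the preprocessed stacks.
#' @return An object of class `measurement_matrix`: list with `values`
#'   (F x P), `frame_map` (data.frame), `grid`, `pixel_um`, `frame_rate`.
#' @export
assemble_measurement_matrix <- function(stacks, stim = NULL, pixel_um = 19.4,
                                        frame_rate = NULL) {
  if (length(stacks) == 0L) stop("no recordings to assemble")
  stacks <- lapply(stacks, as_stack)
  d1 <- dim(stacks[[1]])[1:2]
  for (s in stacks) {
    if (!all(dim(s)[1:2] == d1)) stop("recordings differ in spatial shape")
  }
  frame_rate <- frame_rate %||% attr(stacks[[1]], "frame_rate")
  rows <- list(); maps <- list()
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    nf <- dim(s)[3]
    rows[[i]] <- t(apply(s, 3L, as.vector)) # row f = as.vector(frame f)
    maps[[i]] <- data.frame(
      recording = i,
      odorant = attr(s, "odorant") %||% stim$odorant[i],
      trial = attr(s, "trial") %||% stim$trial[i],
      is_blank = attr(s, "is_blank") %||% (stim$is_blank[i] %||% FALSE),
      frame = seq_len(nf),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    values = do.call(rbind, rows),
    frame_map = do.call(rbind, maps),
    grid = d1, pixel_um = pixel_um, frame_rate = frame_rate
  ), class = "measurement_matrix")
}

#' @export
print.measurement_matrix <- function(x, ...) {
  cat(sprintf("Measurement matrix: %d frames x %d pixels (%dx%d grid, %.3g Hz, %.3g um/px)\n",
              nrow(x$values), ncol(x$values), x$grid[1], x$grid[2],
              x$frame_rate %||% NA_real_, x$pixel_um))
  cat(sprintf("  %d recordings, %d odorants\n",
              max(x$frame_map$recording),
              length(unique(x$frame_map$odorant[!x$frame_map$is_blank]))))
  invisible(x)
}

## internal: coerce matrix -> 1-frame stack, check 3-D
as_stack <- function(x) {
  if (is.matrix(x)) {
    a <- attributes(x)
    dim(x) <- c(dim(x), 1L)
    for (nm in setdiff(names(a), c("dim", "dimnames"))) {
      attr(x, nm) <- a[[nm]]
    }
  }
  if (length(dim(x)) != 3L) stop("expected a height x width x frames array")
  x
}

apply_frames_mean <- function(stack, frames) {
  d <- dim(stack)
  m <- stack[, , frames[1L]]
  if (length(frames) > 1L) {
    for (f in frames[-1L]) m <- m + stack[, , f]
    m <- m / length(frames)
  }
  m
}

copy_movie_attrs <- function(to, from) {
  for (nm in c("frame_rate", "odorant", "trial", "is_blank")) {
    if (!is.null(attr(from, nm))) attr(to, nm) <- attr(from, nm)
  }
  to
}
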