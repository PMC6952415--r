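## Glomerular response spectra -----------------------------------------------
##
## Turns rNMF components into per-odorant response spectra: responses are
## window means of the activation course (IOS 4.8-9.6 s, SpH 6.6-10.3 s,
## selected in seconds), components are kept only if their spectra repeat
## across trials (correlation > 0.6), the reference glomerulus is labelled
## by footprint/mask overlap, and responses are normalized to the reference
## ligand and aggregated as the median over animals.

#' Frames whose centres fall inside a time window
#'
#' Frame i (1-based) covers `[(i-1)/rate, i/rate)`; it is selected when its
#' centre `(i - 0.5)/rate` lies in `[from, to]`. At the 5/12 Hz binned IOS
#' rate the 4.8-9.6 s window selects exactly frames 3 and 4.
#'
#' @param n_frames frames per recording.
#' @param frame_rate effective frame rate in Hz.
#' @param window `c(from, to)` in seconds after recording onset.
#' @return Integer vector of frame indices.
#' @export
frames_in_window <- function(n_frames, frame_rate, window) {
  centre <- (seq_len(n_frames) - 0.5) / frame_rate
  which(centre >= window[1] & centre <= window[2])
}

#' Extract trial-wise odorant responses from an rNMF fit
#'
#' Per component, odorant and trial, the response is the mean activation
#' over the modality's response window (IOS: 4.8-9.6 s, SpH: 6.6-10.3 s
#' after recording onset), selected in seconds via [frames_in_window()].
#'
#' @param fit an [fit_rnmf()] result whose `frame_map` covers the window,
#'   or a plain F x K activation matrix plus explicit `frame_map`.
#' @param frame_map data.frame with `odorant`, `trial`, `is_blank`, `frame`
#'   per matrix row (defaults to the fit's own).
#' @param modality `"ios"` or `"sph"`, or use `window` directly.
#' @param frame_rate effective frame rate of the rows in Hz.
#' @param window optional explicit `c(from, to)` seconds window.
#' @return data.frame with columns `component`, `odorant`, `trial`,
#'   `is_blank`, `response`.
#' @export
extract_responses <- function(fit, frame_map = NULL,
                              modality = c("ios", "sph"),
                              frame_rate, window = NULL) {
  modality <- match.arg(modality)
  A <- if (inherits(fit, "rnmf")) fit$temporal else fit
  frame_map <- frame_map %||% (if (inherits(fit, "rnmf")) fit$frame_map)
  if (is.null(frame_map)) stop("no frame map available")
  window <- window %||%
    switch(modality, ios = c(4.8, 9.6), sph = c(6.6, 10.3))
  n_per <- max(frame_map$frame)
  sel_frames <- frames_in_window(n_per, frame_rate, window)
  if (length(sel_frames) == 0L) {
    stop("response window lies outside the recording")
  }
  keep <- frame_map$frame %in% sel_frames
  key <- interaction(frame_map$odorant, frame_map$trial, drop = TRUE)[keep]
  out <- do.call(rbind, lapply(split(which(keep), key), function(rows) {
    data.frame(
      odorant = frame_map$odorant[rows[1]],
      trial = frame_map$trial[rows[1]],
      is_blank = frame_map$is_blank[rows[1]],
      t(colMeans(A[rows, , drop = FALSE]))
    )
  }))
  K <- ncol(A)
  long <- data.frame(
    component = rep(seq_len(K), each = nrow(out)),
    odorant = rep(out$odorant, K),
    trial = rep(out$trial, K),
    is_blank = rep(out$is_blank, K),
    response = as.vector(as.matrix(out[, -(1:3), drop = FALSE]))
  )
  rownames(long) <- NULL
  long
}

#' Spread trial-wise responses into per-trial spectrum matrices
#'
#' @param responses data.frame from [extract_responses()].
#' @param drop_blank exclude blank recordings (default TRUE).
#' @return list of components -> (trial x odorant) spectrum matrices.
#' @export
trial_spectra <- function(responses, drop_blank = TRUE) {
  if (drop_blank) responses <- responses[!responses$is_blank, , drop = FALSE]
  odorants <- sort(unique(responses$odorant))
  lapply(split(responses, responses$component), function(d) {
    trials <- sort(unique(d$trial))
    m <- matrix(NA_real_, length(trials), length(odorants),
                dimnames = list(trials, odorants))
    m[cbind(match(d$trial, trials), match(d$odorant, odorants))] <- d$response
    m
  })
}

#' Trial-to-trial repeatability filter
#'
#' A component is retained iff the Pearson correlation between the
#' response spectra of odour-set repetitions exceeds `threshold`; with
#' more than two repetitions the mean over all trial pairs is used.
#'
#' @param spectra list from [trial_spectra()] (trial x odorant matrices).
#' @param threshold correlation threshold (default 0.6).
#' @return Integer (or named) vector of retained component ids.
#' @export
trial_filter <- function(spectra, threshold = 0.6) {
  keep <- vapply(spectra, function(m) {
    m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
    if (nrow(m) < 2L) {
      stop("trial filter requires at least two odour-set repetitions")
    }
    cc <- stats::cor(t(m))
    vals <- cc[upper.tri(cc)]
    mean(vals, na.rm = TRUE) > threshold
  }, logical(1L))
  ids <- names(spectra) %||% seq_along(spectra)
  as.integer(ids[keep & !is.na(keep)])
}

#' Label components overlapping a reference mask
#'
#' Automatic surrogate for the manual assignment of components to the
#' GFP-marked reference glomerulus: a component is labelled when the
#' fraction of its footprint mass inside the mask exceeds
#' `overlap_fraction`.
#'
#' @param fit an `rnmf` object (or K x P spatial matrix).
#' @param mask logical or 0/1 matrix on the same pixel grid.
#' @param overlap_fraction required mass fraction (default 0.5).
#' @return Integer vector of labelled component indices.
#' @export
assign_reference <- function(fit, mask, overlap_fraction = 0.5) {
  X <- if (inherits(fit, "rnmf")) fit$spatial else fit
  m <- as.numeric(as.vector(mask) != 0)
  if (length(m) != ncol(X)) stop("mask grid does not match the footprints")
  if (sum(m) == 0) stop("empty reference mask")
  tot <- rowSums(X)
  frac <- as.vector(X %*% m) / ifelse(tot > 0, tot, 1)
  which(tot > 0 & frac > overlap_fraction)
}

#' Normalize responses to the reference ligand
#'
#' Per measurement (animal), responses are divided by the response to the
#' reference odorant in the same measurement (`a_rel = a / a_ref`).
#' Measurements whose reference response does not exceed `min_ref` are
#' excluded from aggregation (not zero-filled). Responses are on the
#' fractional Delta R/R scale, so the protocol's 0.2 per-mille criterion
#' is `min_ref = 2e-4`.
#'
#' @param responses data.frame with columns `animal`, `odorant`,
#'   `response` (one spectrum per animal, e.g. trial means of the labelled
#'   reference component).
#' @param reference_odorant id of the reference ligand (e.g. methyl
#'   propionate).
#' @param min_ref inclusion threshold on the reference response.
#' @return data.frame of the retained measurements with an added
#'   `relative` column; attribute `excluded_animals` lists rejections.
#' @export
normalize_to_reference_ligand <- function(responses, reference_odorant,
                                          min_ref = 2e-4) {
  if (!reference_odorant %in% responses$odorant) {
    stop("reference odorant '", reference_odorant, "' absent from the panel")
  }
  parts <- split(responses, responses$animal)
  excluded <- character(0)
  kept <- lapply(parts, function(d) {
    aref <- d$response[match(reference_odorant, d$odorant)]
    if (is.na(aref) || aref <= min_ref) {
      excluded <<- c(excluded, as.character(d$animal[1])); return(NULL)
    }
    d$relative <- d$response / aref
    d
  })
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  attr(out, "excluded_animals") <- excluded
  out
}

#' Median odour response across animals
#'
#' @param relative data.frame from [normalize_to_reference_ligand()] with
#'   columns `animal`, `odorant`, `relative`.
#' @return data.frame per odorant: `median_relative`, `n_animals`; odorants
#'   with zero valid animals are absent (flagged via the
#'   `missing_odorants` attribute when `panel` is given).
#' @param panel optional full odorant panel to check for missing odorants.
#' @export
aggregate_median <- function(relative, panel = NULL) {
  sp <- split(relative$relative, relative$odorant)
  out <- data.frame(
    odorant = names(sp),
    median_relative = vapply(sp, stats::median, numeric(1L)),
    n_animals = vapply(sp, length, integer(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(panel)) {
    attr(out, "missing_odorants") <- setdiff(panel, out$odorant)
  }
  out
}

#' Two-sample t-test of odour responses against the control
#'
#' Welch two-sided t-test of each odorant's replicate responses against
#' the control (carrier gas) replicates. Degenerate inputs in which both
#' groups have zero variance return p = 1 (no evidence of a difference).
#'
#' @param responses data.frame with columns `odorant`, `response`
#'   (replicates across trials/animals).
#' @param control_responses numeric vector of control replicates.
#' @return data.frame per odorant with `p_value` and replicate counts.
#' @export
ttest_vs_control <- function(responses, control_responses) {
  if (length(control_responses) < 2L) stop("need at least 2 control replicates")
  sp <- split(responses$response, responses$odorant)
  p <- vapply(sp, function(x) {
    if (length(x) < 2L) stop("need at least 2 replicates per odorant")
    if (stats::sd(x) == 0 && stats::sd(control_responses) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(control_responses)))) 1 else 0)
    }
    stats::t.test(x, control_responses)$p.value
  }, numeric(1L))
  data.frame(odorant = names(sp), p_value = unname(p),
             n = vapply(sp, length, integer(1L)),
             n_control = length(control_responses),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scale a response spectrum to unit Euclidean length
#'
#' @param spectrum numeric vector; must not be all zero.
#' @return `spectrum / ||spectrum||`.
#' @export
unit_norm <- function(spectrum) {
  n <- sqrt(sum(spectrum^2))
  if (n == 0) stop("cannot unit-normalize an all-zero spectrum")
  spectrum / n
}
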