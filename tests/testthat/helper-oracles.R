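# Independent oracles, coded without reference to the package internals.

# pool-adjacent-violators, written as an explicit stack algorithm
# (independent of stats::isoreg, which the package uses)
pava_oracle <- function(y, weights = rep(1, length(y))) {
  vals <- c(); wts <- c(); cnt <- c()
  for (i in seq_along(y)) {
    vals <- c(vals, y[i]); wts <- c(wts, weights[i]); cnt <- c(cnt, 1L)
    while (length(vals) > 1L &&
           vals[length(vals) - 1L] > vals[length(vals)]) {
      n <- length(vals)
      w <- wts[n - 1L] + wts[n]
      v <- (vals[n - 1L] * wts[n - 1L] + vals[n] * wts[n]) / w
      vals <- c(vals[seq_len(n - 2L)], v)
      wts <- c(wts[seq_len(n - 2L)], w)
      cnt <- c(cnt[seq_len(n - 2L)], cnt[n - 1L] + cnt[n])
    }
  }
  rep(vals, cnt)
}

# exact unimodal least-squares via exhaustive mode split, using pava_oracle
unimodal_oracle <- function(y) {
  n <- length(y)
  best <- NULL
  for (m in 0:n) {
    inc <- if (m > 0) pava_oracle(y[seq_len(m)]) else numeric(0)
    dec <- if (m < n) rev(pava_oracle(rev(y[seq(m + 1L, n)]))) else numeric(0)
    fit <- c(inc, dec)
    sse <- sum((y - fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(fitted = fit, sse = sse)
  }
  best
}

# brute-force average-linkage agglomeration from the original distance
# matrix; returns merge heights and the partition after each merge
average_linkage_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        h <- mean(D[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions[[length(partitions) + 1L]] <-
      canonical_partition(clusters, n)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(clusters, n) {
  assign <- integer(n)
  for (k in seq_along(clusters)) assign[clusters[[k]]] <- k
  # canonical form: relabel by first occurrence
  paste(match(assign, unique(assign)), collapse = ",")
}

# brute-force normalized Mann-Whitney U (intra larger, half-weight ties)
normalized_u_oracle <- function(intra, extra) {
  tot <- 0
  for (a in intra) for (b in extra) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(intra) * length(extra))
}

# direct EVA evaluator: literal double loop over grid points and modes
eva_oracle <- function(freqs, sigma, q_max = 4000) {
  q <- seq(0, q_max - sigma, by = sigma)
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    s <- 0
    for (f in freqs) s <- s + exp(-(q[i] - f)^2 / (2 * sigma^2))
    out[i] <- s
  }
  out
}

# simple prediction models for q^2 scoring tests
oracle_model <- function(fun) structure(list(fun = fun), class = "glom_test_oracle")
predict.glom_test_oracle <- function(object, newdata, ...) object$fun(newdata)
registerS3method("predict", "glom_test_oracle", predict.glom_test_oracle)

mean_model <- function(m) structure(list(m = m), class = "glom_test_mean")
predict.glom_test_mean <- function(object, newdata, ...) rep(object$m, nrow(newdata))
registerS3method("predict", "glom_test_mean", predict.glom_test_mean)

# build a small synthetic measurement matrix with planted footprints;
# returns the truth alongside
make_synth_matrix <- function(n_glomeruli, grid, n_odorants = 12L,
                              n_trials = 2L, frames = 5L, onset = 2L,
                              overlap = 0, noise_sd = 0, seed = 1L,
                              widths = NULL, snr = NULL) {
  ens <- gen_ensemble(1, n_glomeruli, grid, overlap_level = overlap,
                      chemotopy_strength = 0, seed = seed)
  if (!is.null(widths)) ens$tuning_widths[] <- widths
  desc <- gen_descriptor_table(ens, n_odorants, 3L + 2L, 1, seed = seed + 1L)
  amp <- gen_response_amplitudes(ens, desc$latent)
  stim <- gen_stimulus_table(rownames(desc$latent), n_trials, 0L,
                             seed = seed + 2L)
  mov <- gen_movie(ens, amp, stim, frames_per_recording = frames,
                   frame_rate = 5 / 12, stimulus_onset_frame = onset,
                   pixel_noise_sd = 0, global_signal_sd = 0,
                   seed = seed + 3L)
  pre <- lapply(mov, function(m)
    ios_delta_r(m, baseline_seconds = (onset - 1) * 12 / 5))
  mm <- assemble_measurement_matrix(pre, stim, frame_rate = 5 / 12)
  if (!is.null(snr)) noise_sd <- max(abs(mm$values)) / snr
  if (noise_sd > 0) {
    mm$values <- mm$values + glomtopo:::with_seed(seed + 4L,
      matrix(stats::rnorm(length(mm$values), sd = noise_sd),
             nrow(mm$values)))
  }
  list(mm = mm, ensemble = ens, amplitudes = amp, stim = stim,
       latent = desc$latent, noise_sd = noise_sd)
}
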