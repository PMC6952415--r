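test_that("ensemble geometry honours overlap and chemotopy settings", {
  # zero overlap, zero chemotopy: truncated footprints are pairwise disjoint
  ens <- gen_ensemble(1, 3, c(64, 84), overlap_level = 0,
                      chemotopy_strength = 0, seed = 1)
  fp <- ens$footprints
  for (i in 1:2) for (j in seq(i + 1, 3)) {
    expect_equal(sum(fp[[i]] * fp[[j]]), 0)
  }
  expect_true(all(vapply(fp, function(f) all(f >= 0) && sum(f) > 0,
                         logical(1))))

  # full chemotopy: spatial and tuning distances positively rank correlated
  # within every animal (and exactly rank 1 at strength 1)
  e2 <- gen_ensemble(7, 20, c(64, 84), overlap_level = 0.3,
                     chemotopy_strength = 1, seed = 7)
  for (a in 1:7) {
    idx <- which(e2$animal_ids == a)
    sd_ <- c(dist(e2$positions_px[idx, ]))
    td <- c(dist(e2$tuning_centres[idx, ]))
    rc <- cor(sd_, td, method = "spearman")
    expect_gt(rc, 0)
    expect_equal(rc, 1, tolerance = 1e-12)
  }

  # every animal carries a reference-flagged glomerulus; shared identities
  # share tuning centres
  expect_true(all(tapply(e2$reference_flag, e2$animal_ids, any)))
  for (g in unique(e2$shared_identity)) {
    tc <- e2$tuning_centres[e2$shared_identity == g, , drop = FALSE]
    expect_lt(max(apply(tc, 2, function(x) diff(range(x)))), 1e-12)
  }
})

test_that("ensemble generation is deterministic and validates input", {
  a <- gen_ensemble(2, 4, c(32, 42), 0.3, 0.5, seed = 9)
  b <- gen_ensemble(2, 4, c(32, 42), 0.3, 0.5, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_identical(a$footprints, b$footprints)
  expect_error(gen_ensemble(1, 2, c(32, 42)), "at least")
  expect_error(gen_ensemble(1, 10, c(8, 8), overlap_level = 0,
                            chemotopy_strength = 0), "too small")
})

test_that("descriptor tables carry planted, linearly recoverable structure", {
  ens <- gen_ensemble(2, 4, c(32, 42), 0.3, 0.5, seed = 2)
  out <- gen_descriptor_table(ens, 48, 100, 0.3, seed = 2)
  expect_equal(dim(out$table$values), c(48L, 100L))
  expect_length(out$table$blocks, 100L)
  expect_equal(sum(out$table$blocks == "NOISE"), 70L)

  # noiseless, all-informative: latent coordinates recoverable by linear
  # regression with residual ~ 0
  clean <- gen_descriptor_table(ens, 30, 10, 1, seed = 3, noise_sd = 0)
  fitres <- lm.fit(cbind(1, clean$table$values[, 1:3]), clean$latent)
  expect_lt(max(abs(fitres$residuals)), 1e-8)

  # planted tuning: mean amplitude decreases with latent distance
  amp <- gen_response_amplitudes(ens, out$latent)
  k <- 1L
  d <- sqrt(colSums((t(out$latent) - ens$tuning_centres[k, ])^2))
  bins <- cut(d, quantile(d, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE)
  mb <- tapply(amp[k, ], bins, mean)
  expect_true(all(diff(mb) < 0))
  expect_error(gen_descriptor_table(ens, 1, 10, 0.5), "at least 2")
})

test_that("response amplitudes follow the Gaussian tuning kernel", {
  ens <- gen_ensemble(2, 3, c(32, 42), 0, 0, seed = 4)
  # odorant exactly at glomerulus 1's tuning centre, plus one at distance
  # = width along the first latent axis
  z <- rbind(ens$tuning_centres[1, ],
             ens$tuning_centres[1, ] + c(ens$tuning_widths[1], 0, 0))
  rownames(z) <- c("at_centre", "at_width")
  amp <- gen_response_amplitudes(ens, z, noise_sd = 0)
  expect_equal(amp[1, "at_centre"], ens$scales[1])
  expect_equal(amp[1, "at_width"], ens$scales[1] * exp(-1 / 2))

  # same shared identity in another animal: identical spectrum (corr 1)
  z2 <- matrix(rnorm(15), 5, 3)
  rownames(z2) <- paste0("o", 1:5)
  amp2 <- gen_response_amplitudes(ens, z2, noise_sd = 0)
  expect_equal(cor(amp2[1, ], amp2[4, ]), 1) # identity 1, animals 1 and 2
  expect_error(gen_response_amplitudes(ens, z2, noise_sd = -1),
               "non-negative")
})

test_that("movies contain the planted signal and nothing else", {
  ens <- gen_ensemble(1, 3, c(64, 84), 0, 0, seed = 5)
  z <- matrix(rnorm(6), 2, 3, dimnames = list(c("a", "b"), NULL))
  amp <- gen_response_amplitudes(ens, z)
  stim <- gen_stimulus_table(c("a", "b"), 2, 1, seed = 6)

  mv <- gen_movie(ens, amp, stim, frames_per_recording = 6,
                  stimulus_onset_frame = 3, seed = 7)
  # blank recording with all noise sources off: every frame = baseline
  blank <- mv[[which(stim$is_blank)[1]]]
  expect_equal(max(abs(blank - 1000)), 0)

  # stimulated recording: post-onset mean inside a footprint exceeds
  # pre-onset mean (IOS: reflectance decrease, so compare inverted)
  rec <- which(!stim$is_blank)[1]
  m <- mv[[rec]]
  o <- stim$odorant[rec]
  k <- which.max(amp[, o])
  inside <- ens$footprints[[k]] > 0.5
  pre <- mean(m[, , 1][inside]); post <- mean(m[, , 6][inside])
  expect_lt(post, pre)

  # bit-identical on repeat; stimulus term absent before onset
  mv2 <- gen_movie(ens, amp, stim, frames_per_recording = 6,
                   stimulus_onset_frame = 3, seed = 7)
  expect_identical(mv, mv2)
  expect_equal(max(abs(m[, , 2] - 1000)), 0)
  expect_error(gen_movie(ens, amp, stim[0, ], seed = 1), "empty")
  expect_error(gen_movie(ens, amp, stim, frames_per_recording = 4,
                         stimulus_onset_frame = 9), "onset")
})

test_that("line spectra are sorted, in range and reproducible", {
  forced <- gen_line_spectra(1, modes_range = c(1, 1),
                             freq_range = c(2000, 2000), seed = 1)
  expect_equal(forced[[1]], 2000)

  sp <- gen_line_spectra(10, c(20, 60), seed = 2)
  expect_length(sp, 10)
  for (s in sp) {
    expect_true(!is.unsorted(s))
    expect_true(all(s >= 0 & s <= 4000))
  }
  expect_identical(sp, gen_line_spectra(10, c(20, 60), seed = 2))
  expect_error(gen_line_spectra(2, freq_range = c(-10, 100)), "outside")
})

test_that("stimulus tables repeat every odorant and flag blanks", {
  stim <- gen_stimulus_table(c("a", "b", "c"), n_trials = 2, n_blanks = 2,
                             seed = 3)
  tab <- table(stim$odorant[!stim$is_blank])
  expect_true(all(tab >= 2))
  expect_equal(sum(stim$is_blank), 2L)
  expect_true(all(stim$odorant[stim$is_blank] == "blank"))
  expect_error(gen_stimulus_table("a", n_trials = 1), "twice")
})
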