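test_that("response windows are selected in seconds", {
  # binned IOS rate 5/12 Hz: the 4.8-9.6 s window is exactly frames 3-4
  expect_equal(frames_in_window(5, 5 / 12, c(4.8, 9.6)), c(3L, 4L))
  # SpH at 0.94 Hz, 6.6-10.3 s by frame centres
  expect_equal(frames_in_window(12, 0.94, c(6.6, 10.3)), 7:10)
})

test_that("responses are window means of the activation course", {
  frame_map <- data.frame(
    recording = rep(1:2, each = 5),
    odorant = rep(c("a", "b"), each = 5),
    trial = 1L, is_blank = FALSE, frame = rep(1:5, 2))
  # constant activation c -> response c
  A <- cbind(rep(2.5, 10), c(rep(0, 2), rep(1, 3), rep(0, 2), rep(1, 3)))
  resp <- extract_responses(A, frame_map, modality = "ios",
                            frame_rate = 5 / 12)
  r1 <- resp[resp$component == 1 & resp$odorant == "a", "response"]
  expect_equal(r1, 2.5)
  # zero pre-onset, one in-window -> response 1
  r2 <- resp[resp$component == 2 & resp$odorant == "a", "response"]
  expect_equal(r2, 1)
  expect_error(extract_responses(A, frame_map, frame_rate = 5 / 12,
                                 window = c(100, 200)), "outside")
})

test_that("trial filter keeps repeatable spectra only", {
  sp <- list(
    `1` = rbind(c(1, 2, 3, 4), c(1, 2, 3, 4)),        # identical: keep
    `2` = rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)),        # anticorrelated: drop
    `3` = rbind(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.2)) # close: keep
  )
  expect_equal(trial_filter(sp, 0.6), c(1L, 3L))
  expect_error(trial_filter(list(`1` = matrix(1:4, 1))), "two")

  # pure-noise component: removed in > 90% of simulations
  removed <- vapply(1:100, function(s) {
    m <- glomtopo:::with_seed(1000 + s, matrix(rnorm(2 * 12), 2, 12))
    length(trial_filter(list(`1` = m), 0.6)) == 0L
  }, logical(1))
  expect_gt(mean(removed), 0.9)
})

test_that("reference labelling follows footprint/mask overlap mass", {
  grid <- c(8, 10)
  f_in <- matrix(0, 8, 10); f_in[2:4, 2:4] <- 1      # inside the mask
  f_out <- matrix(0, 8, 10); f_out[6:8, 7:9] <- 1    # zero overlap
  mask <- matrix(0, 8, 10); mask[1:5, 1:5] <- 1
  X <- rbind(as.vector(f_in), as.vector(f_out))
  expect_equal(assign_reference(X, mask), 1L)
  expect_error(assign_reference(X, matrix(0, 8, 10)), "empty")
  expect_error(assign_reference(X, matrix(1, 4, 4)), "grid")
})

test_that("reference-ligand normalization divides and excludes correctly", {
  resp <- data.frame(
    animal = rep(1:3, each = 3),
    odorant = rep(c("MP", "x", "y"), 3),
    response = c(1e-3, 1e-3, 2e-3,   # animal 1: rel 1, 1, 2
                 1e-4, 5e-4, 1e-4,   # animal 2: a_MP below 2e-4 -> excluded
                 4e-4, 8e-4, 2e-4))
  out <- normalize_to_reference_ligand(resp, "MP")
  expect_equal(attr(out, "excluded_animals"), "2")
  a1 <- out[out$animal == 1, ]
  expect_equal(a1$relative, c(1, 1, 2))
  expect_equal(out$relative[out$animal == 3 & out$odorant == "MP"], 1)
  expect_error(normalize_to_reference_ligand(resp, "absent"), "absent")
})

test_that("median aggregation is robust and order invariant", {
  rel <- data.frame(animal = 1:3, odorant = "x", relative = c(1, 2, 100))
  expect_equal(aggregate_median(rel)$median_relative, 2)
  one <- data.frame(animal = 1, odorant = "x", relative = 7)
  expect_equal(aggregate_median(one)$median_relative, 7)
  perm <- rel[c(3, 1, 2), ]
  expect_equal(aggregate_median(perm), aggregate_median(rel))
  out <- aggregate_median(rel, panel = c("x", "z"))
  expect_equal(attr(out, "missing_odorants"), "z")
})

test_that("t-test against control handles degenerate and planted cases", {
  # both groups identical constants: p = 1 policy
  r <- data.frame(odorant = "x", response = c(2, 2, 2))
  expect_equal(ttest_vs_control(r, c(2, 2, 2))$p_value, 1)

  # planted 10-sigma effect, n = 10: p < 1e-6 in at least 99 of 100 runs
  hits <- vapply(1:100, function(s) {
    glomtopo:::with_seed(s, {
      a <- rnorm(10, mean = 10); b <- rnorm(10, mean = 0)
      ttest_vs_control(data.frame(odorant = "x", response = a), b)$p_value
    })
  }, numeric(1))
  expect_gte(sum(hits < 1e-6), 99L)

  # two-sided p unchanged under group swap
  set.seed(5)
  a <- rnorm(6); b <- rnorm(6, 1)
  p1 <- ttest_vs_control(data.frame(odorant = "x", response = a), b)$p_value
  p2 <- ttest_vs_control(data.frame(odorant = "x", response = b), a)$p_value
  expect_equal(p1, p2)
  expect_error(ttest_vs_control(r, 1), "control")
})

test_that("unit normalization is exact, idempotent and scale invariant", {
  expect_equal(unit_norm(c(3, 4)), c(0.6, 0.8))
  u <- unit_norm(c(1, 2, 2) / 3)
  expect_equal(unit_norm(u), u)
  s <- runif(5)
  expect_equal(unit_norm(7 * s), unit_norm(s))
  expect_error(unit_norm(c(0, 0)), "zero")
})

test_that("noiseless end-to-end spectra match planted amplitudes", {
  s <- make_synth_matrix(4, c(32, 42), n_odorants = 8, seed = 12)
  fit <- suppressWarnings(fit_rnmf(s$mm, K = 4, alpha_sm = 2,
                                   alpha_sp = 0.5, seed = 1,
                                   max_iter = 300))
  resp <- extract_responses(fit, modality = "ios", frame_rate = 5 / 12)
  tsp <- trial_spectra(resp)
  expect_equal(trial_filter(tsp, 0.6), 1:4) # noiseless: all repeatable
  spec <- t(vapply(tsp, colMeans, colMeans(tsp[[1]])))
  m <- match_footprints(fit, s$ensemble$footprints)
  for (g in 1:4) {
    comp <- m$component[g]
    planted <- s$amplitudes[g, colnames(spec)]
    expect_gt(cor(spec[comp, ], planted), 0.99)
  }
})
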