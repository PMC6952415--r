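test_that("correlation distance hits its analytic anchors", {
  s <- c(1, 2, 3)
  expect_equal(correlation_distance(s, s), 0)
  expect_equal(correlation_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  expect_equal(correlation_distance(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_error(correlation_distance(c(1, 1, 1), s), "constant")
  expect_error(correlation_distance(1:2, 1:2), "length")

  m <- rbind(a = c(1, 2, 3, 1), b = c(2, 4, 6, 2), c = c(3, 2, 1, 3))
  D <- correlation_distance_matrix(m)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(D, t(D), ignore_attr = TRUE)
  expect_true(all(D >= 0 & D <= 2))
  expect_equal(D["a", "b"], 0)
})

test_that("barycentres are activation-weighted means relative to the panel", {
  X <- rbind(c(1, 0), c(0, 1))
  # equal weights, panel mean (0.5, 0.5): exactly the origin
  expect_equal(barycentre(c(0.5, 0.5), X), c(0, 0))
  # all activity on one odorant: x_o minus the panel mean
  expect_equal(barycentre(c(1, 0), X), c(1, 0) - c(0.5, 0.5))
  # equal activity on all odorants: origin
  X3 <- matrix(rnorm(12), 4, 3)
  expect_equal(barycentre(rep(0.25, 4), X3), rep(0, 3), tolerance = 1e-12)
  # translation covariance: shifting all descriptors cancels
  shift <- matrix(5, 4, 3)
  a <- runif(4)
  expect_equal(barycentre(a, X3 + shift), barycentre(a, X3),
               tolerance = 1e-12)
  expect_error(barycentre(c(0, 0, 0, 0), X3), "all-zero")
  expect_error(barycentre(c(-1, 1, 1, 1), X3), "non-negative")
})

test_that("cosine distance hits its analytic anchors", {
  x <- c(1, 2, 3)
  expect_equal(cosine_distance(x, 2 * x), 0)
  expect_equal(cosine_distance(x, -x), 2)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_error(cosine_distance(c(0, 0), x[1:2]), "zero")
  B <- rbind(c(1, 0), c(0, 2), c(-3, 0))
  D <- cosine_distance_matrix(B)
  expect_equal(D[1, 3], 2)
  expect_equal(D[1, 2], 1)
  expect_true(all(D >= 0 & D <= 2) && all(diag(D) == 0))
})

test_that("UPGMA matches hand cases and the brute-force oracle", {
  # two leaves at distance d: one merge at height d
  d2 <- matrix(c(0, 3, 3, 0), 2)
  t2 <- upgma(d2)
  expect_equal(t2$height, 3)

  # three leaves: AB at 1, then C joins at mean(4, 4) = 4
  d3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3)
  t3 <- upgma(d3)
  expect_equal(t3$height, c(1, 4))
  expect_equal(sort(cut_tree(t3, 2)), sort(c(1L, 1L, 2L)))

  # oracle equivalence on random matrices up to n = 10
  for (s in 1:12) {
    n <- 4L + (s %% 7L)
    D <- glomtopo:::with_seed(100 + s, {
      M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0; M
    })
    tree <- upgma(D)
    oracle <- average_linkage_oracle(D)
    expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
    expect_true(!is.unsorted(tree$height)) # ultrametric heights
    for (i in seq_len(n - 1L)) {
      part <- cut_tree(tree, oracle$heights[i] + 1e-9)
      groups <- split(seq_len(n), part)
      expect_equal(canonical_partition(unname(groups), n),
                   oracle$partitions[[i]])
    }
  }
  expect_error(upgma(matrix(0, 1, 1)), "2 leaves")
})

test_that("cluster validity requires enough animals", {
  assign <- c(1, 1, 1, 2, 2, 3)
  animals <- c(1, 2, 3, 1, 1, 2)
  v <- valid_clusters(assign, animals, min_animals = 3)
  expect_equal(v, c(1, 1, 1, NA, NA, NA))
  expect_equal(valid_clusters(assign, animals, min_animals = 1), assign)
})

test_that("cluster prototypes separate members from non-members", {
  sp <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  cp <- cluster_prototype(sp, members = 1:2)
  expect_equal(cp$prototype, unit_norm(c(1, 2, 3, 4)))
  expect_equal(cp$r_centre[1:2], c(1, 1), ignore_attr = TRUE)
  expect_lt(cp$r_centre[3], 0)
  expect_error(cluster_prototype(sp, integer(0)), "empty")

  # planted clusters: member/non-member r_centre separates (AUC > 0.9)
  ens <- gen_ensemble(5, 8, c(32, 42), 0.3, 0, seed = 31)
  z <- glomtopo:::with_seed(32, matrix(rnorm(12 * 3), 12, 3))
  amp <- gen_response_amplitudes(ens, z, noise_sd = 0.05, seed = 33)
  members <- which(ens$shared_identity == 2)
  cp2 <- cluster_prototype(amp, members)
  r_in <- cp2$r_centre[members]
  r_out <- cp2$r_centre[-members]
  auc <- mean(outer(r_in, r_out, ">") + 0.5 * outer(r_in, r_out, "=="))
  expect_gt(auc, 0.9)
})

test_that("reference similarity flags shrink monotonically with threshold", {
  pr <- list(ref = unit_norm(c(1, 2, 3, 4)),
             close = unit_norm(c(1, 2, 3, 5)),
             ortho = unit_norm(c(3, -1, 2, -1.2)))
  out <- reference_similarity(pr, "ref", 0.2)
  expect_true(out$flagged[out$cluster == "ref"])   # r = 1 with itself
  expect_true(out$flagged[out$cluster == "close"])
  expect_false(out$flagged[out$cluster == "ortho"])
  flags <- vapply(c(-0.5, 0, 0.5, 0.99),
                  function(th) sum(reference_similarity(pr, "ref", th)$flagged),
                  numeric(1))
  expect_true(all(diff(flags) <= 0))
  expect_error(reference_similarity(pr, "missing"), "missing")
})

test_that("normalized U agrees with brute-force pair counting", {
  # tiny worked case: intra {1,2}, extra {3}: no intra larger -> 0
  r <- patch_proximity_test(c(1, 2, 3), c(TRUE, TRUE, FALSE),
                            n_shuffles = 200, seed = 1)
  expect_equal(r$u_norm, 0)

  # total separation in the other direction
  r2 <- patch_proximity_test(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                             n_shuffles = 200, seed = 1)
  expect_equal(r2$u_norm, 1)

  # random inputs incl. ties, groups up to 50 x 50
  for (s in 1:10) {
    glomtopo:::with_seed(200 + s, {
      ni <- sample(3:50, 1); ne <- sample(3:50, 1)
      d <- c(sample(1:8, ni, TRUE), sample(1:8, ne, TRUE))
      member <- rep(c(TRUE, FALSE), c(ni, ne))
      r <- patch_proximity_test(d, member, n_shuffles = 100, seed = 1)
      expect_equal(r$u_norm,
                   normalized_u_oracle(d[member], d[!member]))
    })
  }
  expect_error(patch_proximity_test(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("exchangeable groups give a centred shuffle null", {
  set.seed(7)
  d <- runif(60)
  member <- rep(c(TRUE, FALSE), c(20, 40))
  r <- patch_proximity_test(d, member, n_shuffles = 2000, seed = 5)
  expect_lt(abs(r$shuffle_mean - 0.5), 0.02)
  expect_gt(r$p_value, 0.001) # identically distributed: no real effect
})

test_that("near/far chemotopy sweep detects planted structure", {
  ens <- gen_ensemble(1, 30, c(64, 84), 0.3, 1, seed = 41)
  ref <- which(ens$reference_flag)
  sp_d <- distance_to_reference(ens$positions, ref)
  # chemical distance proxy: tuning-centre distance to the reference
  ch_d <- sqrt(rowSums(sweep(ens$tuning_centres, 2,
                             ens$tuning_centres[ref[1], ])^2))
  thr <- quantile(sp_d[-ref], 0.3)
  out <- nearfar_chemotopy_sweep(sp_d[-ref], ch_d[-ref], c(thr, 1e6),
                                 n_shuffles = 300, seed = 2)
  expect_true(out$defined[1])
  expect_lt(out$u_norm[1], 0.5)
  expect_lt(out$p_value[1], 0.05)
  expect_false(out$defined[2]) # far group empty at a huge threshold
  # shuffle control sits at 0.5
  expect_lt(abs(out$shuffle_mean[1] - 0.5), 0.05)
})

test_that("supercluster axes recover planted geometry equivariantly", {
  set.seed(51)
  pos <- rbind(cbind(rnorm(6, 0, 5), rnorm(6, 0, 5)),
               cbind(rnorm(6, 0, 5), rnorm(6, 300, 5)))
  labels <- rep(c("A", "B"), each = 6)
  out <- supercluster_axis(pos, labels, rep(1, 12), pair = c("A", "B"),
                           reference_axis = c(0, 1), n_shuffles = 400,
                           seed = 3)
  expect_lt(abs(out$angle_deg), 5)
  expect_gte(out$shuffle_percentile, 0.95)

  # rotating all positions rotates the reported angle accordingly
  th <- 30 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- supercluster_axis(pos %*% t(Rm), labels, rep(1, 12),
                           pair = c("A", "B"), reference_axis = c(0, 1),
                           n_shuffles = 0, seed = 3)
  expect_lt(abs((rot$angle_deg - out$angle_deg) - 30), 5)

  # an animal missing one label is skipped with a message
  expect_message(
    empty <- supercluster_axis(pos, c(rep("A", 12)), rep(1, 12),
                               pair = c("A", "B"), n_shuffles = 0),
    "skipped")
  expect_null(empty)
})

test_that("nearest-instance distances honour both modes", {
  pos <- rbind(c(0, 0), c(0, 10), c(0, 4))
  d_near <- distance_to_reference(pos, c(1, 2))
  expect_equal(d_near, c(0, 0, 4))
  d_cen <- distance_to_reference(pos, c(1, 2), mode = "centroid")
  expect_equal(d_cen, c(5, 5, 1))
})
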