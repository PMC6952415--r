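test_that("isotonic fits are exact on monotone and unimodal inputs", {
  x <- matrix(1:6, ncol = 1)
  up <- fit_activation_model(x, c(1, 2, 3, 5, 8, 9), "isotonic")
  expect_equal(up$fit$fitted, c(1, 2, 3, 5, 8, 9))
  expect_equal(up$fit$sse, 0)

  peak <- fit_activation_model(matrix(1:5, ncol = 1), c(1, 3, 7, 4, 2),
                               "unimodal_isotonic")
  expect_equal(peak$fit$fitted, c(1, 3, 7, 4, 2))
  expect_equal(peak$fit$sse, 0)

  expect_error(fit_activation_model(matrix(1:6, 3), 1:3, "isotonic"),
               "univariate")
})

test_that("unimodal-isotonic equals the exhaustive-enumeration oracle", {
  # the worked example
  f <- fit_activation_model(matrix(1:5, ncol = 1), c(1, 3, 2, 4, 0),
                            "unimodal_isotonic")
  o <- unimodal_oracle(c(1, 3, 2, 4, 0))
  expect_equal(f$fit$fitted, c(1, 2.5, 2.5, 4, 0))
  expect_equal(f$fit$sse, o$sse)

  # random sequences against the independent PAVA-based oracle
  for (s in 1:25) {
    y <- glomtopo:::with_seed(s, round(rnorm(sample(4:9, 1)), 2))
    f <- fit_activation_model(matrix(seq_along(y), ncol = 1), y,
                              "unimodal_isotonic")
    o <- unimodal_oracle(y)
    expect_equal(f$fit$sse, o$sse, tolerance = 1e-10)
    expect_equal(f$fit$fitted, o$fitted, tolerance = 1e-10)
    # unimodal SSE never beats neither monotone direction alone
    inc <- sum((y - pava_oracle(y))^2)
    dec <- sum((y - rev(pava_oracle(rev(y))))^2)
    expect_lte(f$fit$sse, min(inc, dec) + 1e-12)
  }
})

test_that("the coefficient of determination follows its formula", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
  expect_error(r_squared(1, 1), "paired")
})

test_that("bootstrap q^2 scores oracle, mean and adversarial predictors", {
  set.seed(11)
  n <- 40
  z <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("o%02d", 1:n), c("a", "b", "c")))
  truth <- function(M) exp(-rowSums(M[, 1:3, drop = FALSE]^2) / 4)
  y <- truth(z)

  r_or <- q_squared_bootstrap(function(X, y) oracle_model(truth),
                              z, y, B = 20, seed = 1)
  expect_equal(r_or$q_squared, 1)

  yn <- y + rnorm(n, sd = 0.1)
  r_mn <- q_squared_bootstrap(function(X, y) mean_model(mean(y)),
                              z, yn, B = 50, seed = 1)
  expect_lt(abs(r_mn$q_squared), 0.1)

  # anti-signal predictor: q^2 < 0 yet bounded above by 1
  r_ad <- q_squared_bootstrap(function(X, y)
    oracle_model(function(M) -truth(M) + 2 * mean(y)),
    z, y, B = 20, seed = 1)
  expect_lt(r_ad$q_squared, 0)
  expect_lte(r_ad$q_squared, 1)
  expect_lte(r_or$q_squared, 1)

  # determinism given the seed
  r_rep <- q_squared_bootstrap(function(X, y) mean_model(mean(y)),
                               z, yn, B = 50, seed = 1)
  expect_identical(r_mn$q_squared, r_rep$q_squared)
  expect_error(q_squared_bootstrap(function(X, y) mean_model(0),
                                   z[1:3, ], y[1:3]), "at least 5")
})

test_that("space benchmarking is paired and favours information", {
  set.seed(21)
  n <- 60
  z <- matrix(rnorm(n * 3), n, 3, dimnames = list(sprintf("o%02d", 1:n), NULL))
  y <- exp(-rowSums(z^2) / 4) + rnorm(n, sd = 0.05)
  noise <- matrix(rnorm(n * 3), n, 3, dimnames = dimnames(z))
  tab <- benchmark_spaces(list(latent = z, noise = noise, latent2 = z),
                          y, B = 25, seed = 3)
  expect_gt(tab$q_squared[tab$space == "latent"][1],
            tab$q_squared[tab$space == "noise"])
  # duplicated space: identical q^2 because the resamples are shared
  expect_equal(tab$q_squared[tab$space == "latent"],
               tab$q_squared[tab$space == "latent2"])
  expect_error(benchmark_spaces(list(), y), "empty")
})

test_that("metric MDS reproduces embeddable geometries", {
  pts <- cbind(c(0, 1, 2, 5), 0)
  D <- as.matrix(dist(pts))
  emb <- mds_embed(D, 2)
  expect_lt(max(abs(as.matrix(dist(emb)) - D)), 1e-6)
  # colinear input stays colinear: second coordinate is degenerate
  expect_lt(max(abs(emb[, 2])), 1e-6)

  set.seed(2)
  cloud <- matrix(rnorm(20), 10, 2)
  D2 <- as.matrix(dist(cloud))
  e2 <- mds_embed(D2, 2)
  stress <- sqrt(sum((as.matrix(dist(e2)) - D2)^2) / sum(D2^2))
  expect_lt(stress, 1e-8)
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("virtual screening ranks by prediction with stable ties", {
  set.seed(31)
  n <- 30
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("m%02d", 1:n), letters[1:4]))
  y <- exp(-rowSums(X^2) / 6)
  m <- fit_activation_model(X, y, "svr")
  best <- rownames(X)[which.max(y)]
  cand <- descriptor_table(X, "B")
  ranked <- virtual_screen(m, cand, top_n = 100)
  expect_equal(nrow(ranked), n) # top_n larger than candidates: full list
  expect_lte(which(ranked$molecule == best), 3L)
  expect_identical(ranked, virtual_screen(m, cand, top_n = 100))
  # tie-break by molecule id
  mm <- mean_model(1)
  r2 <- virtual_screen(mm, cand)
  expect_equal(r2$molecule, sort(rownames(X)))
})

test_that("SVR with all responses inside the epsilon tube degrades to the mean", {
  set.seed(41)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(sprintf("m%d", 1:10), NULL))
  y <- rnorm(10, sd = 1e-4) # flat: no support vectors
  m <- fit_activation_model(X, y, "svr")
  expect_equal(predict(m, X), rep(mean(y), 10), tolerance = 1e-6)
})
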