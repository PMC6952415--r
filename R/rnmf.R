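## Regularized NMF segmentation ----------------------------------------------
##
## Disaggregates the frames x pixels measurement matrix Y into K components,
## each with a non-negative spatial footprint x_k ("pixel participation")
## and a common activation course a_k. The objective is
##
##   || Y - A X ||_F^2  +  alpha_sm * sum_k ||a_k||^2 * || grad x_k ||^2
##                      +  alpha_sp * sum_{j<k} max(0, cos(x_j, x_k))
##
## i.e. squared reconstruction error plus a first-difference spatial
## smoothness penalty and a positive pairwise cosine overlap (sparseness)
## penalty. The smoothness term is weighted by each component's activation
## energy, which makes it invariant under the (a_k / c, c x_k) rescaling
## ambiguity of any factorization: without the weight the optimizer could
## shrink footprints and grow activations to evade the penalty entirely.
## Optimization alternates block updates: an exact (ridge) least-squares
## solve for unconstrained activations, projected-gradient steps with
## backtracking otherwise. Every accepted step decreases the objective, so
## the convergence log is monotone non-increasing by construction.

#' Fit a regularized non-negative matrix factorization
#'
#' @param Y a [assemble_measurement_matrix()] result, or a plain
#'   frames x pixels matrix (then `grid` is required when `alpha_sm > 0`).
#' @param K number of components; at most `min(F, P)`.
#' @param alpha_sm spatial smoothness weight (squared first differences of
#'   each footprint on the pixel grid).
#' @param alpha_sp sparseness weight on positive pairwise cosine overlap
#'   between footprints.
#' @param nonneg_activations keep the non-negativity constraint on the
#'   activation courses (default TRUE). Dropping it allows odour-induced
#'   inhibition to be captured, at the price of signed activations.
#' @param seed integer seed perturbing the deterministic SVD-based
#'   initialization.
#' @param max_iter,tol stopping rule: relative objective change below
#'   `tol` (default 1e-6) or `max_iter` (default 500) outer iterations;
#'   hitting `max_iter` is flagged with a warning, never silent.
#' @param grid `c(height, width)` of the pixel grid; taken from `Y` when it
#'   is a measurement matrix.
#' @param inner_iter gradient steps per block per outer iteration.
#' @param init `"greedy"` (default; Gaussian-blob seeds at successive
#'   peaks of a robust per-pixel activation map, as functional-imaging
#'   segmentation pipelines initialize) or `"nndsvd"` (non-negative
#'   double-SVD); both deterministic and seed-perturbed. `"greedy"`
#'   requires the pixel grid and falls back to `"nndsvd"` without one.
#' @return An object of class `rnmf`: `spatial` (K x P, non-negative, rows
#'   scaled to unit maximum), `temporal` (F x K activation courses, carrying
#'   the scale), `objective` (per-iteration log), `converged`, `iterations`,
#'   `grid`, `frame_map` (if available) and the regularization record in
#'   `params`.
#' @export
fit_rnmf <- function(Y, K, alpha_sm = 0, alpha_sp = 0,
                     nonneg_activations = TRUE, seed = 1L,
                     max_iter = 500L, tol = 1e-6, grid = NULL,
                     inner_iter = 5L, init = c("greedy", "nndsvd")) {
  frame_map <- NULL
  if (inherits(Y, "measurement_matrix")) {
    grid <- Y$grid; frame_map <- Y$frame_map; Y <- Y$values
  }
  Fn <- nrow(Y); P <- ncol(Y)
  if (K > min(Fn, P)) stop("K must not exceed min(frames, pixels)")
  if (alpha_sm < 0 || alpha_sp < 0) stop("penalty weights must be >= 0")
  if (alpha_sm > 0 && is.null(grid)) stop("alpha_sm > 0 requires the pixel grid")
  if (!is.null(grid) && grid[1] * grid[2] != P) {
    stop("grid does not match the pixel count")
  }

  init <- match.arg(init)
  if (init == "greedy" && is.null(grid)) init <- "nndsvd"
  ini <- if (init == "greedy") {
    greedy_init(Y, K, grid, seed, nonneg_activations)
  } else {
    nndsvd_init(Y, K, seed, nonneg_activations)
  }
  A <- ini$A; X <- ini$X

  yss <- sum(Y^2)

  ## squared first-difference gradient energy of each footprint; the
  ## smoothness penalty is alpha_sm * sum_k ||a_k||^2 * ||grad x_k||^2 --
  ## weighting by the activation energy makes the penalty invariant under
  ## the (a_k / c, c * x_k) scale ambiguity, so alpha_sm acts at data scale
  grad_energy <- function(X) {
    if (alpha_sm == 0) return(numeric(K))
    vapply(seq_len(K), function(k) {
      img <- matrix(X[k, ], grid[1], grid[2])
      sum(diff(img)^2) + sum(t(diff(t(img)))^2)
    }, numeric(1L))
  }
  pen_sm <- function(A, X) {
    if (alpha_sm == 0) return(0)
    alpha_sm * sum(colSums(A^2) * grad_energy(X))
  }
  grad_sm <- function(X, wk) {
    G <- matrix(0, K, ncol(X))
    if (alpha_sm == 0) return(G)
    for (k in seq_len(K)) {
      if (wk[k] == 0) next
      img <- matrix(X[k, ], grid[1], grid[2])
      dv <- diff(img); dh <- t(diff(t(img)))
      g <- matrix(0, grid[1], grid[2])
      g[-1, ] <- g[-1, ] + dv; g[-grid[1], ] <- g[-grid[1], ] - dv
      g[, -1] <- g[, -1] + dh; g[, -grid[2]] <- g[, -grid[2]] - dh
      G[k, ] <- as.vector(2 * alpha_sm * wk[k] * g)
    }
    G
  }
  pen_sp <- function(X) {
    if (alpha_sp == 0 || K < 2L) return(0)
    nrm <- sqrt(rowSums(X^2)); nrm[nrm == 0] <- 1
    C <- tcrossprod(X / nrm)
    alpha_sp * sum(pmax(0, C[upper.tri(C)]))
  }
  grad_sp <- function(X) {
    G <- matrix(0, K, ncol(X))
    if (alpha_sp == 0 || K < 2L) return(G)
    nrm <- sqrt(rowSums(X^2)); nrm[nrm == 0] <- 1
    Xn <- X / nrm
    C <- tcrossprod(Xn)
    act <- C > 0; diag(act) <- FALSE
    for (k in seq_len(K)) {
      js <- which(act[k, ])
      if (length(js) == 0L) next
      g <- colSums(Xn[js, , drop = FALSE]) -
        sum(C[k, js]) * Xn[k, ]
      G[k, ] <- alpha_sp * g / nrm[k]
    }
    G
  }

  fit_err <- function(A, X, AtY = NULL, XXt = NULL) {
    XXt <- XXt %||% tcrossprod(X)
    AtA <- crossprod(A)
    AtY <- AtY %||% crossprod(A, Y)
    yss - 2 * sum(AtY * X) + sum(AtA * XXt)
  }
  objective <- function(A, X) fit_err(A, X) + pen_sm(A, X) + pen_sp(X)

  obj <- objective(A, X)
  log_obj <- numeric(max_iter + 1L); log_obj[1L] <- obj
  converged <- FALSE; it <- 0L

  for (it in seq_len(max_iter)) {
    ## --- A block: quadratic in A (ridge from the weighted smoothness) ---
    XXt <- tcrossprod(X)
    YXt <- Y %*% t(X)
    sk <- alpha_sm * grad_energy(X) # per-component ridge weights
    errA <- function(A) {
      yss - 2 * sum(YXt * A) + sum(crossprod(A) * XXt) +
        sum(sk * colSums(A^2))
    }
    if (!nonneg_activations) {
      A_new <- t(solve(XXt + diag(sk, K) + diag(1e-10, K), t(YXt)))
      if (errA(A_new) <= errA(A)) A <- A_new
    } else {
      LA <- 2 * max(eigen(XXt, symmetric = TRUE,
                          only.values = TRUE)$values) +
        2 * max(sk, 0) + 1e-12
      eA <- errA(A)
      for (s in seq_len(inner_iter)) {
        gA <- 2 * (A %*% XXt - YXt) + 2 * sweep(A, 2L, sk, `*`)
        step <- 1 / LA
        for (bt in 1:30) {
          A_try <- A - step * gA
          A_try[A_try < 0] <- 0
          e_try <- errA(A_try)
          if (e_try <= eA) break
          step <- step / 2
        }
        if (e_try <= eA) { A <- A_try; eA <- e_try } else break
      }
    }

    ## --- X block (reconstruction + both penalties) ---
    AtA <- crossprod(A)
    AtY <- crossprod(A, Y)
    wk <- colSums(A^2)
    fX <- function(X) {
      (yss - 2 * sum(AtY * X) + sum(AtA * tcrossprod(X))) +
        pen_sm(A, X) + pen_sp(X)
    }
    LX <- 2 * max(eigen(AtA, symmetric = TRUE,
                        only.values = TRUE)$values) +
      8 * alpha_sm * max(wk, 0) + alpha_sp * K + 1e-12
    eX <- fX(X)
    for (s in seq_len(inner_iter)) {
      gX <- 2 * (AtA %*% X - AtY) + grad_sm(X, wk) + grad_sp(X)
      step <- 1 / LX
      for (bt in 1:30) {
        X_try <- X - step * gX
        X_try[X_try < 0] <- 0
        e_try <- fX(X_try)
        if (e_try <= eX) break
        step <- step / 2
      }
      if (e_try <= eX) { X <- X_try; eX <- e_try } else break
    }

    obj_new <- objective(A, X)
    log_obj[it + 1L] <- obj_new
    if (abs(obj - obj_new) <= tol * max(obj, .Machine$double.eps)) {
      obj <- obj_new; converged <- TRUE; break
    }
    obj <- obj_new
  }
  if (!converged) {
    warning("rNMF did not converge within ", max_iter, " iterations")
  }

  ## sign/scale convention: footprints at unit maximum, scale in activation
  mx <- apply(X, 1L, max)
  pos <- mx > 0
  X[pos, ] <- X[pos, , drop = FALSE] / mx[pos]
  A[, pos] <- sweep(A[, pos, drop = FALSE], 2L, mx[pos], `*`)

  res <- sqrt(max(0, fit_err(A, X)) / yss)
  structure(list(
    spatial = X, temporal = A,
    objective = log_obj[seq_len(it + 1L)],
    converged = converged, iterations = it,
    residual = res, grid = grid, frame_map = frame_map,
    params = list(K = K, alpha_sm = alpha_sm, alpha_sp = alpha_sp,
                  nonneg_activations = nonneg_activations, seed = seed,
                  max_iter = max_iter, tol = tol)
  ), class = "rnmf")
}

## Greedy peak-picking initialization (the approach functional-imaging
## segmentation pipelines use): footprint seeds are Gaussian blobs at the
## successive peaks of a robust per-pixel activation map, each peak
## suppressed before the next pick; deterministic, seed-perturbed.
greedy_init <- function(Y, K, grid, seed, nonneg_activations,
                        blob_sigma = 1.7) {
  h <- grid[1]; w <- grid[2]
  ## robust activation map: per pixel, mean of the top 20% of frames
  ntop <- max(1L, ceiling(0.2 * nrow(Y)))
  M <- matrix(apply(Y, 2L, function(col) {
    mean(sort.int(col, decreasing = TRUE)[seq_len(ntop)])
  }), h, w)
  M[M < 0] <- 0
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  X <- matrix(0, K, h * w)
  Mw <- gauss_blur(M, 1)
  for (k in seq_len(K)) {
    p <- arrayInd(which.max(Mw), dim(Mw))
    d2 <- (yy - p[1])^2 + (xx - p[2])^2
    blob <- exp(-d2 / (2 * blob_sigma^2))
    blob[d2 > (3 * blob_sigma)^2] <- 0
    X[k, ] <- as.vector(blob)
    Mw[d2 <= (3 * blob_sigma)^2] <- 0 # suppress this peak
  }
  XXt <- tcrossprod(X)
  A <- Y %*% t(X) %*% solve(XXt + diag(1e-8 * max(XXt), K))
  if (nonneg_activations) A[A < 0] <- 0
  eps <- mean(abs(Y)) * 1e-3
  with_seed(seed, {
    X <- X + matrix(stats::runif(length(X), 0, eps), nrow(X))
    A <- A + matrix(stats::runif(length(A), 0, eps), nrow(A))
  })
  list(A = A, X = X)
}

## NNDSVD-style deterministic initialization, seed-perturbed
nndsvd_init <- function(Y, K, seed, nonneg_activations) {
  sv <- svd(Y, nu = K, nv = K)
  A <- matrix(0, nrow(Y), K); X <- matrix(0, K, ncol(Y))
  pos <- function(v) pmax(v, 0); neg <- function(v) pmax(-v, 0)
  for (k in seq_len(K)) {
    u <- sv$u[, k]; v <- sv$v[, k]; d <- sv$d[k]
    if (k == 1L) {
      A[, 1L] <- sqrt(d) * abs(u); X[1L, ] <- sqrt(d) * abs(v)
      next
    }
    up <- pos(u); un <- neg(u); vp <- pos(v); vn <- neg(v)
    mp <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    mn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (mp >= mn && mp > 0) {
      A[, k] <- sqrt(d * mp) * up / sqrt(sum(up^2))
      X[k, ] <- sqrt(d * mp) * vp / sqrt(sum(vp^2))
    } else if (mn > 0) {
      A[, k] <- sqrt(d * mn) * un / sqrt(sum(un^2))
      X[k, ] <- sqrt(d * mn) * vn / sqrt(sum(vn^2))
    }
  }
  eps <- mean(abs(Y)) * 1e-3
  with_seed(seed, {
    X <- X + matrix(stats::runif(length(X), 0, eps), nrow(X))
    jig <- matrix(stats::runif(length(A), 0, eps), nrow(A))
    A <- if (nonneg_activations) A + jig else A + jig - eps / 2
  })
  list(A = A, X = X)
}

#' @export
print.rnmf <- function(x, ...) {
  cat(sprintf("rNMF fit: %d components, %d frames x %d pixels\n",
              x$params$K, nrow(x$temporal), ncol(x$spatial)))
  cat(sprintf("  alpha_sm = %g, alpha_sp = %g, activations %s\n",
              x$params$alpha_sm, x$params$alpha_sp,
              if (x$params$nonneg_activations) "non-negative" else "signed"))
  cat(sprintf("  %s after %d iterations, relative residual %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

#' @export
summary.rnmf <- function(object, ...) {
  mc <- max_spatial_correlation(object)
  cat_print <- utils::capture.output(print(object))
  structure(list(fit = object, max_spatial_correlation = mc,
                 printed = cat_print),
            class = "summary.rnmf")
}

#' @export
print.summary.rnmf <- function(x, ...) {
  writeLines(x$printed)
  cat(sprintf("  max pairwise spatial correlation: %.3f\n",
              x$max_spatial_correlation))
  invisible(x)
}

#' @export
coef.rnmf <- function(object, ...) object$spatial

#' @export
fitted.rnmf <- function(object, ...) object$temporal %*% object$spatial

#' Plot rNMF footprints
#'
#' @param x an `rnmf` fit.
#' @param components which footprints to draw (default first 4).
#' @param ... passed to [graphics::image()].
#' @export
plot.rnmf <- function(x, components = seq_len(min(4L, x$params$K)), ...) {
  if (is.null(x$grid)) stop("fit carries no pixel grid")
  op <- graphics::par(mfrow = c(1, length(components)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (k in components) {
    graphics::image(t(matrix(x$spatial[k, ], x$grid[1], x$grid[2]))[,
                    x$grid[1]:1],
                    axes = FALSE, main = paste("component", k), ...)
  }
  invisible(x)
}

#' Maximal pairwise Pearson correlation between fitted footprints
#'
#' @param fit an `rnmf` object (or a K x P spatial matrix).
#' @return The largest off-diagonal correlation, or 0 for K < 2.
#' @export
max_spatial_correlation <- function(fit) {
  X <- if (inherits(fit, "rnmf")) fit$spatial else fit
  if (nrow(X) < 2L) return(0)
  keep <- apply(X, 1L, stats::sd) > 0
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2L) return(0)
  C <- stats::cor(t(X))
  max(C[upper.tri(C)])
}

#' Tune the sparseness weight to a target footprint correlation
#'
#' Searches a logarithmic grid over `alpha_sp`, refined by bisection, for
#' the smallest tested weight whose fit has maximal pairwise spatial
#' correlation at or below `target_corr` (the protocol uses "just below
#' 0.5").
#'
#' @inheritParams fit_rnmf
#' @param target_corr correlation ceiling in `(0, 1)` (default 0.5).
#' @param bounds `c(low, high)` search interval for `alpha_sp`.
#' @param n_grid number of logarithmic grid points.
#' @param refine_n bisection refinement steps.
#' @param ... further arguments to [fit_rnmf()].
#' @return list with `alpha_sp`, the corresponding `fit`, the
#'   `achieved_corr`, and the full `search` table (alpha, max correlation).
#' @export
tune_sparseness <- function(Y, K, alpha_sm = 0, target_corr = 0.5,
                            bounds = c(1e-2, 1e4), n_grid = 6L,
                            refine_n = 3L, seed = 1L, ...) {
  if (target_corr <= 0 || target_corr >= 1) stop("target_corr must be in (0,1)")
  try_alpha <- function(a) {
    fit <- fit_rnmf(Y, K, alpha_sm = alpha_sm, alpha_sp = a, seed = seed, ...)
    list(alpha = a, fit = fit, corr = max_spatial_correlation(fit))
  }
  search <- list()
  best <- NULL
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  prev_alpha <- NULL
  for (a in grid) {
    r <- try_alpha(a)
    search[[length(search) + 1L]] <- r
    if (r$corr <= target_corr) { best <- r; break }
    prev_alpha <- a
  }
  if (is.null(best)) {
    tab <- do.call(rbind, lapply(search, function(r)
      data.frame(alpha_sp = r$alpha, max_corr = r$corr)))
    stop("target correlation ", target_corr,
         " not achievable within the search bounds; achieved:\n",
         paste(utils::capture.output(print(tab)), collapse = "\n"))
  }
  if (!is.null(prev_alpha)) {
    lo <- prev_alpha; hi <- best$alpha
    for (i in seq_len(refine_n)) {
      mid <- exp((log(lo) + log(hi)) / 2)
      r <- try_alpha(mid)
      search[[length(search) + 1L]] <- r
      if (r$corr <= target_corr) { best <- r; hi <- mid } else lo <- mid
    }
  }
  tab <- do.call(rbind, lapply(search, function(r)
    data.frame(alpha_sp = r$alpha, max_corr = r$corr)))
  list(alpha_sp = best$alpha, fit = best$fit, achieved_corr = best$corr,
       search = tab[order(tab$alpha_sp), ])
}

#' Protocol parameter bundles for the two imaging modalities
#'
#' @return list with the `ios` bundle (150 components, smoothness 2) and
#'   the `sph` bundle (20 components, smoothness 5).
#' @export
default_configs <- function() {
  list(ios = list(K = 150L, alpha_sm = 2, target_corr = 0.5),
       sph = list(K = 20L, alpha_sm = 5, target_corr = 0.5))
}

#' Match fitted footprints to planted ground truth
#'
#' Greedy one-to-one assignment by maximal Pearson correlation between
#' fitted footprints and ground-truth footprint images.
#'
#' @param fit an `rnmf` object or K x P spatial matrix.
#' @param footprints list of ground-truth footprint matrices.
#' @return data.frame with `truth` (index), `component` (matched fitted
#'   component) and `correlation`.
#' @export
match_footprints <- function(fit, footprints) {
  X <- if (inherits(fit, "rnmf")) fit$spatial else fit
  Tm <- vapply(footprints, as.vector, numeric(ncol(X)))
  C <- suppressWarnings(stats::cor(t(X), Tm)) # K x n_truth
  C[is.na(C)] <- -1
  n <- length(footprints)
  out <- data.frame(truth = seq_len(n), component = NA_integer_,
                    correlation = NA_real_)
  Cw <- C
  for (i in seq_len(min(n, nrow(X)))) {
    ij <- which(Cw == max(Cw), arr.ind = TRUE)[1L, ]
    out$component[ij[2]] <- ij[1]
    out$correlation[ij[2]] <- C[ij[1], ij[2]]
    Cw[ij[1], ] <- -Inf; Cw[, ij[2]] <- -Inf
  }
  out
}
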