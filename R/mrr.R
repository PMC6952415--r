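## Molecular-receptive-range activation models -------------------------------
##
## Fits activation models a_hat = f(x) in a descriptor space: multivariate
## support vector regression with Gaussian kernel, and univariate linear,
## isotonic and unimodal-isotonic regressions. Goodness of fit is the
## coefficient of determination R^2 = 1 - SSE/SST; predictive power q^2 is
## the out-of-bag analogue pooled over bootstrap resamples.

#' Fit an activation model
#'
#' SVR uses a radial-basis kernel with pinned defaults (regularization
#' cost 1, epsilon 0.1, kernel scale `1 / (n_features * var(X))`), so the
#' fit is reproducible across library versions. Isotonic fits are
#' least-squares monotone fits (pool-adjacent-violators); the
#' unimodal-isotonic fit searches all candidate modes, fitting increasing
#' before and decreasing after the mode, and keeps the least-SSE mode
#' (exhaustive, hence exact).
#'
#' @param X descriptor matrix or [descriptor_table()] (univariate kinds
#'   require exactly one column).
#' @param y numeric activations, one per row of `X`.
#' @param kind one of `"svr"`, `"linear"`, `"isotonic"`,
#'   `"unimodal_isotonic"`.
#' @return An object of class `activation_model` with a [predict] method.
#' @export
fit_activation_model <- function(X, y,
                                 kind = c("svr", "linear", "isotonic",
                                          "unimodal_isotonic")) {
  kind <- match.arg(kind)
  space_id <- if (inherits(X, "descriptor_table")) "descriptor_table" else NULL
  if (inherits(X, "descriptor_table")) X <- X$values
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match y")
  if (nrow(X) < 3L) stop("too few samples to fit an activation model")
  if (kind != "svr" && ncol(X) != 1L) {
    stop(kind, " regression is univariate; X must have exactly 1 column")
  }
  fitobj <- switch(kind,
    svr = {
      v <- stats::var(as.vector(X))
      gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
      ## responses entirely inside the epsilon tube leave no support
      ## vectors; such a degenerate model predicts the training mean
      tryCatch(
        e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   cost = 1, epsilon = 0.1, gamma = gamma, scale = FALSE),
        error = function(e) {
          if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) {
            NULL
          } else stop(e)
        })
    },
    linear = {
      d <- data.frame(x = X[, 1L], y = y)
      stats::lm(y ~ x, data = d)
    },
    isotonic = iso_fit(X[, 1L], y, decreasing = FALSE),
    unimodal_isotonic = unimodal_iso_fit(X[, 1L], y)
  )
  structure(list(kind = kind, fit = fitobj, columns = colnames(X),
                 space_id = space_id, train_ids = rownames(X),
                 train_mean = mean(y)),
            class = "activation_model")
}

#' @export
print.activation_model <- function(x, ...) {
  cat(sprintf("Activation model (%s) on %d descriptor column(s)\n",
              x$kind, length(x$columns)))
  invisible(x)
}

#' Predict activations for new molecules
#'
#' @param object an `activation_model`.
#' @param newdata matrix or `descriptor_table` in the model's descriptor
#'   space (same columns).
#' @param ... unused.
#' @return Numeric vector of predicted activations.
#' @export
predict.activation_model <- function(object, newdata, ...) {
  if (inherits(newdata, "descriptor_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (!is.null(object$columns)) {
    if (!is.null(colnames(newdata))) {
      if (!all(object$columns %in% colnames(newdata))) {
        stop("newdata does not cover the model's descriptor space")
      }
      newdata <- newdata[, object$columns, drop = FALSE]
    } else if (ncol(newdata) != length(object$columns)) {
      stop("newdata does not match the model's descriptor space")
    }
  }
  switch(object$kind,
    svr = {
      if (is.null(object$fit) || (object$fit$tot.nSV %||% 0L) == 0L) {
        rep(object$train_mean, nrow(newdata))
      } else {
        as.numeric(stats::predict(object$fit, newdata))
      }
    },
    linear = as.numeric(stats::predict(object$fit,
                                       data.frame(x = newdata[, 1L]))),
    isotonic = ,
    unimodal_isotonic = iso_predict(object$fit, newdata[, 1L])
  )
}

## -- isotonic machinery ------------------------------------------------------

## least-squares monotone fit via stats::isoreg; x need not be sorted
iso_fit <- function(x, y, decreasing = FALSE) {
  ord <- order(x)
  ys <- y[ord]
  yf <- if (decreasing) -stats::isoreg(-ys)$yf else stats::isoreg(ys)$yf
  list(x = x[ord], fitted = yf, sse = sum((ys - yf)^2), mode = NA_integer_)
}

## exact unimodal LS fit: exhaustive split m = 0..n into an increasing
## prefix and a decreasing suffix (any such concatenation is unimodal,
## and the optimum is among them); smallest-SSE m, ties to the smallest m
unimodal_iso_fit <- function(x, y) {
  ord <- order(x)
  ys <- y[ord]
  n <- length(ys)
  best <- NULL
  for (m in 0:n) {
    inc <- if (m > 0) stats::isoreg(ys[seq_len(m)])$yf else numeric(0)
    dec <- if (m < n) -stats::isoreg(-ys[seq(m + 1L, n)])$yf else numeric(0)
    fit <- c(inc, dec)
    sse <- sum((ys - fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(x = x[ord], fitted = fit, sse = sse, mode = m)
    }
  }
  best
}

## stepwise-linear interpolation of a fitted monotone/unimodal curve
iso_predict <- function(fit, xout) {
  ux <- fit$x; uy <- fit$fitted
  if (anyDuplicated(ux)) {
    agg <- tapply(uy, ux, mean)
    ux <- as.numeric(names(agg)); uy <- as.numeric(agg)
  }
  if (length(ux) == 1L) return(rep(uy, length(xout)))
  stats::approx(ux, uy, xout = xout, rule = 2)$y
}

## -- scoring -----------------------------------------------------------------

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((a - a_hat)^2) / sum((a - <a>)^2)` over observations.
#'
#' @param observed,fitted numeric vectors of equal length (at least 2);
#'   `observed` must not be constant.
#' @return Real number `<= 1`.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) < 2L || length(observed) != length(fitted)) {
    stop("need >= 2 paired observations")
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("R^2 undefined for constant observations")
  1 - sum((observed - fitted)^2) / sst
}

#' Bootstrap predictive power q^2
#'
#' Fits the model on `B` bootstrap resamples (odorants drawn with
#' replacement) and predicts the odorants left out of each resample. The
#' predictive power pools squared out-of-bag errors and squared deviations
#' from the single global mean over all (resample, held-out odorant)
#' pairs: `q^2 = 1 - sum sum (a - a_hat)^2 / sum sum (a - <a>)^2`.
#' Resamples with no out-of-bag odorant are redrawn (counted in the
#' report). Deterministic given the seed.
#'
#' @param factory function `(X, y) -> model` where the model supports
#'   `predict(model, X)`; see [model_factory()].
#' @param X descriptor matrix or `descriptor_table`.
#' @param y activations.
#' @param B number of bootstrap resamples (default 50).
#' @param seed integer seed.
#' @return Object of class `fit_report`: `q_squared`, `r_squared` (full
#'   fit), `B`, `seed`, `oob` (per-pair predictions), `n_redrawn`.
#' @export
q_squared_bootstrap <- function(factory, X, y, B = 50L, seed = 1L) {
  if (B < 2L) stop("need at least 2 bootstrap resamples")
  if (inherits(X, "descriptor_table")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 odorants")
  samples <- with_seed(seed, {
    redrawn <- 0L
    out <- vector("list", B)
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(setdiff(seq_len(n), idx)) > 0L) break
        redrawn <- redrawn + 1L
      }
      out[[b]] <- idx
    }
    attr(out, "redrawn") <- redrawn
    out
  })
  gmean <- mean(y)
  num <- 0; den <- 0
  oob <- vector("list", B)
  for (b in seq_len(B)) {
    inb <- samples[[b]]
    out_idx <- setdiff(seq_len(n), inb)
    model <- factory(X[inb, , drop = FALSE], y[inb])
    pred <- stats::predict(model, X[out_idx, , drop = FALSE])
    num <- num + sum((y[out_idx] - pred)^2)
    den <- den + sum((y[out_idx] - gmean)^2)
    oob[[b]] <- data.frame(bootstrap = b, index = out_idx,
                           observed = y[out_idx], predicted = pred)
  }
  full <- factory(X, y)
  structure(list(
    q_squared = 1 - num / den,
    r_squared = r_squared(y, stats::predict(full, X)),
    B = B, seed = seed, oob = do.call(rbind, oob),
    n_redrawn = attr(samples, "redrawn")
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Fit report: r^2 = %.3f, q^2 = %.3f (B = %d bootstraps, seed %d)\n",
              x$r_squared, x$q_squared, x$B, x$seed))
  invisible(x)
}

#' Model factory for [q_squared_bootstrap()]
#'
#' @param kind model kind, see [fit_activation_model()].
#' @return Function `(X, y)` returning a fitted `activation_model`.
#' @export
model_factory <- function(kind = "svr") {
  force(kind)
  function(X, y) fit_activation_model(X, y, kind = kind)
}

#' Benchmark descriptor spaces by bootstrap q^2
#'
#' All spaces share the identical bootstrap resample sequence (derived
#' from `seed`), so comparisons are paired.
#'
#' @param spaces named list of descriptor tables / matrices over the same
#'   odorant set.
#' @param y activations.
#' @param B bootstrap resamples per space.
#' @param seed master seed.
#' @param factory model factory (default SVR).
#' @return data.frame ranked by decreasing `q_squared`.
#' @export
benchmark_spaces <- function(spaces, y, B = 50L, seed = 1L,
                             factory = model_factory("svr")) {
  if (length(spaces) == 0L) stop("empty space list")
  nm <- names(spaces) %||% sprintf("space_%d", seq_along(spaces))
  q2 <- vapply(spaces, function(Xs) {
    q_squared_bootstrap(factory, Xs, y, B = B, seed = seed)$q_squared
  }, numeric(1L))
  out <- data.frame(space = nm, q_squared = unname(q2),
                    stringsAsFactors = FALSE)
  out[order(-out$q_squared), , drop = FALSE]
}

#' Metric multidimensional scaling of odour-space distances
#'
#' Classical (Torgerson) scaling of a symmetric distance matrix; exact
#' (zero stress) whenever the distances are Euclidean-embeddable in
#' `dims` dimensions, and fully deterministic — the `seed` argument is
#' accepted for interface stability but unused.
#'
#' @param d square symmetric non-negative matrix with zero diagonal.
#' @param dims embedding dimension (default 2).
#' @param seed ignored (deterministic method).
#' @return n x dims coordinate matrix.
#' @export
mds_embed <- function(d, dims = 2L, seed = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  stats::cmdscale(stats::as.dist(d), k = dims)
}

#' Rank candidate molecules by predicted activation
#'
#' @param model an `activation_model`.
#' @param candidates `descriptor_table` (or matrix with rownames) in the
#'   model's descriptor space.
#' @param top_n number of top candidates to return (default all).
#' @return data.frame `molecule`, `predicted`, sorted by decreasing
#'   prediction; ties broken by molecule id.
#' @export
virtual_screen <- function(model, candidates, top_n = Inf) {
  ids <- if (inherits(candidates, "descriptor_table")) {
    rownames(candidates$values)
  } else rownames(as.matrix(candidates))
  pred <- predict(model, candidates)
  out <- data.frame(molecule = ids %||% seq_along(pred), predicted = pred,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$predicted, out$molecule), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
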