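#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded package
#' functions do not disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream of child seeds from one master seed
#'
#' Used wherever a procedure needs several independent reproducible random
#' streams (e.g. paired bootstrap sequences across descriptor spaces).
#'
#' @param seed master seed.
#' @param n number of child seeds.
#' @return Integer vector of length `n`, all below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## 1-D Gaussian kernel truncated at 4 sigma, normalized to sum 1
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

## reflect-pad a vector index: 1..n mirrored without repeating the edge pixel
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * (n - 1L))
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

#' Separable Gaussian blur of a 2-D image with reflective borders
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Blurred matrix of the same shape.
#' @keywords internal
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  blur1 <- function(m) { # along rows (dimension 1)
    n <- nrow(m)
    idx <- reflect_index(seq(1L - r, n + r), n)
    pad <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[seq(j, j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(img))))
}

## block mean over non-overlapping wh x ww windows; errors on non-divisible
block_mean <- function(img, wh, ww) {
  h <- nrow(img); w <- ncol(img)
  if (h %% wh != 0L || w %% ww != 0L) {
    stop(sprintf("image shape %dx%d not divisible by window %dx%d (no silent cropping)",
                 h, w, wh, ww))
  }
  dim(img) <- c(wh, h %/% wh, w) # fold rows
  tmp <- colMeans(img)           # (h/wh) x w
  tmp <- t(tmp)
  dim(tmp) <- c(ww, w %/% ww, h %/% wh)
  t(colMeans(tmp))
}

## Pearson correlation that tolerates zero-variance input by returning NA
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
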