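## Physico-chemical descriptor spaces ----------------------------------------
##
## A descriptor table is a molecules x descriptors matrix whose columns
## carry block labels (conventional descriptor blocks, literature subsets,
## or EVA_sigma vibrational descriptors) plus a normalization state. EVA
## descriptors are built by Gaussian-smoothing a molecule's vibrational
## line spectrum and sampling the result on a regular grid over
## [0, 4000] cm^-1.

#' Construct a descriptor table
#'
#' @param values numeric matrix, rows = molecules (rownames required),
#'   columns = named descriptors.
#' @param blocks character vector of block labels, one per column.
#' @param normalized normalization state (`FALSE` = raw).
#' @param reference_id identifier of the normalization reference set.
#' @return An object of class `descriptor_table`.
#' @export
descriptor_table <- function(values, blocks, normalized = FALSE,
                             reference_id = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("molecule ids (rownames) are required")
  if (anyDuplicated(rownames(values))) stop("duplicate molecule ids")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("d%04d", seq_len(ncol(values)))
  }
  if (length(blocks) == 1L) blocks <- rep(blocks, ncol(values))
  if (length(blocks) != ncol(values)) {
    stop("need one block label per descriptor column")
  }
  structure(list(values = values, blocks = as.character(blocks),
                 normalized = normalized, reference_id = reference_id),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  bl <- table(x$blocks)
  cat(sprintf("Descriptor table: %d molecules x %d descriptors (%s)\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$normalized)) "z-scored" else "raw"))
  cat("  blocks:", paste(sprintf("%s[%d]", names(bl), bl), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' @export
as.matrix.descriptor_table <- function(x, ...) x$values

#' EVA vibrational descriptor of a line spectrum
#'
#' Places a Gaussian kernel of unit height and standard deviation `sigma`
#' on each vibrational frequency, `S(q) = sum_f exp(-(q - f)^2 /
#' (2 sigma^2))`, and samples the smoothed spectrum at
#' `q = 0, sigma, 2 sigma, ..., 4000 - sigma`, i.e. an inclusive-start,
#' exclusive-end grid of `4000 / sigma` values (800 descriptors at
#' sigma = 5, so that together with a 1600-column conventional table the
#' combined space has 2400 columns).
#'
#' @param freqs numeric vector of vibrational frequencies in cm^-1, all in
#'   `[0, 4000]`; an empty spectrum yields the all-zero vector.
#' @param sigma kernel standard deviation in cm^-1 (protocol values 1, 5,
#'   10, 20, 50, 100).
#' @param q_max upper end of the spectral range (default 4000).
#' @return Named numeric vector of length `q_max / sigma`.
#' @export
eva <- function(freqs, sigma = 5, q_max = 4000) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length(freqs) && (any(freqs < 0) || any(freqs > q_max))) {
    stop("vibrational frequencies must lie in [0, ", q_max, "]")
  }
  q <- seq(0, q_max - sigma, by = sigma)
  s <- numeric(length(q))
  for (f in freqs) s <- s + exp(-(q - f)^2 / (2 * sigma^2))
  names(s) <- sprintf("EVA%g_q%g", sigma, q)
  s
}

#' EVA descriptor table for a set of line spectra
#'
#' @param spectra named list of frequency vectors (molecule id -> modes).
#' @param sigma kernel standard deviation in cm^-1.
#' @param q_max upper end of the spectral range.
#' @return A [descriptor_table()] with block label `EVA_<sigma>`.
#' @export
eva_table <- function(spectra, sigma = 5, q_max = 4000) {
  vals <- t(vapply(spectra, eva, eva(numeric(0), sigma, q_max),
                   sigma = sigma, q_max = q_max))
  descriptor_table(vals, sprintf("EVA_%g", sigma))
}

#' Combine descriptor tables column-wise
#'
#' All tables must cover the identical molecule set; columns appear in
#' argument order, block labels are preserved, and duplicate column names
#' are rejected.
#'
#' @param tables list of `descriptor_table` objects.
#' @return The combined `descriptor_table`.
#' @export
combine_descriptors <- function(tables) {
  if (length(tables) == 0L) stop("no tables to combine")
  ids <- rownames(tables[[1]]$values)
  for (t in tables[-1]) {
    if (!setequal(rownames(t$values), ids)) {
      stop("molecule sets differ between tables")
    }
  }
  mats <- lapply(tables, function(t) t$values[ids, , drop = FALSE])
  values <- do.call(cbind, mats)
  if (anyDuplicated(colnames(values))) {
    stop("duplicate column names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  norm <- unique(vapply(tables, function(t) isTRUE(t$normalized), logical(1)))
  descriptor_table(values, unlist(lapply(tables, `[[`, "blocks")),
                   normalized = length(norm) == 1L && norm)
}

#' Z-normalize descriptors against a reference library
#'
#' Each column is centred and scaled by the mean and standard deviation of
#' the same column in the reference table (the stand-in for the in-house
#' odour library). Columns with zero variance in the reference are
#' dropped with a warning.
#'
#' @param table `descriptor_table` to normalize.
#' @param reference `descriptor_table` covering all of `table`'s columns;
#'   defaults to `table` itself.
#' @param reference_id label recorded as the normalization reference.
#' @return The z-scored `descriptor_table`.
#' @export
z_normalize <- function(table, reference = table, reference_id = "self") {
  miss <- setdiff(colnames(table$values), colnames(reference$values))
  if (length(miss)) {
    stop("columns missing from the reference: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  ref <- reference$values[, colnames(table$values), drop = FALSE]
  mu <- colMeans(ref)
  sd <- apply(ref, 2L, stats::sd)
  drop <- sd == 0 | !is.finite(sd)
  if (any(drop)) {
    warning(sum(drop), " zero-variance reference column(s) dropped: ",
            paste(utils::head(colnames(ref)[drop], 5), collapse = ", "))
  }
  keep <- which(!drop)
  vals <- sweep(sweep(table$values[, keep, drop = FALSE], 2L, mu[keep]),
                2L, sd[keep], `/`)
  descriptor_table(vals, table$blocks[keep], normalized = TRUE,
                   reference_id = reference_id)
}

#' Restrict a descriptor table to named blocks or columns
#'
#' @param table `descriptor_table`.
#' @param block block label(s) to keep, or `NULL`.
#' @param columns explicit column names to keep, or `NULL`.
#' @return The restricted `descriptor_table`.
#' @export
select_block <- function(table, block = NULL, columns = NULL) {
  if (is.null(block) == is.null(columns)) {
    stop("give exactly one of `block` or `columns`")
  }
  keep <- if (!is.null(block)) {
    if (!all(block %in% table$blocks)) {
      stop("unknown block(s): ",
           paste(setdiff(block, table$blocks), collapse = ", "))
    }
    which(table$blocks %in% block)
  } else {
    if (!all(columns %in% colnames(table$values))) {
      stop("unknown column(s): ",
           paste(setdiff(columns, colnames(table$values)), collapse = ", "))
    }
    match(columns, colnames(table$values))
  }
  descriptor_table(table$values[, keep, drop = FALSE], table$blocks[keep],
                   normalized = table$normalized,
                   reference_id = table$reference_id)
}
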