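## Tunotopy and chemotopy ----------------------------------------------------
##
## Distances between glomeruli (correlation distance of response spectra,
## cosine distance of activation barycentres), UPGMA clustering with the
## cross-animal cluster constraint, and the spatial statistics: normalized
## Mann-Whitney U proximity tests with shuffle controls, the near/far
## chemotopy sweep, and the supercluster centre-of-mass axis analysis.

#' Correlation distance between response spectra
#'
#' `d_r = 1 - r(s_j, s_k)` (Pearson): identical or perfectly correlated
#' spectra have distance 0, exactly anticorrelated spectra distance 2.
#'
#' @param s_j,s_k numeric spectra of equal length (at least 3), neither
#'   constant.
#' @return Real in `[0, 2]`.
#' @export
correlation_distance <- function(s_j, s_k) {
  if (length(s_j) != length(s_k) || length(s_j) < 3L) {
    stop("spectra must have equal length >= 3")
  }
  if (stats::sd(s_j) == 0 || stats::sd(s_k) == 0) {
    stop("correlation distance undefined for constant spectra")
  }
  1 - stats::cor(s_j, s_k)
}

#' Pairwise correlation-distance matrix
#'
#' @param spectra glomeruli x odorants matrix of response spectra.
#' @return Symmetric matrix of `1 - r` with zero diagonal, metric tag in
#'   the `metric` attribute.
#' @export
correlation_distance_matrix <- function(spectra) {
  sds <- apply(spectra, 1L, stats::sd)
  if (any(sds == 0)) stop("constant spectra: ",
                          paste(which(sds == 0), collapse = ", "))
  d <- 1 - stats::cor(t(spectra))
  diag(d) <- 0
  attr(d, "metric") <- "correlation"
  d
}

#' Barycentre of activation in descriptor space
#'
#' Activation-weighted mean descriptor vector of a glomerulus's ligands,
#' relative to the odorant-panel mean: `x_k = sum_o a_o x_o / sum_o a_o -
#' <x>_o`. A glomerulus equally active on all odorants sits at the origin.
#'
#' @param a_norm non-negative (unit-norm) response spectrum over the panel.
#' @param X normalized descriptor matrix or `descriptor_table`, one row
#'   per panel odorant, in spectrum order.
#' @return Numeric descriptor-space vector.
#' @export
barycentre <- function(a_norm, X) {
  if (inherits(X, "descriptor_table")) X <- X$values
  X <- as.matrix(X)
  if (length(a_norm) != nrow(X)) stop("spectrum does not cover the panel")
  if (any(a_norm < 0)) stop("spectrum must be non-negative")
  s <- sum(a_norm)
  if (s == 0) stop("barycentre undefined for an all-zero spectrum")
  as.vector(crossprod(X, a_norm) / s) - colMeans(X)
}

#' Cosine distance between descriptor-space positions
#'
#' `d_cos = 1 - (x_j . x_k) / (||x_j|| ||x_k||)`.
#'
#' @param x_j,x_k non-zero numeric vectors of equal length.
#' @return Real in `[0, 2]`.
#' @export
cosine_distance <- function(x_j, x_k) {
  nj <- sqrt(sum(x_j^2)); nk <- sqrt(sum(x_k^2))
  if (nj == 0 || nk == 0) stop("cosine distance undefined for a zero vector")
  1 - sum(x_j * x_k) / (nj * nk)
}

#' Pairwise cosine-distance matrix of barycentres
#'
#' @param B glomeruli x descriptors matrix of barycentres (rows non-zero).
#' @return Symmetric matrix with zero diagonal, `metric` attribute
#'   `"cosine"`.
#' @export
cosine_distance_matrix <- function(B) {
  nrm <- sqrt(rowSums(B^2))
  if (any(nrm == 0)) stop("zero barycentre row(s): ",
                          paste(which(nrm == 0), collapse = ", "))
  d <- 1 - tcrossprod(B / nrm)
  d[d < 0] <- 0
  diag(d) <- 0
  attr(d, "metric") <- "cosine"
  d
}

#' UPGMA (average linkage) hierarchical clustering
#'
#' @param d symmetric distance matrix (or `dist`) over glomeruli.
#' @return Object of class `cluster_tree`: the underlying `hclust` merge
#'   structure (`merge`, `height`, `labels`) with non-decreasing merge
#'   heights.
#' @export
upgma <- function(d) {
  dm <- if (inherits(d, "dist")) d else stats::as.dist(as.matrix(d))
  if (attr(dm, "Size") < 2L) stop("need at least 2 leaves")
  hc <- stats::hclust(dm, method = "average")
  class(hc) <- c("cluster_tree", "hclust")
  hc
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree over %d glomeruli; merge heights %.3g .. %.3g\n",
              length(x$order), min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a cluster tree at a height threshold
#'
#' @param tree a [upgma()] result.
#' @param height cut height; merges at or below it form flat clusters.
#' @return Integer cluster assignment per leaf.
#' @export
cut_tree <- function(tree, height) {
  stats::cutree(structure(unclass(tree), class = "hclust"), h = height)
}

#' Export a cluster tree as a Newick string
#'
#' @param tree a [upgma()] result.
#' @param file optional path; when given the tree is written there.
#' @return Newick string (invisibly when writing to file).
#' @export
tree_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(structure(unclass(tree), class = "hclust"))
  if (is.null(file)) ape::write.tree(phy) else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' Keep clusters spanning enough animals
#'
#' @param assignment integer cluster id per glomerulus.
#' @param animal_ids animal id per glomerulus.
#' @param min_animals minimum number of distinct animals (default 3).
#' @return Assignment with glomeruli of discarded clusters set to `NA`.
#' @export
valid_clusters <- function(assignment, animal_ids, min_animals = 3L) {
  keep <- vapply(split(animal_ids, assignment),
                 function(a) length(unique(a)) >= min_animals, logical(1L))
  ok <- names(keep)[keep]
  out <- assignment
  out[!as.character(assignment) %in% ok] <- NA
  out
}

#' Cluster prototype and member correlations
#'
#' The prototype is the member-wise mean of unit-norm member spectra;
#' `r_centre` is the Pearson correlation of every glomerulus (member or
#' not) to the prototype.
#'
#' @param spectra glomeruli x odorants matrix (all glomeruli).
#' @param members indices of the cluster members (at least 2).
#' @return list with `prototype` (unit-norm) and `r_centre` (per
#'   glomerulus).
#' @export
cluster_prototype <- function(spectra, members) {
  if (length(members) < 1L) stop("empty cluster")
  if (length(members) < 2L) {
    proto <- unit_norm(spectra[members, ])
  } else {
    un <- t(apply(spectra[members, , drop = FALSE], 1L, unit_norm))
    proto <- unit_norm(colMeans(un))
  }
  r <- apply(spectra, 1L, function(s) safe_cor(s, proto))
  list(prototype = proto, r_centre = r)
}

#' Flag clusters similar to a reference cluster
#'
#' @param prototypes named list of cluster prototype spectra.
#' @param reference name (or index) of the reference cluster.
#' @param threshold correlation threshold (default 0.2).
#' @return data.frame per cluster with `r_reference` and `flagged`.
#' @export
reference_similarity <- function(prototypes, reference, threshold = 0.2) {
  if (is.character(reference) && !reference %in% names(prototypes)) {
    stop("reference cluster '", reference, "' missing")
  }
  ref <- prototypes[[reference]]
  r <- vapply(prototypes, function(p) safe_cor(p, ref), numeric(1L))
  data.frame(cluster = names(prototypes) %||% seq_along(prototypes),
             r_reference = unname(r), flagged = unname(r) > threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

## normalized Mann-Whitney U: fraction of (intra, extra) pairs in which the
## intra distance is LARGER (ties half-weighted); < 0.5 means the intra
## group is closer
normalized_u <- function(intra, extra) {
  gr <- sum(vapply(intra, function(x) sum(x > extra), numeric(1L)))
  ti <- sum(vapply(intra, function(x) sum(x == extra), numeric(1L)))
  (gr + 0.5 * ti) / (length(intra) * length(extra))
}

#' Patch-proximity test with shuffle control
#'
#' Compares the spatial distances (to the nearest reference glomerulus)
#' of patch members against non-members. The statistic is the normalized
#' Mann-Whitney U — the probability that a randomly drawn member is
#' *farther* than a randomly drawn non-member, ties half-weighted — so
#' values below 0.5 mean patch members are closer. The p-value comes from
#' the two-sided rank-sum test; the shuffle null permutes distances over
#' glomeruli and reports the mean/sd of the shuffled normalized U plus an
#' empirical p-value.
#'
#' @param distances numeric spatial distance per glomerulus (µm).
#' @param member logical patch membership per glomerulus; both groups must
#'   be non-empty.
#' @param n_shuffles shuffle-control repetitions (default 10000; below 100
#'   a warning is issued).
#' @param seed integer seed for the shuffles.
#' @return Object of class `proximity_test`: `u_norm`, `p_value`,
#'   `n_intra`, `n_extra`, `shuffle_mean`, `shuffle_sd`, `p_shuffle`,
#'   `n_shuffles`.
#' @export
patch_proximity_test <- function(distances, member, n_shuffles = 10000L,
                                 seed = 1L) {
  member <- as.logical(member)
  intra <- distances[member]; extra <- distances[!member]
  if (length(intra) == 0L || length(extra) == 0L) {
    stop("both patch and non-patch groups must be non-empty")
  }
  if (n_shuffles < 100L) warning("fewer than 100 shuffles: weak control")
  u <- normalized_u(intra, extra)
  p <- suppressWarnings(stats::wilcox.test(intra, extra)$p.value)
  sh <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    d <- sample(distances)
    normalized_u(d[member], d[!member])
  }, numeric(1L)))
  p_sh <- (1 + sum(abs(sh - 0.5) >= abs(u - 0.5))) / (n_shuffles + 1)
  structure(list(u_norm = u, p_value = p,
                 n_intra = length(intra), n_extra = length(extra),
                 shuffle_mean = mean(sh), shuffle_sd = stats::sd(sh),
                 p_shuffle = p_sh, n_shuffles = n_shuffles),
            class = "proximity_test")
}

#' @export
print.proximity_test <- function(x, ...) {
  cat(sprintf("Normalized U = %.3f (n = %d vs %d), rank-sum p = %.3g\n",
              x$u_norm, x$n_intra, x$n_extra, x$p_value))
  cat(sprintf("  shuffle null (%d): mean %.3f, sd %.3f, empirical p = %.3g\n",
              x$n_shuffles, x$shuffle_mean, x$shuffle_sd, x$p_shuffle))
  invisible(x)
}

#' Near/far chemotopy sweep over spatial thresholds
#'
#' At each spatial threshold, glomeruli are split into "near" and "far"
#' groups (distance to the reference at or below / above the threshold)
#' and their chemical distances to the reference are compared with a
#' one-sided rank-sum test for the near group being chemically more
#' similar; `u_norm < 0.5` means near glomeruli are chemically closer. A
#' shuffle control permutes the pairing of chemical and spatial
#' distances. Thresholds yielding an empty group are marked undefined.
#'
#' @param spatial_dist spatial distance to the reference per glomerulus.
#' @param chemical_dist chemical (cosine) distance to the reference per
#'   glomerulus.
#' @param thresholds spatial thresholds (µm).
#' @param n_shuffles shuffle repetitions per threshold (0 to skip).
#' @param seed integer seed.
#' @return data.frame per threshold: `threshold`, `n_near`, `n_far`,
#'   `u_norm`, `p_value`, `shuffle_mean`, `defined`.
#' @export
nearfar_chemotopy_sweep <- function(spatial_dist, chemical_dist, thresholds,
                                    n_shuffles = 1000L, seed = 1L) {
  seeds <- derive_seeds(seed, length(thresholds))
  rows <- lapply(seq_along(thresholds), function(i) {
    th <- thresholds[i]
    near <- spatial_dist <= th
    if (sum(near) == 0L || sum(!near) == 0L) {
      return(data.frame(threshold = th, n_near = sum(near),
                        n_far = sum(!near), u_norm = NA_real_,
                        p_value = NA_real_, shuffle_mean = NA_real_,
                        defined = FALSE))
    }
    u <- normalized_u(chemical_dist[near], chemical_dist[!near])
    p <- suppressWarnings(stats::wilcox.test(chemical_dist[near],
                                             chemical_dist[!near],
                                             alternative = "less")$p.value)
    shm <- if (n_shuffles > 0L) {
      mean(with_seed(seeds[i], vapply(seq_len(n_shuffles), function(j) {
        cd <- sample(chemical_dist)
        normalized_u(cd[near], cd[!near])
      }, numeric(1L))))
    } else NA_real_
    data.frame(threshold = th, n_near = sum(near), n_far = sum(!near),
               u_norm = u, p_value = p, shuffle_mean = shm, defined = TRUE)
  })
  do.call(rbind, rows)
}

#' Supercluster centre-of-mass axis per animal
#'
#' For each animal, computes the vector between the centres of mass of
#' the two supercluster label groups, its angle relative to a configured
#' anatomical reference axis, the centre distance, and the percentile of
#' that distance under shuffling of the labels within the animal.
#' Animals missing one of the labels are skipped with a message.
#'
#' @param positions n x 2 matrix of glomerulus positions (µm).
#' @param labels supercluster label per glomerulus (`NA` = unlabelled);
#'   exactly the two values in `pair` are used.
#' @param animal_ids animal id per glomerulus.
#' @param pair the two supercluster labels `c(a, b)`; the axis points from
#'   the centre of `a` to the centre of `b`.
#' @param reference_axis unit vector of the anatomical reference direction
#'   (default `c(1, 0)`; acquisition-dependent).
#' @param n_shuffles label shuffles per animal (default 1000).
#' @param seed integer seed.
#' @return data.frame per analysed animal: `animal`, `angle_deg` (signed,
#'   in `(-180, 180]`), `centre_distance`, `shuffle_percentile` (fraction
#'   of shuffles with smaller centre distance).
#' @export
supercluster_axis <- function(positions, labels, animal_ids,
                              pair = sort(unique(stats::na.omit(labels)))[1:2],
                              reference_axis = c(1, 0),
                              n_shuffles = 1000L, seed = 1L) {
  reference_axis <- reference_axis / sqrt(sum(reference_axis^2))
  animals <- unique(animal_ids)
  seeds <- derive_seeds(seed, length(animals))
  rows <- list()
  for (i in seq_along(animals)) {
    a <- animals[i]
    in_a <- animal_ids == a
    la <- labels[in_a]; po <- positions[in_a, , drop = FALSE]
    g1 <- which(!is.na(la) & la == pair[1])
    g2 <- which(!is.na(la) & la == pair[2])
    if (length(g1) == 0L || length(g2) == 0L) {
      message("animal ", a, ": missing supercluster label, skipped")
      next
    }
    c1 <- colMeans(po[g1, , drop = FALSE])
    c2 <- colMeans(po[g2, , drop = FALSE])
    v <- c2 - c1
    dist_obs <- sqrt(sum(v^2))
    ## signed angle between v and the reference axis
    ang <- atan2(v[2], v[1]) -
      atan2(reference_axis[2], reference_axis[1])
    ang <- ((ang * 180 / pi + 180) %% 360) - 180
    if (ang == -180) ang <- 180
    lab_idx <- c(g1, g2)
    nn1 <- length(g1)
    pct <- if (n_shuffles > 0L) {
      sh <- with_seed(seeds[i], vapply(seq_len(n_shuffles), function(j) {
        pick <- sample(lab_idx)
        s1 <- pick[seq_len(nn1)]; s2 <- pick[-seq_len(nn1)]
        d <- colMeans(po[s2, , drop = FALSE]) -
          colMeans(po[s1, , drop = FALSE])
        sqrt(sum(d^2))
      }, numeric(1L)))
      mean(sh < dist_obs)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      animal = a, angle_deg = ang, centre_distance = dist_obs,
      shuffle_percentile = pct)
  }
  do.call(rbind, rows)
}

#' Spatial distance of every glomerulus to the nearest reference instance
#'
#' @param positions n x 2 matrix of positions (µm).
#' @param reference_idx indices of the reference glomeruli.
#' @param mode `"nearest"` (default; per the protocol) or `"centroid"`
#'   (distance to the centre of gravity of the reference instances).
#' @return Numeric distance per glomerulus (0 for the reference
#'   instances themselves under `"nearest"`).
#' @export
distance_to_reference <- function(positions, reference_idx,
                                  mode = c("nearest", "centroid")) {
  mode <- match.arg(mode)
  if (length(reference_idx) == 0L) stop("no reference glomeruli")
  if (mode == "centroid") {
    ctr <- colMeans(positions[reference_idx, , drop = FALSE])
    return(sqrt(rowSums(sweep(positions, 2L, ctr)^2)))
  }
  apply(positions, 1L, function(p) {
    min(sqrt(rowSums(sweep(positions[reference_idx, , drop = FALSE],
                           2L, p)^2)))
  })
}
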