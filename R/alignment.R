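# Spatial comparison of score maps: between-bin similarity and clustering,
# alignment with reference cortical axis maps, and spatial-rotation
# ("spin") null models for map-map correlations.

#' Between-bin similarity of score maps
#'
#' Pearson correlation between every pair of bin columns (across regions),
#' plus a two-cluster partition of the bins from average-linkage
#' hierarchical clustering on the distance `1 - r`.
#'
#' @param group_scores A `cofluct_scores` (usually group-averaged).
#' @return Object of class `cofluct_binsim`: list with `values` (bins x
#'   bins correlation matrix), `cluster_labels` (per-bin, k = 2), and
#'   `bin_labels`.
#' @export
bin_similarity <- function(group_scores) {
  stopifnot(inherits(group_scores, "cofluct_scores"))
  S <- group_scores$scores
  if (ncol(S) < 3L) cf_stop("need at least 3 bins")
  const <- which(apply(S, 2L, stats::var) < 1e-300)
  if (length(const)) {
    cf_stop("constant score map in bin(s) %s: correlation undefined",
            paste(colnames(S)[const], collapse = ", "))
  }
  R <- stats::cor(S)
  d <- 1 - R
  if (max(d) < 1e-12) {
    labels <- rep(1L, ncol(S))  # all maps identical: one effective cluster
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    labels <- stats::cutree(hc, k = 2L)
  }
  structure(list(values = R, cluster_labels = labels,
                 bin_labels = colnames(S)),
            class = "cofluct_binsim")
}

#' @export
print.cofluct_binsim <- function(x, ...) {
  cat(sprintf("Bin-map similarity: %d bins; cluster sizes %s\n",
              ncol(x$values),
              paste(table(x$cluster_labels), collapse = "/")))
  invisible(x)
}

# Coerce a reference map (named numeric vector, or two-column
# region_id/value data frame) to a numeric vector over region_ids.
as_region_map <- function(map, region_ids = NULL) {
  if (is.data.frame(map)) {
    stopifnot(ncol(map) >= 2L)
    v <- stats::setNames(as.numeric(map[[2L]]), as.character(map[[1L]]))
  } else {
    v <- as.numeric(map)
    names(v) <- names(map)
  }
  if (!is.null(region_ids)) {
    if (!is.null(names(v)) && all(region_ids %in% names(v))) {
      v <- v[region_ids]
    } else if (length(v) != length(region_ids)) {
      cf_stop("map length (%d) does not match region set (%d)",
              length(v), length(region_ids))
    }
  }
  v
}

#' Correlation between two per-region maps
#'
#' @param map_a,map_b Numeric per-region maps (vectors, optionally named
#'   by region id, or two-column data frames).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return The correlation coefficient, or `NA` (with a warning) for a
#'   constant map.
#' @export
map_alignment <- function(map_a, map_b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  a <- as_region_map(map_a)
  b <- as_region_map(map_b, names(a))
  if (length(a) != length(b)) cf_stop("maps must cover the same region set")
  if (length(a) < 10L) cf_stop("need at least 10 regions")
  if (stats::var(a) < 1e-300 || stats::var(b) < 1e-300) {
    cf_warn("constant map: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

# One Haar-uniform random 3x3 rotation (QR of a Gaussian matrix with the
# sign convention, reflected to det +1 if needed).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Spin-rotation permutations of a parcel set
#'
#' Generates `n_rotations` uniformly random 3D rotations, applies each to
#' the left-hemisphere parcel centroids and the mirrored rotation to the
#' right, and reassigns every parcel the index of the nearest rotated
#' original centroid within its hemisphere.  The resulting index matrix
#' turns any per-region map into spatial-autocorrelation-preserving null
#' maps (`map[perm[, r]]`).
#'
#' @param geometry A `cofluct_geometry` (unit-sphere centroids,
#'   `hemisphere` in L/R).
#' @param n_rotations Number of rotations (>= 100 for inference).
#' @param seed Integer seed.
#' @return Integer regions x rotations matrix of source indices, with
#'   attribute `duplicate_fraction` (mean fraction of parcels sharing a
#'   nearest source — duplicate assignments are standard parcel-spin
#'   behaviour).
#' @export
spin_permutations <- function(geometry, n_rotations, seed = 1) {
  stopifnot(inherits(geometry, "data.frame"),
            all(c("x", "y", "z", "hemisphere") %in% names(geometry)))
  C <- as.matrix(geometry[, c("x", "y", "z")])
  if (any(!is.finite(C))) cf_stop("missing or non-finite parcel centroid")
  if (any(abs(sqrt(rowSums(C^2)) - 1) > 1e-6)) {
    C <- C / sqrt(rowSums(C^2))
  }
  hemi <- as.character(geometry$hemisphere)
  iL <- which(hemi == "L")
  iR <- which(hemi == "R")
  CL <- C[iL, , drop = FALSE]
  CR <- C[iR, , drop = FALSE]
  M <- diag(c(-1, 1, 1))  # mirror across the midline (x = left-right)
  n <- nrow(C)
  perm <- matrix(NA_integer_, n, n_rotations)
  dup <- numeric(n_rotations)
  with_seed(seed, {
    for (r in seq_len(n_rotations)) {
      R3 <- random_rotation()
      if (length(iL)) {
        rotL <- CL %*% t(R3)
        # unit vectors: nearest = largest dot product
        src <- max.col(CL %*% t(rotL), ties.method = "first")
        perm[iL, r] <- iL[src]
      }
      if (length(iR)) {
        rotR <- CR %*% t(M %*% R3 %*% M)
        src <- max.col(CR %*% t(rotR), ties.method = "first")
        perm[iR, r] <- iR[src]
      }
      dup[r] <- 1 - length(unique(perm[, r])) / n
    }
  })
  attr(perm, "duplicate_fraction") <- mean(dup)
  perm
}

#' Spin test for a map-map correlation
#'
#' Two-tailed significance for the correlation between two per-region maps
#' against a spatial-rotation null: `map_a` is rotated on the sphere (see
#' [spin_permutations()]) and re-correlated with the fixed `map_b`;
#' `p = (1 + #{|null| >= |observed|}) / (1 + n_rotations)`.
#'
#' @param map_a,map_b Per-region maps (as in [map_alignment()]).
#' @param geometry A `cofluct_geometry`.
#' @param n_rotations Number of rotations (default 10000; p-values have
#'   resolution `1/(n_rotations + 1)`).
#' @param seed Integer seed.
#' @param method Correlation method, `"spearman"` or `"pearson"`.
#' @param perm Optional precomputed permutation matrix from
#'   [spin_permutations()] (e.g. shared across bins, or an identity
#'   column for degenerate-rotation checks); overrides `n_rotations` and
#'   `seed`.
#' @return Object of class `cofluct_spin`: list with `observed`,
#'   `p_value`, `nulls`, `n_rotations`, `method`.
#' @export
spin_test <- function(map_a, map_b, geometry, n_rotations = 10000, seed = 1,
                      method = c("spearman", "pearson"), perm = NULL) {
  method <- match.arg(method)
  a <- as_region_map(map_a, geometry$region_id)
  b <- as_region_map(map_b, geometry$region_id)
  observed <- map_alignment(a, b, method = method)
  if (is.null(perm)) {
    if (n_rotations < 100L) cf_stop("n_rotations must be >= 100")
    perm <- spin_permutations(geometry, n_rotations, seed)
  }
  n_rot <- ncol(perm)
  if (method == "spearman") {
    rb <- rank(b)
    nulls <- vapply(seq_len(n_rot), function(r)
      stats::cor(rank(a[perm[, r]]), rb), numeric(1))
  } else {
    nulls <- vapply(seq_len(n_rot), function(r)
      stats::cor(a[perm[, r]], b), numeric(1))
  }
  p <- (1 + sum(abs(nulls) >= abs(observed))) / (1 + n_rot)
  structure(list(observed = observed, p_value = p, nulls = nulls,
                 n_rotations = n_rot, method = method,
                 duplicate_fraction = attr(perm, "duplicate_fraction")),
            class = "cofluct_spin")
}

#' @export
print.cofluct_spin <- function(x, ...) {
  cat(sprintf("Spin test (%s): observed r = %.3f, p = %.4g (%d rotations)\n",
              x$method, x$observed, x$p_value, x$n_rotations))
  invisible(x)
}

#' Per-bin alignment of score maps with a reference axis
#'
#' Spearman correlation of the group score map in every amplitude bin with
#' a reference per-region map (e.g. a sensorimotor-association rank map),
#' with a spin-test p-value per bin.  All bins share one set of rotations
#' (drawn from `seed`), so profiles are reproducible.
#'
#' @param group_scores A group-level `cofluct_scores`.
#' @param reference_map Per-region reference map.
#' @param geometry A `cofluct_geometry`.
#' @param n_rotations,seed Passed to [spin_permutations()].
#' @param reference_name Label stored on the result.
#' @return Object of class `cofluct_alignment`: data frame with `bin`,
#'   `bin_label`, `bin_mean_global`, `correlation`, `p_spin`.
#' @export
alignment_profile <- function(group_scores, reference_map, geometry,
                              n_rotations = 10000, seed = 1,
                              reference_name = "reference") {
  stopifnot(inherits(group_scores, "cofluct_scores"))
  perm <- spin_permutations(geometry, n_rotations, seed)
  ref <- as_region_map(reference_map, group_scores$region_ids)
  res <- lapply(seq_len(group_scores$n_bins), function(m) {
    st <- spin_test(stats::setNames(group_scores$scores[, m],
                                    group_scores$region_ids),
                    ref, geometry, perm = perm)
    data.frame(bin = m, bin_label = colnames(group_scores$scores)[m],
               bin_mean_global = group_scores$bin_mean_global[m],
               correlation = st$observed, p_spin = st$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "reference_name") <- reference_name
  class(out) <- c("cofluct_alignment", "data.frame")
  out
}

#' @export
print.cofluct_alignment <- function(x, ...) {
  cat(sprintf("Alignment profile vs %s (%d bins)\n",
              attr(x, "reference_name"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.cofluct_alignment <- function(x, ...) {
  graphics::plot(x$bin, x$correlation, type = "b", pch = 16,
                 xlab = "amplitude bin (low to high)",
                 ylab = sprintf("Spearman r vs %s",
                                attr(x, "reference_name")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
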