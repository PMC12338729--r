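# Amplitude binning and co-fluctuation scores.
#
# Retained frames are sorted by global RSS and split into quantile bins of
# (near-)equal size.  The co-fluctuation score of region i in bin m is
#   score[i, m] = mean_{t in T_m} rss_region[t, i] / mean_{t in T_m} rss_global[t],
# the region's relative contribution to whole-brain co-fluctuation in that
# amplitude stratum.

#' Assign retained frames to amplitude bins
#'
#' Frames are ordered by `rss_global` (ties broken by original frame
#' order, so the assignment is deterministic) and cut into `n_bins`
#' contiguous blocks whose sizes differ by at most one; when `T` is not a
#' multiple of `n_bins` the extra frames go to the highest-amplitude bins.
#'
#' @param amp A [compute_amplitudes()] result.
#' @param n_bins Number of bins (default 20, i.e. 5% of frames per bin).
#' @return Object of class `cofluct_bins`: list with `n_bins`,
#'   `bin_of_frame` (bin index per retained frame, in frame order),
#'   `bin_sizes`, and `bin_mean_global` (non-decreasing).
#' @export
bin_frames <- function(amp, n_bins = 20) {
  stopifnot(inherits(amp, "cofluct_amplitudes"))
  if (!is_count(n_bins) || n_bins < 2) cf_stop("n_bins must be a count >= 2")
  Tn <- length(amp$rss_global)
  if (Tn < 2L * n_bins) {
    cf_stop("need at least %d retained frames for %d bins (got %d)",
            2L * n_bins, n_bins, Tn)
  }
  ord <- order(amp$rss_global, seq_len(Tn))
  base <- Tn %/% n_bins
  r <- Tn %% n_bins
  sizes <- c(rep(base, n_bins - r), rep(base + 1L, r))
  bin_of_frame <- integer(Tn)
  bin_of_frame[ord] <- rep.int(seq_len(n_bins), sizes)
  bin_mean_global <- as.numeric(
    rowsum(amp$rss_global, bin_of_frame, reorder = TRUE) / sizes)
  structure(list(n_bins = as.integer(n_bins),
                 bin_of_frame = bin_of_frame,
                 bin_sizes = as.integer(sizes),
                 bin_mean_global = bin_mean_global),
            class = "cofluct_bins")
}

bin_labels <- function(n_bins) {
  lo <- round(100 * (seq_len(n_bins) - 1L) / n_bins)
  hi <- round(100 * seq_len(n_bins) / n_bins)
  sprintf("%02d-%02d", lo, hi)
}

#' Co-fluctuation score matrix
#'
#' The ratio of within-bin mean regional RSS to within-bin mean global RSS
#' for every region and amplitude bin.  If all regions carry the same
#' signal the score is `sqrt(2/N)` in every cell.
#'
#' @param amp A [compute_amplitudes()] result.
#' @param bins A [bin_frames()] result derived from `amp`.
#' @param subject_id,condition Optional metadata carried on the result
#'   (default: taken from `amp` where available).
#' @return Object of class `cofluct_scores`: list with `scores` (regions x
#'   bins, strictly positive), `bin_mean_global`, `n_bins`, `region_ids`,
#'   `subject_id`, `condition`.
#' @export
#' @examples
#' scan <- standardize_scan(matrix(rnorm(400 * 8), 400, 8))
#' sm <- cofluctuation_scores(compute_amplitudes(scan), bin_frames(compute_amplitudes(scan), 10))
cofluctuation_scores <- function(amp, bins, subject_id = NULL,
                                 condition = NA_character_) {
  stopifnot(inherits(amp, "cofluct_amplitudes"), inherits(bins, "cofluct_bins"))
  if (length(bins$bin_of_frame) != length(amp$rss_global)) {
    cf_stop("bins were not derived from these amplitudes (frame counts differ)")
  }
  stopifnot(all(tabulate(bins$bin_of_frame, bins$n_bins) == bins$bin_sizes))
  mean_region <- rowsum(amp$rss_region, bins$bin_of_frame, reorder = TRUE) /
    bins$bin_sizes                                  # bins x regions
  mean_global <- as.numeric(
    rowsum(amp$rss_global, bins$bin_of_frame, reorder = TRUE) / bins$bin_sizes)
  scores <- t(mean_region / mean_global)            # regions x bins
  dimnames(scores) <- list(amp$region_ids, bin_labels(bins$n_bins))
  structure(list(scores = scores,
                 bin_mean_global = mean_global,
                 n_bins = bins$n_bins,
                 region_ids = amp$region_ids,
                 subject_id = subject_id %||% amp$subject_id,
                 condition = condition),
            class = "cofluct_scores")
}

#' One-call scoring of a standardized scan
#'
#' Convenience wrapper: amplitudes, binning, and scores.
#'
#' @param scan A `cofluct_scan`.
#' @param n_bins Number of amplitude bins.
#' @inheritParams cofluctuation_scores
#' @return A `cofluct_scores` object.
#' @export
score_scan <- function(scan, n_bins = 20, subject_id = NULL,
                       condition = NA_character_) {
  amp <- compute_amplitudes(scan)
  cofluctuation_scores(amp, bin_frames(amp, n_bins),
                       subject_id = subject_id, condition = condition)
}

#' @export
print.cofluct_scores <- function(x, ...) {
  cat(sprintf("Co-fluctuation scores: %d regions x %d bins", nrow(x$scores),
              x$n_bins))
  if (!is.null(x$subject_id) && !is.na(x$subject_id)) {
    cat(sprintf(" (subject %s)", x$subject_id))
  }
  cat("\n")
  invisible(x)
}

#' Average score matrices across subjects (optionally by group)
#'
#' Element-wise unweighted mean of the score matrices (and of the per-bin
#' mean global amplitudes) across subjects, the group-level score map used
#' for spatial analyses.
#'
#' @param matrices List of `cofluct_scores` with identical regions/bins.
#' @param grouping Optional vector of group labels, one per matrix (or
#'   named by subject id).  `NULL` averages everything into one map.
#' @return A single `cofluct_scores` (no grouping) or a named list of
#'   them, one per group level.
#' @export
group_average_scores <- function(matrices, grouping = NULL) {
  if (inherits(matrices, "cofluct_scores")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, TRUE, "cofluct_scores")))
  ref <- matrices[[1L]]
  bad <- which(vapply(matrices, function(m) {
    m$n_bins != ref$n_bins || !identical(m$region_ids, ref$region_ids)
  }, TRUE))
  if (length(bad)) {
    cf_stop("score matrices with mismatched regions/bins at positions: %s",
            paste(bad, collapse = ", "))
  }
  average <- function(ms) {
    out <- ref
    out$scores <- Reduce(`+`, lapply(ms, `[[`, "scores")) / length(ms)
    out$bin_mean_global <-
      Reduce(`+`, lapply(ms, `[[`, "bin_mean_global")) / length(ms)
    out$subject_id <- NA_character_
    out
  }
  if (is.null(grouping)) return(average(matrices))
  if (length(grouping) != length(matrices)) {
    cf_stop("grouping length (%d) does not match number of matrices (%d)",
            length(grouping), length(matrices))
  }
  lapply(split(matrices, factor(grouping)), average)
}

#' Map a fractional amplitude range to bin indices
#'
#' Returns the indices of the bins wholly contained in the fraction
#' interval, e.g. `c(0.9, 1)` with 20 bins selects bins 19-20 (the
#' 90-100% stratum) and `c(0.4, 0.6)` selects bins 9-12.
#'
#' @param bin_range Two-element fraction interval within \[0, 1\].
#' @param n_bins Total number of bins.
#' @return Integer vector of bin indices.
#' @export
bin_range_to_bins <- function(bin_range, n_bins) {
  stopifnot(length(bin_range) == 2L, bin_range[1L] < bin_range[2L],
            bin_range[1L] >= 0, bin_range[2L] <= 1)
  eps <- 1e-9
  m <- seq_len(n_bins)
  idx <- which((m - 1L) / n_bins >= bin_range[1L] - eps &
                 m / n_bins <= bin_range[2L] + eps)
  if (!length(idx)) {
    cf_stop("bin range [%g, %g] contains no whole bin out of %d",
            bin_range[1L], bin_range[2L], n_bins)
  }
  idx
}
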