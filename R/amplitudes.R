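# Edge co-fluctuation amplitudes.
#
# The edge timeseries (ETS) of a region pair is the frame-wise product of
# their z-scored signals; its temporal mean is exactly the Pearson
# correlation (functional connectivity) of the pair.  Per-frame global and
# regional root-sum-square (RSS) amplitudes are computed by closed forms
# that never materialize the N(N-1)/2 edge matrix:
#   rss_global(t)    = sqrt(((sum_i z_i^2)^2 - sum_i z_i^4) / 2)
#   rss_region(t, i) = sqrt(z_i^2 * (sum_j z_j^2 - z_i^2))
# which satisfy sum_i rss_region^2 = 2 * rss_global^2 at every frame.

#' Standardize a scan
#'
#' Z-scores each region's timeseries using mean and population SD computed
#' over retained frames only; censored frames are dropped from all
#' downstream computation.  With the population (divide-by-n) convention
#' the mean of every edge timeseries equals the corresponding Pearson
#' correlation exactly.
#'
#' @param raw Numeric frames x regions matrix.
#' @param frame_mask Logical per frame, `TRUE` = retained.  Default keeps
#'   all frames.
#' @param tr_seconds Repetition time (seconds), carried as metadata.
#' @param scan_id,subject_id Identifiers carried as metadata.
#' @return Object of class `cofluct_scan`: list with `values` (retained
#'   frames x regions, standardized), `frame_index` (original positions of
#'   retained frames), `n_frames_total`, `region_ids`, `tr_seconds`,
#'   `scan_id`, `subject_id`.
#' @export
#' @examples
#' x <- matrix(rnorm(200 * 4), 200, 4)
#' scan <- standardize_scan(x)
#' colMeans(scan$values)  # ~0
standardize_scan <- function(raw, frame_mask = NULL, tr_seconds = NA_real_,
                             scan_id = NA_character_,
                             subject_id = NA_character_) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) cf_stop("scan values must be numeric")
  n_frames <- nrow(raw)
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, n_frames)
  frame_mask <- as.logical(frame_mask)
  if (length(frame_mask) != n_frames) {
    cf_stop("frame_mask length (%d) does not match frame count (%d)",
            length(frame_mask), n_frames)
  }
  retained <- which(frame_mask)
  if (length(retained) < 2L) cf_stop("fewer than 2 retained frames")
  x <- raw[retained, , drop = FALSE]
  if (any(!is.finite(x))) cf_stop("non-finite values among retained frames")
  std <- standardize_cols(x)
  zero_var <- which(std$sd < 1e-12)
  if (length(zero_var)) {
    ids <- colnames(raw) %||% as.character(seq_len(ncol(raw)))
    cf_stop("zero-variance region(s) over retained frames: %s",
            paste(ids[zero_var], collapse = ", "))
  }
  structure(list(values = std$values,
                 frame_index = retained,
                 n_frames_total = n_frames,
                 region_ids = colnames(raw) %||%
                   sprintf("R%03d", seq_len(ncol(raw))),
                 tr_seconds = tr_seconds,
                 scan_id = scan_id, subject_id = subject_id),
            class = "cofluct_scan")
}

#' @export
print.cofluct_scan <- function(x, ...) {
  cat(sprintf("Parcellated scan: %d/%d frames retained, %d regions\n",
              nrow(x$values), x$n_frames_total, ncol(x$values)))
  invisible(x)
}

#' Edge timeseries of one region pair
#'
#' Frame-wise product of the two standardized columns over retained
#' frames.  Its mean equals the Pearson correlation of the pair.
#'
#' @param scan A `cofluct_scan`.
#' @param i,j Distinct region indices (or region ids).
#' @return Numeric vector, one value per retained frame.
#' @export
edge_timeseries <- function(scan, i, j) {
  stopifnot(inherits(scan, "cofluct_scan"))
  if (is.character(i)) i <- match(i, scan$region_ids)
  if (is.character(j)) j <- match(j, scan$region_ids)
  n <- ncol(scan$values)
  if (anyNA(c(i, j)) || i < 1 || j < 1 || i > n || j > n) {
    cf_stop("invalid region index")
  }
  if (i == j) cf_stop("edge requires two distinct regions (i != j)")
  scan$values[, i] * scan$values[, j]
}

#' Per-frame global and regional co-fluctuation amplitudes
#'
#' Computes, for each retained frame, the root sum of squares of edge
#' co-fluctuations over all region pairs (`rss_global`) and over the edges
#' incident to each region (`rss_region`), via closed forms in the
#' standardized values.
#'
#' @param scan A `cofluct_scan`.
#' @return Object of class `cofluct_amplitudes`: list with `rss_global`
#'   (length T), `rss_region` (T x regions), `frame_index`, `region_ids`,
#'   and scan metadata.
#' @export
#' @examples
#' scan <- standardize_scan(matrix(rnorm(100 * 6), 100, 6))
#' amp <- compute_amplitudes(scan)
#' # sum rule at every frame:
#' max(abs(rowSums(amp$rss_region^2) - 2 * amp$rss_global^2))
compute_amplitudes <- function(scan) {
  stopifnot(inherits(scan, "cofluct_scan"))
  Z <- scan$values
  Z2 <- Z^2
  s2 <- rowSums(Z2)
  s4 <- rowSums(Z2^2)
  rss_global <- sqrt(pmax((s2^2 - s4) / 2, 0))
  rss_region <- sqrt(pmax(Z2 * (s2 - Z2), 0))
  dimnames(rss_region) <- list(NULL, scan$region_ids)
  structure(list(rss_global = rss_global,
                 rss_region = rss_region,
                 frame_index = scan$frame_index,
                 region_ids = scan$region_ids,
                 scan_id = scan$scan_id, subject_id = scan$subject_id),
            class = "cofluct_amplitudes")
}

#' @export
print.cofluct_amplitudes <- function(x, ...) {
  cat(sprintf("Co-fluctuation amplitudes: %d frames, %d regions; global RSS range [%.3g, %.3g]\n",
              length(x$rss_global), ncol(x$rss_region),
              min(x$rss_global), max(x$rss_global)))
  invisible(x)
}
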