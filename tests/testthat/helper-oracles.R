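# Shared fixtures and independent oracles used across tests.

# A standardized random scan.
make_random_scan <- function(n_frames, n_regions, seed = 1, mask = NULL) {
  set.seed(seed)
  standardize_scan(matrix(rnorm(n_frames * n_regions), n_frames, n_regions),
                   frame_mask = mask)
}

# Brute-force RSS oracle: explicit enumeration over all N(N-1)/2 edges.
oracle_amplitudes <- function(scan) {
  Z <- scan$values
  n <- ncol(Z)
  Tn <- nrow(Z)
  rss_global <- numeric(Tn)
  rss_region <- matrix(0, Tn, n)
  for (t in seq_len(Tn)) {
    E <- outer(Z[t, ], Z[t, ])
    rss_global[t] <- sqrt(sum(E[upper.tri(E)]^2))
    for (i in seq_len(n)) {
      rss_region[t, i] <- sqrt(sum(E[i, -i]^2))
    }
  }
  list(rss_global = rss_global, rss_region = rss_region)
}

# Independently coded per-bin mean-ratio score oracle.
oracle_scores <- function(amp, bins) {
  n_bins <- bins$n_bins
  out <- matrix(NA_real_, ncol(amp$rss_region), n_bins)
  for (m in seq_len(n_bins)) {
    sel <- bins$bin_of_frame == m
    out[, m] <- colMeans(amp$rss_region[sel, , drop = FALSE]) /
      mean(amp$rss_global[sel])
  }
  out
}

# Build a bare amplitudes object from explicit rss values (for toy cases).
make_amplitudes <- function(rss_global, rss_region) {
  structure(list(rss_global = rss_global, rss_region = rss_region,
                 frame_index = seq_along(rss_global),
                 region_ids = sprintf("R%03d", seq_len(ncol(rss_region))),
                 scan_id = NA_character_, subject_id = NA_character_),
            class = "cofluct_amplitudes")
}

# Score a whole cohort: list of per-subject score matrices.
score_cohort <- function(cohort, n_bins = 20) {
  lapply(names(cohort$scans), function(id)
    score_scan(cohort$scans[[id]], n_bins = n_bins, subject_id = id))
}

# Small random per-subject score-matrix stack (no signal), for contrast
# and FDR simulations.
make_noise_scores <- function(n_regions, n_subjects, n_bins = 20, seed = 1,
                              sd = 0.01) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    structure(list(scores = matrix(0.2 + rnorm(n_regions * n_bins, sd = sd),
                                   n_regions, n_bins,
                                   dimnames = list(sprintf("R%03d",
                                                           seq_len(n_regions)),
                                                   NULL)),
                   bin_mean_global = sort(runif(n_bins, 1, 5)),
                   n_bins = n_bins,
                   region_ids = sprintf("R%03d", seq_len(n_regions)),
                   subject_id = sprintf("S%03d", s),
                   condition = NA_character_),
              class = "cofluct_scores")
  })
}
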