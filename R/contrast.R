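# Group-level condition contrasts with FDR control across regions.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) cf_stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired condition contrast of band-averaged scores
#'
#' For each region, averages every subject's scores over the bins in
#' `bin_range` in both conditions and tests the within-subject differences
#' (condition A minus condition B) with a two-sided paired test,
#' controlling the false discovery rate across regions with
#' Benjamini-Hochberg.
#'
#' @param scores_a,scores_b Lists of per-subject `cofluct_scores` for the
#'   two conditions; subjects are paired by `subject_id`.
#' @param bin_range Fraction interval, e.g. `c(0.9, 1)` (high amplitudes)
#'   or `c(0.4, 0.6)` (intermediate).
#' @param alpha FDR threshold used for the `significant` flag.
#' @param method `"t"` (paired t-test, default) or `"wilcoxon"` (paired
#'   signed-rank).
#' @return Data frame of class `cofluct_contrast`: `region_id`,
#'   `mean_difference`, `statistic`, `p_raw`, `p_fdr`, `significant`,
#'   `flagged` (zero-variance differences).
#' @export
condition_contrast <- function(scores_a, scores_b, bin_range = c(0.9, 1),
                               alpha = 0.05, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  ids_a <- vapply(scores_a, `[[`, "", "subject_id")
  ids_b <- vapply(scores_b, `[[`, "", "subject_id")
  if (!setequal(ids_a, ids_b) || anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    cf_stop("unpaired subjects; only in A: %s; only in B: %s",
            paste(setdiff(ids_a, ids_b), collapse = ",") ,
            paste(setdiff(ids_b, ids_a), collapse = ","))
  }
  if (length(ids_a) < 5L) cf_stop("need at least 5 subject pairs")
  scores_b <- scores_b[match(ids_a, ids_b)]
  ref <- scores_a[[1L]]
  idx <- bin_range_to_bins(bin_range, ref$n_bins)
  band <- function(lst) vapply(lst, function(sm)
    rowMeans(sm$scores[, idx, drop = FALSE]), numeric(nrow(ref$scores)))
  D <- band(scores_a) - band(scores_b)   # regions x subjects
  res <- lapply(seq_len(nrow(D)), function(r) {
    d <- D[r, ]
    if (stats::sd(d) < 1e-12) {
      return(data.frame(region_id = ref$region_ids[r],
                        mean_difference = mean(d), statistic = NA_real_,
                        p_raw = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    tst <- if (method == "t") stats::t.test(d) else
      suppressWarnings(stats::wilcox.test(d, exact = FALSE))
    data.frame(region_id = ref$region_ids[r], mean_difference = mean(d),
               statistic = unname(tst$statistic), p_raw = tst$p.value,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- bh_fdr(out$p_raw)
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  out <- out[, c("region_id", "mean_difference", "statistic",
                 "p_raw", "p_fdr", "significant", "flagged")]
  attr(out, "method") <- method
  attr(out, "bin_range") <- bin_range
  attr(out, "alpha") <- alpha
  class(out) <- c("cofluct_contrast", "data.frame")
  out
}

#' @export
print.cofluct_contrast <- function(x, ...) {
  cat(sprintf("Paired %s contrast over bins [%g, %g]: %d/%d regions significant at FDR %g\n",
              attr(x, "method"), attr(x, "bin_range")[1L],
              attr(x, "bin_range")[2L], sum(x$significant), nrow(x),
              attr(x, "alpha")))
  invisible(x)
}
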