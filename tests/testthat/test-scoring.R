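# Amplitude binning and the co-fluctuation score matrix.

test_that("bins partition frames with near-equal sizes, extras to the top", {
  cases <- expand.grid(T = c(100, 103, 1197), n_bins = c(10, 20))
  for (i in seq_len(nrow(cases))) {
    Tn <- cases$T[i]; nb <- cases$n_bins[i]
    set.seed(i)
    amp <- make_amplitudes(runif(Tn), matrix(runif(Tn * 3), Tn))
    bins <- bin_frames(amp, nb)
    expect_identical(sort(unique(bins$bin_of_frame)), 1:nb)
    expect_identical(as.integer(tabulate(bins$bin_of_frame, nb)),
                     bins$bin_sizes)
    expect_lte(diff(range(bins$bin_sizes)), 1L)
    expect_identical(sum(bins$bin_sizes), as.integer(Tn))
    # remainder frames land in the highest-amplitude bins
    r <- Tn %% nb
    if (r > 0) {
      expect_identical(bins$bin_sizes,
                       as.integer(c(rep(Tn %/% nb, nb - r),
                                    rep(Tn %/% nb + 1, r))))
    }
    expect_true(all(diff(bins$bin_mean_global) >= 0))
  }
})

test_that("exact 5% bins for T = 100, n_bins = 20", {
  amp <- make_amplitudes(runif(100), matrix(runif(300), 100))
  expect_identical(bin_frames(amp, 20)$bin_sizes, rep(5L, 20))
})

test_that("tied amplitudes break by frame order (stable bins)", {
  amp <- make_amplitudes(rep(1, 40), matrix(runif(80), 40))
  bins <- bin_frames(amp, 4)
  expect_identical(bins$bin_of_frame, rep(1:4, each = 10))
})

test_that("too few frames for the binning is an informative error", {
  amp <- make_amplitudes(runif(30), matrix(runif(60), 30))
  expect_error(bin_frames(amp, 20), "at least 40")
})

test_that("scores are the exact ratio of within-bin means", {
  # one bin, two frames: region RSS (2, 6), global RSS (3, 5) -> 4/4 = 1
  amp <- make_amplitudes(c(3, 5, 10, 20), cbind(c(2, 6, 1, 1)))
  bins <- bin_frames(amp, 2)
  sm <- cofluctuation_scores(amp, bins)
  expect_identical(sm$scores[1, 1], 1)

  scan <- make_random_scan(260, 12, seed = 10)
  amp <- compute_amplitudes(scan)
  bins <- bin_frames(amp, 20)
  sm <- cofluctuation_scores(amp, bins)
  expect_lt(max(abs(unname(sm$scores) - oracle_scores(amp, bins))), 1e-12)
  expect_true(all(sm$scores > 0))
})

test_that("identical-signal regions score sqrt(2/N) in every bin", {
  z <- rnorm(200)
  sm <- score_scan(standardize_scan(matrix(z, 200, 8)), n_bins = 10)
  expect_equal(as.numeric(sm$scores), rep(0.5, 80), tolerance = 1e-12)
})

test_that("scores are invariant to a common positive rescaling of RSS", {
  set.seed(11)
  amp <- make_amplitudes(runif(80, 1, 4), matrix(runif(80 * 5, 0.1, 2), 80))
  bins <- bin_frames(amp, 8)
  s1 <- cofluctuation_scores(amp, bins)
  amp2 <- make_amplitudes(3.7 * amp$rss_global, 3.7 * amp$rss_region)
  s2 <- cofluctuation_scores(amp2, bin_frames(amp2, 8))
  expect_equal(s2$scores, s1$scores, tolerance = 1e-12)
})

test_that("group averaging is the element-wise mean with shape checks", {
  ms <- make_noise_scores(6, 3, n_bins = 5, seed = 2)
  g <- group_average_scores(ms)
  expect_equal(g$scores,
               (ms[[1]]$scores + ms[[2]]$scores + ms[[3]]$scores) / 3,
               tolerance = 1e-12)
  expect_equal(group_average_scores(ms[1])$scores, ms[[1]]$scores)
  # two maps M and -M + 2c average to the constant c
  m2 <- ms[1:2]
  m2[[2]]$scores <- -m2[[1]]$scores + 0.6
  expect_equal(as.numeric(group_average_scores(m2)$scores),
               rep(0.3, 30), tolerance = 1e-12)
  bad <- make_noise_scores(6, 1, n_bins = 4)
  expect_error(group_average_scores(c(ms, bad)), "mismatched")
  # grouping splits into per-group maps
  gg <- group_average_scores(ms, grouping = c("a", "b", "a"))
  expect_named(gg, c("a", "b"))
  expect_equal(gg$b$scores, ms[[2]]$scores)
})

test_that("fraction intervals select whole bins", {
  expect_identical(bin_range_to_bins(c(0.9, 1), 20), 19:20)
  expect_identical(bin_range_to_bins(c(0.4, 0.6), 20), 9:12)
  expect_identical(bin_range_to_bins(c(0.9, 1), 10), 10L)
  expect_error(bin_range_to_bins(c(0.41, 0.44), 20), "no whole bin")
})

test_that("10-bin scores rank regions like pairwise-merged 20-bin scores", {
  coh <- generate_cohort(cohort_spec(n_subjects = 6, n_frames = 1200,
                                     seed = 31))
  s20 <- group_average_scores(score_cohort(coh, 20))
  s10 <- group_average_scores(score_cohort(coh, 10))
  merged <- (s20$scores[, seq(1, 19, 2)] + s20$scores[, seq(2, 20, 2)]) / 2
  rhos <- vapply(1:10, function(m)
    cor(merged[, m], s10$scores[, m], method = "spearman"), numeric(1))
  expect_gt(min(rhos), 0.95)
})
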