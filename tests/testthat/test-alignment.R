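# Map alignment, bin-map similarity, and spin-rotation null models.

test_that("map alignment reproduces hand-computed rank correlations", {
  ranks <- 1:12
  expect_identical(map_alignment(ranks, ranks), 1)
  expect_identical(map_alignment(ranks, rev(ranks)), -1)
  # 10-region embedding of the 4-point example keeps the precondition;
  # hand oracle on (1,2,3,4) vs (2,1,4,3): rho = 0.6
  expect_equal(cor(c(1, 2, 3, 4), c(2, 1, 4, 3), method = "spearman"), 0.6,
               tolerance = 1e-12)
  a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  b <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  expect_equal(map_alignment(a, b),
               cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_warning(out <- map_alignment(rep(1, 10), 1:10), "constant")
  expect_true(is.na(out))
  expect_error(map_alignment(1:5, 1:5), "at least 10")
})

test_that("alignment with the spearman method ignores monotone transforms", {
  set.seed(1)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(map_alignment(exp(a), b), map_alignment(a, b),
               tolerance = 1e-12)
  expect_equal(map_alignment(a, b^3 + 2 * b), map_alignment(a, b),
               tolerance = 1e-12)
})

test_that("bin similarity finds the planted two-block structure", {
  ms <- make_noise_scores(30, 1, n_bins = 6, seed = 5)[[1]]
  base <- ms$scores[, 1]
  ms$scores <- cbind(base, base + rnorm(30, sd = 3e-4),
                     base + rnorm(30, sd = 3e-4),
                     -base, -base + rnorm(30, sd = 3e-4),
                     -base + rnorm(30, sd = 3e-4))
  colnames(ms$scores) <- sprintf("b%d", 1:6)
  bs <- bin_similarity(ms)
  expect_true(isSymmetric(bs$values))
  expect_equal(unname(diag(bs$values)), rep(1, 6))
  expect_lt(max(bs$values[1:3, 4:6]), -0.99)
  lab <- unname(bs$cluster_labels)
  expect_identical(lab[1:3], rep(lab[1], 3))
  expect_identical(lab[4:6], rep(lab[4], 3))
  expect_false(lab[1] == lab[4])

  # identical maps in every bin: a single effective cluster
  ms$scores <- matrix(base, 30, 6, dimnames = dimnames(ms$scores))
  expect_identical(unname(bin_similarity(ms)$cluster_labels), rep(1L, 6))

  ms$scores[, 2] <- 1
  expect_error(bin_similarity(ms), "constant")
})

test_that("spin permutations preserve values and respect hemispheres", {
  geom <- generate_parcel_geometry(60, seed = 3)
  perm <- spin_permutations(geom, 50, seed = 9)
  expect_identical(dim(perm), c(60L, 50L))
  hemi <- geom$hemisphere
  for (r in c(1, 25, 50)) {
    expect_identical(hemi[perm[, r]], hemi)  # within-hemisphere reassignment
    if (!anyDuplicated(perm[, r])) {
      # bijective rotations relabel: value multiset is invariant
      expect_identical(sort(geom$sa_rank[perm[, r]]), sort(geom$sa_rank))
    }
  }
  expect_identical(perm, spin_permutations(geom, 50, seed = 9))
})

test_that("an identity permutation reproduces the observed statistic", {
  geom <- generate_parcel_geometry(40, seed = 2)
  set.seed(5)
  a <- rnorm(40); b <- rnorm(40)
  id_perm <- matrix(1:40, 40, 1)
  st <- spin_test(a, b, geom, perm = id_perm)
  expect_equal(st$nulls[1], st$observed, tolerance = 1e-12)
  expect_identical(st$p_value, 1)  # the single null ties the observed
})

test_that("spin p-values are seeded, floored, and two-tailed", {
  geom <- generate_parcel_geometry(50, seed = 7)
  a <- geom$sa_rank  # perfectly aligned with itself
  st1 <- spin_test(a, a, geom, n_rotations = 199, seed = 4)
  st2 <- spin_test(a, a, geom, n_rotations = 199, seed = 4)
  expect_identical(st1$p_value, st2$p_value)
  expect_gte(st1$p_value, 1 / 200)
  # observed more extreme than every null reaches the floor exactly
  if (all(abs(st1$nulls) < 1)) expect_identical(st1$p_value, 1 / 200)
  expect_error(spin_test(a, a, geom, n_rotations = 50), ">= 100")
})

test_that("alignment profiles carry one correlation and spin p per bin", {
  coh <- generate_cohort(cohort_spec(n_subjects = 4, n_frames = 600,
                                     seed = 41))
  gm <- group_average_scores(score_cohort(coh))
  sa <- setNames(scale(coh$geometry$sa_rank)[, 1], coh$geometry$region_id)
  ap1 <- alignment_profile(gm, sa, coh$geometry, n_rotations = 150, seed = 6)
  ap2 <- alignment_profile(gm, sa, coh$geometry, n_rotations = 150, seed = 6)
  expect_identical(ap1$p_spin, ap2$p_spin)
  expect_identical(nrow(ap1), 20L)
  expect_true(all(ap1$correlation >= -1 & ap1$correlation <= 1))
  expect_true(all(ap1$p_spin > 0 & ap1$p_spin <= 1))
  # reference equal to a bin map correlates perfectly in that bin
  ref_map <- setNames(gm$scores[, 20], gm$region_ids)
  expect_equal(map_alignment(ref_map, setNames(gm$scores[, 20],
                                               gm$region_ids)), 1)
})

test_that("synthetic score maps align negatively with the axis at high bins, positively at mid bins", {
  coh <- generate_cohort(cohort_spec(n_subjects = 6, n_frames = 1200,
                                     seed = 43))
  gm <- group_average_scores(score_cohort(coh))
  sa <- setNames(coh$geometry$sa_rank, coh$geometry$region_id)
  cors <- vapply(1:20, function(m)
    map_alignment(setNames(gm$scores[, m], gm$region_ids), sa), numeric(1))
  expect_lt(cors[20], 0)     # top-amplitude bin: sensorimotor-dominated
  expect_gt(cors[10], 0)     # intermediate bin: association/limbic side
})
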