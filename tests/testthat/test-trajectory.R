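# Penalized-smooth trajectory fits: analytic limits, derivative
# estimates, covariate behaviour, and batch fitting.

linear_data <- function(n = 40) {
  data.frame(global_amplitude = seq(0, 1, length.out = n),
             score = 2 * seq(0, 1, length.out = n))
}

test_that("a noiseless line is reproduced with full partial R2 and no curvature", {
  fit <- fit_trajectory(linear_data(), covariates = NULL)
  expect_gt(fit$partial_r2, 0.999)
  expect_lt(abs(fit$mean_second_derivative), 1e-3)
  expect_gt(fit$primary_effect, 0)
  expect_identical(fit$regime, "increasing")
  expect_equal(fit$mean_first_derivative, 2, tolerance = 0.01)
})

test_that("a constant response yields a null smooth", {
  d <- data.frame(global_amplitude = seq(0, 1, length.out = 30), score = 1)
  fit <- fit_trajectory(d, covariates = NULL)
  expect_lt(fit$partial_r2, 1e-6)
  expect_gt(fit$p_smooth, 0.9)
  expect_identical(fit$regime, "flat")
})

test_that("a noiseless quadratic recovers its analytic second derivative", {
  x <- seq(0, 1, length.out = 60)
  d <- data.frame(global_amplitude = x, score = -(x - 0.5)^2)
  fit <- fit_trajectory(d, covariates = NULL)
  expect_equal(fit$mean_second_derivative, -2, tolerance = 0.05)
  expect_identical(fit$regime, "inverted-U")
})

test_that("derivative estimates are grid-converged on smooth fits", {
  x <- seq(0, 1, length.out = 80)
  set.seed(4)
  d <- data.frame(global_amplitude = x,
                  score = sin(2 * x) + rnorm(80, sd = 0.02))
  f200 <- fit_trajectory(d, covariates = NULL, grid_n = 200)
  f400 <- fit_trajectory(d, covariates = NULL, grid_n = 400)
  expect_lt(abs(f400$mean_first_derivative - f200$mean_first_derivative) /
              abs(f200$mean_first_derivative), 0.01)
  expect_lt(abs(f400$mean_second_derivative - f200$mean_second_derivative) /
              max(abs(f200$mean_second_derivative), 1e-6), 0.01)
})

test_that("partial R2 is bounded and the reduced model never fits better", {
  set.seed(7)
  for (i in 1:5) {
    d <- data.frame(global_amplitude = runif(50),
                    score = rnorm(50),
                    sex = rbinom(50, 1, 0.5), mean_fd = runif(50, 0, 0.3))
    fit <- fit_trajectory(d)
    expect_gte(fit$partial_r2, 0)
    expect_lte(fit$partial_r2, 1)
    expect_lte(sum(residuals(fit)^2),
               sum(residuals(fit$reduced_model)^2) + 1e-10)
    expect_identical(sign(fit$primary_effect),
                     sign(fit$mean_first_derivative) *
                       (fit$partial_r2 > 0))
  }
})

test_that("adding a constant shifts the curve but not effects", {
  set.seed(9)
  d <- data.frame(global_amplitude = runif(60),
                  score = runif(60)^2,
                  sex = rbinom(60, 1, 0.5), mean_fd = runif(60, 0, 0.3))
  f1 <- fit_trajectory(d)
  d$score <- d$score + 5
  f2 <- fit_trajectory(d)
  expect_equal(f2$partial_r2, f1$partial_r2, tolerance = 1e-6)
  expect_equal(f2$mean_first_derivative, f1$mean_first_derivative,
               tolerance = 1e-6)
  expect_equal(f2$mean_second_derivative, f1$mean_second_derivative,
               tolerance = 1e-4)
  expect_equal(f2$fitted_curve$score, f1$fitted_curve$score + 5,
               tolerance = 1e-6)
})

test_that("constant covariates are dropped with a warning", {
  d <- linear_data()
  d$sex <- 0
  d$mean_fd <- 0
  expect_warning(fit <- fit_trajectory(d), "constant covariate")
  expect_identical(sort(fit$dropped_covariates), c("mean_fd", "sex"))
  expect_gt(fit$partial_r2, 0.999)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_trajectory(linear_data(5), covariates = NULL),
               "at least 10")
  d <- data.frame(global_amplitude = rep(c(0, 1), 10), score = rnorm(20))
  expect_error(fit_trajectory(d, covariates = NULL), "distinct")
})

test_that("fit methods expose prediction, coefficients and residuals", {
  fit <- fit_trajectory(linear_data(), covariates = NULL, region_id = "R001")
  expect_equal(predict(fit, c(0.25, 0.75)), c(0.5, 1.5), tolerance = 1e-6)
  expect_length(predict(fit), 200)
  expect_true(is.numeric(coef(fit)))
  expect_length(residuals(fit), 40)
  expect_output(print(fit), "R001")
  expect_output(print(summary(fit)), "partial R2")
})

test_that("batch fitting recovers planted regimes and tolerates failures", {
  coh <- generate_cohort(cohort_spec(n_subjects = 8, n_frames = 1500,
                                     seed = 17))
  sl <- score_cohort(coh)
  fits <- fit_all_regions(sl, coh$covariates)
  tb <- merge(fits$table, coh$geometry[, c("region_id", "region_class")])
  expect_gte(mean(tb$regime[tb$region_class == "S"] == "increasing"), 0.9)
  expect_gte(mean(tb$regime[tb$region_class == "L"] == "decreasing"), 0.9)
  expect_gte(mean(tb$mean_second_derivative[tb$region_class == "A"] < 0), 0.9)
  expect_identical(nrow(fits$table), 60L)
  expect_identical(dim(fits$curves), c(200L, 60L))

  # single-region input: a batch of one
  one <- lapply(sl, function(sm) {
    sm$scores <- sm$scores[1, , drop = FALSE]
    sm$region_ids <- sm$region_ids[1]
    sm
  })
  f1 <- fit_all_regions(one, coh$covariates)
  expect_identical(nrow(f1$table), 1L)
})

test_that("shuffling scores across bins destroys significance at the nominal rate", {
  coh <- generate_cohort(cohort_spec(n_subjects = 8, n_frames = 800,
                                     seed = 23))
  sl <- score_cohort(coh)
  set.seed(23)
  shuffled <- lapply(sl, function(sm) {
    sm$scores <- t(apply(sm$scores, 1, sample))
    sm
  })
  fits <- fit_all_regions(shuffled, coh$covariates)
  expect_lte(mean(fits$table$p_smooth < 0.05), 0.10)
})

test_that("age effects vanish without developmental sharpening and need distinct ages", {
  coh <- generate_cohort(cohort_spec(n_subjects = 16, n_frames = 600,
                                     age_range = c(6, 18),
                                     dev_sharpening = 0, seed = 29))
  sl <- score_cohort(coh)
  ae <- age_effect(sl, coh$covariates, bin_range = c(0.9, 1), k = 5)
  expect_lte(mean(ae$p_raw < 0.05), 0.10)
  cov_flat <- coh$covariates
  cov_flat$age <- 10
  expect_error(age_effect(sl, cov_flat, k = 5), "distinct ages")
})

test_that("developmental sharpening raises high-amplitude S-class scores with age", {
  coh <- generate_cohort(cohort_spec(n_subjects = 24, n_frames = 800,
                                     age_range = c(6, 18),
                                     dev_sharpening = 0.1, seed = 37))
  sl <- score_cohort(coh)
  ae <- age_effect(sl, coh$covariates, bin_range = c(0.9, 1), k = 5)
  s_regions <- coh$geometry$region_id[coh$geometry$region_class == "S"]
  expect_gt(mean(ae$effect[ae$region_id %in% s_regions] > 0), 0.5)
})

test_that("profile similarity is the Spearman correlation of bin sequences", {
  expect_equal(trajectory_similarity(1:5, 1:5), 1, tolerance = 1e-12)
  expect_equal(trajectory_similarity(1:5, 5:1), -1, tolerance = 1e-12)
  expect_equal(trajectory_similarity(c(1, 2, 3, 5), c(1, 3, 2, 5)), 0.8,
               tolerance = 1e-12)
  expect_warning(out <- trajectory_similarity(rep(1, 4), 1:4), "constant")
  expect_true(is.na(out))
  expect_error(trajectory_similarity(1:3, 1:4), "equal length")
})
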