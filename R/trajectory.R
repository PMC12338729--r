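# Penalized-smooth trajectory models of co-fluctuation score versus global
# amplitude.
#
# For one region, observations are (score, amplitude) at subject x bin
# granularity with sex and mean head motion as linear covariates.  The full
# model is a thin-plate regression spline smooth of amplitude plus the
# linear covariates (mgcv, REML smoothness selection); the reduced model
# drops only the smooth.  The primary amplitude effect is the partial
# R-squared of the smooth, signed by the averaged first derivative of the
# fitted curve; the second amplitude effect is the averaged second
# derivative (negative = inverted-U, positive = U-shaped).

#' Fit a co-fluctuation score trajectory for one region
#'
#' @param data Data frame of observations with the response, the smooth
#'   predictor, and optional linear covariates.
#' @param smooth_var Name of the smooth predictor column (default
#'   `"global_amplitude"`; [age_effect()] reuses the machinery with age).
#' @param response Name of the response column (default `"score"`).
#' @param covariates Character vector of linear covariate columns present
#'   in `data`; constant covariates are dropped with a warning.  Use
#'   `NULL` for none.
#' @param k Basis dimension of the thin-plate smooth (default 10); clamped
#'   to the number of distinct predictor values.
#' @param grid_n Number of uniform grid points over the observed predictor
#'   range used for the fitted curve and its finite-difference derivatives
#'   (default 200).
#' @param region_id Optional identifier carried on the fit.
#' @return Object of class `cofluct_fit` with components `partial_r2`
#'   (in \[0, 1\]), `p_smooth` (F-type full-vs-reduced comparison using
#'   effective degrees of freedom), `mean_first_derivative`,
#'   `mean_second_derivative`, `primary_effect`
#'   (`sign(mean_first_derivative) * partial_r2`), `regime` (one of
#'   `"increasing"`, `"inverted-U"`, `"decreasing"`, `"flat"`),
#'   `fitted_curve` (data frame over the grid), and the underlying mgcv
#'   fit in `model`.
#' @seealso [fit_all_regions()] for batch fitting,
#'   [predict.cofluct_fit()], [plot.cofluct_fit()].
#' @export
#' @examples
#' d <- data.frame(global_amplitude = seq(0, 1, length.out = 40))
#' d$score <- 2 * d$global_amplitude
#' fit <- fit_trajectory(d, covariates = NULL)
#' fit$partial_r2  # ~1: a line is recovered exactly
fit_trajectory <- function(data, smooth_var = "global_amplitude",
                           response = "score",
                           covariates = c("sex", "mean_fd"),
                           k = 10, grid_n = 200, region_id = NA_character_) {
  data <- as.data.frame(data)
  needed <- c(response, smooth_var, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    cf_stop("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  data <- data[stats::complete.cases(data[, needed, drop = FALSE]), ,
               drop = FALSE]
  n <- nrow(data)
  if (n < 10L) cf_stop("need at least 10 observations (got %d)", n)
  x <- data[[smooth_var]]
  n_distinct <- length(unique(x))
  if (n_distinct < 3L) {
    cf_stop("need at least 3 distinct values of %s (got %d)",
            smooth_var, n_distinct)
  }
  dropped <- character(0)
  if (length(covariates)) {
    const <- vapply(covariates,
                    function(v) stats::var(as.numeric(data[[v]])) < 1e-12,
                    TRUE)
    dropped <- covariates[const]
    if (length(dropped)) {
      cf_warn("dropping constant covariate(s): %s",
              paste(dropped, collapse = ", "))
      covariates <- covariates[!const]
    }
  }
  # third-order penalty: quadratics sit in the penalty null space, so the
  # curvature that the second amplitude effect measures is not shrunk
  # toward zero by smoothing; very sparse designs fall back to the
  # second-order penalty the basis dimension still supports
  if (n_distinct >= 5L) {
    k_eff <- max(4L, min(as.integer(k), n_distinct))
    m_pen <- 3L
  } else {
    k_eff <- n_distinct
    m_pen <- 2L
  }
  rhs_lin <- if (length(covariates)) paste(covariates, collapse = " + ") else NULL
  full_fml <- stats::reformulate(
    c(sprintf("s(%s, k = %d, bs = \"tp\", m = %d)", smooth_var, k_eff, m_pen),
      rhs_lin),
    response = response)
  red_fml <- stats::reformulate(rhs_lin %||% "1", response = response)
  reduced <- stats::lm(red_fml, data = data)
  y <- as.numeric(data[[response]])
  if (stats::var(y) < 1e-20 * max(1, mean(y)^2)) {
    # constant response: the smooth has nothing to explain
    return(degenerate_fit(data, reduced, smooth_var, response, covariates,
                          dropped, grid_n, region_id, n))
  }
  fit <- withCallingHandlers(
    tryCatch(
      mgcv::gam(full_fml, data = data, method = "REML"),
      error = function(e) {
        cf_stop("smooth model failed for region %s (n = %d, k = %d): %s",
                region_id, n, k_eff, conditionMessage(e))
      }),
    warning = function(w) {
      # REML's Newton step stalls when the residual variance is numerically
      # zero (noise-free inputs); the penalized fit itself is exact there
      if (grepl("step failure", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  sse_full <- sum(stats::residuals(fit)^2)
  sse_red <- sum(stats::residuals(reduced)^2)
  y_scale <- sum((data[[response]] - mean(data[[response]]))^2)
  if (sse_red <= 1e-12 * max(y_scale, 1e-300) || sse_red == 0) {
    # response explained (or constant) without the smooth
    partial_r2 <- 0
    p_smooth <- 1
  } else {
    partial_r2 <- min(1, max(0, (sse_red - sse_full) / sse_red))
    df_full <- sum(fit$hat)            # trace of the hat matrix (edf)
    df_red <- length(stats::coef(reduced))
    df1 <- max(df_full - df_red, 1e-8)
    df2 <- max(n - df_full, 1)
    f_stat <- ((sse_red - sse_full) / df1) / (sse_full / df2)
    p_smooth <- if (!is.finite(f_stat)) 0 else
      stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }

  grid <- seq(min(x), max(x), length.out = grid_n)
  newdata <- stats::setNames(data.frame(grid), smooth_var)
  for (v in covariates) newdata[[v]] <- mean(as.numeric(data[[v]]))
  fitted_grid <- as.numeric(stats::predict(fit, newdata = newdata))
  h <- grid[2L] - grid[1L]
  interior <- 2:(grid_n - 1L)
  d1 <- (fitted_grid[interior + 1L] - fitted_grid[interior - 1L]) / (2 * h)
  d2 <- (fitted_grid[interior + 1L] - 2 * fitted_grid[interior] +
           fitted_grid[interior - 1L]) / h^2
  mfd <- mean(d1)
  msd <- mean(d2)

  structure(list(region_id = region_id,
                 partial_r2 = partial_r2,
                 p_smooth = p_smooth,
                 mean_first_derivative = mfd,
                 mean_second_derivative = msd,
                 primary_effect = sign(mfd) * partial_r2,
                 regime = classify_regime(p_smooth, mfd, msd, fitted_grid),
                 fitted_curve = stats::setNames(
                   data.frame(grid, fitted_grid),
                   c(smooth_var, response)),
                 model = fit, reduced_model = reduced,
                 n_obs = n, k = k_eff,
                 smooth_var = smooth_var, response = response,
                 covariates = covariates, dropped_covariates = dropped,
                 covariate_means = vapply(covariates, function(v)
                   mean(as.numeric(data[[v]])), numeric(1))),
            class = "cofluct_fit")
}

# Null fit for a constant response: no amplitude effect by construction.
degenerate_fit <- function(data, reduced, smooth_var, response, covariates,
                           dropped, grid_n, region_id, n) {
  x <- data[[smooth_var]]
  grid <- seq(min(x), max(x), length.out = grid_n)
  newdata <- stats::setNames(data.frame(grid), smooth_var)
  for (v in covariates) newdata[[v]] <- mean(as.numeric(data[[v]]))
  fitted_grid <- as.numeric(stats::predict(reduced, newdata = newdata))
  structure(list(region_id = region_id, partial_r2 = 0, p_smooth = 1,
                 mean_first_derivative = 0, mean_second_derivative = 0,
                 primary_effect = 0, regime = "flat",
                 fitted_curve = stats::setNames(
                   data.frame(grid, fitted_grid), c(smooth_var, response)),
                 model = reduced, reduced_model = reduced,
                 n_obs = n, k = NA_integer_,
                 smooth_var = smooth_var, response = response,
                 covariates = covariates, dropped_covariates = dropped,
                 covariate_means = vapply(covariates, function(v)
                   mean(as.numeric(data[[v]])), numeric(1))),
            class = "cofluct_fit")
}

# Regime labels from the fitted trajectory: "flat" when the smooth is not
# significant; "inverted-U" when the curvature is clearly negative and the
# curve peaks in the interior of the amplitude range; otherwise the sign
# of the averaged first derivative decides.
classify_regime <- function(p_smooth, mfd, msd, fitted_grid,
                            p_threshold = 0.05, curvature_floor = 1e-3) {
  if (!is.finite(p_smooth) || p_smooth >= p_threshold) return("flat")
  n <- length(fitted_grid)
  peak_frac <- (which.max(fitted_grid) - 1L) / (n - 1L)
  if (msd < -curvature_floor && peak_frac > 0.02 && peak_frac < 0.98) {
    return("inverted-U")
  }
  if (mfd >= 0) "increasing" else "decreasing"
}

#' @export
print.cofluct_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Co-fluctuation trajectory fit%s (n = %d, k = %d)\n",
              if (is.na(x$region_id)) "" else paste0(" for ", x$region_id),
              x$n_obs, x$k))
  cat(sprintf("  partial R2 = %.*g, p(smooth) = %.3g, regime = %s\n",
              digits, x$partial_r2, x$p_smooth, x$regime))
  cat(sprintf("  primary effect = %.*g, mean d2 = %.*g\n",
              digits, x$primary_effect, digits, x$mean_second_derivative))
  invisible(x)
}

#' @export
summary.cofluct_fit <- function(object, ...) {
  structure(list(fit = object, gam_summary = summary(object$model)),
            class = "summary.cofluct_fit")
}

#' @export
print.summary.cofluct_fit <- function(x, ...) {
  print(x$fit)
  if (length(x$fit$dropped_covariates)) {
    cat("  dropped constant covariates:",
        paste(x$fit$dropped_covariates, collapse = ", "), "\n")
  }
  cat("\nUnderlying smooth model:\n")
  print(x$gam_summary)
  invisible(x)
}

#' Predict from a trajectory fit
#'
#' @param object A `cofluct_fit`.
#' @param newdata Optional data frame (or numeric vector of smooth-variable
#'   values; covariates default to their training means).
#' @param ... Passed to [mgcv::predict.gam()].
#' @return Numeric vector of predicted scores.
#' @export
predict.cofluct_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_curve[[object$response]])
  if (is.numeric(newdata)) {
    newdata <- stats::setNames(data.frame(newdata), object$smooth_var)
  }
  for (v in object$covariates) {
    if (is.null(newdata[[v]])) newdata[[v]] <- object$covariate_means[[v]]
  }
  as.numeric(stats::predict(object$model, newdata = newdata, ...))
}

#' @export
coef.cofluct_fit <- function(object, ...) stats::coef(object$model)

#' @export
residuals.cofluct_fit <- function(object, ...) stats::residuals(object$model)

#' @export
fitted.cofluct_fit <- function(object, ...) stats::fitted(object$model)

#' Plot a fitted score trajectory
#'
#' @param x A `cofluct_fit`.
#' @param points Logical: overlay the observations.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cofluct_fit <- function(x, points = TRUE, ...) {
  cv <- x$fitted_curve
  graphics::plot(cv[[1L]], cv[[2L]], type = "l", lwd = 2,
                 xlab = x$smooth_var, ylab = x$response,
                 main = if (is.na(x$region_id)) "Score trajectory"
                        else paste("Score trajectory:", x$region_id), ...)
  if (points && !is.null(x$model$model)) {
    graphics::points(x$model$model[[x$smooth_var]],
                     x$model$model[[x$response]],
                     pch = 16, cex = 0.4, col = grDevices::grey(0.5, 0.5))
  }
  invisible(x)
}

# Long observation table: one row per subject x bin for one region.
region_observations <- function(score_matrices, covariates, region) {
  do.call(rbind, lapply(score_matrices, function(sm) {
    cov_row <- covariates[match(sm$subject_id, covariates$subject_id), ,
                          drop = FALSE]
    data.frame(score = sm$scores[region, ],
               global_amplitude = sm$bin_mean_global,
               sex = cov_row$sex, mean_fd = cov_row$mean_fd,
               subject_id = sm$subject_id,
               row.names = NULL)
  }))
}

#' Fit score trajectories for every region
#'
#' Fits [fit_trajectory()] per region on subject x bin observations pooled
#' across the supplied score matrices.  Failures in individual regions are
#' caught and reported without aborting the batch.
#'
#' @param score_matrices List of per-subject `cofluct_scores` (identical
#'   region sets and bin counts; `subject_id` must match `covariates`).
#' @param covariates Data frame with `subject_id`, `sex`, `mean_fd`.
#' @param k,grid_n Passed to [fit_trajectory()].
#' @param keep_models Keep the per-region `cofluct_fit` objects (default
#'   `FALSE`: only the summary table and fitted curves are retained).
#' @return Object of class `cofluct_trajectories`: list with `table` (one
#'   row per region: `region_id`, `partial_r2`, `p_smooth`,
#'   `mean_first_derivative`, `mean_second_derivative`, `primary_effect`,
#'   `regime`), `curves` (grid x regions matrix of fitted scores),
#'   `grid`, `failed` (named character vector of error messages), and
#'   optionally `fits`.
#' @export
fit_all_regions <- function(score_matrices, covariates, k = 10, grid_n = 200,
                            keep_models = FALSE) {
  if (inherits(score_matrices, "cofluct_scores")) {
    score_matrices <- list(score_matrices)
  }
  ref <- score_matrices[[1L]]
  regions <- ref$region_ids
  same <- vapply(score_matrices, function(m)
    identical(m$region_ids, regions) && m$n_bins == ref$n_bins, TRUE)
  if (!all(same)) cf_stop("inconsistent region sets or bin counts")
  table_rows <- vector("list", length(regions))
  curves <- NULL
  grid <- NULL
  fits <- if (keep_models) vector("list", length(regions)) else NULL
  failed <- character(0)
  seen_warnings <- character(0)
  for (r in seq_along(regions)) {
    obs <- region_observations(score_matrices, covariates, r)
    res <- withCallingHandlers(
      tryCatch(
        fit_trajectory(obs, k = k, grid_n = grid_n, region_id = regions[r]),
        error = function(e) e),
      warning = function(w) {
        # the same design issue repeats across regions; report it once
        seen_warnings <<- union(seen_warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      failed[regions[r]] <- conditionMessage(res)
      next
    }
    if (is.null(curves)) {
      curves <- matrix(NA_real_, nrow = grid_n, ncol = length(regions),
                       dimnames = list(NULL, regions))
      grid <- res$fitted_curve$global_amplitude
    }
    curves[, r] <- res$fitted_curve[[res$response]]
    if (keep_models) fits[[r]] <- res
    table_rows[[r]] <- data.frame(
      region_id = regions[r], partial_r2 = res$partial_r2,
      p_smooth = res$p_smooth,
      mean_first_derivative = res$mean_first_derivative,
      mean_second_derivative = res$mean_second_derivative,
      primary_effect = res$primary_effect, regime = res$regime,
      stringsAsFactors = FALSE)
  }
  for (w in seen_warnings) cf_warn("%s", w)
  if (length(failed)) {
    cf_warn("trajectory fit failed for %d region(s): %s", length(failed),
            paste(names(failed), collapse = ", "))
  }
  structure(list(table = do.call(rbind, table_rows),
                 curves = curves,
                 grid = grid,
                 failed = failed,
                 fits = fits,
                 n_subjects = length(score_matrices),
                 n_bins = ref$n_bins),
            class = "cofluct_trajectories")
}

#' @export
print.cofluct_trajectories <- function(x, ...) {
  cat(sprintf("Trajectory fits: %d regions, %d subjects, %d bins\n",
              nrow(x$table), x$n_subjects, x$n_bins))
  print(table(regime = x$table$regime))
  if (length(x$failed)) cat(sprintf("%d region(s) failed\n", length(x$failed)))
  invisible(x)
}

#' @export
as.data.frame.cofluct_trajectories <- function(x, ...) x$table

#' @export
summary.cofluct_trajectories <- function(object, ...) {
  with(object$table, {
    cat(sprintf("partial R2: median %.3f (range %.3f-%.3f)\n",
                stats::median(partial_r2), min(partial_r2), max(partial_r2)))
  })
  print(object)
  invisible(object)
}

#' Age effects on band-averaged co-fluctuation scores
#'
#' Averages each subject's scores over the bins in `bin_range`, then fits
#' the same smooth-model machinery per region with age as the smooth term
#' and sex and mean head motion as linear covariates.  The effect is the
#' partial R-squared of the age smooth signed by its averaged first
#' derivative.
#'
#' @param score_matrices List of per-subject `cofluct_scores`.
#' @param covariates Data frame with `subject_id`, `age`, `sex`, `mean_fd`.
#' @param bin_range Fraction interval, e.g. `c(0.9, 1)` for the highest
#'   decile of amplitudes or `c(0.4, 0.6)` for the intermediate band.
#' @param k Smooth basis dimension (clamped to the distinct ages).
#' @return Data frame of class `cofluct_age_effect`: `region_id`,
#'   `effect` (signed partial R2), `p_raw`, `p_fdr` (Benjamini-Hochberg
#'   across regions).
#' @export
age_effect <- function(score_matrices, covariates, bin_range = c(0.9, 1),
                       k = 10) {
  n_subj <- length(score_matrices)
  if (n_subj < 15L) cf_stop("need at least 15 subjects (got %d)", n_subj)
  ref <- score_matrices[[1L]]
  ages <- covariates$age[match(vapply(score_matrices, `[[`, "", "subject_id"),
                               covariates$subject_id)]
  if (length(unique(ages)) < 3L) {
    cf_stop("need at least 3 distinct ages to model an age smooth")
  }
  idx <- bin_range_to_bins(bin_range, ref$n_bins)
  band <- vapply(score_matrices, function(sm)
    rowMeans(sm$scores[, idx, drop = FALSE]), numeric(nrow(ref$scores)))
  rows <- lapply(seq_along(ref$region_ids), function(r) {
    d <- data.frame(score = band[r, ], age = ages,
                    sex = covariates$sex, mean_fd = covariates$mean_fd)
    fit <- fit_trajectory(d, smooth_var = "age", k = k,
                          region_id = ref$region_ids[r])
    data.frame(region_id = ref$region_ids[r],
               effect = fit$primary_effect, p_raw = fit$p_smooth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  class(out) <- c("cofluct_age_effect", "data.frame")
  out
}

#' Rank correlation of two per-bin profiles
#'
#' Spearman correlation of two equal-length per-bin scalar sequences,
#' e.g. alignment profiles of two age groups.
#'
#' @param profile_a,profile_b Numeric vectors of equal length >= 3.
#' @return Spearman's rho, or `NA` (with a warning) if a profile is
#'   constant.
#' @export
trajectory_similarity <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b) || length(profile_a) < 3L) {
    cf_stop("profiles must have equal length >= 3")
  }
  if (stats::var(profile_a) < 1e-300 || stats::var(profile_b) < 1e-300) {
    cf_warn("constant profile: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(profile_a, profile_b, method = "spearman")
}
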