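# Synthetic cohort generator: seeded parcellated BOLD-like timeseries whose
# amplitude-dependent co-fluctuation structure is known by construction.
#
# Each region belongs to one of three classes whose coupling to a shared
# class factor is gated by a latent per-frame global-amplitude state
# a ~ Uniform(0, 1):
#   S ("sensorimotor-like")  gain increasing in a,
#   A ("association-like")   gain unimodal with an interior maximum,
#   L ("limbic-like")        weak gain, non-increasing in a.
# Signals are x_i(t) = sqrt(g_class(a_t)) * f_class(t) + noise_sd * eps_i(t)
# with f and eps i.i.d. standard normal, then z-scored per region.

#' Default gain profiles for the three synthetic region classes
#'
#' Returns the per-class gain functions mapping latent amplitude
#' `a` in \[0, 1\] to a non-negative factor weight.  Each gain is
#' `baseline + scale * shape(a)^exponent` where `shape` is a normalized
#' curve in \[0, 1\]:
#' \itemize{
#'   \item S: `0.1 + 0.9 * (a^2)^e` — increasing, strongest at high amplitude;
#'   \item A: `0.3 + 0.5 * (4 a (1 - a))^e` — unimodal, interior maximum;
#'   \item L: `0.05 + 0.1 * ((1 - a)^2)^e` — weakly coupled, non-increasing.
#' }
#' The L class is deliberately weak relative to the noise floor: a weakly
#' coupled region's co-fluctuation score declines mechanically with global
#' amplitude (its regional RSS grows like the square root of the global
#' sum of squares while the global RSS grows linearly in it), which is the
#' decreasing regime the generator must realize.
#'
#' The exponent `e >= 1` (see `dev_sharpening` in [cohort_spec()]) raises
#' gain contrast monotonically with subject age, emulating developmental
#' sharpening of the amplitude gating.
#'
#' @return Named list of gain profiles, each with fields `region_class`,
#'   `baseline`, `scale`, and `shape` (a function of `a`).
#' @export
#' @examples
#' g <- default_gain_profiles()
#' gain_value(g$S, c(0, 0.5, 1))
default_gain_profiles <- function() {
  list(
    S = list(region_class = "S", baseline = 0.10, scale = 0.90,
             shape = function(a) a^2),
    A = list(region_class = "A", baseline = 0.30, scale = 0.50,
             shape = function(a) 4 * a * (1 - a)),
    L = list(region_class = "L", baseline = 0.05, scale = 0.10,
             shape = function(a) (1 - a)^2)
  )
}

#' Evaluate a gain profile
#'
#' @param profile One element of [default_gain_profiles()].
#' @param a Latent amplitude values in \[0, 1\].
#' @param exponent Contrast exponent (>= 0); 1 leaves the shape unchanged.
#' @return Numeric vector of gains, always `>= baseline > 0`.
#' @export
gain_value <- function(profile, a, exponent = 1) {
  stopifnot(is.numeric(a), all(a >= 0 & a <= 1))
  profile$baseline + profile$scale * pmin(pmax(profile$shape(a), 0), 1)^exponent
}

#' Specify a synthetic cohort
#'
#' Bundles the generator parameters.  Defaults are the package's reference
#' study conditions: 20 subjects, 20 regions per class (60 total), 2000
#' frames per scan, moderate measurement noise, adult age range, and no
#' developmental sharpening.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions_per_class Named or ordered counts for classes S, A, L.
#' @param n_frames Frames per scan.
#' @param noise_sd Standard deviation of i.i.d. measurement noise added to
#'   each region's factor signal (the factor itself has unit variance scale).
#' @param age_range Two-element years interval; subject ages are uniform on it.
#' @param dev_sharpening Slope (per year) of the gain-contrast exponent
#'   `e = 1 + dev_sharpening * (age - 6)`; 0 disables age effects.
#' @param ar_phi AR(1) coefficient for the latent amplitude state; 0 (the
#'   default) makes frames exchangeable, matching the binning model.
#' @param tr_seconds Repetition time recorded on generated scans.
#' @param seed Integer master seed; every draw derives from it.
#' @return Object of class `cofluct_spec`.
#' @export
cohort_spec <- function(n_subjects = 20,
                        n_regions_per_class = c(S = 20, A = 20, L = 20),
                        n_frames = 2000,
                        noise_sd = 0.3,
                        age_range = c(22, 35),
                        dev_sharpening = 0,
                        ar_phi = 0,
                        tr_seconds = 0.72,
                        seed = 1) {
  if (!is_count(n_subjects)) cf_stop("n_subjects must be a positive count")
  n_regions_per_class <- as.integer(n_regions_per_class)
  if (length(n_regions_per_class) != 3L || any(n_regions_per_class < 1)) {
    cf_stop("n_regions_per_class must give three positive counts (S, A, L)")
  }
  names(n_regions_per_class) <- c("S", "A", "L")
  if (!is_count(n_frames)) cf_stop("n_frames must be a positive count")
  if (!is.numeric(noise_sd) || noise_sd < 0) cf_stop("noise_sd must be >= 0")
  if (length(age_range) != 2L || diff(age_range) < 0) {
    cf_stop("age_range must be an increasing two-element interval")
  }
  if (abs(ar_phi) >= 1) cf_stop("ar_phi must lie in (-1, 1)")
  structure(list(n_subjects = n_subjects,
                 n_regions_per_class = n_regions_per_class,
                 n_frames = n_frames, noise_sd = noise_sd,
                 age_range = as.numeric(age_range),
                 dev_sharpening = dev_sharpening, ar_phi = ar_phi,
                 tr_seconds = tr_seconds, seed = as.integer(seed)),
            class = "cofluct_spec")
}

#' Generate synthetic parcel geometry
#'
#' Samples parcel centroids uniformly on the unit sphere of each hemisphere
#' and assigns a spatially autocorrelated axis rank (`sa_rank`) as the rank
#' of a smooth function of centroid latitude, so rotation-based null models
#' have realistic structure to preserve.  Region classes follow the rank:
#' the lowest ranks are class S, the middle A, the highest L, emulating a
#' sensorimotor-to-association-to-limbic ordering along the axis.
#'
#' @param n_regions Even total number of parcels (split across hemispheres).
#' @param seed Integer seed.
#' @param class_counts Optional S/A/L counts summing to `n_regions`;
#'   defaults to (near-)equal tertiles.
#' @return A `data.frame` of class `cofluct_geometry` with columns
#'   `region_id`, `hemisphere`, `x`, `y`, `z`, `network`, `sa_rank`,
#'   `region_class`.  Centroids have unit norm.
#' @export
#' @examples
#' geom <- generate_parcel_geometry(60, seed = 7)
#' table(geom$hemisphere, geom$region_class)
generate_parcel_geometry <- function(n_regions, seed = 1, class_counts = NULL) {
  if (!is_count(n_regions)) cf_stop("n_regions must be a positive count")
  if (n_regions %% 2L != 0L) {
    cf_stop("n_regions must be even (parcels are split across hemispheres)")
  }
  if (is.null(class_counts)) {
    class_counts <- diff(round(n_regions * 0:3 / 3))
  }
  class_counts <- as.integer(class_counts)
  if (length(class_counts) != 3L || sum(class_counts) != n_regions) {
    cf_stop("class_counts must give three counts summing to n_regions")
  }
  n_half <- n_regions %/% 2L
  with_seed(seed, {
    pts <- matrix(stats::rnorm(3L * n_regions), ncol = 3L)
    pts <- pts / sqrt(rowSums(pts^2))
    hemi <- rep(c("L", "R"), each = n_half)
    pts[, 1L] <- ifelse(hemi == "L", -abs(pts[, 1L]), abs(pts[, 1L]))
    # Smooth function of latitude (z) plus a low-order harmonic: spatially
    # autocorrelated, with a tiny jitter only to break exact ties.
    axis_val <- pts[, 3L] + 0.25 * pts[, 1L] * pts[, 2L] +
      1e-6 * stats::rnorm(n_regions)
    sa_rank <- rank(axis_val, ties.method = "first")
    region_class <- character(n_regions)
    ord <- order(sa_rank)
    region_class[ord] <- rep(c("S", "A", "L"), times = class_counts)
    network <- character(n_regions)
    for (k in c("S", "A", "L")) {
      idx <- ord[region_class[ord] == k]
      nets <- switch(k,
                     S = c("Vis", "SomMot"),
                     A = c("DorsAttn", "Default"),
                     L = "Limbic")
      network[idx] <- rep(nets, length.out = length(idx))
    }
    out <- data.frame(region_id = sprintf("R%03d", seq_len(n_regions)),
                      hemisphere = hemi,
                      x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                      network = network,
                      sa_rank = as.integer(sa_rank),
                      region_class = region_class,
                      stringsAsFactors = FALSE)
    class(out) <- c("cofluct_geometry", "data.frame")
    out
  })
}

# Per-region gain matrix (frames x regions is built column-wise from this):
# rows = classes in geometry order. "movie" blends the visual S subset's
# gain halfway toward the A profile, moving those regions' engagement from
# high toward intermediate amplitudes.
region_gains <- function(geometry, a, exponent, condition) {
  profiles <- default_gain_profiles()
  g_class <- vapply(profiles,
                    function(p) gain_value(p, a, exponent),
                    numeric(length(a)))
  cls <- match(geometry$region_class, c("S", "A", "L"))
  G <- t(g_class)[cls, , drop = FALSE]  # regions x frames
  if (identical(condition, "movie")) {
    vis <- which(geometry$region_class == "S" & geometry$network == "Vis")
    if (length(vis)) {
      G[vis, ] <- 0.5 * G[vis, ] +
        0.5 * matrix(g_class[, "A"], nrow = length(vis),
                     ncol = length(a), byrow = TRUE)
    }
  }
  G
}

#' Generate one synthetic scan
#'
#' Draws a latent amplitude state per frame, three class factors, and
#' per-region noise, producing a standardized scan (see
#' [standardize_scan()]) whose co-fluctuation structure is gated by the
#' latent amplitude.
#'
#' @param spec A [cohort_spec()].
#' @param geometry A [generate_parcel_geometry()] result consistent with
#'   the spec's class counts.
#' @param subject List or one-row data.frame with at least `age` (used by
#'   `dev_sharpening`); `subject_id` is carried onto the scan if present.
#' @param seed Integer seed for this scan.
#' @param condition `"rest"` or `"movie"` (a documented gain perturbation
#'   of the visual S-class subset).
#' @param n_bins_intended Number of downstream amplitude bins used for the
#'   thin-bin warning; `NULL` disables the check.
#' @return A `cofluct_scan` (all frames retained).
#' @export
generate_scan <- function(spec, geometry, subject = list(age = NA_real_),
                          seed = 1, condition = c("rest", "movie"),
                          n_bins_intended = 20) {
  condition <- match.arg(condition)
  stopifnot(inherits(spec, "cofluct_spec"))
  n_regions <- sum(spec$n_regions_per_class)
  if (nrow(geometry) != n_regions) {
    cf_stop("geometry has %d parcels but spec expects %d",
            nrow(geometry), n_regions)
  }
  cc <- table(factor(geometry$region_class, levels = c("S", "A", "L")))
  if (!all(as.integer(cc) == spec$n_regions_per_class)) {
    cf_stop("geometry class counts (%s) do not match spec (%s)",
            paste(cc, collapse = "/"),
            paste(spec$n_regions_per_class, collapse = "/"))
  }
  if (!is.null(n_bins_intended) && spec$n_frames < 10 * n_bins_intended) {
    cf_warn("n_frames = %d is fewer than 10 frames per intended bin (%d bins): bins too thin",
            spec$n_frames, n_bins_intended)
  }
  age <- suppressWarnings(as.numeric(subject$age %||% NA_real_))
  exponent <- 1
  if (is.finite(age) && spec$dev_sharpening != 0) {
    exponent <- max(1 + spec$dev_sharpening * (age - 6), 0.25)
  }
  Tn <- spec$n_frames
  with_seed(seed, {
    if (spec$ar_phi != 0) {
      u <- numeric(Tn)
      u[1L] <- stats::rnorm(1L)
      innov <- stats::rnorm(Tn - 1L, sd = sqrt(1 - spec$ar_phi^2))
      for (t in 2:Tn) u[t] <- spec$ar_phi * u[t - 1L] + innov[t - 1L]
      a <- stats::pnorm(u)
    } else {
      a <- stats::runif(Tn)
    }
    f <- matrix(stats::rnorm(3L * Tn), nrow = 3L)
    G <- region_gains(geometry, a, exponent, condition)  # regions x frames
    cls <- match(geometry$region_class, c("S", "A", "L"))
    X <- t(sqrt(G) * f[cls, , drop = FALSE])             # frames x regions
    if (spec$noise_sd > 0) {
      X <- X + spec$noise_sd * matrix(stats::rnorm(Tn * n_regions), nrow = Tn)
    }
    colnames(X) <- geometry$region_id
    standardize_scan(X, tr_seconds = spec$tr_seconds,
                     scan_id = sprintf("%s_%s", condition, seed),
                     subject_id = subject$subject_id %||% NA_character_)
  })
}

#' Generate a synthetic cohort
#'
#' Draws subject covariates (age uniform on `spec$age_range`, sex
#' Bernoulli(0.5), mean framewise displacement `|N(0.1, 0.03)|`) and one
#' scan per subject via [generate_scan()] with per-subject seeds derived
#' deterministically from `spec$seed`, so a cohort is a pure function of
#' its spec.  Rest and movie cohorts built from the same spec share
#' subjects (covariates and seed derivation), giving a paired design.
#'
#' @param spec A [cohort_spec()].
#' @param geometry Optional geometry; generated from `spec$seed` if absent.
#' @param condition `"rest"` or `"movie"`.
#' @return Object of class `cofluct_cohort`: list with `scans` (named by
#'   subject), `covariates` (data.frame), `geometry`, `spec`, `condition`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 2, n_frames = 400, seed = 3))
#' names(coh$scans)
generate_cohort <- function(spec, geometry = NULL,
                            condition = c("rest", "movie")) {
  condition <- match.arg(condition)
  stopifnot(inherits(spec, "cofluct_spec"))
  if (is.null(geometry)) {
    geometry <- generate_parcel_geometry(sum(spec$n_regions_per_class),
                                         seed = spec$seed,
                                         class_counts = spec$n_regions_per_class)
  }
  n <- spec$n_subjects
  covariates <- with_seed(derive_seed(spec$seed, 1L), {
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               age = stats::runif(n, spec$age_range[1L], spec$age_range[2L]),
               sex = stats::rbinom(n, 1L, 0.5),
               mean_fd = abs(stats::rnorm(n, 0.1, 0.03)),
               condition = condition,
               stringsAsFactors = FALSE)
  })
  cond_off <- if (condition == "movie") 499979L else 0L
  scans <- lapply(seq_len(n), function(i) {
    generate_scan(spec, geometry,
                  subject = as.list(covariates[i, , drop = FALSE]),
                  seed = derive_seed(spec$seed, 2L, i, cond_off),
                  condition = condition)
  })
  names(scans) <- covariates$subject_id
  structure(list(scans = scans, covariates = covariates,
                 geometry = geometry, spec = spec, condition = condition),
            class = "cofluct_cohort")
}

#' @export
print.cofluct_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d regions, %d frames/scan (%s)\n",
              length(x$scans), nrow(x$geometry), x$spec$n_frames, x$condition))
  invisible(x)
}
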