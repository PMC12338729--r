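# TSV readers/writers for all pipeline artifacts and the end-to-end driver.
# TSV is the single interchange format: parcellated data at this
# granularity has no dominant binary standard, and plain text keeps every
# artifact diffable and re-readable by the package's own readers.

#' Read a parcellated scan from TSV
#'
#' Expects a header row of region ids and a numeric body (frames x
#' regions).  Parse problems are reported with line numbers.
#'
#' @param path Path to a tab-separated file.
#' @return List with `values` (numeric matrix) and `region_ids`.
#' @export
read_scan <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) cf_stop("%s: empty file", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  dup <- unique(header[duplicated(header)])
  if (length(dup)) {
    cf_stop("%s: duplicate region id(s) in header: %s", path,
            paste(dup, collapse = ", "))
  }
  body <- lines[-1L]
  if (!length(body)) cf_stop("%s: no data rows", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(parts)
  bad <- which(lens != length(header))
  if (length(bad)) {
    cf_stop("%s: ragged row at line %d (%d fields, expected %d)",
            path, bad[1L] + 1L, lens[bad[1L]], length(header))
  }
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_line <- (which(is.na(vals))[1L] - 1L) %/% length(header) + 2L
    cf_stop("%s: non-numeric cell at line %d", path, bad_line)
  }
  m <- matrix(vals, ncol = length(header), byrow = TRUE,
              dimnames = list(NULL, header))
  list(values = m, region_ids = header)
}

#' Write a matrix (or scan) as TSV
#'
#' @param x Numeric matrix with column names, or a `cofluct_scan` (its
#'   standardized retained-frame values are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(x, path) {
  if (inherits(x, "cofluct_scan")) {
    m <- x$values
    colnames(m) <- x$region_ids
    x <- m
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a frame mask (or framewise-displacement column) from TSV
#'
#' A one-column file: values all in `{0, 1}` are taken as a retain mask
#' directly; otherwise they are framewise displacement in mm and frames
#' with `fd > fd_threshold` are censored.
#'
#' @param path Path to the one-column TSV (no header).
#' @param fd_threshold Censoring threshold in mm (default 0.2).
#' @return Logical vector, `TRUE` = retained.
#' @export
read_frame_mask <- function(path, fd_threshold = 0.2) {
  v <- scan(path, quiet = TRUE)
  if (all(v %in% c(0, 1))) return(v == 1)
  v <= fd_threshold
}

#' Write / read a co-fluctuation score matrix as TSV
#'
#' Rows are regions (first column `region_id`), columns are bin labels,
#' plus a `bin_mean_global` footer row.
#'
#' @param scores A `cofluct_scores`.
#' @param path File path.
#' @return `path` (writer, invisibly) or a `cofluct_scores` (reader).
#' @export
write_score_matrix <- function(scores, path) {
  stopifnot(inherits(scores, "cofluct_scores"))
  body <- data.frame(region_id = scores$region_ids, scores$scores,
                     check.names = FALSE, stringsAsFactors = FALSE)
  footer <- data.frame(region_id = "bin_mean_global",
                       t(scores$bin_mean_global), check.names = FALSE)
  names(footer) <- names(body)
  utils::write.table(rbind(body, footer), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @param subject_id,condition Metadata attached to the read result.
#' @export
read_score_matrix <- function(path, subject_id = NA_character_,
                              condition = NA_character_) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  stopifnot(names(d)[1L] == "region_id")
  foot <- d$region_id == "bin_mean_global"
  if (sum(foot) != 1L) cf_stop("%s: missing bin_mean_global footer", path)
  scores <- as.matrix(d[!foot, -1L, drop = FALSE])
  rownames(scores) <- d$region_id[!foot]
  structure(list(scores = scores,
                 bin_mean_global = as.numeric(d[foot, -1L]),
                 n_bins = ncol(scores),
                 region_ids = d$region_id[!foot],
                 subject_id = subject_id, condition = condition),
            class = "cofluct_scores")
}

#' Write / read parcel geometry as TSV
#'
#' Columns: `region_id`, `hemisphere`, `x`, `y`, `z`, `network`,
#' `sa_rank`, `region_class`.
#'
#' @param geometry A `cofluct_geometry`.
#' @param path File path.
#' @export
write_geometry <- function(geometry, path) {
  utils::write.table(as.data.frame(geometry), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("region_id", "hemisphere", "x", "y", "z", "sa_rank")
  miss <- setdiff(needed, names(d))
  if (length(miss)) {
    cf_stop("%s: missing geometry column(s): %s", path,
            paste(miss, collapse = ", "))
  }
  class(d) <- c("cofluct_geometry", "data.frame")
  d
}

#' Read a two-column reference map (region_id, value) from TSV
#'
#' Serves any per-region reference: an axis rank map, a myelination map,
#' a gene-expression contrast map.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_reference_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) cf_stop("%s: reference map needs two columns", path)
  stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end analysis with the
#' package defaults: 20 amplitude bins, 0.2 mm framewise-displacement
#' censoring, 10000 spin rotations, the 90-100% high and 40-60%
#' intermediate amplitude bands.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Integer master seed.
#' @param stages Character subset of
#'   `c("simulate", "score", "trajectories", "alignment", "contrast")`.
#' @param n_bins Number of amplitude bins.
#' @param fd_threshold Censoring threshold (mm) applied by readers.
#' @param n_rotations Spin rotations for alignment p-values.
#' @param bin_range_high,bin_range_mid Fraction intervals for the high and
#'   intermediate amplitude analyses.
#' @param k Smooth basis dimension for trajectory fits.
#' @param simulate A [cohort_spec()] used when the `"simulate"` stage is
#'   active (its `seed` is overridden by `seed`).
#' @param scans_dir,covariates_path,geometry_path Input locations used
#'   when `"simulate"` is not among the stages.
#' @return Object of class `cofluct_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            stages = c("simulate", "score", "trajectories",
                                       "alignment"),
                            n_bins = 20,
                            fd_threshold = 0.2,
                            n_rotations = 10000,
                            bin_range_high = c(0.9, 1),
                            bin_range_mid = c(0.4, 0.6),
                            k = 10,
                            simulate = cohort_spec(),
                            scans_dir = NULL,
                            covariates_path = NULL,
                            geometry_path = NULL) {
  stages <- match.arg(stages, c("simulate", "score", "trajectories",
                                "alignment", "contrast"),
                      several.ok = TRUE)
  for (v in list(n_bins = n_bins, fd_threshold = fd_threshold,
                 n_rotations = n_rotations, k = k)) {
    if (!is.numeric(v) || v <= 0) cf_stop("config numeric fields must be positive")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 n_bins = as.integer(n_bins), fd_threshold = fd_threshold,
                 n_rotations = as.integer(n_rotations),
                 bin_range_high = bin_range_high, bin_range_mid = bin_range_mid,
                 k = as.integer(k), simulate = simulate,
                 scans_dir = scans_dir, covariates_path = covariates_path,
                 geometry_path = geometry_path),
            class = "cofluct_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `simulate:` block maps onto [cohort_spec()].
#'
#' @param path YAML file path.
#' @param out_dir,seed Optional overrides.
#' @return A `cofluct_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(cohort_spec, y$simulate)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  do.call(pipeline_config, y)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages (simulate or read scans; standardize,
#' amplitudes, bin, score; group averaging; trajectory fits; axis
#' alignment; rest-vs-movie contrast) and writes every artifact as TSV
#' under `config$out_dir`, plus a JSON manifest with input hashes, the
#' seed, package version and per-stage timings.  Given the same config
#' and seed the numeric outputs are byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage progress to stderr.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "cofluct_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- covariates <- scans <- group_map <- NULL
  artifacts <- character(0)
  timings <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      cf_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    pipeline_log(verbose, "[%s] done in %.1fs", name, timings[[name]])
    res
  }
  emit <- function(obj, file, writer) {
    p <- file.path(config$out_dir, file)
    writer(obj, p)
    artifacts <<- c(artifacts, p)
    p
  }

  if ("simulate" %in% config$stages) {
    cohort <- stage("simulate", {
      spec <- config$simulate
      spec$seed <- config$seed
      generate_cohort(spec)
    })
    geometry <- cohort$geometry
    covariates <- cohort$covariates
    scans <- cohort$scans
    emit(geometry, "geometry.tsv", write_geometry)
    emit(covariates, "covariates.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    for (id in names(scans)) {
      emit(scans[[id]], sprintf("scan_%s.tsv", id), write_scan)
    }
  } else {
    stage("read", {
      geometry <<- read_geometry(config$geometry_path)
      covariates <<- utils::read.delim(config$covariates_path,
                                       stringsAsFactors = FALSE)
      files <- sort(list.files(config$scans_dir, pattern = "\\.tsv$",
                               full.names = TRUE))
      if (!length(files)) cf_stop("no scan TSVs in %s", config$scans_dir)
      scans <<- lapply(files, function(f) {
        raw <- read_scan(f)
        mask_file <- sub("\\.tsv$", "_fd.tsv", f)
        mask <- if (file.exists(mask_file)) {
          read_frame_mask(mask_file, config$fd_threshold)
        } else NULL
        standardize_scan(raw$values, frame_mask = mask,
                         subject_id = sub("^scan_", "",
                                          sub("\\.tsv$", "", basename(f))))
      })
      names(scans) <<- vapply(scans, `[[`, "", "subject_id")
      NULL
    })
  }

  score_list <- NULL
  if (any(c("score", "trajectories", "alignment", "contrast") %in%
          config$stages)) {
    score_list <- stage("score", {
      lapply(names(scans), function(id)
        score_scan(scans[[id]], n_bins = config$n_bins, subject_id = id))
    })
    names(score_list) <- names(scans)
    for (id in names(score_list)) {
      emit(score_list[[id]], sprintf("scores_%s.tsv", id), write_score_matrix)
    }
    group_map <- group_average_scores(score_list)
    emit(group_map, "scores_group.tsv", write_score_matrix)
  }

  if ("trajectories" %in% config$stages) {
    traj <- stage("trajectories",
                  fit_all_regions(score_list, covariates, k = config$k))
    emit(traj$table, "trajectories.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  if ("alignment" %in% config$stages) {
    al <- stage("alignment", {
      sa_map <- stats::setNames(scale(geometry$sa_rank)[, 1L],
                                geometry$region_id)
      alignment_profile(group_map, sa_map, geometry,
                        n_rotations = config$n_rotations,
                        seed = derive_seed(config$seed, 11L),
                        reference_name = "sa_rank")
    })
    emit(as.data.frame(al), "alignment_profile.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    bs <- bin_similarity(group_map)
    emit(data.frame(bin = bs$bin_labels, cluster = bs$cluster_labels,
                    bs$values, check.names = FALSE),
         "bin_similarity.tsv", function(o, p)
           utils::write.table(o, p, sep = "\t", quote = FALSE,
                              row.names = FALSE))
  }

  if ("contrast" %in% config$stages) {
    ct <- stage("contrast", {
      if (!"simulate" %in% config$stages) {
        cf_stop("the contrast stage requires the simulate stage (paired movie cohort)")
      }
      spec <- config$simulate
      spec$seed <- config$seed
      movie <- generate_cohort(spec, geometry = geometry,
                               condition = "movie")
      movie_scores <- lapply(names(movie$scans), function(id)
        score_scan(movie$scans[[id]], n_bins = config$n_bins,
                   subject_id = id))
      condition_contrast(score_list, movie_scores,
                         bin_range = config$bin_range_high)
    })
    emit(as.data.frame(ct), "contrast_high.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  manifest <- list(
    package = "cofluct",
    version = as.character(utils::packageVersion("cofluct")),
    seed = config$seed,
    n_bins = config$n_bins,
    stages = config$stages,
    artifacts = lapply(stats::setNames(nm = basename(artifacts)), function(f)
      unname(tools::md5sum(file.path(config$out_dir, f)))),
    timings_seconds = timings)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  pipeline_log(verbose, "pipeline complete: %d artifacts in %s",
               length(artifacts), config$out_dir)
  invisible(manifest)
}
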