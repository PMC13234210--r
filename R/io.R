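#' Read one subject's region time-series file
#'
#' Delimited text with a header row of region names and one row per
#' timepoint (rows = timepoints, columns = regions; this orientation is
#' fixed to rule out silent transposition).
#'
#' @param path File path (comma- or tab-delimited; guessed from content).
#' @param tr Repetition time in seconds, attached to the result.
#' @return Timepoints x regions numeric matrix with attribute `"tr"`.
#' @export
read_roi_timeseries <- function(path, tr) {
  d <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  x <- as.matrix(d)
  if (!is.numeric(x)) invalid_config(sprintf("non-numeric values in %s", path))
  attr(x, "tr") <- tr
  x
}

#' Read and validate a cohort manifest
#'
#' The manifest lists one subject per row: `subject_id`, `path` (time-series
#' file, relative paths resolved against the manifest's directory), `group`,
#' `age`, `sex`, `handedness`, and optionally `education`.
#'
#' @param path Manifest file path (delimited text).
#' @param tr Repetition time passed to [read_roi_timeseries()].
#' @param load Read the per-subject time series into a `ts` list-column
#'   (default `TRUE`).
#' @return Tibble with the manifest columns (and `ts` when `load = TRUE`).
#' @export
read_manifest <- function(path, tr, load = TRUE) {
  man <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "path", "group", "age", "sex", "handedness")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols)) {
    invalid_config(sprintf("manifest is missing column(s): %s",
                           paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(man$subject_id)) {
    invalid_config(sprintf(
      "duplicate subject_id in manifest: %s",
      paste(unique(man$subject_id[duplicated(man$subject_id)]), collapse = ", ")
    ))
  }
  if (anyNA(man[required])) {
    bad <- man$subject_id[!complete.cases(man[required])]
    invalid_config(sprintf("missing required covariates for subject(s): %s",
                           paste(bad, collapse = ", ")))
  }
  root <- dirname(path)
  files <- ifelse(file.exists(man$path), man$path, file.path(root, man$path))
  gone <- !file.exists(files)
  if (any(gone)) {
    abort(
      sprintf("time-series file missing for subject(s): %s",
              paste(man$subject_id[gone], collapse = ", ")),
      class = "leidar_io_error"
    )
  }
  man$path <- files
  man <- as_tibble(man)
  if (load) {
    man$ts <- purrr::map(files, read_roi_timeseries, tr = tr)
  }
  man
}

#' Read an atlas membership table
#'
#' @param path Delimited file with columns `region` and `network`.
#' @return Atlas tibble with `network` as a factor in order of first
#'   appearance.
#' @export
read_atlas <- function(path) {
  a <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("region", "network") %in% names(a))) {
    invalid_config("atlas table must have columns 'region' and 'network'")
  }
  a$network <- factor(a$network, levels = unique(a$network))
  as_tibble(a)
}

#' Write a simulated cohort to disk as plain text
#'
#' Writes one CSV per subject (header = region names, rows = timepoints),
#' plus `manifest.csv`, `truth_labels.csv`, `planted_states.csv` and
#' `atlas.csv`, so a simulated cohort round-trips through [read_manifest()].
#'
#' @param cohort A `leida_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "leida_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  paths <- file.path("timeseries", paste0(cohort$subjects$subject_id, ".csv"))
  purrr::walk2(cohort$subjects$ts, paths, function(x, p) {
    readr::write_csv(as.data.frame(x), file.path(dir, p))
  })
  man <- cohort$subjects |>
    select("subject_id", "group", "age", "sex", "handedness", "education") |>
    mutate(path = paths, .after = "subject_id")
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  truth <- cohort$subjects |>
    select("subject_id", "truth_labels") |>
    tidyr::unnest_longer("truth_labels", values_to = "state",
                         indices_to = "volume")
  readr::write_csv(truth, file.path(dir, "truth_labels.csv"))
  readr::write_csv(
    as.data.frame(cohort$states) |> tibble::rownames_to_column("state"),
    file.path(dir, "planted_states.csv")
  )
  readr::write_csv(cohort$atlas, file.path(dir, "atlas.csv"))
  invisible(dir)
}

#' Run the full state-dynamics pipeline
#'
#' End-to-end composition: per-subject eigenvector series, pooling, k-means
#' sweep with Dunn-index selection, occupancy ordering, per-subject dynamic
#' metrics, network mapping (when an atlas is supplied), and the group
#' statistics battery. Deterministic for a fixed seed.
#'
#' @param subjects Subjects tibble (from [read_manifest()] or
#'   `leida_cohort$subjects`) with `subject_id`, `group`, covariates, and a
#'   `ts` list-column; or a `leida_cohort` (its atlas is used when `atlas`
#'   is `NULL`).
#' @param atlas Optional atlas tibble for network mapping.
#' @param tr Repetition time in seconds (defaults to the `"tr"` attribute
#'   of the first subject's matrix).
#' @param low_hz,high_hz,trim_edges Phase-extraction settings.
#' @param k_min,k_max Cluster-number sweep.
#' @param n_restarts k-means restarts per k.
#' @param covariates Covariates for the ANCOVA battery.
#' @param seed Master seed.
#' @return A `leida_run` list: `states` (selected, occupancy-ordered
#'   solution with `$sweep`), `labels` (per-subject streams), `metrics`
#'   (long table), `network` (profiles or `NULL`), `stats`
#'   (`leida_stats` or `NULL` if fewer than 2 groups), `report` (settings,
#'   seed, warnings).
#' @export
run_pipeline <- function(subjects, atlas = NULL, tr = NULL,
                         low_hz = 0.01, high_hz = 0.1, trim_edges = 1,
                         k_min = 5, k_max = 10, n_restarts = 20,
                         covariates = c("age", "sex", "handedness"),
                         seed = 1) {
  if (inherits(subjects, "leida_cohort")) {
    atlas <- atlas %||% subjects$atlas
    subjects <- subjects$subjects
  }
  tr <- tr %||% attr(subjects$ts[[1]], "tr")
  if (is.null(tr)) invalid_config("tr not given and not attached to the data")
  eigs <- cohort_eigenvectors(subjects, tr = tr, low_hz = low_hz,
                              high_hz = high_hz, trim_edges = trim_edges)
  pooled <- pool_eigenvectors(eigs)
  states <- select_k(pooled, k_min = k_min, k_max = k_max,
                     seed = seed, n_restarts = n_restarts)
  states <- order_states(states)
  labels <- subject_labels(states) |>
    left_join(
      subjects |> select(!dplyr::any_of(c("ts", "eig", "labels", "truth_labels", "path"))),
      by = "subject_id"
    )
  metrics <- cohort_metrics(labels, n_states = states$k, tr = tr)
  network <- if (!is.null(atlas)) map_states(states, atlas) else NULL
  stats <- if ("group" %in% names(subjects) &&
               length(unique(subjects$group)) == 2) {
    run_stats_battery(metrics, subjects, covariates = covariates)
  } else {
    NULL
  }
  report <- list(
    n_subjects = nrow(subjects), tr = tr,
    band = c(low_hz, high_hz), trim_edges = trim_edges,
    k_range = c(k_min, k_max), n_restarts = n_restarts, seed = seed,
    selected_k = states$k, dunn = states$dunn,
    sweep = states$sweep,
    undefined_metric_entries = sum(is.na(metrics$value)),
    package_version = as.character(utils::packageVersion("leidar")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(
    list(states = states, labels = labels, metrics = metrics,
         network = network, stats = stats, report = report),
    class = "leida_run"
  )
}

#' Write pipeline results as delimited text plus a JSON run report
#'
#' Full-precision CSV tables with fixed schemas: `centroids.csv` (states x
#' regions), `labels.csv` (subject, volume, state), `k_sweep.csv`,
#' `metrics.csv` (long), `network_profiles.csv`, `stats_states.csv`,
#' `stats_transitions.csv`, and `run_report.json` (settings, seed, selected
#' k, warnings, file checksums).
#'
#' @param run A `leida_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "leida_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    as.data.frame(run$states$centroids) |> tibble::rownames_to_column("state"),
    file.path(dir, "centroids.csv")
  )
  run$labels |>
    select("subject_id", "labels") |>
    tidyr::unnest_longer("labels", values_to = "state", indices_to = "volume") |>
    readr::write_csv(file.path(dir, "labels.csv"))
  readr::write_csv(run$states$sweep, file.path(dir, "k_sweep.csv"))
  readr::write_csv(run$metrics, file.path(dir, "metrics.csv"))
  if (!is.null(run$network)) {
    readr::write_csv(run$network, file.path(dir, "network_profiles.csv"))
  }
  if (!is.null(run$stats)) {
    readr::write_csv(run$stats$states, file.path(dir, "stats_states.csv"))
    readr::write_csv(run$stats$transitions, file.path(dir, "stats_transitions.csv"))
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  report <- run$report
  report$checksums <- as.list(tools::md5sum(files))
  names(report$checksums) <- basename(files)
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.leida_run <- function(x, ...) {
  cat(sprintf(
    "<leida_run> %d subjects, selected k = %d (Dunn %.4g), %d metric rows\n",
    x$report$n_subjects, x$states$k, x$states$dunn, nrow(x$metrics)
  ))
  invisible(x)
}
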