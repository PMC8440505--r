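## End-to-end orchestration: ingest -> features -> clustering -> prescribing
## comparison -> deprivation, with CSV/JSON outputs and a machine-readable
## run summary. Identical config + seed gives byte-identical outputs.

#' Build a pipeline run configuration
#'
#' @param synthetic generate the inputs with [generate_records()] instead of
#'   reading files.
#' @param paths named list of input CSV paths (`dispensing`, `prescribing`,
#'   `sizes`, `coordinates`, `areas`); ignored when `synthetic = TRUE`.
#' @param window_start first month of the 12-month clustering window.
#' @param months number of months to generate in synthetic mode (`>= 12`);
#'   the prescribing series uses every month present in the data.
#' @param k_range candidate k values for the elbow curve (must start at 1).
#' @param seed master seed for every stochastic stage.
#' @param n_init k-means restarts.
#' @param rank_direction deprivation rank convention (see
#'   [assign_quartiles()]).
#' @param alpha significance level for section t-tests.
#' @param out_dir output directory, or NULL to skip writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = FALSE, paths = NULL,
                       window_start = "2018-04", months = 12L,
                       k_range = 1:10, seed = 42L, n_init = 50L,
                       rank_direction = "most_deprived_first",
                       alpha = 0.05, out_dir = NULL) {
  if (!synthetic) {
    need <- c("dispensing", "prescribing", "sizes", "coordinates", "areas")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stop_(sprintf("paths must name all of: %s", paste(need, collapse = ", ")))
    }
  }
  structure(list(synthetic = synthetic, paths = paths,
                 window_start = window_start, months = as.integer(months),
                 k_range = as.integer(k_range), seed = as.integer(seed),
                 n_init = as.integer(n_init),
                 rank_direction = rank_direction, alpha = alpha,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full archetype-discovery pipeline
#'
#' Executes every stage in order: load (or generate) the five input tables,
#' derive the six-feature profiles over the 12-month window, standardise,
#' select k (elbow corroborated by silhouette -- silhouette wins on
#' disagreement), fit k-means, label the clusters by population density,
#' summarise centroids, project with PCA, summarise pharmacy dispersion,
#' compare prescribing by chapter/section RMSE, run chapter-4 section
#' t-tests, and cross-tabulate deprivation quartiles. Any stage error aborts
#' the run with the stage name.
#'
#' @param config a [run_config()].
#' @return A list of all stage outputs plus `summary` (the JSON-ready run
#'   summary), invisibly writing CSV/JSON files when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  inputs <- stage("ingest", {
    if (config$synthetic) {
      cohort <- generate_records(months = config$months, seed = config$seed,
                                 start_month = config$window_start)
      cohort[c("dispensing", "prescribing", "sizes", "coordinates", "areas")]
    } else {
      list(dispensing = read_dispensing(config$paths$dispensing),
           prescribing = read_prescribing(config$paths$prescribing),
           sizes = read_practice_sizes(config$paths$sizes),
           coordinates = load_coordinate_lookup(config$paths$coordinates),
           areas = read_area_attributes(config$paths$areas))
    }
  })
  coords <- stage("coordinates", load_coordinate_lookup(inputs$coordinates))
  window <- ym_seq(config$window_start, 12L)

  profiles <- stage("features", build_practice_profiles(
    inputs$dispensing, inputs$sizes, coords, inputs$areas, window))

  std <- stage("standardise", standardise(profiles))
  inertias <- stage("inertia_curve", inertia_curve(
    std$X, config$k_range, seed = config$seed, n_init = config$n_init))
  k_elbow <- stage("elbow", select_k_elbow(inertias))
  sil_range <- config$k_range[config$k_range >= 2L &
                                config$k_range <= nrow(std$X) - 1L]
  sil <- stage("silhouette", {
    D <- dist(std$X)
    vapply(sil_range, function(k) {
      fit <- fit_kmeans(std$X, k, seed = derive_seed(config$seed, k),
                        n_init = config$n_init)
      mean(cluster::silhouette(fit$assignments, D)[, "sil_width"])
    }, numeric(1))
  })
  k_sil <- sil_range[which.max(sil)]
  k_chosen <- if (k_elbow == k_sil) k_elbow else k_sil  # silhouette arbitrates

  model <- stage("kmeans", fit_kmeans(std$X, k_chosen,
                                      seed = derive_seed(config$seed, 999L),
                                      n_init = config$n_init))
  two_clusters <- model$k == 2L
  if (two_clusters) {
    model <- stage("labelling", label_clusters(model, std$params))
  } else {
    warning("chosen k != 2: density labels and two-cluster comparisons skipped",
            call. = FALSE)
  }
  assignments <- assignment_table(model)
  centroids <- stage("centroids", centroid_summary(model, std$params,
                                                   profiles))
  pca <- stage("pca", pca_project(std$X))
  dispersion <- stage("dispersion", {
    disp <- practice_dispersion(inputs$dispensing[year_month %in% window],
                                coords)
    cluster_dispersion_summary(assignments[, .(practice_id, label)], disp)
  })

  cleaned <- stage("clean_bnf", clean_bnf(inputs$prescribing))
  series_total <- stage("series", monthly_cluster_series(
    cleaned$records, inputs$sizes, assignments, "total"))
  if (two_clusters) {
    chapter_rmse <- stage("chapter_rmse", chapter_rmse_ranking(
      cleaned$records, inputs$sizes, assignments))
    section_rmse <- stage("section_rmse", section_rmse_ranking(
      cleaned$records, inputs$sizes, assignments, chapter = 4L))
    ttests <- stage("ttests", section_ttests(
      cleaned$records, inputs$sizes, assignments, chapter = 4L,
      alpha = config$alpha))
  } else {
    chapter_rmse <- section_rmse <- ttests <- NULL
  }

  deprivation <- stage("deprivation", {
    wards <- inputs$areas[, .(ward_code = location_code, deprivation_rank)]
    quartiles <- assign_quartiles(wards, config$rank_direction)
    practice_wards <- inputs$areas[, .(practice_id = location_code,
                                       ward_code = location_code)]
    crosstab <- deprivation_crosstab(assignments, practice_wards, quartiles)
    overall <- overall_row(crosstab, crosstab$n)
    list(crosstab = crosstab, overall = overall)
  })

  summary <- list(
    seed = config$seed,
    window = window,
    n_practices = nrow(profiles),
    k_elbow = k_elbow,
    k_silhouette = k_sil,
    k_chosen = k_chosen,
    inertia = model$inertia,
    excluded_bnf_fraction = cleaned$excluded_fraction,
    cluster_sizes = as.list(table(assignments$label)),
    package_version = as.character(utils::packageVersion("gparchetypes")))

  result <- list(profiles = profiles, standardisation = std$params,
                 k_selection = data.table(k = as.integer(names(inertias)),
                                          inertia = as.numeric(inertias)),
                 silhouette = data.table(k = sil_range,
                                         mean_silhouette = sil),
                 model = model, assignments = assignments,
                 centroids = centroids, pca = pca, dispersion = dispersion,
                 series_total = series_total, chapter_rmse = chapter_rmse,
                 section_rmse = section_rmse, ttests = ttests,
                 deprivation = deprivation, summary = summary)

  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  invisible(result)
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(x, name) fwrite(x, file.path(out_dir, name))
  out(result$assignments, "assignments.csv")
  out(result$centroids, "centroids.csv")
  ksel <- merge(result$k_selection,
                result$silhouette, by = "k", all.x = TRUE)
  out(ksel, "k_selection.csv")
  pca_dt <- data.table(practice_id = rownames(result$pca$scores),
                       pc1 = result$pca$scores[, 1],
                       pc2 = result$pca$scores[, 2])
  pca_dt <- merge(pca_dt, result$assignments[, .(practice_id, label)],
                  by = "practice_id")
  out(pca_dt, "pca.csv")
  out(result$dispersion, "dispersion.csv")
  out(result$series_total, "series_total.csv")
  if (!is.null(result$chapter_rmse)) {
    out(result$chapter_rmse, "rmse_by_chapter.csv")
    out(result$section_rmse, "rmse_chapter4_sections.csv")
    out(result$ttests, "ttests_chapter4.csv")
  }
  dep <- copy(result$deprivation$crosstab)
  qcols <- paste0("Q", 1:4)
  dep[, (qcols) := lapply(.SD, round, 1L), .SDcols = qcols]
  all_row <- data.table(label = "All practices",
                        t(round(result$deprivation$overall, 1)),
                        n = sum(result$deprivation$crosstab$n))
  out(rbind(dep, all_row, use.names = TRUE), "deprivation_table.csv")
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
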