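# Pipeline orchestration: simulate -> filter -> occupancy -> activity ->
# diet -> models, with stage outputs written as CSV/GeoJSON/JSON so each
# stage is independently re-runnable.

pipeline_schema <- c("simulate", "seed", "out_dir", "crs",
                     "window_minutes", "camera_rule", "repro_threshold_m",
                     "cell_size", "periods", "bootstrap_B",
                     "brillouin_orderings", "collinearity_threshold",
                     "occurrences_csv", "detections_csv", "scats_csv",
                     "covariates_csv")

#' Assemble and validate a pipeline configuration
#'
#' Either pass a YAML file path or named arguments.  Unknown keys are
#' rejected so typos fail fast rather than silently falling back to a
#' default.
#'
#' @param yaml_path optional YAML file with any of the documented keys.
#' @param ... key = value overrides (applied after the YAML).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(yaml_path = NULL, ...) {
  cfg <- list(simulate = TRUE, seed = 1, out_dir = tempfile("wolfmon_run_"),
              crs = "unspecified", window_minutes = 30,
              camera_rule = "rolling", repro_threshold_m = 20000,
              cell_size = 10000,
              periods = list(c("2015-2019", 2015, 2019),
                             c("2020-2024", 2020, 2024)),
              bootstrap_B = 1000, brillouin_orderings = 100,
              collinearity_threshold = 0.7,
              occurrences_csv = NULL, detections_csv = NULL,
              scats_csv = NULL, covariates_csv = NULL)
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    unknown <- setdiff(names(y), pipeline_schema)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(y)] <- y
  }
  over <- list(...)
  unknown <- setdiff(names(over), pipeline_schema)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(unclass(cfg)))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full monitoring pipeline
#'
#' Executes every analysis stage in order and writes per-stage outputs to
#' \code{config$out_dir}: filtered occurrences and detections (CSV), the
#' classified grid (CSV + GeoJSON), the occupancy summary, pairwise
#' overlap coefficients with classes, the diet FO table with bootstrap
#' CIs and the Brillouin curve, the model ranking and averaged
#' coefficients, and a JSON run report stamped with the config hash.
#' With \code{simulate = TRUE} all inputs come from
#' \code{\link{simulate_inputs}} under the configured seed; otherwise the
#' four input CSV paths must be supplied.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with every stage result and \code{out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  periods <- lapply(config$periods, function(p)
    period(p[[1]], as.integer(p[[2]]), as.integer(p[[3]])))

  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", simulate_inputs(sim_config(
      seed = config$seed, cell_size = config$cell_size)))
    grid <- sim$grid; occ <- sim$occurrences; det <- sim$detections
    scats <- sim$scats; cov <- sim$covariates
  } else {
    occ <- stage("load", read_occurrences(config$occurrences_csv,
                                          crs = config$crs))
    det <- stage("load", utils::read.csv(config$detections_csv,
                                         stringsAsFactors = FALSE))
    scats <- stage("load", read_scats(config$scats_csv))
    cov <- stage("load", utils::read.csv(config$covariates_csv,
                                         stringsAsFactors = FALSE))
    grid <- stage("grid", build_grid(min(occ$x), min(occ$y),
                                     max(occ$x) + 1, max(occ$y) + 1,
                                     config$cell_size))
  }

  # --- filter stage
  filtered <- stage("filter", daily_independence(filter_scalp(occ)))
  det_ind <- stage("filter", camera_independence(
    det, config$window_minutes, rule = config$camera_rule))
  utils::write.csv(as.data.frame(filtered),
                   file.path(config$out_dir, "occurrences_filtered.csv"),
                   row.names = FALSE)
  utils::write.csv(det_ind,
                   file.path(config$out_dir, "detections_independent.csv"),
                   row.names = FALSE)

  # --- occupancy stage
  repro <- stage("occupancy", cluster_reproductions(
    filtered, config$repro_threshold_m))
  statuses <- stage("occupancy", classify_grid(grid, filtered, periods,
                                               repro))
  occ_sum <- stage("occupancy", summarize_occupancy(statuses))
  utils::write.csv(statuses, file.path(config$out_dir,
                                       "cell_statuses.csv"),
                   row.names = FALSE)
  write_grid_geojson(grid, statuses,
                     file.path(config$out_dir, "grid.geojson"),
                     crs_label = config$crs)

  # --- activity stage
  overlaps <- stage("activity", {
    sp <- unique(det_ind$species)
    out <- list()
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
      if (j <= i) next
      s1 <- detection_series(sp[i], "all",
                             time_to_angle(as.POSIXct(
                               det_ind$timestamp[det_ind$species == sp[i]],
                               tz = "UTC")))
      s2 <- detection_series(sp[j], "all",
                             time_to_angle(as.POSIXct(
                               det_ind$timestamp[det_ind$species == sp[j]],
                               tz = "UTC")))
      ov <- suppressWarnings(delta4(s1, s2))
      out[[length(out) + 1L]] <- data.frame(
        species1 = sp[i], species2 = sp[j], n1 = ov$n1, n2 = ov$n2,
        delta4 = ov$delta4, delta1 = ov$delta1, class = ov$class,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  utils::write.csv(overlaps, file.path(config$out_dir, "overlap.csv"),
                   row.names = FALSE)
  rai_tab <- stage("activity", {
    eff <- stats::aggregate(list(detections = det_ind$species),
                            by = list(site = det_ind$site,
                                      species = det_ind$species), length)
    sites <- sim_config(seed = config$seed)$sites
    eff$trap_nights <- sites$trap_nights[match(eff$site, sites$site)]
    eff <- eff[!is.na(eff$trap_nights), , drop = FALSE]
    eff$rai <- rai(eff$detections, eff$trap_nights)
    eff
  })
  utils::write.csv(rai_tab, file.path(config$out_dir, "rai.csv"),
                   row.names = FALSE)

  # --- diet stage
  fo <- stage("diet", bootstrap_fo_ci(scats, B = config$bootstrap_B,
                                      seed = child_seed(config$seed, 5)))
  fo_items <- stage("diet", bootstrap_fo_ci(
    scats, B = config$bootstrap_B, level = "item",
    seed = child_seed(config$seed, 6)))
  curve <- stage("diet", min_sample_size(
    scats, orderings = config$brillouin_orderings,
    seed = child_seed(config$seed, 7)))
  utils::write.csv(rbind(cbind(level = "category", fo),
                         cbind(level = "item", fo_items)),
                   file.path(config$out_dir, "diet_fo.csv"),
                   row.names = FALSE)

  # --- model stage: Permanent (1) vs Sporadic (0) cells, last period
  models <- stage("models", {
    last_p <- periods[[length(periods)]]$label
    st <- statuses[statuses$period == last_p &
                   statuses$status != "Absent", , drop = FALSE]
    tab <- merge(st[c("cell_id", "status")], cov, by = "cell_id")
    tab$status <- as.integer(tab$status == "Permanent")
    if (length(unique(tab$status)) < 2L)
      stop("need both Permanent and Sporadic cells to model status")
    select_status_models(tab, config$collinearity_threshold)
  })
  rt <- models$ranking$table
  utils::write.csv(rt, file.path(config$out_dir, "model_ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(term = names(models$averaged),
                              estimate = as.numeric(models$averaged)),
                   file.path(config$out_dir, "model_averaged.csv"),
                   row.names = FALSE)

  report <- list(
    config_hash = hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("wolfmon")),
    n_occurrences_raw = nrow(occ), n_occurrences_filtered = nrow(filtered),
    n_detections_independent = nrow(det_ind),
    occupancy = list(counts = occ_sum$counts,
                     net_increase = as.list(occ_sum$net_increase)),
    overlap = overlaps,
    diet = list(fo_categories = fo,
                min_sample = curve$min_sample,
                stabilized = curve$stabilized),
    models = list(retained = models$retained,
                  best = rt$model[1], best_weight = rt$weight[1],
                  n_models = nrow(rt),
                  n_competitors = sum(rt$competitor)))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(list(out_dir = config$out_dir, filtered = filtered,
                 detections = det_ind, reproductions = repro,
                 statuses = statuses, occupancy = occ_sum,
                 overlaps = overlaps, rai = rai_tab, fo = fo,
                 fo_items = fo_items, brillouin = curve, models = models,
                 report = report))
}
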