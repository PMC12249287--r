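# Synthetic inputs with the statistical structure the analysis assumes:
# covariates on a planar grid, occupancy linked to covariates through a
# logistic model, von Mises mixture detection times, multinomial scat
# contents.  One master seed fans out to per-module child seeds so each
# stage can be regenerated independently.

#' Derive a reproducible child seed from a master seed
#'
#' Child seeds are drawn by seeding the base RNG with the master seed and
#' taking the \code{index}-th value of a fixed integer stream, so the k-th
#' module always sees the same seed for a given master seed regardless of
#' what ran before it.
#'
#' @param master integer master seed.
#' @param index positive integer position in the stream (one per module).
#' @return An integer seed in \code{[1, 2^31 - 2]}.
#' @export
child_seed <- function(master, index) {
  stopifnot(index >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, index)[index]
}

#' Simulation configuration with field-realistic defaults
#'
#' Default magnitudes approximate a small recolonizing wolf population
#' monitored over a flat 4000-km2 peninsula: a 10-km grid over a
#' 90 x 50 km extent, two five-year periods, three camera sites totalling
#' about 1400 trap-nights, 75 scats, and covariate ranges typical of a
#' human-dominated Mediterranean landscape (road density 1.4-5.9 km/km2,
#' 7-40 forest patches per cell).
#'
#' @param seed master seed.
#' @param ... overrides for any listed component.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    extent = c(min_x = 700000, min_y = 4400000,
               max_x = 790000, max_y = 4450000),
    cell_size = 10000,
    periods = list(period("2015-2019", 2015, 2019),
                   period("2020-2024", 2020, 2024)),
    # occupancy model: logit(P(Permanent)) = b0 + b %*% scaled covariates
    beta = c(intercept = 0, road_density = -0.4, n_farms = 0.2,
             pa_perc = 0.3, forest_perc = 0.4, forest_count = 1.2),
    covariate_ranges = list(road_density = c(1.36, 5.88),
                            n_farms = c(0, 36), pa_perc = c(0, 8.3),
                            forest_perc = c(0.7, 36.7),
                            forest_count = c(7, 40)),
    scalp_probs = c(C1 = 0.85, C2 = 0.08, C3 = 0.07),
    mean_records_base = 1.2,     # Poisson mean per occupied cell-year
    mean_records_span = 6,       # added at the top of the logistic score
    year_trend = 0.35,           # logit increase per year: recolonization
    activity_presets = list(
      wolf = list(means_h = c(22, 4), kappa = c(2, 2), w = c(0.5, 0.5)),
      red_fox = list(means_h = c(23, 5), kappa = c(1.8, 1.8),
                     w = c(0.5, 0.5)),
      badger = list(means_h = c(0, 3), kappa = c(2.5, 2.5),
                    w = c(0.5, 0.5)),
      human = list(means_h = c(10, 16), kappa = c(3, 3), w = c(0.6, 0.4)),
      diurnal = list(means_h = c(12), kappa = c(2), w = c(1))),
    sites = data.frame(site = c("Site 1", "Site 2", "Site 3"),
                       trap_nights = c(732, 480, 190),
                       stringsAsFactors = FALSE),
    n_scats = 75,
    scat_item_probs = c(sheep = 0.21, dog = 0.17, red_fox = 0.12,
                        bird = 0.12, goat = 0.08, cat = 0.06,
                        hare = 0.06, wild_boar = 0.05, rodent = 0.05,
                        fruit = 0.05, other = 0.03),
    items_per_scat = c(`1` = 0.55, `2` = 0.3, `3` = 0.15),
    scat_months = c("2024-06-01", "2024-12-31"))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Simulate the per-cell covariate table
#'
#' Uniform draws within the configured ranges, plus a derived
#' \code{forest_area} (km2) proportional to \code{forest_perc} with
#' multiplicative noise, which reproduces the strong collinearity between
#' forest area and forest percentage that the screening step is meant to
#' catch.
#'
#' @param grid a \code{\link{build_grid}} result.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer; defaults to the config's child seed for this stage.
#' @return Data frame: \code{cell_id} plus one column per covariate.
#' @export
gen_covariates <- function(grid, config = sim_config(),
                           seed = child_seed(config$seed, 1)) {
  set.seed(seed)
  n <- nrow(grid)
  out <- data.frame(cell_id = grid$cell_id, stringsAsFactors = FALSE)
  for (v in names(config$covariate_ranges)) {
    r <- config$covariate_ranges[[v]]
    x <- stats::runif(n, r[1], r[2])
    if (v %in% c("n_farms", "forest_count")) x <- round(x)
    out[[v]] <- x
  }
  cell_km2 <- (config$cell_size / 1000)^2
  out$forest_area <- out$forest_perc / 100 * cell_km2 *
    exp(stats::rnorm(n, 0, 0.1))
  out
}

# standardized logistic score of a covariate table under config$beta
logistic_score <- function(covariates, beta) {
  vars <- setdiff(names(beta), "intercept")
  eta <- rep(beta[["intercept"]], nrow(covariates))
  for (v in vars) {
    x <- covariates[[v]]
    eta <- eta + beta[[v]] * as.numeric(scale(x))
  }
  eta
}

#' Simulate occurrence records over the grid
#'
#' Each cell-year draws a Poisson number of records whose mean increases
#' with the cell's logistic occupancy score, so cells favoured by the
#' covariates accumulate the evidence that the classification rules reward.
#' A positive \code{year_trend} raises cell-year occupancy probability
#' along the study, emulating a recolonization front: later periods have
#' more occupied and more Permanent cells.
#' SCALP codes are assigned with the configured proportions, record
#' locations are uniform within their cell, and reproduction flags are
#' placed in the highest-scoring cells in the later years.
#'
#' @param grid a \code{monitor_grid}.
#' @param covariates the matching \code{\link{gen_covariates}} table.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer; defaults to the stage child seed.
#' @return An \code{occurrence_records} data frame.
#' @export
gen_occurrences <- function(grid, covariates, config = sim_config(),
                            seed = child_seed(config$seed, 2)) {
  set.seed(seed)
  eta <- logistic_score(covariates, config$beta)
  years <- min(vapply(config$periods, `[[`, numeric(1), "start_year")):
           max(vapply(config$periods, `[[`, numeric(1), "end_year"))
  # recolonization: cell-year occupancy probability rises along the study
  mid <- mean(range(years))
  p_cy <- function(yr) stats::plogis(eta + config$year_trend * (yr - mid))
  p <- stats::plogis(eta)
  size <- attr(grid, "cell_size")
  rows <- list()
  rid <- 0L
  n_repro_cells <- max(2L, round(nrow(grid) / 15))
  repro_cells <- grid$cell_id[order(-p)][seq_len(n_repro_cells)]
  for (ci in seq_len(nrow(grid))) {
    lambda <- config$mean_records_base + config$mean_records_span * p[ci]
    # sparse occupancy: a cell is reachable only with probability p
    for (yr in years) {
      if (stats::runif(1) > p_cy(yr)[ci]) next
      n <- stats::rpois(1, lambda)
      if (n == 0) next
      scalp <- sample(names(config$scalp_probs), n, replace = TRUE,
                      prob = config$scalp_probs)
      dates <- as.Date(sprintf("%d-01-01", yr)) +
        sample.int(365, n, replace = TRUE) - 1L
      is_rep <- grid$cell_id[ci] %in% repro_cells &
        yr >= max(years) - 3L & scalp == "C1" &
        stats::runif(n) < 0.15
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = sprintf("occ%06d", rid + seq_len(n)),
        date = dates,
        x = grid$min_x[ci] + stats::runif(n) * size,
        y = grid$min_y[ci] + stats::runif(n) * size,
        source = sample(c("carcass", "depredation", "camera",
                          "observation", "scat"), n, replace = TRUE),
        scalp = scalp,
        area_id = grid$cell_id[ci],
        is_reproduction = is_rep,
        stringsAsFactors = FALSE)
      rid <- rid + n
    }
  }
  d <- do.call(rbind, rows)
  occurrence_records(d$record_id, d$date, d$x, d$y, d$source, d$scalp,
                     d$area_id, d$is_reproduction, crs = "synthetic-utm")
}

#' Simulate diel detection times from a von Mises mixture
#'
#' @param n number of detections.
#' @param mixture list with \code{means_h} (component means, hours),
#'   \code{kappa} (concentrations) and \code{w} (mixing weights summing to
#'   1), or the name of a preset in the config
#'   (\code{"wolf"}, \code{"red_fox"}, \code{"badger"}, \code{"human"},
#'   \code{"diurnal"}).
#' @param seed integer seed.
#' @param config a \code{\link{sim_config}} (used only for presets).
#' @param species,site labels for the returned series.
#' @return A \code{\link{detection_series}}.
#' @export
gen_activity <- function(n, mixture = "wolf", seed = 1,
                         config = sim_config(), species = NULL,
                         site = "sim") {
  if (is.character(mixture)) {
    if (is.null(species)) species <- mixture
    mixture <- config$activity_presets[[mixture]]
    if (is.null(mixture)) stop("unknown activity preset")
  }
  if (is.null(species)) species <- "sim"
  if (abs(sum(mixture$w) - 1) > 1e-8)
    stop("mixture weights must sum to 1")
  set.seed(seed)
  comp <- sample.int(length(mixture$w), n, replace = TRUE,
                     prob = mixture$w)
  times <- vapply(comp, function(k)
    rvonmises(1, time_to_angle(mixture$means_h[k]), mixture$kappa[k]),
    numeric(1))
  detection_series(species, site, times %% (2 * pi))
}

#' Simulate scat contents
#'
#' Each scat draws its number of items from the configured distribution,
#' then draws that many distinct items without replacement with
#' probabilities proportional to the configured item frequencies.
#' Collection dates are uniform over the configured window.
#'
#' @param n number of scats.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer; defaults to the stage child seed.
#' @return A \code{\link{scat_records}} data frame.
#' @export
gen_scats <- function(n = sim_config()$n_scats, config = sim_config(),
                      seed = child_seed(config$seed, 4)) {
  probs <- config$scat_item_probs
  if (any(probs < 0) || sum(probs) <= 0) stop("invalid item probabilities")
  set.seed(seed)
  k_dist <- config$items_per_scat
  ks <- sample(as.integer(names(k_dist)), n, replace = TRUE, prob = k_dist)
  ks <- pmin(ks, sum(probs > 0))
  items <- lapply(ks, function(k)
    sample(names(probs), k, replace = FALSE, prob = probs))
  window <- as.Date(config$scat_months)
  dates <- window[1] + sample.int(as.integer(diff(window)) + 1L, n,
                                  replace = TRUE) - 1L
  scat_records(sprintf("scat%03d", seq_len(n)), dates, items)
}

#' Simulate camera-trap detection logs
#'
#' Per site and species, detection counts proportional to the site's
#' trap-nights are drawn and given timestamps whose time of day follows
#' the species' activity preset, with dates uniform over a two-year
#' window.  The raw log intentionally contains short bursts so the
#' 30-minute independence filter has work to do.
#'
#' @param config a \code{\link{sim_config}}.
#' @param species character vector of preset names to include.
#' @param rate expected raw detections per trap-night and species.
#' @param burst_prob probability a detection is followed by a burst image
#'   within the independence window.
#' @param seed integer; defaults to the stage child seed.
#' @return Data frame: \code{site}, \code{species}, \code{timestamp}.
#' @export
gen_detections <- function(config = sim_config(),
                           species = c("wolf", "red_fox", "badger",
                                       "human"),
                           rate = 0.35, burst_prob = 0.3,
                           seed = child_seed(config$seed, 3)) {
  set.seed(seed)
  rows <- list()
  start <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  for (si in seq_len(nrow(config$sites))) {
    for (sp in species) {
      n <- stats::rpois(1, rate * config$sites$trap_nights[si])
      if (n == 0) next
      days <- sample.int(730, n, replace = TRUE) - 1L
      ang <- gen_activity(n, sp, seed = stats::runif(1, 1, 2^30),
                          config = config)$times
      secs <- ang / (2 * pi) * 86400
      ts <- start + days * 86400 + secs
      burst <- stats::runif(n) < burst_prob
      extra <- ts[burst] + stats::runif(sum(burst), 30, 900)
      rows[[length(rows) + 1L]] <- data.frame(
        site = config$sites$site[si], species = sp,
        timestamp = c(ts, extra), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$site, out$species, out$timestamp), , drop = FALSE]
}

#' Simulate every pipeline input at once
#'
#' Builds the grid and generates covariates, occurrence records, camera
#' detections and scats from one master seed via the child-seed rule.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List: \code{grid}, \code{covariates}, \code{occurrences},
#'   \code{detections}, \code{scats}, \code{config}.
#' @export
simulate_inputs <- function(config = sim_config()) {
  e <- config$extent
  grid <- build_grid(e["min_x"], e["min_y"], e["max_x"], e["max_y"],
                     config$cell_size)
  cov <- gen_covariates(grid, config)
  occ <- gen_occurrences(grid, cov, config)
  det <- gen_detections(config)
  scats <- gen_scats(config$n_scats, config)
  list(grid = grid, covariates = cov, occurrences = occ,
       detections = det, scats = scats, config = config)
}
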