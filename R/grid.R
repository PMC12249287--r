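#' Build a square monitoring grid over a planar extent
#'
#' Cells are axis-aligned squares of side \code{cell_size} metres (default
#' 10 km, the standard mapping resolution for wolf distribution).  The grid
#' origin defaults to the extent's lower-left corner snapped down to a
#' \code{cell_size} lattice, so independently built grids over overlapping
#' extents share cell boundaries; pass \code{snap_origin = FALSE} to anchor
#' exactly at \code{(min_x, min_y)}.  Cells use half-open intervals
#' \code{[min, min + size)} on both axes, so every point maps to exactly one
#' cell.
#'
#' @param min_x,min_y,max_x,max_y extent in metres (projected CRS).
#' @param cell_size cell side in metres; must be positive.
#' @param snap_origin snap the origin down to the cell-size lattice.
#' @return A data frame of class \code{monitor_grid} with columns
#'   \code{cell_id}, \code{row}, \code{col}, \code{min_x}, \code{min_y} and
#'   attribute \code{cell_size}.
#' @export
build_grid <- function(min_x, min_y, max_x, max_y, cell_size = 10000,
                       snap_origin = TRUE) {
  if (cell_size <= 0) stop("cell_size must be positive")
  min_x <- unname(min_x); min_y <- unname(min_y)
  max_x <- unname(max_x); max_y <- unname(max_y)
  if (max_x <= min_x || max_y <= min_y) stop("extent must have positive span")
  ox <- if (snap_origin) floor(min_x / cell_size) * cell_size else min_x
  oy <- if (snap_origin) floor(min_y / cell_size) * cell_size else min_y
  ncol <- ceiling((max_x - ox) / cell_size)
  nrow <- ceiling((max_y - oy) / cell_size)
  g <- expand.grid(col = seq_len(ncol) - 1L, row = seq_len(nrow) - 1L)
  out <- data.frame(cell_id = sprintf("r%02dc%02d", g$row, g$col),
                    row = g$row, col = g$col,
                    min_x = ox + g$col * cell_size,
                    min_y = oy + g$row * cell_size,
                    stringsAsFactors = FALSE)
  attr(out, "cell_size") <- cell_size
  attr(out, "origin") <- c(x = ox, y = oy)
  class(out) <- c("monitor_grid", "data.frame")
  out
}

#' Map point coordinates to grid cells
#'
#' Uses the grid's half-open cell convention: a point lying exactly on a
#' shared edge belongs to the cell whose minimum edge it equals.
#'
#' @param grid a \code{monitor_grid}.
#' @param x,y coordinates in metres.
#' @return Character vector of \code{cell_id}s (\code{NA} outside the grid).
#' @export
assign_cell <- function(grid, x, y) {
  size <- attr(grid, "cell_size")
  org <- attr(grid, "origin")
  col <- floor((x - org["x"]) / size)
  row <- floor((y - org["y"]) / size)
  id <- sprintf("r%02dc%02d", row, col)
  id[!id %in% grid$cell_id] <- NA_character_
  id
}

#' Define an analysis period
#'
#' @param label period label, e.g. \code{"2015-2019"}.
#' @param start_year,end_year first and last calendar year, inclusive.
#' @return A list of class \code{monitor_period}.
#' @export
period <- function(label, start_year, end_year) {
  if (end_year < start_year) stop("end_year before start_year")
  structure(list(label = label, start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 length_years = as.integer(end_year - start_year + 1L)),
            class = "monitor_period")
}

#' Classify one grid cell's occupancy status in a period
#'
#' Statuses follow the evidence-threshold rules used for wolf distribution
#' mapping.  A \emph{qualifying year} is a calendar year with at least one
#' C1 record or at least two C2 records in the cell; a \emph{presence year}
#' has at least one C1-or-C2 record.  The cell is
#' \describe{
#'   \item{Permanent}{when the number of qualifying years is at least half
#'     the period length (\code{ceiling(length_years/2)}, i.e. 3 of 5), or a
#'     reproduction event occurred in the cell within the last three
#'     calendar years of the period;}
#'   \item{Sporadic}{otherwise, when at least one presence year exists;}
#'   \item{Absent}{when no record at all was collected.}
#' }
#' Records must already be SCALP-filtered (no C3) and independence-filtered,
#' and must fall inside the period: out-of-period records are an error so
#' that accidental mis-slicing is caught rather than silently ignored.
#'
#' @param records_in_cell \code{occurrence_records} rows located in the cell.
#' @param period a \code{\link{period}} object.
#' @param reproduction_events optional \code{reproduction_events} rows
#'   already restricted to this cell (only their \code{year} is used).
#' @return A one-row data frame: \code{status}, \code{qualifying_years},
#'   \code{presence_years}, \code{reproduction_recent}.
#' @export
classify_cell <- function(records_in_cell, period,
                          reproduction_events = NULL) {
  recs <- records_in_cell
  if (nrow(recs) && any(recs$scalp == "C3"))
    stop("records must be SCALP-filtered before classification")
  yrs <- if (nrow(recs)) as.integer(format(recs$date, "%Y")) else integer()
  if (length(yrs) && (any(yrs < period$start_year) ||
                      any(yrs > period$end_year)))
    stop("records outside period ", period$label,
         "; slice records per period before calling classify_cell")
  c1 <- table(factor(yrs[recs$scalp == "C1"]))
  c2 <- table(factor(yrs[recs$scalp == "C2"]))
  all_years <- union(names(c1), names(c2))
  qualifying <- sum(vapply(all_years, function(y) {
    (!is.na(c1[y]) && c1[y] >= 1) || (!is.na(c2[y]) && c2[y] >= 2)
  }, logical(1)))
  presence <- length(unique(yrs))
  repro_recent <- FALSE
  if (!is.null(reproduction_events) && nrow(reproduction_events)) {
    recent <- (period$end_year - 2L):period$end_year
    repro_recent <- any(reproduction_events$year %in% recent)
  }
  status <- if (qualifying >= ceiling(period$length_years / 2) ||
                repro_recent) "Permanent"
            else if (presence >= 1L) "Sporadic"
            else "Absent"
  data.frame(status = status, qualifying_years = qualifying,
             presence_years = presence, reproduction_recent = repro_recent,
             stringsAsFactors = FALSE)
}

#' Classify every grid cell in every period
#'
#' Convenience wrapper slicing records and reproduction events by cell and
#' period and applying \code{\link{classify_cell}} to each combination.
#'
#' @param grid a \code{monitor_grid}.
#' @param records SCALP- and independence-filtered \code{occurrence_records}.
#' @param periods list of \code{\link{period}} objects.
#' @param reproduction_events optional \code{reproduction_events} table; each
#'   event is located in the cell containing its centroid.
#' @return Data frame of class \code{cell_statuses}: one row per cell and
#'   period with \code{cell_id}, \code{period}, \code{status},
#'   \code{qualifying_years}, \code{presence_years},
#'   \code{reproduction_recent}.
#' @export
classify_grid <- function(grid, records, periods,
                          reproduction_events = NULL) {
  rec_cell <- assign_cell(grid, records$x, records$y)
  rec_year <- as.integer(format(records$date, "%Y"))
  ev_cell <- if (!is.null(reproduction_events) && nrow(reproduction_events))
    assign_cell(grid, reproduction_events$x, reproduction_events$y)
    else character()
  out <- vector("list", nrow(grid) * length(periods))
  k <- 0L
  for (p in periods) {
    in_p <- !is.na(rec_cell) & rec_year >= p$start_year &
            rec_year <= p$end_year
    for (i in seq_len(nrow(grid))) {
      cid <- grid$cell_id[i]
      recs <- records[in_p & rec_cell == cid, , drop = FALSE]
      evs <- if (length(ev_cell))
        reproduction_events[ev_cell == cid &
                            reproduction_events$year >= p$start_year &
                            reproduction_events$year <= p$end_year, ,
                            drop = FALSE] else NULL
      st <- classify_cell(recs, p, evs)
      k <- k + 1L
      out[[k]] <- cbind(data.frame(cell_id = cid, period = p$label,
                                   stringsAsFactors = FALSE), st)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cell_statuses", "data.frame")
  res
}

#' Summarize occupancy change between periods
#'
#' Counts Permanent, Sporadic and total occupied (Permanent + Sporadic)
#' cells per period and reports the net percentage change between the first
#' and last period: \code{100 * (count2 - count1) / count1}.  When a first-
#' period count is zero the change is undefined and reported as \code{NaN}
#' with a warning.
#'
#' @param statuses a \code{cell_statuses} data frame (>= 2 periods).
#' @return A list of class \code{occupancy_summary}: \code{counts} (one row
#'   per period) and \code{net_increase} (percentages for permanent,
#'   sporadic and total occupied).
#' @export
summarize_occupancy <- function(statuses) {
  per <- unique(statuses$period)
  if (length(per) < 2L) stop("need at least two periods")
  counts <- do.call(rbind, lapply(per, function(p) {
    s <- statuses$status[statuses$period == p]
    data.frame(period = p,
               n_permanent = sum(s == "Permanent"),
               n_sporadic = sum(s == "Sporadic"),
               n_occupied = sum(s != "Absent"),
               stringsAsFactors = FALSE)
  }))
  pct <- function(a, b) {
    if (a == 0) { warning("first-period count is zero; increase undefined")
                  return(NaN) }
    100 * (b - a) / a
  }
  first <- counts[1, ]; last <- counts[nrow(counts), ]
  net <- c(permanent = pct(first$n_permanent, last$n_permanent),
           sporadic = pct(first$n_sporadic, last$n_sporadic),
           occupied = pct(first$n_occupied, last$n_occupied))
  structure(list(counts = counts, net_increase = net),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat("Grid occupancy by period:\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf(paste0("Net change %s -> %s:  Permanent %+.1f%%,",
                     "  Sporadic %+.1f%%,  Occupied %+.1f%%\n"),
              x$counts$period[1], x$counts$period[nrow(x$counts)],
              x$net_increase["permanent"], x$net_increase["sporadic"],
              x$net_increase["occupied"]))
  invisible(x)
}

#' Export a classified grid as GeoJSON
#'
#' Writes one Polygon feature per cell with properties \code{cell_id} and
#' one \code{status_<period>} property per period.  Coordinates are emitted
#' in the grid's projected CRS; the CRS label is stored in a foreign member
#' \code{crs_label} (plain-text, for provenance only).
#'
#' @param grid a \code{monitor_grid}.
#' @param statuses a \code{cell_statuses} data frame.
#' @param path output file.
#' @param crs_label free-text CRS label.
#' @return \code{path}, invisibly.
#' @export
write_grid_geojson <- function(grid, statuses, path,
                               crs_label = "unspecified") {
  size <- attr(grid, "cell_size")
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid$min_x[i]; y0 <- grid$min_y[i]
    ring <- list(c(x0, y0), c(x0 + size, y0), c(x0 + size, y0 + size),
                 c(x0, y0 + size), c(x0, y0))
    props <- list(cell_id = grid$cell_id[i])
    st <- statuses[statuses$cell_id == grid$cell_id[i], , drop = FALSE]
    for (j in seq_len(nrow(st)))
      props[[paste0("status_", st$period[j])]] <- st$status[j]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", crs_label = crs_label,
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
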