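#' Construct and validate a table of occurrence records
#'
#' An occurrence record is one verified wolf datum: a dated, georeferenced
#' sign of presence (carcass, depredation, camera image, direct observation
#' or scat) carrying a SCALP reliability code.  Records are kept in a plain
#' \code{data.frame} with one row per record; all downstream filters and the
#' grid-occupancy classification consume this table.
#'
#' @param record_id character vector of unique record identifiers.
#' @param date record dates (\code{Date} or ISO-8601 strings).
#' @param x,y planar coordinates in metres (projected CRS; the CRS label is
#'   carried as an attribute, not interpreted).
#' @param source one of \code{"carcass"}, \code{"depredation"},
#'   \code{"camera"}, \code{"observation"}, \code{"scat"}.
#' @param scalp SCALP reliability code: \code{"C1"} (hard evidence),
#'   \code{"C2"} (expert-confirmed) or \code{"C3"} (unconfirmed).
#' @param area_id monitoring site or locality label used for the daily
#'   independence rule.
#' @param is_reproduction logical; \code{TRUE} when the record is evidence of
#'   pups.
#' @param timestamp optional \code{POSIXct} used only to break ties within a
#'   day; defaults to midnight of \code{date}.
#' @param crs free-text label of the projected CRS, stored as an attribute.
#' @param study_window optional length-2 \code{Date} vector; records outside
#'   it are rejected.
#'
#' @return A \code{data.frame} of class \code{occurrence_records}.
#' @export
occurrence_records <- function(record_id, date, x, y, source, scalp, area_id,
                               is_reproduction = FALSE, timestamp = NULL,
                               crs = "unspecified", study_window = NULL) {
  date <- as.Date(date)
  n <- length(record_id)
  stopifnot(length(date) == n, length(x) == n, length(y) == n)
  scalp <- rep_len(as.character(scalp), n)
  source <- rep_len(as.character(source), n)
  bad <- setdiff(unique(scalp), c("C1", "C2", "C3"))
  if (length(bad))
    stop("invalid SCALP code(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(source),
                 c("carcass", "depredation", "camera", "observation", "scat"))
  if (length(bad))
    stop("invalid source(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  if (anyDuplicated(record_id))
    stop("record_id must be unique")
  if (!is.null(study_window)) {
    study_window <- as.Date(study_window)
    out <- !is.na(date) & (date < study_window[1] | date > study_window[2])
    if (any(out))
      stop(sum(out), " record(s) fall outside the study window")
  }
  if (is.null(timestamp)) timestamp <- as.POSIXct(date, tz = "UTC")
  df <- data.frame(record_id = as.character(record_id), date = date,
                   x = as.numeric(x), y = as.numeric(y),
                   source = source, scalp = scalp,
                   area_id = as.character(rep_len(area_id, n)),
                   is_reproduction = as.logical(rep_len(is_reproduction, n)),
                   timestamp = timestamp,
                   stringsAsFactors = FALSE)
  attr(df, "crs") <- crs
  class(df) <- c("occurrence_records", "data.frame")
  df
}

#' Read occurrence records from CSV
#'
#' Expects columns \code{record_id,date,x,y,source,scalp,area_id,
#' is_reproduction} with ISO-8601 dates; an optional \code{timestamp}
#' column is honoured.
#'
#' @param path CSV file path.
#' @param crs CRS label attached to the result.
#' @param study_window optional length-2 date vector passed through to
#'   \code{\link{occurrence_records}}.
#' @return An \code{occurrence_records} data frame.
#' @export
read_occurrences <- function(path, crs = "unspecified", study_window = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "date", "x", "y", "source", "scalp", "area_id",
            "is_reproduction")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  ts <- if ("timestamp" %in% names(raw))
    as.POSIXct(raw$timestamp, tz = "UTC") else NULL
  occurrence_records(raw$record_id, raw$date, raw$x, raw$y, raw$source,
                     raw$scalp, raw$area_id,
                     as.logical(raw$is_reproduction), timestamp = ts,
                     crs = crs, study_window = study_window)
}

#' Drop unconfirmed (C3) occurrences
#'
#' SCALP C3 records are unvalidated observations; they are removed before
#' any mapping or modelling so that only hard evidence (C1) and
#' expert-confirmed records (C2) enter the analysis.
#'
#' @param records an \code{occurrence_records} data frame.
#' @return The input rows with \code{scalp != "C3"}, order preserved.
#' @export
filter_scalp <- function(records) {
  records[records$scalp != "C3", , drop = FALSE]
}

#' Enforce one occurrence per area and day
#'
#' Opportunistic records of the same animal often pile up within a locality
#' on a single day; retaining one record per (area, date) pair removes this
#' pseudo-replication.  Within a group the record with the earliest
#' timestamp is kept; remaining ties are broken by lexicographic
#' \code{record_id}, so the result is deterministic.
#'
#' @param records an \code{occurrence_records} data frame.
#' @param area_key name of the grouping column (default \code{"area_id"}).
#' @return The retained subset, in the original row order.
#' @export
daily_independence <- function(records, area_key = "area_id") {
  if (!area_key %in% names(records))
    stop("unknown area_key: ", area_key)
  no_date <- is.na(records$date)
  if (any(no_date)) {
    warning(sum(no_date), " record(s) without a date were rejected")
    records <- records[!no_date, , drop = FALSE]
  }
  if (nrow(records) == 0L) return(records)
  ts <- if ("timestamp" %in% names(records)) records$timestamp
        else as.POSIXct(records$date, tz = "UTC")
  ord <- order(ts, records$record_id)
  grp <- paste(records[[area_key]], records$date, sep = "\r")
  keep_ids <- records$record_id[ord][!duplicated(grp[ord])]
  records[records$record_id %in% keep_ids, , drop = FALSE]
}

#' Thin camera detections to independent events
#'
#' Within each (site, species) stream, consecutive detections of the same
#' species closer together than the independence window are treated as one
#' event.  The default rule is rolling: the first detection is retained and
#' every detection within \code{window_minutes} of the last \emph{retained}
#' detection is discarded, so the window restarts at each retained event
#' (common camera-trap practice).  The alternative \code{"gap"} rule
#' restarts the window at every raw detection, retained or not: a detection
#' is kept only when it falls more than the window after the immediately
#' preceding detection, so a burst of closely spaced images suppresses
#' everything until a true gap occurs.
#'
#' @param detections data frame with columns \code{site}, \code{species} and
#'   \code{timestamp} (\code{POSIXct} or anything \code{as.POSIXct} accepts).
#' @param window_minutes independence window in minutes (default 30).
#' @param group_key column(s) defining the stream; default
#'   \code{c("site","species")} pools cameras at site level.
#' @param rule \code{"rolling"} (default) or \code{"gap"}.
#' @return The retained rows sorted by group and timestamp.
#' @export
camera_independence <- function(detections, window_minutes = 30,
                                group_key = c("site", "species"),
                                rule = c("rolling", "gap")) {
  rule <- match.arg(rule)
  if (window_minutes < 0) stop("window_minutes must be non-negative")
  miss <- setdiff(c(group_key, "timestamp"), names(detections))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(detections$timestamp, tz = "UTC")
  grp <- do.call(paste, c(unname(detections[group_key]), sep = "\r"))
  ord <- order(grp, ts)
  detections <- detections[ord, , drop = FALSE]
  ts <- ts[ord]; grp <- grp[ord]
  w <- window_minutes * 60
  keep <- logical(nrow(detections))
  for (g in split(seq_along(grp), grp)) {
    last <- -Inf
    for (i in g) {
      t <- as.numeric(ts[i])
      if (t - last > w) keep[i] <- TRUE
      # rolling: the clock restarts only at retained events;
      # gap: every raw detection restarts it
      if (keep[i] || rule == "gap") last <- t
    }
  }
  detections[keep, , drop = FALSE]
}

#' Cluster pup records into unique reproduction events
#'
#' Pup evidence recorded in the same calendar year at locations closer than
#' a threshold is assumed to come from the same litter.  Within each year,
#' records are single-linkage clustered, linking two records when their
#' planar distance is strictly below \code{threshold_m}; each cluster is one
#' reproduction event and the yearly event count is the number of clusters.
#'
#' @param pup_records an \code{occurrence_records} data frame with
#'   \code{is_reproduction = TRUE} rows (other rows are ignored).
#' @param threshold_m linkage distance in metres (default 20000, i.e. the
#'   20-km conservative rule for a homogeneous landscape).
#' @return A data frame of class \code{reproduction_events} with one row per
#'   event: \code{event_id}, \code{year}, centroid \code{x}, \code{y},
#'   \code{n_records} and a comma-separated \code{member_record_ids}.
#' @export
cluster_reproductions <- function(pup_records, threshold_m = 20000) {
  recs <- pup_records[pup_records$is_reproduction %in% TRUE, , drop = FALSE]
  out <- list()
  for (yr in sort(unique(as.integer(format(recs$date, "%Y"))))) {
    sub <- recs[as.integer(format(recs$date, "%Y")) == yr, , drop = FALSE]
    sub <- sub[order(sub$record_id), , drop = FALSE]
    lab <- single_linkage(sub$x, sub$y, threshold_m)
    for (cl in sort(unique(lab))) {
      m <- sub[lab == cl, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        event_id = sprintf("R%d-%02d", yr, cl), year = yr,
        x = mean(m$x), y = mean(m$y), n_records = nrow(m),
        member_record_ids = paste(m$record_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(event_id = character(), year = integer(),
                         x = numeric(), y = numeric(), n_records = integer(),
                         member_record_ids = character(),
                         stringsAsFactors = FALSE)
  class(res) <- c("reproduction_events", "data.frame")
  res
}

# Connected components of the graph linking points with d < threshold:
# exactly the single-linkage clusters under a strict cut.  Union-find.
single_linkage <- function(x, y, threshold) {
  n <- length(x)
  if (n == 0L) return(integer())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
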