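#' Default food-item taxonomy
#'
#' Maps each identifiable food item to one of the five diet categories
#' used throughout the analysis: livestock, wild prey, pet, fruit and
#' other.  Users can supply their own named vector (names = items,
#' values = categories) anywhere a taxonomy is accepted.
#'
#' @return Named character vector item -> category.
#' @export
default_food_taxonomy <- function() {
  c(sheep = "livestock", goat = "livestock", cattle = "livestock",
    poultry = "livestock",
    dog = "pet", cat = "pet",
    red_fox = "wild prey", wild_boar = "wild prey", hare = "wild prey",
    badger = "wild prey", beech_marten = "wild prey", bird = "wild prey",
    rodent = "wild prey",
    fruit = "fruit",
    other = "other", garbage = "other")
}

diet_categories <- c("livestock", "wild prey", "pet", "fruit", "other")

check_taxonomy <- function(taxonomy) {
  bad <- setdiff(unique(unname(taxonomy)), diet_categories)
  if (length(bad))
    stop("taxonomy maps to unknown categories: ", paste(bad, collapse = ", "))
  invisible(taxonomy)
}

#' Season of a collection date
#'
#' Astronomical-calendar seasons with half-open boundaries: spring
#' [20 Mar, 21 Jun), summer [21 Jun, 22 Sep), fall [22 Sep, 21 Dec),
#' winter [21 Dec, 20 Mar).  A boundary date belongs to the season it
#' starts.
#'
#' @param date a \code{Date} (or string coercible to one); vectorized.
#' @return Character vector: \code{"spring"}, \code{"summer"},
#'   \code{"fall"} or \code{"winter"}.
#' @export
season_of <- function(date) {
  date <- as.Date(date)
  md <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  ifelse(md >= 320 & md < 621, "spring",
  ifelse(md >= 621 & md < 922, "summer",
  ifelse(md >= 922 & md < 1221, "fall", "winter")))
}

#' Build a scat-content table
#'
#' @param scat_id scat identifiers.
#' @param date collection dates.
#' @param items list of character vectors, one non-empty set of food items
#'   per scat.
#' @return Data frame of class \code{scat_records}: one row per scat with
#'   \code{scat_id}, \code{date}, derived \code{season} and a list column
#'   \code{items}.
#' @export
scat_records <- function(scat_id, date, items) {
  date <- as.Date(date)
  if (length(items) != length(scat_id)) stop("one item set per scat needed")
  if (any(!lengths(items))) stop("every scat must contain at least one item")
  items <- lapply(items, function(v) unique(as.character(v)))
  df <- data.frame(scat_id = as.character(scat_id), date = date,
                   season = season_of(date), stringsAsFactors = FALSE)
  df$items <- items
  class(df) <- c("scat_records", "data.frame")
  df
}

#' Read scat contents from long-format CSV
#'
#' Expects columns \code{scat_id,date,item}, one row per item found in a
#' scat.
#'
#' @param path CSV file path.
#' @return A \code{scat_records} data frame.
#' @export
read_scats <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("scat_id", "date", "item"), names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  ids <- unique(raw$scat_id)
  scat_records(ids,
               raw$date[match(ids, raw$scat_id)],
               lapply(ids, function(i) raw$item[raw$scat_id == i]))
}

# presence/absence matrix scats x units (items or categories)
unit_matrix <- function(scats, taxonomy, level) {
  known <- names(taxonomy)
  all_items <- unique(unlist(scats$items))
  unknown <- setdiff(all_items, known)
  if (length(unknown))
    stop("item(s) not in taxonomy: ", paste(unknown, collapse = ", "))
  # categories are a fixed five-level scheme: report all of them, so a
  # category eaten in no scat shows FO = 0 rather than vanishing
  units <- if (level == "item") sort(all_items) else diet_categories
  m <- sapply(units, function(u) vapply(scats$items, function(it) {
    if (level == "item") u %in% it
    else u %in% unname(taxonomy[it])
  }, logical(1)))
  m <- matrix(m, nrow = nrow(scats), dimnames = list(scats$scat_id, units))
  m
}

#' Frequency of occurrence of food items or categories
#'
#' FO of a unit is the percentage of scats containing it:
#' \code{100 * n_scats_with_unit / N}.  At category level a scat containing
#' several items of the same category counts once.
#'
#' @param scats a \code{scat_records} data frame (N >= 1).
#' @param taxonomy named vector item -> category
#'   (default \code{\link{default_food_taxonomy}}).
#' @param level \code{"category"} (default) or \code{"item"}.
#' @return Data frame: \code{unit}, \code{n} (scats containing it),
#'   \code{fo} (percent).
#' @export
frequency_occurrence <- function(scats, taxonomy = default_food_taxonomy(),
                                 level = c("category", "item")) {
  level <- match.arg(level)
  check_taxonomy(taxonomy)
  if (nrow(scats) < 1L) stop("need at least one scat")
  m <- unit_matrix(scats, taxonomy, level)
  n <- colSums(m)
  data.frame(unit = colnames(m), n = as.integer(n),
             fo = 100 * n / nrow(scats),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bootstrap confidence intervals for frequency of occurrence
#'
#' Resamples whole scats with replacement \code{B} times and reports the
#' percentile interval of the replicate FO values for every unit.
#'
#' @param scats a \code{scat_records} data frame (N >= 2).
#' @param B bootstrap replicates (default 1000).
#' @param taxonomy named vector item -> category.
#' @param level \code{"category"} or \code{"item"}.
#' @param conf confidence level (default 0.95).
#' @param seed optional integer; set for reproducible intervals.
#' @return The \code{\link{frequency_occurrence}} table with columns
#'   \code{ci_low}, \code{ci_high} appended (percent scale).
#' @export
bootstrap_fo_ci <- function(scats, B = 1000,
                            taxonomy = default_food_taxonomy(),
                            level = c("category", "item"), conf = 0.95,
                            seed = NULL) {
  level <- match.arg(level)
  if (B <= 0) stop("B must be positive")
  if (nrow(scats) < 2L) stop("need at least two scats")
  if (!is.null(seed)) set.seed(seed)
  est <- frequency_occurrence(scats, taxonomy, level)
  m <- unit_matrix(scats, taxonomy, level)
  N <- nrow(m)
  idx <- matrix(sample.int(N, N * B, replace = TRUE), nrow = N)
  # replicate FO for unit u: 100 * mean over resampled rows
  reps <- vapply(colnames(m), function(u) {
    cnt <- matrix(m[, u][idx], nrow = N)
    100 * colMeans(cnt)
  }, numeric(B))
  reps <- matrix(reps, nrow = B, dimnames = list(NULL, colnames(m)))
  a <- (1 - conf) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(a, 1 - a), type = 7)
  est$ci_low <- qs[1, est$unit]
  est$ci_high <- qs[2, est$unit]
  est
}

#' Scat-survey transect effort
#'
#' Distance walked per survey round and over the whole campaign, from the
#' number of transects, their mean length and the number of rounds.
#'
#' @param n_transects number of linear transects.
#' @param mean_length_m mean transect length in metres.
#' @param rounds number of complete survey rounds (e.g. monthly visits).
#' @return List: \code{per_round_km}, \code{total_km}.
#' @export
transect_effort <- function(n_transects, mean_length_m, rounds = 1) {
  if (n_transects <= 0 || mean_length_m <= 0 || rounds <= 0)
    stop("all arguments must be positive")
  per <- n_transects * mean_length_m / 1000
  list(per_round_km = per, total_km = per * rounds)
}

#' Brillouin diversity index
#'
#' For pooled item counts \eqn{n_1,\dots,n_S} with \eqn{N=\sum n_i}:
#' \deqn{HB = (\ln N! - \sum_i \ln n_i!)/N,}
#' computed via \code{lgamma}.  HB is 0 exactly when a single distinct
#' item is present.
#'
#' @param item_counts positive integer counts per distinct item.
#' @return The index (>= 0).
#' @export
brillouin <- function(item_counts) {
  if (!length(item_counts)) stop("empty counts")
  if (any(item_counts < 1)) stop("all counts must be >= 1")
  N <- sum(item_counts)
  (lgamma(N + 1) - sum(lgamma(item_counts + 1))) / N
}

#' Minimum sample size from the Brillouin accumulation curve
#'
#' Scats are accumulated one at a time; after each addition the Brillouin
#' index of the pooled item counts is computed, together with its absolute
#' incremental change \eqn{|HB_k - HB_{k-1}|/HB_{k-1} \times 100}.  Because
#' the curve depends on the order in which scats are added, it is averaged
#' over \code{orderings} random permutations (or computed once in
#' collection order).  The minimum sample size is the smallest k at which
#' the averaged change drops below \code{threshold_pct} and stays below it
#' for every larger k; if the change never stabilizes the result is
#' \code{NA} and flagged.
#'
#' @param scats a \code{scat_records} data frame (N >= 3).
#' @param orderings number of random orderings to average (default 100);
#'   ignored when \code{order = "collection"}.
#' @param seed optional integer for reproducible orderings.
#' @param threshold_pct stabilization threshold in percent (default 1).
#' @param order \code{"random"} (default) or \code{"collection"} (scats
#'   added by collection date).
#' @return A list of class \code{brillouin_curve}: \code{k}, \code{hb}
#'   (averaged index), \code{change_pct} (averaged incremental change,
#'   \code{NA} at k = 1), \code{min_sample}, \code{stabilized}.
#' @export
min_sample_size <- function(scats, orderings = 100, seed = NULL,
                            threshold_pct = 1,
                            order = c("random", "collection")) {
  order <- match.arg(order)
  N <- nrow(scats)
  if (N < 3L) stop("need at least three scats")
  if (!is.null(seed)) set.seed(seed)
  perms <- if (order == "collection") list(base::order(scats$date))
           else replicate(orderings, sample.int(N), simplify = FALSE)
  hb_mat <- matrix(NA_real_, nrow = length(perms), ncol = N)
  ch_mat <- matrix(NA_real_, nrow = length(perms), ncol = N)
  for (p in seq_along(perms)) {
    counts <- new.env(parent = emptyenv())
    tally <- list()
    hb_prev <- NA_real_
    for (k in seq_len(N)) {
      for (it in scats$items[[perms[[p]][k]]])
        tally[[it]] <- (if (is.null(tally[[it]])) 0L else tally[[it]]) + 1L
      hb <- brillouin(unlist(tally))
      hb_mat[p, k] <- hb
      if (k >= 2L && !is.na(hb_prev) && hb_prev > 0)
        ch_mat[p, k] <- abs(hb - hb_prev) / hb_prev * 100
      hb_prev <- hb
    }
  }
  hb_avg <- colMeans(hb_mat)
  ch_avg <- colMeans(ch_mat)   # NA until every ordering has HB_{k-1} > 0
  min_sample <- NA_integer_
  stabilized <- FALSE
  ok <- !is.na(ch_avg) & ch_avg < threshold_pct
  if (any(ok)) {
    # smallest k below threshold with all larger k also below
    below_after <- rev(cumprod(rev(replace(ok, is.na(ok), FALSE))))
    cand <- which(ok & as.logical(below_after))
    if (length(cand)) { min_sample <- cand[1]; stabilized <- TRUE }
  }
  if (!stabilized)
    warning("Brillouin curve did not stabilize below ", threshold_pct,
            "% by N = ", N)
  structure(list(k = seq_len(N), hb = hb_avg, change_pct = ch_avg,
                 min_sample = min_sample, stabilized = stabilized,
                 threshold_pct = threshold_pct, orderings = length(perms)),
            class = "brillouin_curve")
}

#' @export
print.brillouin_curve <- function(x, ...) {
  cat(sprintf("Brillouin accumulation over %d scats (%d ordering%s):\n",
              length(x$k), x$orderings, if (x$orderings > 1) "s" else ""))
  if (x$stabilized)
    cat(sprintf("  minimum sample size: %d (change < %g%% thereafter)\n",
                x$min_sample, x$threshold_pct))
  else
    cat("  curve did not stabilize; minimum sample size undefined\n")
  invisible(x)
}

#' @export
plot.brillouin_curve <- function(x, ...) {
  graphics::plot(x$k, x$hb, type = "l", xlab = "Scats accumulated",
                 ylab = "Brillouin index", ...)
  if (x$stabilized) graphics::abline(v = x$min_sample, lty = 2)
  invisible(x)
}
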