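# In-code fixtures and independent oracles shared across test files.

# quick occurrence table builder: positions default to one point per record
make_records <- function(n = length(date), date, scalp = "C1",
                         x = seq_len(n) * 100, y = rep(0, n), area = "A",
                         repro = FALSE, id = sprintf("r%03d", seq_len(n)),
                         timestamp = NULL) {
  occurrence_records(id, date, x, y, source = "observation", scalp = scalp,
                     area_id = area, is_reproduction = repro,
                     timestamp = timestamp)
}

# brute-force O(n^2) rolling independence rule, kept deliberately naive
brute_camera_filter <- function(times_min, window = 30) {
  keep <- integer()
  for (t in sort(times_min)) {
    if (!length(keep) || t - keep[length(keep)] > window)
      keep <- c(keep, t)
  }
  keep
}

# direct status oracle for one cell over a 5-year period: counts per year
# of C1 and C2 records, no shared code with classify_cell
status_oracle <- function(c1_per_year, c2_per_year, length_years = 5,
                          repro_recent = FALSE) {
  qualifying <- sum(c1_per_year >= 1 | c2_per_year >= 2)
  presence <- sum(c1_per_year + c2_per_year >= 1)
  if (qualifying >= ceiling(length_years / 2) || repro_recent) "Permanent"
  else if (presence >= 1) "Sporadic"
  else "Absent"
}

# build an occurrence table realizing given per-year C1/C2 counts in one cell
records_from_counts <- function(c1, c2, start_year = 2020) {
  dates <- character(); scalps <- character()
  for (i in seq_along(c1)) {
    yr <- start_year + i - 1
    if (c1[i] > 0) { dates <- c(dates, sprintf("%d-06-%02d", yr,
                                               seq_len(c1[i])))
                     scalps <- c(scalps, rep("C1", c1[i])) }
    if (c2[i] > 0) { dates <- c(dates, sprintf("%d-07-%02d", yr,
                                               seq_len(c2[i])))
                     scalps <- c(scalps, rep("C2", c2[i])) }
  }
  if (!length(dates))
    return(make_records(n = 0, date = as.Date(character()),
                        scalp = character(0), x = numeric(0),
                        y = numeric(0), id = character(0)))
  make_records(n = length(dates), date = dates, scalp = scalps,
               x = rep(50, length(dates)), y = rep(50, length(dates)),
               id = sprintf("q%03d", seq_along(dates)))
}

# von Mises mixture sampler independent of the package generator
sample_mixture <- function(n, means_h, kappas, w) {
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  vapply(comp, function(k)
    rvonmises(1, means_h[k] * 2 * pi / 24, kappas[k]), numeric(1)) %%
    (2 * pi)
}

# scat table where each scat carries item "a" with probability p and a
# filler item otherwise (binomial FO truth = 100 p for a's category)
binom_scats <- function(N, p, item = "sheep", filler = "fruit") {
  has <- stats::runif(N) < p
  items <- lapply(has, function(h) if (h) item else filler)
  scat_records(sprintf("s%03d", seq_len(N)), rep("2024-07-01", N), items)
}
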