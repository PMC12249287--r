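test_that("grid construction tiles the extent with half-open cells", {
  g <- build_grid(0, 0, 30000, 20000)
  expect_equal(nrow(g), 6)
  expect_error(build_grid(0, 0, 1000, 1000, cell_size = 0), "positive")

  # a point on a shared edge belongs to the cell whose min edge it equals
  expect_equal(assign_cell(g, 10000, 0), "r00c01")
  expect_equal(assign_cell(g, 9999.999, 0), "r00c00")

  set.seed(5)
  for (i in 1:10) {
    ext <- sort(runif(2, -50000, 50000)); exty <- sort(runif(2, 0, 80000))
    g <- build_grid(ext[1], exty[1], ext[2] + 1, exty[2] + 1,
                    cell_size = 7000)
    expect_gte(nrow(g) * 7000^2, (ext[2] + 1 - ext[1]) *
                                 (exty[2] + 1 - exty[1]))
    px <- runif(20, ext[1], ext[2]); py <- runif(20, exty[1], exty[2])
    expect_false(any(is.na(assign_cell(g, px, py))))
  }
})

test_that("cell classification follows the evidence-threshold rules", {
  p <- period("2020-2024", 2020, 2024)
  # one C1 in each of three years: 3 qualifying years >= ceil(5/2)
  r <- records_from_counts(c1 = c(1, 1, 1, 0, 0), c2 = rep(0, 5))
  expect_equal(classify_cell(r, p)$status, "Permanent")
  # two C2 in a single year: one presence year, below the Permanent bar
  r <- records_from_counts(c1 = rep(0, 5), c2 = c(0, 2, 0, 0, 0))
  st <- classify_cell(r, p)
  expect_equal(st$status, "Sporadic")
  expect_equal(st$qualifying_years, 1)
  # no records at all
  r <- records_from_counts(c1 = rep(0, 5), c2 = rep(0, 5))
  expect_equal(classify_cell(r, p)$status, "Absent")
  # reproduction in the last three years promotes to Permanent
  r <- records_from_counts(c1 = c(1, 0, 0, 0, 0), c2 = rep(0, 5))
  ev <- data.frame(event_id = "R2023-01", year = 2023, x = 50, y = 50,
                   n_records = 1, member_record_ids = "p01")
  expect_equal(classify_cell(r, p, ev)$status, "Permanent")
  expect_true(classify_cell(r, p, ev)$reproduction_recent)
  # ... but an old reproduction does not
  ev$year <- 2020
  expect_equal(classify_cell(r, p, ev)$status, "Sporadic")
  # ambiguous case: single C2 in each of four years never qualifies
  r <- records_from_counts(c1 = rep(0, 5), c2 = c(1, 1, 1, 1, 0))
  expect_equal(classify_cell(r, p)$status, "Sporadic")
})

test_that("cell classification rejects unfiltered or mis-sliced input", {
  p <- period("2020-2024", 2020, 2024)
  bad <- make_records(date = "2021-01-01", scalp = "C3")
  expect_error(classify_cell(bad, p), "SCALP")
  out <- make_records(date = "2019-06-01")
  expect_error(classify_cell(out, p), "outside period")
})

test_that("classification matches an exhaustive year-pattern oracle", {
  p <- period("2020-2024", 2020, 2024)
  # all per-year patterns with C1 in {0,1}, C2 in {0,1,2} over 3 of the 5
  # years (remaining years empty): 216 cell histories
  pats <- expand.grid(a1 = 0:1, a2 = 0:2, b1 = 0:1, b2 = 0:2,
                      c1 = 0:1, c2 = 0:2)
  for (i in seq_len(nrow(pats))) {
    q <- pats[i, ]
    c1 <- c(q$a1, q$b1, q$c1, 0, 0); c2 <- c(q$a2, q$b2, q$c2, 0, 0)
    got <- classify_cell(records_from_counts(c1, c2), p)$status
    expect_identical(got, status_oracle(c1, c2), label = paste(
      "pattern", i, "c1:", paste(c1, collapse = ","), "c2:",
      paste(c2, collapse = ",")))
  }
})

test_that("adding hard evidence never demotes a cell", {
  p <- period("2020-2024", 2020, 2024)
  rank <- c(Absent = 0, Sporadic = 1, Permanent = 2)
  set.seed(21)
  for (i in 1:25) {
    c1 <- rpois(5, 0.5); c2 <- rpois(5, 0.7)
    before <- classify_cell(records_from_counts(c1, c2), p)$status
    extra_year <- sample.int(5, 1)
    c1b <- c1; c1b[extra_year] <- c1b[extra_year] + 1
    after <- classify_cell(records_from_counts(c1b, c2), p)$status
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("classification is invariant to record order", {
  p <- period("2020-2024", 2020, 2024)
  r <- records_from_counts(c1 = c(1, 0, 1, 0, 1), c2 = c(0, 2, 0, 1, 0))
  base <- classify_cell(r, p)
  set.seed(9)
  perm <- r[sample.int(nrow(r)), , drop = FALSE]
  class(perm) <- c("occurrence_records", "data.frame")
  expect_equal(classify_cell(perm, p), base)
})

test_that("grid-wide classification covers every cell in every period", {
  sim <- simulate_inputs(sim_config(seed = 4))
  f <- daily_independence(filter_scalp(sim$occurrences))
  ps <- list(period("2015-2019", 2015, 2019),
             period("2020-2024", 2020, 2024))
  st <- classify_grid(sim$grid, f, ps, cluster_reproductions(f))
  expect_equal(nrow(st), nrow(sim$grid) * 2)
  expect_true(all(st$status %in% c("Permanent", "Sporadic", "Absent")))
  # statuses partition the grid: per period the three counts sum to all cells
  for (pl in unique(st$period))
    expect_equal(sum(st$period == pl), nrow(sim$grid))
  # Absent exactly when nothing at all was recorded in the cell
  expect_true(all(st$presence_years[st$status == "Absent"] == 0))
  expect_true(all(st$status[st$presence_years == 0 &
                            !st$reproduction_recent] == "Absent"))
})

test_that("occupancy summary computes net percentage increases", {
  st <- data.frame(
    cell_id = c(sprintf("a%02d", 1:15), sprintf("b%02d", 1:33)),
    period = rep(c("P1", "P2"), c(15, 33)),
    status = c(rep("Permanent", 4), rep("Sporadic", 11),
               rep("Permanent", 15), rep("Sporadic", 18)))
  s <- summarize_occupancy(st)
  expect_equal(unname(s$net_increase["permanent"]), 275)
  expect_equal(unname(s$net_increase["occupied"]), 120)

  same <- data.frame(cell_id = c("a", "b"), period = c("P1", "P2"),
                     status = c("Permanent", "Permanent"))
  # sporadic counts are zero in both periods here, which itself warns
  s_same <- suppressWarnings(summarize_occupancy(same))
  expect_equal(unname(s_same$net_increase["permanent"]), 0)
  zero <- data.frame(cell_id = c("a", "b"), period = c("P1", "P2"),
                     status = c("Absent", "Permanent"))
  w <- capture_warnings(s0 <- summarize_occupancy(zero))
  expect_true(any(grepl("zero", w)))
  expect_true(is.nan(s0$net_increase["permanent"]))
  expect_error(summarize_occupancy(st[st$period == "P1", ]), "two periods")
})

test_that("GeoJSON export writes one polygon per cell with statuses", {
  g <- build_grid(0, 0, 20000, 10000)
  st <- data.frame(cell_id = rep(g$cell_id, 2),
                   period = rep(c("P1", "P2"), each = nrow(g)),
                   status = "Sporadic")
  path <- tempfile(fileext = ".geojson")
  write_grid_geojson(g, st, path, crs_label = "EPSG:32633")
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(g))
  f1 <- gj$features[[1]]
  expect_equal(f1$geometry$type, "Polygon")
  expect_length(f1$geometry$coordinates[[1]], 5)  # closed ring
  expect_equal(f1$properties$status_P1, "Sporadic")
})
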