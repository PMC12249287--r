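test_that("AICc arithmetic matches hand-computed values", {
  expect_equal(aicc(-12.5049, 2, 26), 29.5316, tolerance = 1e-3)
  expect_equal(aicc(-11.7519, 3, 26), 30.5948, tolerance = 1e-3)
  expect_error(aicc(-10, 5, 6), "undefined")
  # correction vanishes for large n
  expect_lt(abs(aicc(-100, 4, 1e6) - (-2 * -100 + 2 * 4)), 1e-4)
})

test_that("collinearity screen drops the redundant member of each pair", {
  set.seed(31)
  n <- 200
  base <- data.frame(status = rbinom(n, 1, 0.5),
                     road_density = runif(n, 1.4, 5.9),
                     n_farms = rpois(n, 10),
                     pa_perc = runif(n, 0, 8),
                     forest_perc = runif(n, 1, 37))
  base$forest_count <- rpois(n, 20)
  base$forest_area <- base$forest_perc * exp(rnorm(n, 0, 0.05))
  kept <- collinearity_screen(base)
  expect_false("forest_area" %in% kept && "forest_perc" %in% kept)
  expect_length(kept, 5)

  dup <- base[c("status", "road_density")]
  dup$copy <- dup$road_density
  expect_length(collinearity_screen(dup), 1)

  set.seed(32)
  indep <- data.frame(status = rbinom(1000, 1, 0.5),
                      a = rnorm(1000), b = rnorm(1000), c = rnorm(1000))
  expect_setequal(collinearity_screen(indep), c("a", "b", "c"))

  const <- data.frame(status = rbinom(20, 1, 0.5), a = rnorm(20), b = 1)
  expect_warning(kc <- collinearity_screen(const), "constant")
  expect_equal(kc, "a")
})

test_that("all-subsets enumeration has 2^p candidates", {
  expect_length(enumerate_models(letters[1:5]), 32)
  expect_length(enumerate_models(character(0)), 1)
  expect_length(enumerate_models(letters[1:3]), 8)
  expect_error(enumerate_models(letters), "refus")
})

test_that("logistic fits report logLik, AIC and AICc consistently", {
  set.seed(41)
  n <- 26
  tab <- data.frame(status = rep(0:1, 13), xv = rnorm(n))
  f <- fit_logistic(tab, "xv")
  expect_equal(f$k, 2)
  expect_equal(f$n, n)
  expect_equal(f$aicc, aicc(f$logLik, f$k, n), tolerance = 1e-12)
  expect_equal(f$aic, -2 * f$logLik + 2 * f$k, tolerance = 1e-12)

  # balanced null model: intercept 0, logLik = n log(1/2)
  nul <- fit_logistic(data.frame(status = rep(0:1, 10)), character(0))
  expect_equal(unname(nul$coefficients), 0, tolerance = 1e-8)
  expect_equal(nul$logLik, 20 * log(0.5), tolerance = 1e-10)

  # perfectly separable data are flagged, not silently ranked
  sep <- data.frame(status = rep(0:1, each = 10),
                    xv = c(rnorm(10, -5), rnorm(10, 5)))
  expect_warning(fs <- fit_logistic(sep, "xv"), "separation")
  expect_true(fs$separation)
  expect_error(fit_logistic(data.frame(status = rep(0:1, 3),
                                       a = rnorm(6), b = rnorm(6),
                                       c = rnorm(6), d = rnorm(6)),
                            c("a", "b", "c", "d")), "n - k - 1")
})

test_that("ranking produces normalized Akaike weights and competitors", {
  mock_fit <- function(ll, k, n = 26, terms = letters[seq_len(k - 1)])
    structure(list(terms = terms, coefficients = stats::setNames(
      rep(0.1, k), c("(Intercept)", terms)), logLik = ll, k = k, n = n,
      aic = -2 * ll + 2 * k, aicc = aicc(ll, k, n), separation = FALSE),
      class = "candidate_fit")

  # printed-table arithmetic: second weight = best weight * exp(-delta/2)
  fits <- list(mock_fit(-12.5049, 2), mock_fit(-11.7519, 3))
  rk <- rank_and_weight(fits)
  expect_equal(rk$table$delta[2], 1.0632, tolerance = 1e-3)
  ratio <- rk$table$weight[2] / rk$table$weight[1]
  expect_equal(0.2020 * ratio, 0.1187, tolerance = 5e-4)

  single <- rank_and_weight(list(mock_fit(-10, 2)))
  expect_equal(single$table$weight, 1)

  set.seed(51)
  many <- lapply(rnorm(32, -15, 3), mock_fit, k = 3)
  rk32 <- rank_and_weight(many)
  expect_equal(sum(rk32$table$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(rk32$table$AICc) >= 0))
  expect_equal(rk32$table$competitor, rk32$table$delta < 2)

  # adding a constant to every logLik leaves delta and weights unchanged
  shifted <- lapply(many, function(f) mock_fit(f$logLik + 7, f$k))
  rks <- rank_and_weight(shifted)
  expect_equal(rks$table$delta, rk32$table$delta, tolerance = 1e-10)
  expect_equal(rks$table$weight, rk32$table$weight, tolerance = 1e-10)

  flagged <- mock_fit(-9, 2); flagged$separation <- TRUE
  expect_warning(rkf <- rank_and_weight(list(mock_fit(-10, 2), flagged)),
                 "excluded")
  expect_equal(nrow(rkf$table), 1)
})

test_that("model averaging weights coefficients over the competitor set", {
  mk <- function(ll, coefs) structure(list(
    terms = setdiff(names(coefs), "(Intercept)"), coefficients = coefs,
    logLik = ll, k = length(coefs), n = 26,
    aic = -2 * ll + 2 * length(coefs),
    aicc = aicc(ll, length(coefs), 26), separation = FALSE),
    class = "candidate_fit")

  # equal weights, coefficient c vs absent: full average halves it
  f1 <- mk(-10, c("(Intercept)" = 0.2, xv = 0.8))
  f2 <- mk(-11, c("(Intercept)" = 0.1))
  rk <- rank_and_weight(list(f1, f2))
  rk$table$weight <- c(0.5, 0.5)  # force equal weights for the arithmetic
  avg <- average_models(rk)
  expect_equal(unname(avg["xv"]), 0.4)
  cond <- average_models(rk, method = "conditional")
  expect_equal(unname(cond["xv"]), 0.8)

  # single competitor: identity
  f3 <- mk(-20, c("(Intercept)" = 1, zz = 2))  # delta >> 2
  rk2 <- rank_and_weight(list(f1, f3))
  expect_equal(average_models(rk2),
               f1$coefficients, ignore_attr = TRUE)

  # hand-computed weighted sum over a seeded 5-model set
  set.seed(61)
  lls <- c(-10, -10.3, -10.6, -10.8, -10.9)
  fits <- lapply(lls, function(ll)
    mk(ll, c("(Intercept)" = rnorm(1), xv = rnorm(1))))
  rk3 <- rank_and_weight(fits)
  w <- rk3$table$weight[rk3$table$competitor]
  w <- w / sum(w)
  hand <- sum(w * vapply(rk3$fits[rk3$table$competitor],
                         function(f) f$coefficients["xv"], numeric(1)))
  expect_equal(unname(average_models(rk3)["xv"]), hand, tolerance = 1e-12)
})

test_that("the full modelling stage recovers a strong simulated effect", {
  set.seed(71)
  n <- 120
  tab <- data.frame(cell_id = sprintf("c%03d", 1:n),
                    road_density = runif(n, 1.4, 5.9),
                    n_farms = rpois(n, 10),
                    forest_count = rpois(n, 20))
  eta <- -0.5 + 1.2 * as.numeric(scale(tab$forest_count))
  tab$status <- rbinom(n, 1, plogis(eta))
  res <- select_status_models(tab)
  expect_setequal(res$retained, c("road_density", "n_farms",
                                  "forest_count"))
  expect_equal(nrow(res$ranking$table), 8)
  expect_match(res$ranking$table$model[1], "forest_count")
  expect_gt(unname(res$averaged["forest_count"]), 0)
})
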