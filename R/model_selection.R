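#' Screen covariates for collinearity
#'
#' Computes pairwise Pearson correlations and iteratively removes
#' covariates until every remaining pair has \code{|r| <= threshold}.  At
#' each step the currently worst pair is considered and the member with the
#' larger mean absolute correlation against all other remaining covariates
#' is dropped (alphabetical order breaks exact ties).  Constant covariates
#' have undefined correlations and are dropped up front with a warning.
#'
#' @param table data frame of numeric covariates (response columns are
#'   ignored via \code{exclude}).
#' @param threshold correlation threshold (default 0.7).
#' @param exclude column names to leave out of the screen (e.g. the
#'   response); they are not returned either.
#' @return Character vector of retained covariate names.
#' @export
collinearity_screen <- function(table, threshold = 0.7,
                                exclude = c("status", "cell_id")) {
  vars <- setdiff(names(table), exclude)
  if (length(vars) < 2L) stop("need at least two covariates")
  if (nrow(table) < 3L) stop("need at least three rows")
  const <- vars[vapply(vars, function(v) stats::sd(table[[v]]) == 0,
                       logical(1))]
  if (length(const)) {
    warning("constant covariate(s) dropped: ", paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  repeat {
    if (length(vars) < 2L) break
    r <- abs(stats::cor(table[vars]))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- vars[worst]
    mean_r <- vapply(pair, function(v) mean(r[v, setdiff(vars, v)]),
                     numeric(1))
    drop <- if (abs(diff(mean_r)) < 1e-12) sort(pair)[2]
            else pair[which.max(mean_r)]
    vars <- setdiff(vars, drop)
  }
  vars
}

#' Enumerate all candidate term sets
#'
#' All-subsets enumeration: every subset of the retained covariates,
#' including the intercept-only (null) model, so p covariates yield
#' \code{2^p} candidate models.
#'
#' @param covariates character vector of covariate names (p <= 20).
#' @return List of character vectors; \code{character(0)} is the null model.
#' @export
enumerate_models <- function(covariates) {
  p <- length(covariates)
  if (p > 20L) stop("refusing to enumerate 2^", p, " models")
  sets <- list(character(0))
  for (v in covariates)
    sets <- c(sets, lapply(sets, function(s) c(s, v)))
  sets
}

#' Fit one binomial logistic candidate model
#'
#' Fits status ~ terms with a logit link (iteratively reweighted least
#' squares via \code{stats::glm}) and reports the information-criterion
#' quantities used for ranking: \code{logLik}, number of estimated
#' parameters k (terms + intercept), \code{AIC = -2 logLik + 2k} and the
#' small-sample correction
#' \code{AICc = AIC + 2k(k+1)/(n-k-1)}.  Complete separation is detected
#' through diverging coefficients (\code{|beta| > 50}), non-convergence,
#' or fitted probabilities at the 0/1 boundary, and flags the fit so the
#' ranking can exclude it.
#'
#' @param table data frame containing \code{response} and the term columns.
#' @param terms character vector of covariate names (may be empty for the
#'   null model).
#' @param response name of the 0/1 response column (default
#'   \code{"status"}).
#' @return A list of class \code{candidate_fit}: \code{terms},
#'   \code{coefficients}, \code{logLik}, \code{k}, \code{n}, \code{aic},
#'   \code{aicc}, \code{separation}, \code{model} (the glm object).
#' @export
fit_logistic <- function(table, terms, response = "status") {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fo <- stats::as.formula(paste(response, "~", rhs))
  boundary <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fo, family = stats::binomial(), data = table,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        boundary <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit))
  ll <- as.numeric(stats::logLik(fit))
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 <= 0 (n = ", n, ", k = ", k, ")")
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 50) ||
    (boundary && length(terms) > 0)
  if (separation)
    warning("possible complete separation for model ~ ", rhs)
  structure(list(terms = terms, coefficients = stats::coef(fit),
                 logLik = ll, k = k, n = n, aic = aic, aicc = aicc,
                 separation = separation, model = fit),
            class = "candidate_fit")
}

#' Small-sample Akaike information criterion
#'
#' \code{AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param logLik model log-likelihood.
#' @param k number of estimated parameters (including the intercept).
#' @param n sample size; requires \code{n - k - 1 > 0}.
#' @return The criterion value.
#' @export
aicc <- function(logLik, k, n) {
  if (any(n - k - 1 <= 0)) stop("AICc undefined: n - k - 1 <= 0")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models and compute Akaike weights
#'
#' Sorts valid fits by AICc, computes \eqn{\Delta_i = AICc_i - \min AICc}
#' and Akaike weights \eqn{\omega_i = e^{-\Delta_i/2} / \sum_j
#' e^{-\Delta_j/2}} over \emph{all} candidates, and marks the competitor
#' set \eqn{\{\Delta < 2\}} used for model averaging.  Separation-flagged
#' fits are excluded with a warning.
#'
#' @param fits list of \code{candidate_fit} objects.
#' @return A list of class \code{model_ranking}: \code{table} (one row per
#'   model: terms, df, logLik, AICc, delta, weight, competitor) and
#'   \code{fits} in ranked order.
#' @export
rank_and_weight <- function(fits) {
  if (inherits(fits, "candidate_fit")) fits <- list(fits)
  sep <- vapply(fits, function(f) f$separation, logical(1))
  if (any(sep)) {
    warning(sum(sep), " separation-flagged fit(s) excluded from ranking")
    fits <- fits[!sep]
  }
  if (!length(fits)) stop("no valid fits to rank")
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  ord <- order(aiccs)
  fits <- fits[ord]; aiccs <- aiccs[ord]
  delta <- aiccs - aiccs[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(null)",
      character(1)),
    df = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = aiccs, delta = delta, weight = w,
    competitor = delta < 2,
    stringsAsFactors = FALSE)
  structure(list(table = tab, fits = fits), class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ..., n = 10) {
  cat("Model ranking by AICc (top", min(n, nrow(x$table)), "of",
      nrow(x$table), "models):\n")
  tab <- utils::head(x$table, n)
  tab$logLik <- round(tab$logLik, 4)
  tab$AICc <- round(tab$AICc, 4)
  tab$delta <- round(tab$delta, 4)
  tab$weight <- round(tab$weight, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Model-average coefficients over the competitor set
#'
#' Averages coefficients across the competitor models (\eqn{\Delta < 2})
#' with weights renormalized over that set.  Full averaging (default)
#' treats a term absent from a model as a zero coefficient, shrinking
#' terms that appear in few competitors; conditional averaging divides by
#' the summed weight of only the models containing the term.
#'
#' @param ranking a \code{model_ranking}.
#' @param method \code{"full"} (default) or \code{"conditional"}.
#' @return Named numeric vector of averaged coefficients (attribute
#'   \code{weights}: the renormalized competitor weights).  With a single
#'   competitor the best model's coefficients are returned unchanged.
#' @export
average_models <- function(ranking, method = c("full", "conditional")) {
  method <- match.arg(method)
  comp <- ranking$table$competitor
  fits <- ranking$fits[comp]
  w <- ranking$table$weight[comp]
  w <- w / sum(w)
  if (length(fits) == 1L) {
    out <- fits[[1]]$coefficients
    attr(out, "weights") <- w
    return(out)
  }
  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  beta <- matrix(0, nrow = length(fits), ncol = length(terms),
                 dimnames = list(NULL, terms))
  present <- matrix(FALSE, nrow = length(fits), ncol = length(terms),
                    dimnames = list(NULL, terms))
  for (i in seq_along(fits)) {
    cf <- fits[[i]]$coefficients
    beta[i, names(cf)] <- cf
    present[i, names(cf)] <- TRUE
  }
  out <- if (method == "full") colSums(beta * w)
         else vapply(terms, function(tm) {
           wi <- w[present[, tm]]
           sum(beta[present[, tm], tm] * wi) / sum(wi)
         }, numeric(1))
  attr(out, "weights") <- w
  out
}

#' Run the full status-modelling stage
#'
#' Collinearity screen, all-subsets enumeration, logistic fits, AICc
#' ranking and (when at least two competitors exist) model averaging, in
#' one call.
#'
#' @param table covariate table with a 0/1 \code{status} column
#'   (1 = Permanent, 0 = Sporadic).
#' @param threshold collinearity threshold passed to
#'   \code{\link{collinearity_screen}}.
#' @param response response column name.
#' @return A list: \code{retained} covariates, \code{ranking}
#'   (\code{model_ranking}) and \code{averaged} coefficients (or the best
#'   model's, when it has no competitors).
#' @export
select_status_models <- function(table, threshold = 0.7,
                                 response = "status") {
  retained <- collinearity_screen(table, threshold,
                                  exclude = c(response, "cell_id"))
  sets <- enumerate_models(retained)
  fits <- lapply(sets, function(s) fit_logistic(table, s, response))
  ranking <- rank_and_weight(fits)
  averaged <- average_models(ranking)
  list(retained = retained, ranking = ranking, averaged = averaged)
}
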