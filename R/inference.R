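# Mixed-model inference: metric ~ trait number and metric ~ trait
# correlation, with polynomial form selection by AIC, a per-plot random
# intercept, and Benjamini-Hochberg adjustment.
#
# All fits use maximum likelihood (not REML) so AIC comparisons across
# fixed-effect structures are valid. The within-plot autoregressive
# correlation structure sometimes paired with repeated measures is omitted:
# trait subsets have no natural ordering to index an AR(1) process, and the
# random intercept is retained as the repeated-measures control.

.lmerCtrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore",
                    check.scaleX = "ignore")
}

.fitPoly <- function(df, degree) {
  multiPlot <- length(unique(df$plot)) > 1
  fmlFix <- sprintf("value ~ poly(x, %d, raw = TRUE)", degree)
  if (multiPlot) {
    fit <- tryCatch(
      lmerTest::lmer(stats::as.formula(paste(fmlFix, "+ (1 | plot)")),
                     data = df, REML = FALSE, control = .lmerCtrl()),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
    warning(sprintf("mixed fit failed at degree %d; falling back to OLS",
                    degree))
  }
  stats::lm(stats::as.formula(fmlFix), data = df)
}

.fitNull <- function(df) {
  if (length(unique(df$plot)) > 1) {
    fit <- tryCatch(
      lme4::lmer(value ~ 1 + (1 | plot), data = df, REML = FALSE,
                 control = .lmerCtrl()),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  stats::lm(value ~ 1, data = df)
}

.coefTable <- function(fit) {
  cs <- stats::coef(summary(fit))
  data.frame(term = rownames(cs), estimate = cs[, "Estimate"],
             se = cs[, "Std. Error"], p = cs[, ncol(cs)],
             row.names = NULL, stringsAsFactors = FALSE)
}

.reVariance <- function(fit) {
  if (inherits(fit, "merMod")) unname(unlist(lme4::VarCorr(fit))[1])
  else NA_real_
}

.fitModelSet <- function(df, response, predictor, degrees = 1:4) {
  df <- df[stats::complete.cases(df[, c("value", "x", "plot")]), ,
           drop = FALSE]
  nx <- length(unique(df$x))
  if (nx < 2) stop("predictor has zero variance (fewer than 2 distinct values)")
  degrees <- degrees[degrees <= nx - 1]
  fits <- list()
  tab <- NULL
  for (dg in degrees) {
    fit <- tryCatch(.fitPoly(df, dg), error = function(e) {
      warning(sprintf("degree %d fit failed and was skipped: %s", dg,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(fit)) next
    ll <- stats::logLik(fit)
    fits[[as.character(dg)]] <- fit
    tab <- rbind(tab, data.frame(degree = dg,
                                 nPar = attr(ll, "df"),
                                 logLik = as.numeric(ll),
                                 AIC = stats::AIC(fit)))
  }
  if (is.null(tab)) stop("no polynomial degree could be fitted")
  sel <- tab$degree[which.min(tab$AIC)]   # first minimum = lowest degree
  selFit <- fits[[as.character(sel)]]
  null <- .fitNull(df)
  lrStat <- 2 * (as.numeric(stats::logLik(selFit)) -
                   as.numeric(stats::logLik(null)))
  dfDiff <- attr(stats::logLik(selFit), "df") -
    attr(stats::logLik(null), "df")
  pValue <- stats::pchisq(max(lrStat, 0), df = max(dfDiff, 1),
                          lower.tail = FALSE)
  new("ModelFitSet", response = response, predictor = predictor,
      fits = fits, table = tab, selectedDegree = as.integer(sel),
      coefficients = .coefTable(selFit),
      randomInterceptVariance = .reVariance(selFit),
      pValue = pValue, nObs = nrow(df))
}

#' Fit metric ~ trait number
#'
#' For each polynomial degree 1-4, fits the metric against the number of
#' traits in the subset with a per-plot random intercept (maximum
#' likelihood), and selects the minimum-AIC fit, breaking ties toward the
#' lower degree. With a single plot the fit degrades to ordinary least
#' squares.
#'
#' @param sweep data.frame from [runSweep()]
#' @param metric metric name (e.g. `"FRich"`)
#' @param kRange trait numbers to include (default 2:10)
#' @param distance distance type to condition on (default `"gower"`)
#' @param degrees candidate polynomial degrees
#' @return a [ModelFitSet-class]
#' @export
fitMetricVsTraitNumber <- function(sweep, metric, kRange = 2:10,
                                   distance = "gower", degrees = 1:4) {
  df <- sweep[sweep$metric == metric & sweep$distance == distance &
                sweep$k %in% kRange & !is.na(sweep$value), , drop = FALSE]
  if (!nrow(df)) stop("no observations for metric ", metric)
  .fitModelSet(data.frame(value = df$value, x = df$k, plot = df$plot),
               response = metric, predictor = "k", degrees = degrees)
}

#' Fit metric ~ trait-correlation summary at fixed trait number
#'
#' Joins the sweep records at `k = 4` to the per-subset correlation
#' summaries and fits the metric against the chosen correlation statistic
#' with the same polynomial/AIC machinery as
#' [fitMetricVsTraitNumber()].
#'
#' @param sweep data.frame from [runSweep()]
#' @param corr data.frame from [correlationTable()]
#' @param metric metric name
#' @param predictor `"mean"`, `"min"` or `"max"` trait correlation
#' @param distance distance type to condition on
#' @param degrees candidate polynomial degrees
#' @param minSubsets minimum number of distinct subsets required
#' @return a [ModelFitSet-class]
#' @export
fitMetricVsCorrelation <- function(sweep, corr, metric,
                                   predictor = c("mean", "min", "max"),
                                   distance = "gower", degrees = 1:4,
                                   minSubsets = 10) {
  predictor <- match.arg(predictor)
  col <- paste0(predictor, "_corr")
  k <- unique(corr$k)
  df <- sweep[sweep$metric == metric & sweep$distance == distance &
                sweep$k %in% k & !is.na(sweep$value), , drop = FALSE]
  df <- merge(df, corr[, c("subset", col)], by = "subset")
  if (length(unique(df$subset)) < minSubsets)
    stop("need at least ", minSubsets, " subsets for the correlation analysis")
  .fitModelSet(data.frame(value = df$value, x = df[[col]], plot = df$plot),
               response = metric, predictor = paste0(predictor, "_corr"),
               degrees = degrees)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: sort ascending, take
#' `q_(i) = min_(j >= i) (m p_(j) / j)` capped at 1, and return in the
#' original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values, same length and order
#' @export
benjaminiHochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full inference stage on a sweep
#'
#' Fits metric ~ trait number for every metric (and, when a correlation
#' table is supplied, metric ~ min/max/mean trait correlation at `k = 4`),
#' then applies Benjamini-Hochberg adjustment across all tests of the run
#' (the adjustment family is everything fitted in this call).
#'
#' @param sweep data.frame from [runSweep()]
#' @param corr optional data.frame from [correlationTable()]
#' @param metrics metric names to test (default: all eight)
#' @param kRange trait numbers for the trait-number models
#' @param distance distance type to condition on
#' @return list with `table` (metric, predictor, degree, AIC, rawP, adjP,
#'   nObs) and `fits` (the [ModelFitSet-class] objects)
#' @export
runInference <- function(sweep, corr = NULL, metrics = METRIC_NAMES,
                         kRange = 2:10, distance = "gower") {
  fits <- list()
  for (m in metrics) {
    dist <- if (m %in% c("KDErich", "KDEeven", "KDEdisp")) "euclidean"
    else distance
    fit <- tryCatch(
      fitMetricVsTraitNumber(sweep, m, kRange, distance = dist),
      error = function(e) {
        message(sprintf("trait-number model for %s skipped: %s", m,
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(fit)) fits[[paste0(m, "~k")]] <- fit
    if (!is.null(corr)) {
      for (pred in c("min", "max", "mean")) {
        fit <- tryCatch(
          fitMetricVsCorrelation(sweep, corr, m, predictor = pred,
                                 distance = dist),
          error = function(e) {
            message(sprintf("correlation model %s ~ %s skipped: %s", m,
                            pred, conditionMessage(e)))
            NULL
          })
        if (!is.null(fit)) fits[[paste0(m, "~", pred, "_corr")]] <- fit
      }
    }
  }
  if (!length(fits)) stop("no model could be fitted")
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(metric = f@response, predictor = f@predictor,
               degree = f@selectedDegree,
               AIC = f@table$AIC[f@table$degree == f@selectedDegree],
               rawP = f@pValue, nObs = f@nObs,
               stringsAsFactors = FALSE)))
  tab$adjP <- benjaminiHochberg(tab$rawP)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Write an inference summary table to CSV
#' @param inference list from [runInference()]
#' @param path CSV path
#' @export
writeInferenceTable <- function(inference, path) {
  utils::write.csv(inference$table, path, row.names = FALSE)
  invisible(path)
}
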