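test_that("Benjamini-Hochberg reproduces the step-up rule", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjaminiHochberg(0.2), 0.2)
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjaminiHochberg(c(0.1, 1.2)), "0, 1")

  # adjusted values never fall below the raw ones and respect ordering
  set.seed(71)
  p <- runif(20)
  q <- benjaminiHochberg(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("a linear trait-number effect is recovered with degree 1 selected", {
  sweep <- simulateTraitNumberSweep(seed = 5)
  fit <- fitMetricVsTraitNumber(sweep, "FRich")
  expect_equal(fit@selectedDegree, 1L)
  co <- fit@coefficients
  slopeRow <- co[grepl("poly", co$term), ]
  expect_lt(abs(slopeRow$estimate - (-0.1)), 2 * slopeRow$se)
  expect_gte(fit@randomInterceptVariance, 0)
  expect_lt(fit@pValue, 0.001)
})

test_that("a near-constant response selects degree 1 by the AIC tie-break", {
  sweep <- simulateTraitNumberSweep(slope = 0, plotSd = 0, noiseSd = 1e-6,
                                    nPlots = 1, subsetsPerK = 4, seed = 6)
  fit <- suppressWarnings(suppressMessages(
    fitMetricVsTraitNumber(sweep, "FRich")))
  expect_equal(fit@selectedDegree, 1L)
  slope <- fit@coefficients$estimate[grepl("poly", fit@coefficients$term)]
  expect_lt(abs(slope), 1e-5)
})

test_that("quadratic structure beats the linear fit in most replicates", {
  wins <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    sweep <- simulateTraitNumberSweep(nPlots = 10, subsetsPerK = 2,
                                      slope = 0.3, quad = -0.04,
                                      noiseSd = 0.05, seed = 100 + r)
    df <- data.frame(value = sweep$value, x = sweep$k, plot = sweep$plot)
    f1 <- fdsweep:::.fitPoly(df, 1)
    f2 <- fdsweep:::.fitPoly(df, 2)
    if (AIC(f2) < AIC(f1)) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.9)
})

test_that("AIC selects the generating degree in calibration simulations", {
  hits <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    dg <- 1 + (r %% 2)
    # noise sd ~ 25% of the response range over k = 2..10
    sweep <- if (dg == 1)
      simulateTraitNumberSweep(nPlots = 40, subsetsPerK = 1, slope = -0.1,
                               noiseSd = 0.2, plotSd = 0.05, seed = 200 + r)
    else
      simulateTraitNumberSweep(nPlots = 40, subsetsPerK = 1, slope = 0.5,
                               quad = -0.045, noiseSd = 0.22, plotSd = 0.05,
                               seed = 200 + r)
    fit <- fitMetricVsTraitNumber(sweep, "FRich")
    if (fit@selectedDegree == dg) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("metric ~ correlation recovers a linear effect and rejects degenerate input", {
  set.seed(81)
  nSub <- 30
  corr <- data.frame(subset = sprintf("s%02d", 1:nSub), k = 4,
                     min_corr = runif(nSub, 0, 0.3),
                     max_corr = runif(nSub, 0.5, 1),
                     mean_corr = runif(nSub, 0.2, 0.8))
  plots <- sprintf("p%d", 1:8)
  sweep <- expand.grid(plot = plots, subset = corr$subset,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sweep$study <- "s"; sweep$metric <- "FDis"; sweep$distance <- "gower"
  sweep$k <- 4; sweep$dims <- NA_integer_
  b <- -0.8
  plotEff <- rnorm(8, 0, 0.05)
  sweep$value <- 1 + b * corr$mean_corr[match(sweep$subset, corr$subset)] +
    plotEff[match(sweep$plot, plots)] + rnorm(nrow(sweep), 0, 0.1)
  fit <- fitMetricVsCorrelation(sweep, corr, "FDis", predictor = "mean")
  co <- fit@coefficients
  bRow <- co[grepl("poly", co$term), ][1, ]
  expect_lt(abs(bRow$estimate - b), 2.5 * bRow$se)

  # zero-variance predictor errors
  corr0 <- corr; corr0$mean_corr <- 0.5
  expect_error(fitMetricVsCorrelation(sweep, corr0, "FDis",
                                      predictor = "mean"),
               "zero variance")
  # too few subsets errors
  expect_error(fitMetricVsCorrelation(sweep[sweep$subset %in%
                                              corr$subset[1:5], ],
                                      corr, "FDis", predictor = "mean"),
               "at least 10")
})

test_that("null correlation predictors rarely reach adjusted significance", {
  falsePos <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(300 + r)
    nSub <- 25
    corr <- data.frame(subset = sprintf("s%02d", 1:nSub), k = 4,
                       min_corr = runif(nSub), max_corr = runif(nSub),
                       mean_corr = runif(nSub))
    plots <- sprintf("p%d", 1:6)
    sweep <- expand.grid(plot = plots, subset = corr$subset,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sweep$study <- "s"; sweep$metric <- "FDis"; sweep$distance <- "gower"
    sweep$k <- 4; sweep$dims <- NA_integer_
    sweep$value <- rnorm(nrow(sweep))    # pure noise
    ps <- sapply(c("min", "max", "mean"), function(pred)
      fitMetricVsCorrelation(sweep, corr, "FDis", predictor = pred,
                             degrees = 1)@pValue)
    if (any(benjaminiHochberg(ps) < 0.05)) falsePos <- falsePos + 1
  }
  expect_gte(1 - falsePos / reps, 0.9)
})

test_that("a single plot degrades gracefully to ordinary least squares", {
  sweep <- simulateTraitNumberSweep(nPlots = 1, subsetsPerK = 5, seed = 7)
  fit <- fitMetricVsTraitNumber(sweep, "FRich")
  expect_true(is.na(fit@randomInterceptVariance))
  expect_s3_class(fit@fits[[as.character(fit@selectedDegree)]], "lm")
  # the underlying linear effect is still recovered
  co <- fit@coefficients
  slopeRow <- co[grepl("poly", co$term), ][1, ]
  expect_lt(abs(slopeRow$estimate - (-0.1)), 3 * slopeRow$se)
})

test_that("AIC bookkeeping is internally consistent", {
  sweep <- simulateTraitNumberSweep(seed = 8)
  fit <- fitMetricVsTraitNumber(sweep, "FRich")
  tab <- fit@table
  expect_equal(tab$AIC, 2 * tab$nPar - 2 * tab$logLik, tolerance = 1e-6)
})
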