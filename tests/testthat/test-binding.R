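test_that("the one-site fit recovers noiseless dissociation constants exactly", {
  for (kd in c(10, 100, 456, 1400, 4400, 10000)) {
    fit <- fitKd(simulateBindingCurve(kd))
    expect_lt(abs(kdEstimate(fit) - kd) / kd, 1e-6)
    expect_equal(bmaxEstimate(fit), 1)
  }
  # micromolar input converts to nM
  y <- 0.8 * c(0, 5, 10, 20, 50, 100, 200, 500, 1000) /
    (4400 + c(0, 5, 10, 20, 50, 100, 200, 500, 1000))
  f <- fitKd(c(0, 5, 10, 20, 50, 100, 200, 500, 1000) / 1000, y,
             unit = "uM", fixBmax = FALSE)
  expect_lt(abs(kdEstimate(f) - 4400) / 4400, 1e-6)
  expect_equal(bmaxEstimate(f), 0.8, tolerance = 1e-6)
})

test_that("degenerate titrations are rejected before fitting", {
  expect_error(fitKd(c(0, 456), c(0, 0.5)), "3 distinct")
  expect_error(fitKd(c(0, 10, 100), c(0, 0, 0)), "not identifiable")
  expect_error(fitKd(c(0, 10, 100), c(0, NA, 0.5)), "finite")
  expect_warning(fitKd(c(1, 10, 100, 1000), c(0.8, 0.6, 0.4, 0.2)),
                 "decreases")
})

test_that("the estimator is nearly unbiased under titration noise and consistent", {
  set.seed(30)
  est <- replicate(200,
    kdEstimate(fitKd(simulateBindingCurve(456, noiseSd = 0.05))))
  expect_lt(abs(stats::median(est) - 456) / 456, 0.10)
  # bias shrinks as the noise vanishes
  set.seed(31)
  estLo <- replicate(100,
    kdEstimate(fitKd(simulateBindingCurve(456, noiseSd = 0.005))))
  expect_lt(abs(stats::median(estLo) - 456),
            abs(stats::median(est) - 456))
})

test_that("relative binding normalises to the reference and ignores global scale", {
  one <- relativeBinding(c(TelG5 = 12), "TelG5")
  expect_equal(one$relative_intensity, 1)
  tab <- relativeBinding(c(TelG5 = 10, TelG5TTT = 90, TelG5TT = 130),
                         "TelG5")
  expect_equal(tab$relative_intensity, c(1, 9, 13))
  tab2 <- relativeBinding(c(TelG5 = 10, TelG5TTT = 90, TelG5TT = 130) * pi,
                          "TelG5")
  expect_equal(tab2$relative_intensity, tab$relative_intensity)
  expect_error(relativeBinding(c(A = 1), "B"), "not present")
  expect_error(relativeBinding(c(A = 0, B = 1), "A"), "positive")
})

test_that("dynamics and binding pair by construct with a verifiable rank correlation", {
  mkSummary <- function(lab, dd) new("DynamicsSummary", label = lab,
                                     nTotal = 100L, nTransitioning = 50L,
                                     fractionTransitioning = 0.5,
                                     directDensity = dd)
  bind <- relativeBinding(c(TelG5 = 10, TelG5TAA = 4, TelG5TTT = 90,
                            TelG5TT = 130), "TelG5")
  sums <- list(mkSummary("TelG5", 0.05), mkSummary("TelG5TAA", 0.02),
               mkSummary("TelG5TTT", 0.30), mkSummary("TelG5TT", 0.36))
  res <- dynamicsBindingTable(sums, bind)
  expect_equal(nrow(res$table), 4L)
  expect_equal(res$rankCorrelation, 1)

  # one rank swap: verify against a brute-force concordant/discordant count
  sumsSwap <- list(mkSummary("TelG5", 0.05), mkSummary("TelG5TAA", 0.02),
                   mkSummary("TelG5TTT", 0.36), mkSummary("TelG5TT", 0.30))
  resSwap <- dynamicsBindingTable(sumsSwap, bind)
  kendallOracle <- function(x, y) {
    conc <- 0; disc <- 0
    for (i in seq_along(x)) for (j in seq_len(i - 1)) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
    (conc - disc) / choose(length(x), 2)
  }
  expect_equal(resSwap$rankCorrelation,
               kendallOracle(resSwap$table$direct_density,
                             resSwap$table$relative_intensity))

  single <- dynamicsBindingTable(list(mkSummary("TelG5", 0.05)), bind)
  expect_equal(nrow(single$table), 1L)
  expect_true(is.na(single$rankCorrelation))
  expect_error(dynamicsBindingTable(list(mkSummary("X", 0.1)), bind),
               "no shared")
})

test_that("replicate Kd fits aggregate to a mean and spread", {
  set.seed(32)
  fits <- lapply(1:3, function(i)
    fitKd(simulateBindingCurve(456, noiseSd = 0.02)))
  agg <- aggregateKd(fits)
  expect_equal(agg$n, 3)
  expect_equal(agg$mean_kd, mean(vapply(fits, kdEstimate, numeric(1))))
})
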