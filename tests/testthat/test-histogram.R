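test_that("FRET efficiency follows the ratiometric formula with corrections", {
  expect_equal(efficiency(computeFret(constantTrace(d = 500, a = 500))),
               rep(0.5, 100))
  expect_equal(efficiency(computeFret(constantTrace(d = 800, a = 0)))[1], 0)
  expect_equal(efficiency(computeFret(constantTrace(d = 0, a = 800)))[1], 1)
  # leakage and gamma corrections
  tr <- constantTrace(d = 400, a = 600, T = 1)
  e <- efficiency(computeFret(tr, leakage = 0.1, gamma = 1.2))
  expect_equal(e, (600 - 40) / (1.2 * 400 + 600 - 40))
  # zero total intensity pre-bleach -> NA with a warning
  tr0 <- constantTrace(T = 3)
  tr0@donor[2] <- 0
  tr0@acceptor[2] <- 0
  expect_warning(traj <- computeFret(tr0), "zero total intensity")
  expect_true(is.na(efficiency(traj)[2]))
})

test_that("histograms are unit-area and reproduce degenerate and uniform inputs", {
  h <- buildHistogram(makeTraj(rep(0.5, 50)), window = 5)
  w <- diff(binEdges(h))
  expect_equal(sum(binDensity(h) * w), 1)
  occupied <- binDensity(h) > 0
  expect_equal(sum(occupied), 1L)
  expect_equal(binDensity(h)[occupied], 1 / w[occupied])

  set.seed(10)
  hu <- buildHistogram(makeTraj(runif(1e6)), window = 1e9)
  mid <- (binEdges(hu)[-1] + binEdges(hu)[-57]) / 2
  inner <- mid > 0 & mid < 1
  expect_equal(binDensity(hu)[inner], rep(1, sum(inner)), tolerance = 0.02)
  expect_true(all(binDensity(hu)[mid < 0 | mid > 1] == 0))

  expect_error(buildHistogram(makeTraj(NA_real_), window = 2), "no valid")
})

test_that("histogram pooling respects the per-molecule window and bleach truncation", {
  t1 <- makeTraj(c(rep(0.3, 20), rep(0.9, 200)))     # 2 s window: only 0.3
  t2 <- makeTraj(rep(0.7, 100), validUntil = 10)     # bleach truncation
  h <- buildHistogram(list(t1, t2), window = 2)
  mid <- (binEdges(h)[-1] + binEdges(h)[-57]) / 2
  expect_equal(sum(binDensity(h)[abs(mid - 0.9) < 0.05]), 0)
  lowMass <- sum(binDensity(h)[abs(mid - 0.3) < 0.02] * 0.025)
  expect_equal(lowMass, 20 / 30, tolerance = 1e-9)
})

test_that("anchored mixture fits recover planted components", {
  # self-fit of a single exact Gaussian
  h1 <- exactMixtureHistogram(0.47, 0.05, 1)
  f1 <- fitMixture(h1, c(NP = 0.47))
  expect_lt(abs(components(f1)$center - 0.47), 1e-3)
  expect_lt(abs(components(f1)$sd - 0.05), 1e-3)
  expect_equal(unname(population(f1)), 1)

  # two well-separated components at the published population split
  h2 <- exactMixtureHistogram(c(0.47, 0.66), c(0.05, 0.05), c(0.63, 0.37))
  f2 <- fitMixture(h2, c(NP = 0.47, P = 0.66))
  expect_equal(unname(population(f2)), c(0.63, 0.37), tolerance = 0.01)

  # three anchors plus one free component planted at the bound-state level
  h3 <- exactMixtureHistogram(c(0.24, 0.47, 0.66, 0.57),
                              c(0.05, 0.05, 0.05, 0.05),
                              c(0.10, 0.35, 0.25, 0.30))
  f3 <- fitMixture(h3, defaultAnchors(), freeComponents = 1)
  free <- components(f3)[components(f3)$label == "free1", ]
  expect_equal(free$center, 0.57, tolerance = 0.01)
  expect_equal(sum(population(f3)), 1)

  # anchored centers never drift beyond the tolerance
  expect_true(all(abs(components(f3)$center[1:3] -
                        as.numeric(defaultAnchors())) <= 0.01 + 1e-9))
  # tolerance 0 pins the centers exactly
  f0 <- fitMixture(h2, c(NP = 0.47, P = 0.66), tolerance = 0)
  expect_equal(components(f0)$center, c(0.47, 0.66))
})

test_that("differential densities are zero-sum, antisymmetric and track mass transfer", {
  ref <- exactMixtureHistogram(c(0.47, 0.66), c(0.02, 0.02), c(0.5, 0.5))
  d0 <- differentialDensity(ref, ref)
  expect_true(all(binDensity(d0) == 0))
  expect_equal(positiveSum(d0), 0)

  # 20% of the mass redirected into a bound-state component
  with <- exactMixtureHistogram(c(0.47, 0.66, 0.57), c(0.02, 0.02, 0.02),
                                c(0.4, 0.4, 0.2))
  d <- differentialDensity(with, ref)
  w <- diff(binEdges(d))
  expect_lt(abs(sum(binDensity(d) * w)), 1e-9)        # zero net mass
  expect_lt(abs(positiveSum(d) - 0.2), 0.01)
  dRev <- differentialDensity(ref, with)
  expect_equal(binDensity(dRev), -binDensity(d))      # antisymmetry

  other <- exactMixtureHistogram(0.5, 0.05, 1,
                                 breaks = seq(-0.2, 1.2, by = 0.05))
  expect_error(differentialDensity(with, other), "bin edges differ")
})
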