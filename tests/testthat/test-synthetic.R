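test_that("state paths tile the duration with exponential dwell statistics", {
  m1 <- kineticModel("only", matrix(0, 1, 1), 0.5)
  set.seed(1)
  p <- simulateStatePath(m1, 42)
  expect_equal(nrow(segments(p)), 1L)
  expect_equal(segments(p)$start, 0)
  expect_equal(segments(p)$end, 42)

  # closed-form mean dwell 1/rate = 2 s for the symmetric two-state chain
  m2 <- kineticModel(c("A", "B"), matrix(c(0, 0.5, 0.5, 0), 2, byrow = TRUE),
                     c(0.3, 0.7))
  set.seed(2)
  p2 <- simulateStatePath(m2, 1e5)
  seg <- segments(p2)
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])   # contiguous tiling
  d <- (seg$end - seg$start)[-nrow(seg)]             # last dwell censored
  expect_equal(mean(d), 2, tolerance = 0.03)
})

test_that("construct-parameterised paths reproduce their mean dwells within 5%", {
  # 3e4 s keeps the Monte-Carlo error of the rare parallel state below 5%
  m <- presetModel("TelG5TAA", dockedFraction = 0)
  set.seed(3)
  p <- simulateStatePath(m, 3e4)
  seg <- segments(p)[-c(1, nrow(segments(p))), ]     # censor first/last
  got <- tapply(seg$end - seg$start, seg$state, mean)[c("UF", "NP", "P")]
  expect_lt(max(abs(got - c(4.3, 6.1, 11.1)) / c(4.3, 6.1, 11.1)), 0.05)
})

test_that("dwell samples pass an exponential goodness-of-fit check", {
  m <- presetModel("TelG5", dockedFraction = 0)
  set.seed(4)
  dw <- numeric(0)
  while (length(dw) < 1e4) {
    seg <- segments(simulateStatePath(m, 2000))
    keep <- seg$state == "NP"
    keep[c(1, length(keep))] <- FALSE
    dw <- c(dw, (seg$end - seg$start)[keep])
  }
  ks <- suppressWarnings(stats::ks.test(dw, "pexp", rate = 1 / 7.6))
  expect_gt(ks$p.value, 0.01)
})

test_that("long-run state occupancy converges to the CTMC stationary solution", {
  m <- presetModel("TelG5TTT", dockedFraction = 0)
  set.seed(5)
  seg <- segments(simulateStatePath(m, 1e4))
  occ <- tapply(seg$end - seg$start, seg$state, sum) / 1e4
  pi <- ctmcStationary(m)
  expect_lt(max(abs(occ[names(pi)] - as.numeric(pi))), 0.03)
})

test_that("the camera model renders exact intensities without noise", {
  m <- kineticModel("s", matrix(0, 1, 1), 0.5, emissionSd = 1e-12)
  cfg <- simulationConfig(m, nMolecules = 1, duration = 1,
                          intensityNoiseSd = 0, seed = 1)
  set.seed(1)
  tr <- renderIntensities(simulateStatePath(m, 1), cfg)
  expect_equal(donor(tr), rep(500, 10), tolerance = 1e-6)
  expect_equal(acceptor(tr), rep(500, 10), tolerance = 1e-6)

  # a switch at a frame boundary renders each frame at its segment level
  m2 <- kineticModel(c("lo", "hi"), matrix(0, 2, 2), c(0.2, 0.8),
                     emissionSd = 1e-12)
  p <- new("StatePath", moleculeId = "x",
           segments = data.frame(state = c("lo", "hi"),
                                 start = c(0, 0.5), end = c(0.5, 1)),
           centers = c(lo = 0.2, hi = 0.8), source = "simulated")
  cfg2 <- simulationConfig(m2, nMolecules = 1, duration = 1,
                           intensityNoiseSd = 0, seed = 1)
  set.seed(1)
  tr2 <- renderIntensities(p, cfg2, m2)
  e <- acceptor(tr2) / (donor(tr2) + acceptor(tr2))
  expect_equal(e, rep(c(0.2, 0.8), each = 5), tolerance = 1e-9)
})

test_that("computed FRET of rendered frames averages to the emission level", {
  m <- kineticModel("NP", matrix(0, 1, 1), 0.47)
  cfg <- simulationConfig(m, nMolecules = 1, duration = 1000, seed = 6)
  set.seed(6)
  tr <- renderIntensities(simulateStatePath(m, 1000, initialState = "NP"),
                          cfg)
  e <- efficiency(computeFret(tr))
  expect_equal(mean(e), 0.47, tolerance = 0.01)
})

test_that("dataset generation honours the docked fraction exactly and is deterministic", {
  m <- presetModel("TelG5", dockedFraction = 1)
  cfg <- simulationConfig(m, nMolecules = 20, duration = 10, seed = 7)
  set <- simulateDataset(cfg)
  nseg <- vapply(groundTruth(set)$paths, function(p) nrow(segments(p)),
                 integer(1))
  expect_true(all(nseg == 1L))

  m2 <- presetModel("TelG5", dockedFraction = 0.52)
  cfg2 <- simulationConfig(m2, nMolecules = 250, duration = 2, seed = 8)
  set2 <- simulateDataset(cfg2)
  expect_equal(sum(groundTruth(set2)$docked), floor(0.52 * 250))

  # identical config twice -> bit-identical traces
  setA <- simulateDataset(cfg2)
  expect_identical(lapply(traces(setA), donor), lapply(traces(set2), donor))
  expect_identical(lapply(traces(setA), acceptor),
                   lapply(traces(set2), acceptor))
})

test_that("binding-curve generation evaluates the one-site model", {
  cv <- simulateBindingCurve(100, concentrations = c(0, 100, 1000))
  expect_equal(cv@boundFraction, c(0, 0.5, 1000 / 1100))
  cv2 <- simulateBindingCurve(456)
  expect_equal(cv2@boundFraction[cv2@concentrations == 1000], 1000 / 1456)
  expect_equal(cv2@boundFraction[cv2@concentrations == 0], 0)
  expect_error(simulateBindingCurve(-1), "kd")
})
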