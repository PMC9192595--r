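test_that("a noiseless square wave is segmented exactly with K = 2", {
  e <- rep(rep(c(0.3, 0.7), each = 25), times = 4)
  r <- inferStatePath(makeTraj(e), details = TRUE)
  expect_equal(r$report$K[r$report$selected], 2)
  seg <- segments(r$path)
  expect_equal(nrow(seg), 8L)
  expect_equal(seg$end[-8], seq(2.5, 17.5, by = 2.5))
  expect_equal(unname(stateCenters(r$path)), c(0.3, 0.7))
})

test_that("single-level traces reject extra states through the selection penalty", {
  set.seed(20)
  e <- pmin(1.2, pmax(-0.2, rnorm(500, 0.47, 0.06)))
  r <- inferStatePath(makeTraj(e), details = TRUE)
  expect_equal(nrow(segments(r$path)), 1L)
  expect_equal(r$nStates, 1L)
  expect_error(inferStatePath(makeTraj(rep(0.5, 10))), "20 valid frames")
})

test_that("frame-level inference recovers simulated 3-state paths above 95% accuracy", {
  cfg <- simulationConfig(presetModel("TelG5", dockedFraction = 0),
                          nMolecules = 10, duration = 200, seed = 11)
  set <- simulateDataset(cfg)
  trajs <- computeFretSet(set)
  truth <- groundTruth(set)$paths
  acc <- vapply(names(trajs), function(id) {
    p <- assignStateLabels(inferStatePath(trajs[[id]]), defaultAnchors())
    T <- validUntil(trajs[[id]])
    mean(frameStates(p, T) == frameStates(truth[[id]], T))
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("state labelling maps centers to anchors with the stated tie and distance rules", {
  mkpath <- function(centers) {
    labs <- paste0("S", seq_along(centers))
    st <- rep(labs, length.out = max(2, length(centers)))
    st <- labs
    seg <- data.frame(state = labs,
                      start = seq(0, by = 1, length.out = length(labs)),
                      end = seq(1, by = 1, length.out = length(labs)))
    new("StatePath", moleculeId = "x", segments = seg,
        centers = stats::setNames(centers, labs), source = "inferred")
  }
  a <- defaultAnchors(includeBD = TRUE)
  p1 <- assignStateLabels(mkpath(c(0.25, 0.48, 0.65)), defaultAnchors())
  expect_equal(segments(p1)$state, c("UF", "NP", "P"))
  p2 <- assignStateLabels(mkpath(c(0.25, 0.57)), a)
  expect_equal(segments(p2)$state[2], "BD")
  # exact midpoint between NP (0.47) and BD (0.57) resolves to the lower anchor
  p3 <- assignStateLabels(mkpath(c(0.52, 0.24)), c(NP = 0.47, BD = 0.57))
  expect_equal(segments(p3)$state[1], "NP")
  # farther than 0.08 from every anchor -> other
  p4 <- assignStateLabels(mkpath(c(0.05, 0.47)), defaultAnchors())
  expect_equal(segments(p4)$state[1], "other")
  expect_error(assignStateLabels(p4, numeric(0)), "anchors")
})

test_that("docked and transitioning molecules are classified from their state path", {
  set.seed(12)
  docked <- pmin(1.2, pmax(-0.2, rnorm(1000, 0.47, 0.066)))
  expect_equal(classifyTrajectory(makeTraj(docked)), "docked")
  switcher <- rep(rep(c(0.47, 0.66), each = 50), 10) +
    rnorm(1000, 0, 0.066)
  expect_equal(classifyTrajectory(makeTraj(pmin(1.2, pmax(-0.2, switcher)))),
               "transitioning")
  # sub-threshold jumps do not count
  small <- rep(rep(c(0.50, 0.57), each = 50), 10) + rnorm(1000, 0, 0.02)
  expect_equal(classifyTrajectory(makeTraj(small), minJump = 0.1), "docked")
  expect_warning(classifyTrajectory(makeTraj(docked[1:300])), "window")
})

test_that("transition counting matches hand counts and keeps BD/other apart", {
  seg <- data.frame(state = c("UF", "NP", "UF", "P"),
                    start = 0:3, end = 1:4)
  p <- new("StatePath", moleculeId = "m", segments = seg,
           centers = c(UF = 0.24, NP = 0.47, P = 0.66),
           source = "simulated")
  ct <- countTransitions(p)
  expect_equal(transitionCounts(ct)[["UF->NP"]], 1)
  expect_equal(transitionCounts(ct)[["NP->UF"]], 1)
  expect_equal(transitionCounts(ct)[["UF->P"]], 1)
  expect_equal(ct@nTransitions, 3)

  ct0 <- countTransitions(list())
  expect_equal(ct0@nTransitions, 0)

  segB <- data.frame(state = c("NP", "BD", "P"), start = 0:2, end = 1:3)
  pB <- new("StatePath", moleculeId = "b", segments = segB,
            centers = c(NP = 0.47, BD = 0.57, P = 0.66),
            source = "simulated")
  ctB <- countTransitions(pB)
  expect_equal(ctB@nTransitions, 0)          # BD pairs excluded from core
  expect_equal(sum(ctB@extra), 2)
})

test_that("dwell tables censor terminal segments and flag undefined means", {
  seg <- data.frame(state = c("UF", "NP", "P"), start = c(0, 2, 9.6),
                    end = c(2, 9.6, 12))
  p <- new("StatePath", moleculeId = "m", segments = seg,
           centers = c(UF = 0.24, NP = 0.47, P = 0.66), source = "simulated")
  dt <- dwellAnalysis(p)
  expect_equal(unname(dwellMeans(dt)["NP"]), 7.6)
  expect_true(is.na(dwellMeans(dt)["UF"]))   # first dwell censored
  expect_true(is.na(dwellMeans(dt)["P"]))    # last dwell censored

  single <- new("StatePath", moleculeId = "s",
                segments = data.frame(state = "NP", start = 0, end = 5),
                centers = c(NP = 0.47), source = "simulated")
  expect_true(all(is.na(dwellMeans(dwellAnalysis(single)))))
})

test_that("transition density plots are normalised and respect detailed balance", {
  seg <- data.frame(state = c("UF", "NP"), start = 0:1, end = 1:2)
  p <- new("StatePath", moleculeId = "m", segments = seg,
           centers = c(UF = 0.24, NP = 0.47), source = "simulated")
  tdp <- transitionDensityPlot(p)
  expect_equal(sum(tdp$density), 1)
  expect_equal(sum(tdp$density > 0), 1L)
  expect_false(tdp$empty)
  expect_true(transitionDensityPlot(list())$empty)

  # reversible two-state chain -> symmetric density across the diagonal
  m2 <- kineticModel(c("NP", "P"), matrix(c(0, 0.4, 0.4, 0), 2, byrow = TRUE),
                     c(0.47, 0.66))
  set.seed(13)
  paths <- lapply(1:50, function(i) simulateStatePath(m2, 100, paste0("m", i)))
  tdp2 <- transitionDensityPlot(paths)
  expect_equal(sum(tdp2$density), 1)
  expect_equal(max(abs(tdp2$density - t(tdp2$density))), 0,
               tolerance = 0.05)

  # direct-transition-dominated construct concentrates mass in NP<->P cells
  m3 <- presetModel("TelG5TTT", dockedFraction = 0)
  set.seed(14)
  paths3 <- lapply(1:50, function(i) simulateStatePath(m3, 100, paste0("m", i)))
  tdp3 <- transitionDensityPlot(paths3)
  mid <- (tdp3$breaks[-1] + tdp3$breaks[-length(tdp3$breaks)]) / 2
  iNP <- which.min(abs(mid - 0.47)); iP <- which.min(abs(mid - 0.66))
  expect_gt(tdp3$density[iNP, iP] + tdp3$density[iP, iNP], 0.5)
})

test_that("the direct-transition density follows its defining formula", {
  ct <- new("TransitionCounts",
            counts = c("UF->NP" = 5, "NP->UF" = 0, "UF->P" = 0, "P->UF" = 0,
                       "NP->P" = 3, "P->NP" = 2),
            extra = numeric(0), nTransitions = 10)
  s <- directTransitionDensity(ct, nTotal = 10, nTransitioning = 5)
  expect_equal(directDensity(s), 0.25)
  expect_equal(fractionTransitioning(s), 0.5)

  ctNo <- new("TransitionCounts",
              counts = c("UF->NP" = 4, "NP->UF" = 4, "UF->P" = 0, "P->UF" = 0,
                         "NP->P" = 0, "P->NP" = 0),
              extra = numeric(0), nTransitions = 8)
  expect_equal(directDensity(directTransitionDensity(ctNo, 10, 5)), 0)
  s0 <- directTransitionDensity(countTransitions(list()), 10, 0)
  expect_equal(directDensity(s0), 0)
  # bounded by the transitioning fraction
  expect_lte(directDensity(s), fractionTransitioning(s))
})

test_that("a stronger direct NP<->P pathway strictly raises the statistic", {
  base <- presetModel("TelG5", dockedFraction = 0)
  r4 <- transitionRates(base)
  r4["NP", "P"] <- 4 * r4["NP", "P"]
  r4["P", "NP"] <- 4 * r4["P", "NP"]
  fast <- kineticModel(stateLabels(base), r4, base@emissionMean)
  dd <- vapply(list(base, fast), function(m) {
    set.seed(15)
    paths <- lapply(1:100, function(i) simulateStatePath(m, 200, paste0("m", i)))
    directDensity(directTransitionDensity(countTransitions(paths), 100, 100))
  }, numeric(1))
  expect_gt(dd[2], dd[1])
})

test_that("statistics from inferred paths equal ground-truth recomputation on noiseless data", {
  m <- presetModel("TelG5", dockedFraction = 0)
  sim <- simulateNoiseless(m, n = 30, duration = 100, seed = 21)
  inferred <- lapply(sim$trajs, function(tr)
    assignStateLabels(inferStatePath(tr), defaultAnchors()))
  ci <- countTransitions(inferred)
  ct <- countTransitions(sim$paths)
  expect_identical(transitionCounts(ci), transitionCounts(ct))
  expect_identical(dwellMeans(dwellAnalysis(inferred))[c("UF", "NP", "P")],
                   dwellMeans(dwellAnalysis(sim$paths))[c("UF", "NP", "P")])
  ti <- transitionDensityPlot(inferred)
  tt <- transitionDensityPlot(sim$paths)
  expect_equal(ti$density, tt$density)
})
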