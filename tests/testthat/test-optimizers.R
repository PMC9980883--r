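test_that("LSE matches the identity and normal-equations oracles", {
  ## identity lead field: raw currents are the target vector itself
  lfI <- leadFieldFromMatrix(diag(4))
  tg <- TargetSpec(list(c(1L, 3L)), nNodes = 4)
  p <- lseOptimize(lfI, tg)
  free <- f1Currents(p)[-1]
  expect_equal(free / max(abs(free)), c(1, 0, 1, 0))

  ## random well-conditioned instances vs (E'E)^-1 E' Etarget
  set.seed(404)
  for (rep in 1:10) {
    E <- matrix(rnorm(20 * 8), 20, 8)
    lf <- leadFieldFromMatrix(E)
    tgt <- TargetSpec(list(sample(20, 4)), nNodes = 20)
    et <- targetField(tgt)
    oracle <- solve(crossprod(E), crossprod(E, et))[, 1]
    pLse <- lseOptimize(lf, tgt)
    pOracle <- normalizeCurrents(CurrentPattern(expandCurrents(oracle)))
    expect_equal(f1Currents(pLse), f1Currents(pOracle), tolerance = 1e-8)
  }
  ## both channels equal: single-frequency stimulation
  expect_identical(f1Currents(p), f2Currents(p))
})

test_that("an all-zero ideal field is rejected as a degenerate montage", {
  lf <- leadFieldFromMatrix(matrix(rnorm(12), 6, 2), nElec = 3L)
  tg <- TargetSpec(list(1:2), nNodes = 6, targetField = rep(0, 6))
  expect_error(lseOptimize(lf, tg), "degenerate")
})

test_that("analytic pipeline gradients agree with central finite differences", {
  ns <- asNamespace("tistim")
  fx <- tinyFixture(61, n_nodes = 25, n_electrodes = 5)
  E <- lfMatrix(fx$lf)
  cases <- list(
    list(mode = "tTIS", form = "envelope_min", normMode = "per_frequency"),
    list(mode = "tTIS", form = "signed_difference", normMode = "per_frequency"),
    list(mode = "tTIS", form = "envelope_min", normMode = "joint"),
    list(mode = "tACS", form = "envelope_min", normMode = "per_frequency")
  )
  set.seed(62)
  for (cs in cases) {
    env <- list(E = E, ref = 1L, F = ncol(E), tidx = targetNodes(fx$target),
                slope = 1, mode = cs$mode, form = cs$form,
                normMode = cs$normMode)
    nOut <- if (cs$mode == "tTIS") 2L * ncol(E) else ncol(E)
    o <- rnorm(nOut)
    res <- ns$.usnnPipeline(o, env)
    h <- 1e-6
    gnum <- vapply(seq_along(o), function(j) {
      op <- o; om <- o
      op[j] <- op[j] + h; om[j] <- om[j] - h
      (ns$.usnnPipeline(op, env)$loss - ns$.usnnPipeline(om, env)$loss) / (2 * h)
    }, 1)
    expect_lt(max(abs(gnum - res$dOut)), 1e-6 * (1 + max(abs(gnum))))
  }
})

test_that("generator training beats the uniform-currents baseline on a separable fixture", {
  ## column 1 is exactly the binary target vector; the other columns are
  ## supported off-target, so one pair can hit the target cleanly
  set.seed(71)
  E <- cbind(c(rep(1, 3), rep(0, 9)),
             c(rep(0, 3), rnorm(9) * 0.5),
             c(rep(0, 3), rnorm(9) * 0.5))
  lf <- leadFieldFromMatrix(E)
  tg <- TargetSpec(list(1:3), nNodes = 12)
  baseline <- patternLoss(
    lf, normalizeCurrents(CurrentPattern(expandCurrents(rep(1, 3)))), tg)
  res <- usnnOptimize(lf, tg, UsnnConfig(epochs = 200L, seed = 7L))
  h <- lossHistory(res)
  expect_lt(min(h), h[1])
  expect_lt(min(h), baseline)
  expect_gt(finalMetrics(res)@PR, 1)
})

test_that("with one effective node the optimum saturates both channels at 2 mA", {
  lf <- leadFieldFromMatrix(matrix(c(0.1, 0), 2, 1), nElec = 2L)
  tg <- TargetSpec(list(1L), nNodes = 2)
  res <- usnnOptimize(lf, tg, UsnnConfig(epochs = 30L, seed = 1L))
  p <- bestPattern(res)
  expect_equal(sort(abs(f1Currents(p))), c(2, 2), tolerance = 1e-12)
  expect_equal(sort(abs(f2Currents(p))), c(2, 2), tolerance = 1e-12)
})

test_that("small-instance generator loss approaches the grid-search optimum", {
  ## stochastic optimizer: run the default configuration from a small set of
  ## starts and compare the best against the dense direction-grid optimum
  fx <- tinyFixture(81, n_nodes = 10, n_electrodes = 3, k = 2)
  gridBest <- gridSearchOptimum(fx$lf, fx$target, nAngle = 180L)
  best <- min(vapply(1:3, function(s) {
    min(lossHistory(usnnOptimize(fx$lf, fx$target, UsnnConfig(seed = s))))
  }, 1))
  expect_lte(best, 1.05 * gridBest)
})

test_that("returned patterns satisfy the stage-I safety invariants exactly", {
  fx <- tinyFixture(91)
  res <- usnnOptimize(fx$lf, fx$target, UsnnConfig(epochs = 60L, seed = 3L))
  ga <- gaOptimize(fx$lf, fx$target,
                   GaConfig(population = 20L, generations = 10L,
                            eliteCount = 2L, seed = 3L))
  lse <- lseOptimize(fx$lf, fx$target)
  for (p in list(bestPattern(res), bestPattern(ga), lse)) {
    expect_equal(currentStage(p), "I")
    for (ch in list(f1Currents(p), f2Currents(p))) {
      expect_lte(max(abs(ch)), 2 + 1e-9)
      expect_lte(sum(abs(ch)), 8 + 1e-9)
      expect_lt(abs(sum(ch)), 1e-9)
    }
  }
})

test_that("recorded best loss is consistent with re-evaluating the returned pattern", {
  fx <- tinyFixture(95)
  res <- usnnOptimize(fx$lf, fx$target, UsnnConfig(epochs = 80L, seed = 5L))
  expect_equal(min(lossHistory(res)),
               patternLoss(fx$lf, bestPattern(res), fx$target),
               tolerance = 1e-9)
  ga <- gaOptimize(fx$lf, fx$target,
                   GaConfig(population = 15L, generations = 8L,
                            eliteCount = 2L, seed = 5L))
  expect_equal(min(lossHistory(ga)),
               patternLoss(fx$lf, bestPattern(ga), fx$target),
               tolerance = 1e-9)
})

test_that("tACS-mode output evaluated through the interference pipeline is identical", {
  fx <- tinyFixture(97)
  res <- usnnOptimize(fx$lf, fx$target,
                      UsnnConfig(epochs = 60L, seed = 4L, mode = "tACS"))
  p <- bestPattern(res)
  expect_identical(f1Currents(p), f2Currents(p))
  f <- computeField(fx$lf, f1Currents(p))
  mA <- computeMetrics(tacsModulation(f), fx$target)
  mTI <- evaluatePattern(fx$lf, p, fx$target)
  expect_equal(mTI@PR, mA@PR, tolerance = 1e-12)
  expect_equal(mTI@loss, mA@loss, tolerance = 1e-12)
})

test_that("optimizers are deterministic for a fixed seed", {
  fx <- tinyFixture(99)
  a <- usnnOptimize(fx$lf, fx$target, UsnnConfig(epochs = 40L, seed = 11L))
  b <- usnnOptimize(fx$lf, fx$target, UsnnConfig(epochs = 40L, seed = 11L))
  expect_identical(lossHistory(a), lossHistory(b))
  expect_identical(f1Currents(bestPattern(a)), f1Currents(bestPattern(b)))
  g1 <- gaOptimize(fx$lf, fx$target,
                   GaConfig(population = 16L, generations = 6L,
                            eliteCount = 2L, seed = 12L))
  g2 <- gaOptimize(fx$lf, fx$target,
                   GaConfig(population = 16L, generations = 6L,
                            eliteCount = 2L, seed = 12L))
  expect_identical(lossHistory(g1), lossHistory(g2))
})

test_that("GA elitism makes the per-generation best loss non-increasing", {
  fx <- tinyFixture(103)
  ga <- gaOptimize(fx$lf, fx$target,
                   GaConfig(population = 30L, generations = 15L,
                            eliteCount = 3L, mutationRate = 0.3, seed = 8L))
  expect_true(all(diff(lossHistory(ga)) <= 1e-12))
})

test_that("two-pair GA at saturation finds the exhaustively enumerated optimum", {
  set.seed(111)
  E <- matrix(rnorm(4), 2, 2)
  lf <- leadFieldFromMatrix(E, nElec = 3L)
  tg <- TargetSpec(list(1L), nNodes = 2)
  ## exhaustive enumeration over ordered anode/cathode pairs per frequency
  pairLoss <- function(an1, ca1, an2, ca2) {
    c1 <- numeric(3); c1[an1] <- 1; c1[ca1] <- -1
    c2 <- numeric(3); c2[an2] <- 1; c2[ca2] <- -1
    patternLoss(lf, normalizeCurrents(CurrentPattern(c1, c2)), tg)
  }
  best <- Inf
  for (a1 in 1:3) for (c1 in setdiff(1:3, a1)) {
    for (a2 in 1:3) for (c2 in setdiff(1:3, a2)) {
      best <- min(best, pairLoss(a1, c1, a2, c2))
    }
  }
  ga <- gaOptimize(lf, tg, GaConfig(population = 60L, generations = 40L,
                                    chromosomeKind = "two_pair",
                                    mutationRate = 0.4, eliteCount = 5L,
                                    seed = 21L))
  expect_equal(min(lossHistory(ga)), best, tolerance = 1e-9)
})

test_that("elite-only dynamics freeze the best loss after the first generation", {
  fx <- tinyFixture(107)
  ga <- gaOptimize(fx$lf, fx$target,
                   GaConfig(population = 12L, generations = 8L,
                            crossoverRate = 0, mutationRate = 0,
                            eliteCount = 2L, seed = 9L))
  h <- lossHistory(ga)
  expect_true(all(h[-1] == h[1]))
})

test_that("configuration validity is enforced", {
  expect_error(UsnnConfig(epochs = 0L), "epochs")
  expect_error(UsnnConfig(learningRate = 0), "learningRate")
  expect_error(UsnnConfig(mode = "foo"), "mode")
  expect_error(GaConfig(population = 1L), "population")
  expect_error(GaConfig(population = 10L, eliteCount = 10L), "eliteCount")
  expect_error(GaConfig(population = 10L, eliteCount = 6L), "2 \\* eliteCount")
  expect_error(GaConfig(crossoverRate = 1.5), "crossoverRate")
})
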