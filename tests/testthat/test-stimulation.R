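test_that("field computation matches the dense loop oracle and the definitions", {
  fx <- tinyFixture(21, n_nodes = 5, n_electrodes = 4)
  E <- lfMatrix(fx$lf)
  set.seed(33)
  free <- rnorm(3)
  cur <- expandCurrents(free)
  expect_equal(computeField(fx$lf, cur), loopFieldOracle(E, free),
               tolerance = 1e-12)
  ## all-zero currents give a zero field
  expect_equal(computeField(fx$lf, rep(0, 4)), rep(0, 5))
  ## unit pair current reads out a lead-field column exactly
  expect_equal(computeField(fx$lf, expandCurrents(c(0, 1, 0))), E[, 2])
  ## contract errors
  expect_error(computeField(fx$lf, c(1, 0, 0, 0)), "sum to zero")
  expect_error(computeField(fx$lf, c(1, -1)), "expected 4 currents")
})

test_that("modulation forms implement the beat envelope and its signed variant", {
  expect_equal(modulation(1, 1), 2)
  expect_equal(modulation(1, 1, "envelope_min"), 2)
  expect_equal(modulation(1, 0), 0)
  expect_equal(modulation(1, 0, "envelope_min"), 0)
  expect_equal(modulation(1, -0.5), -1)
  expect_equal(modulation(1, -0.5, "envelope_min"), 1)
  expect_error(modulation(1:3, 1:2), "length mismatch")
  ## tACS: peak-to-peak, twice the amplitude
  expect_equal(tacsModulation(0), 0)
  expect_equal(tacsModulation(-3), 6)
  f <- c(-2, 0.5, 1)
  expect_equal(tacsModulation(f), modulation(f, f, "envelope_min"))
})

test_that("modulation properties hold over random field pairs", {
  set.seed(101)
  for (rep in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    for (form in c("signed_difference", "envelope_min")) {
      expect_equal(modulation(a, b, form), modulation(b, a, form))
    }
    env <- modulation(a, b, "envelope_min")
    expect_true(all(env <= 2 * abs(a) + 1e-12))
    expect_true(all(env <= 2 * abs(b) + 1e-12))
    agree <- a * b >= 0
    expect_equal(modulation(a, b)[agree], env[agree])
  }
})

test_that("focality ratios match brute force and direct reads", {
  expect_equal(peakRatio(c(5, 1, 1), 1L), 5)
  expect_equal(peakRatio(rep(2, 10), 1:3), 1)
  expect_equal(misStimulationRatio(c(2, 2, 0, 0), 1:2), 0)
  expect_equal(misStimulationRatio(c(1, 3, 3), 1L), 2)
  expect_equal(concentrationRatio(rep(1, 8), 2:3), 1)
  ## all modulation on target reaches the algebraic maximum N/|target|
  m <- c(1, 2, 0, 0, 0, 0, 0, 0)
  expect_equal(concentrationRatio(m, 1:2), 4)
  set.seed(77)
  for (rep in 1:25) {
    mod <- runif(100)
    tidx <- sample(100, 10)
    bf <- bruteForceRatios(mod, tidx)
    expect_equal(peakRatio(mod, tidx), bf$PR, tolerance = 1e-12)
    expect_equal(concentrationRatio(mod, tidx), bf$CR, tolerance = 1e-12)
    expect_equal(misStimulationRatio(mod, tidx), bf$MR, tolerance = 1e-12)
  }
  ## contract and degenerate cases
  expect_error(peakRatio(1:5, integer(0)), "empty target")
  expect_error(peakRatio(1:5, 1:5), "non-target")
  expect_warning(expect_equal(peakRatio(rep(0, 4), 1L), 0), "0/0")
  expect_equal(peakRatio(c(1, 0, 0), 1L), Inf)
  expect_equal(concentrationRatio(rep(0, 4), 1L), 0)
})

test_that("ratios are scale invariant; the smooth mis-area is not", {
  set.seed(5)
  mod <- runif(60); tidx <- 1:6
  for (c in c(0.1, 3, 17)) {
    expect_equal(peakRatio(c * mod, tidx), peakRatio(mod, tidx))
    expect_equal(concentrationRatio(c * mod, tidx), concentrationRatio(mod, tidx))
    expect_equal(misStimulationRatio(c * mod, tidx), misStimulationRatio(mod, tidx))
  }
  expect_false(isTRUE(all.equal(misAreaSmooth(3 * mod, tidx),
                                misAreaSmooth(mod, tidx))))
})

test_that("smooth mis-area behaves like a sigmoid relaxation of the count", {
  ## every non-target node exactly at the target mean contributes 0.5
  mod <- c(2, 2, 2, 2, 2, 2)
  expect_equal(misAreaSmooth(mod, 1:2), 0.5 * 4)
  ## saturation
  expect_equal(misAreaSmooth(c(1, 1, 1e6), 1:2), 1, tolerance = 1e-6)
  ## steep slope converges to the exact count on tie-free instances
  set.seed(12)
  mod <- runif(80); tidx <- sample(80, 8)
  exact <- misStimulationRatio(mod, tidx) * 8
  expect_lt(abs(misAreaSmooth(mod, tidx, slope = 1e3) - exact), 0.5)
  expect_error(misAreaSmooth(mod, tidx, slope = 0), "slope")
})

test_that("the three-ratio loss reduces to plug-in arithmetic on uniform modulation", {
  n <- 100; tidx <- 1:10
  mod <- rep(1, n)
  ## PR = CR = 1, smooth MR = 0.5 * 90 / 10
  expect_equal(stimLoss(mod, tidx), 0.5 * 90 / 10)
  ## scaling only enters through the sigmoid (needs spread around the mean)
  set.seed(61)
  spread <- runif(n)
  expect_false(isTRUE(all.equal(stimLoss(2 * spread, tidx),
                                stimLoss(spread, tidx))))
  expect_equal(misStimulationRatio(2 * spread, tidx),
               misStimulationRatio(spread, tidx))
  ## degenerate montage
  w <- capture_warnings(v <- stimLoss(rep(0, 10), 1:2))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(v, Inf)
})

test_that("safety normalization enforces both current limits exactly", {
  ## a single pair: only the 2 mA cap binds
  p <- normalizeCurrents(CurrentPattern(c(4, -4)))
  expect_equal(f1Currents(p), c(2, -2))
  expect_equal(currentStage(p), "I")
  ## ten alternating electrodes: the 8 mA cap binds
  raw <- rep(c(1, -1), 5)
  p10 <- normalizeCurrents(CurrentPattern(raw))
  expect_equal(f1Currents(p10), rep(c(0.8, -0.8), 5), tolerance = 1e-12)
  expect_equal(sum(abs(f1Currents(p10))), 8, tolerance = 1e-12)
  ## idempotence when the sum cap is slack
  p2 <- normalizeCurrents(p)
  expect_equal(f1Currents(p2), f1Currents(p), tolerance = 1e-12)
  ## joint mode caps the concatenated channels
  pj <- normalizeCurrents(CurrentPattern(c(4, -4), c(1, -1)), mode = "joint")
  expect_equal(f1Currents(pj), c(2, -2))
  expect_equal(f2Currents(pj), c(0.5, -0.5))
  expect_error(normalizeCurrents(CurrentPattern(rep(0, 4))), "degenerate")
})

test_that("normalization preserves zero-sum and satisfies the bounds for random inputs", {
  set.seed(2024)
  for (rep in 1:50) {
    raw <- rnorm(12)
    raw <- raw - mean(raw)
    p <- normalizeCurrents(CurrentPattern(raw, rev(raw)))
    for (ch in list(f1Currents(p), f2Currents(p))) {
      expect_lt(abs(sum(ch)), 1e-9)
      expect_lte(max(abs(ch)), 2 + 1e-9)
      expect_lte(sum(abs(ch)), 8 + 1e-9)
    }
  }
})

## six-node fixture with hand-computed metrics:
## E = [1 0; 2 0; 0 1; 0 .5; .5 .25; .1 .1], f1 = pair(e2, ref), f2 = pair(e3, ref)
## normalized fields f1 = (2,4,0,0,1,.2), f2 = (0,0,2,1,.5,.2)
## envelope modulation (0,0,0,0,1,.4); target = node 5
handFixture <- function() {
  obj <- list(
    format_version = "1",
    leadfield = matrix(c(1, 2, 0, 0, 0.5, 0.1,
                         0, 0, 1, 0.5, 0.25, 0.1), ncol = 2),
    node_coords = cbind(seq(10, 60, by = 10), 0, 0),
    node_normals = cbind(1, 0, 0)[rep(1, 6), ],
    electrode_positions = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
    electrode_labels = c("ref", "a", "b")
  )
  p <- tempfile(); saveRDS(obj, p)
  loadLeadField(p)
}

test_that("end-to-end evaluation matches the hand calculation on the six-node fixture", {
  lf <- handFixture()
  pat <- normalizeCurrents(CurrentPattern(c(-1, 1, 0), c(-1, 0, 1)))
  tg <- TargetSpec(list(5L), nNodes = 6)
  m <- evaluatePattern(lf, pat, tg)
  expect_equal(m@PR, 2.5, tolerance = 1e-12)
  expect_equal(m@CR, 6 / 1.4, tolerance = 1e-12)
  expect_equal(m@MRexact, 0)
  sigm <- function(x) 1 / (1 + exp(-x))
  mrsHand <- 4 * sigm(-1) + sigm(-0.6)
  expect_equal(m@MRsmooth, mrsHand, tolerance = 1e-12)
  expect_equal(m@loss, mrsHand / (2.5 * 6 / 1.4), tolerance = 1e-12)
})

test_that("a tied-channel pattern reduces to the tACS pipeline", {
  fx <- tinyFixture(31)
  raw <- expandCurrents(c(1, -0.5, 0.25, 0.5))
  pat <- normalizeCurrents(CurrentPattern(raw, raw))
  f <- computeField(fx$lf, f1Currents(pat))
  mTI <- evaluatePattern(fx$lf, pat, fx$target)
  mA <- computeMetrics(tacsModulation(f), fx$target)
  expect_equal(mTI@PR, mA@PR, tolerance = 1e-12)
  expect_equal(mTI@CR, mA@CR, tolerance = 1e-12)
  expect_equal(mTI@MRexact, mA@MRexact, tolerance = 1e-12)
  expect_equal(mTI@loss, mA@loss, tolerance = 1e-12)
})

test_that("per-region metrics reduce to global metrics on the whole-node partition", {
  fx <- tinyFixture(41)
  pat <- normalizeCurrents(CurrentPattern(expandCurrents(c(1, 0, -1, 0.5))))
  m <- evaluatePattern(fx$lf, pat, fx$target,
                       partitions = list(seq_len(nNodes(fx$lf))))
  expect_equal(nrow(m@perRegion), 1L)
  expect_equal(m@perRegion$PR[1], m@PR, tolerance = 1e-12)
  expect_equal(m@perRegion$CR[1], m@CR, tolerance = 1e-12)
  expect_equal(m@perRegion$MRexact[1], m@MRexact, tolerance = 1e-12)
  ## partitions must cover all nodes
  expect_error(
    evaluatePattern(fx$lf, pat, fx$target, partitions = list(1:5)),
    "cover all nodes"
  )
  ## stage contract
  expect_error(evaluatePattern(fx$lf, CurrentPattern(c(1, -1, 0, 0, 0)),
                               fx$target), "stage I")
})

test_that("metrics reports serialize to JSON and TSV", {
  fx <- tinyFixture(51)
  pat <- normalizeCurrents(CurrentPattern(expandCurrents(c(1, -1, 0.5, 0))))
  m <- evaluatePattern(fx$lf, pat, fx$target)
  pj <- tempfile(fileext = ".json")
  writeMetrics(m, pj)
  back <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(back$PR, m@PR, tolerance = 1e-9)
  expect_equal(back$loss, m@loss, tolerance = 1e-9)
  pt <- tempfile(fileext = ".tsv")
  writeMetrics(m, pt, format = "tsv")
  tab <- read.table(pt, header = TRUE, sep = "\t")
  expect_equal(tab$MR_exact, m@MRexact, tolerance = 1e-9)
})
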