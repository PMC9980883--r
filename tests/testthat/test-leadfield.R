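test_that("random lead field is reproducible and shaped correctly", {
  a <- generateRandomLeadField(n_nodes = 40, n_electrodes = 6, seed = 5)
  b <- generateRandomLeadField(n_nodes = 40, n_electrodes = 6, seed = 5)
  expect_identical(lfMatrix(a), lfMatrix(b))
  expect_equal(dim(lfMatrix(a)), c(40L, 5L))
  d <- generateRandomLeadField(n_nodes = 40, n_electrodes = 6, seed = 6)
  expect_false(identical(lfMatrix(a), lfMatrix(d)))
  ## two electrodes give exactly one column
  e2 <- generateRandomLeadField(n_nodes = 10, n_electrodes = 2, seed = 1)
  expect_equal(ncol(lfMatrix(e2)), 1L)
  expect_error(generateRandomLeadField(0, 4, seed = 1), "n_nodes")
  expect_error(generateRandomLeadField(10, 1, seed = 1), "n_electrodes")
  expect_error(generateRandomLeadField(10, 4), "seed")
})

test_that("column magnitude decays with electrode distance only when decay is on", {
  ## correlation between |column| and node-electrode distance over many seeds
  corWithDistance <- function(decay, seed) {
    lf <- generateRandomLeadField(n_nodes = 120, n_electrodes = 5,
                                  depth_decay = decay, seed = seed)
    lay <- electrodeLayout(lf)
    epos <- 92 * lay@positions
    nodes <- nodeCoords(lf)
    free <- setdiff(seq_len(5), lay@referenceIndex)
    mean(vapply(seq_along(free), function(j) {
      d <- sqrt(rowSums((nodes - matrix(epos[free[j], ], nrow(nodes), 3,
                                        byrow = TRUE))^2))
      suppressWarnings(cor(abs(lfMatrix(lf)[, j]), d))
    }, 1), na.rm = TRUE)
  }
  withDecay <- vapply(1:50, function(s) corWithDistance(0.05, s), 1)
  noDecay <- vapply(1:50, function(s) corWithDistance(0, s), 1)
  expect_lt(mean(withDecay), -0.2)        # clear monotone trend
  expect_lt(abs(mean(noDecay)), 0.1)      # no trend within sampling error
})

test_that("depth target selection matches brute-force k-nearest neighbours", {
  lf <- generateRandomLeadField(n_nodes = 80, n_electrodes = 4, seed = 9)
  for (d in c(1L, 4L)) {
    tg <- selectDepthTarget(lf, d, k = 7)
    anchor <- depthAnchor(lf, d)
    dist <- sqrt(rowSums((nodeCoords(lf) -
                            matrix(anchor, 80, 3, byrow = TRUE))^2))
    expect_setequal(targetNodes(tg), order(dist)[1:7])
  }
  ## k = 1 is the single nearest node
  tg1 <- selectDepthTarget(lf, 3, k = 1)
  d3 <- sqrt(rowSums((nodeCoords(lf) -
                        matrix(depthAnchor(lf, 3), 80, 3, byrow = TRUE))^2))
  expect_equal(targetNodes(tg1), which.min(d3))
  ## deeper index anchors closer to the center
  expect_lt(sqrt(sum(depthAnchor(lf, 5)^2)), sqrt(sum(depthAnchor(lf, 1)^2)))
  expect_error(selectDepthTarget(lf, 6), "depth_index")
})

test_that("target specifications enforce their invariants", {
  expect_error(TargetSpec(list(1:3, 3:5), nNodes = 10), "disjoint")
  expect_error(TargetSpec(list(integer(0)), nNodes = 10), "non-empty")
  expect_error(TargetSpec(list(8:12), nNodes = 10), "1, nNodes")
  tg <- TargetSpec(list(2:4, 7:8), nNodes = 10)
  expect_equal(targetNodes(tg), c(2:4, 7:8))
  tf <- targetField(tg)
  expect_equal(tf, c(0, 1, 1, 1, 0, 0, 1, 1, 0, 0))
})

test_that("lead-field containers round-trip bit-exactly and validate schemas", {
  lf <- computeSphericalLeadField(SphereModel(seriesOrder = 40L),
                                  scalpLayout(5), cortexNodes = 12)
  path <- tempfile(fileext = ".lfc")
  saveLeadField(lf, path)
  back <- loadLeadField(path)
  expect_identical(lfMatrix(back), lfMatrix(lf))
  expect_identical(nodeCoords(back), nodeCoords(lf))
  expect_identical(nodeNormals(back), nodeNormals(lf))
  expect_equal(electrodeLayout(back)@labels, electrodeLayout(lf)@labels)
  sm <- S4Vectors::metadata(back)$sphereModel
  expect_s4_class(sm, "SphereModel")
  expect_equal(sm@shellConductivities, c(0.465, 0.010, 1.654, 0.276))

  ## schema errors name the missing field; version mismatches are explicit
  obj <- readRDS(path)
  broken <- obj; broken$node_normals <- NULL
  p2 <- tempfile(); saveRDS(broken, p2)
  expect_error(loadLeadField(p2), "node_normals")
  wrongv <- obj; wrongv$format_version <- "99"
  p3 <- tempfile(); saveRDS(wrongv, p3)
  expect_error(loadLeadField(p3), "version mismatch")
})

test_that("a hand-written minimal container loads with the right shape", {
  obj <- list(
    format_version = "1",
    leadfield = matrix(c(0.1, -0.2, 0.3, 0.4), 2, 2),
    node_coords = rbind(c(10, 0, 0), c(0, 10, 0)),
    node_normals = rbind(c(1, 0, 0), c(0, 1, 0)),
    electrode_positions = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
    electrode_labels = c("ref", "a", "b")
  )
  p <- tempfile(); saveRDS(obj, p)
  lf <- loadLeadField(p)
  expect_equal(dim(lfMatrix(lf)), c(2L, 2L))
  expect_equal(nElectrodes(lf), 3L)
})

test_that("TSV export writes one row per node with electrode columns", {
  lf <- generateRandomLeadField(n_nodes = 7, n_electrodes = 4, seed = 2)
  p <- tempfile(fileext = ".tsv")
  exportLeadFieldTSV(lf, p)
  tab <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 7L)
  expect_equal(ncol(tab), 6L + 3L)  # xyz + normals + 3 free electrodes
  expect_equal(unname(as.matrix(tab[, 7:9])), unname(lfMatrix(lf)),
               tolerance = 1e-12)
})

test_that("target specs serialize to and from JSON", {
  tg <- TargetSpec(list(2:4, c(7L, 9L)), nNodes = 12)
  p <- tempfile(fileext = ".json")
  writeTargetSpec(tg, p)
  back <- readTargetSpec(p)
  expect_equal(regions(back), regions(tg))
  expect_equal(back@nNodes, 12L)
  expect_error(readTargetSpec({
    p2 <- tempfile(); writeLines('{"n_nodes": 5}', p2); p2
  }), "regions")
})
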