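#' @include AllClasses.R AllGenerics.R stimulation.R optim-lse.R
NULL

#' Construct a genetic-algorithm configuration
#'
#' @param population population size (default 1000).
#' @param generations number of generations.
#' @param chromosomeKind `"two_pair"` (anode, cathode and current magnitude
#'   per frequency) or `"hd"` (all free-electrode currents for both
#'   frequencies).
#' @param crossoverRate probability a child is produced by uniform crossover
#'   rather than copied from its first parent.
#' @param mutationRate per-gene mutation probability.
#' @param mutationScale Gaussian mutation s.d. as a fraction of the current
#'   range (4 mA for `hd` genes, 2 mA for pair magnitudes).
#' @param eliteCount best individuals conserved unchanged per generation.
#' @param seed RNG seed.
#' @param slope sigmoid slope of the smooth mis-area.
#' @param useSmoothMR fitness uses the smooth mis-area (default, matching
#'   the generator network's training loss) or the exact count.
#' @return a validated [GaConfig].
#' @export
GaConfig <- function(population = 1000L, generations = 100L,
                     chromosomeKind = "hd", crossoverRate = 0.9,
                     mutationRate = 0.1, mutationScale = 0.2,
                     eliteCount = 10L, seed = 1L, slope = 1,
                     useSmoothMR = TRUE) {
  new("GaConfig", population = as.integer(population),
      generations = as.integer(generations), chromosomeKind = chromosomeKind,
      crossoverRate = crossoverRate, mutationRate = mutationRate,
      mutationScale = mutationScale, eliteCount = as.integer(eliteCount),
      seed = as.integer(seed), slope = slope, useSmoothMR = useSmoothMR)
}

## decode a gene matrix (genes x individuals) into full current matrices
## (electrodes x individuals), one per frequency channel
.gaDecode <- function(G, kind, M, Fn, ref) {
  P <- ncol(G)
  free <- setdiff(seq_len(M), ref)
  C1 <- matrix(0, M, P)
  C2 <- matrix(0, M, P)
  if (kind == "hd") {
    C1[free, ] <- G[seq_len(Fn), , drop = FALSE]
    C2[free, ] <- G[Fn + seq_len(Fn), , drop = FALSE]
    C1[ref, ] <- -colSums(C1[free, , drop = FALSE])
    C2[ref, ] <- -colSums(C2[free, , drop = FALSE])
  } else {
    an1 <- G[1, ]; ca1 <- G[2, ]; i1 <- G[3, ]
    an2 <- G[4, ]; ca2 <- G[5, ]; i2 <- G[6, ]
    idx <- seq_len(P)
    C1[cbind(an1, idx)] <- i1
    C1[cbind(ca1, idx)] <- C1[cbind(ca1, idx)] - i1
    C2[cbind(an2, idx)] <- i2
    C2[cbind(ca2, idx)] <- C2[cbind(ca2, idx)] - i2
  }
  list(C1 = C1, C2 = C2)
}

## columnwise safety normalization; all-zero columns flagged with NA scale
.gaNormalize <- function(C) {
  mx <- apply(abs(C), 2, max)
  bad <- mx == 0
  mx[bad] <- NA_real_
  C <- sweep(C, 2, 2 / mx, "*")
  s <- colSums(abs(C))
  over <- !is.na(s) & s > 8
  if (any(over)) C[, over] <- sweep(C[, over, drop = FALSE], 2, 8 / s[over], "*")
  list(C = C, bad = bad)
}

## vectorized three-ratio loss over a population; bad individuals get +Inf
.gaLoss <- function(E, C1, C2, ref, tidx, slope, smooth) {
  f1 <- E %*% C1[-ref, , drop = FALSE]
  f2 <- E %*% C2[-ref, , drop = FALSE]
  Mod <- 2 * pmin(abs(f1), abs(f2))
  N <- nrow(Mod)
  Tn <- length(tidx)
  Modt <- Mod[tidx, , drop = FALSE]
  Modnt <- Mod[-tidx, , drop = FALSE]
  mu <- colMeans(Modt)
  MRs <- if (smooth) {
    colSums(1 / (1 + exp(-slope * sweep(Modnt, 2, mu)))) / Tn
  } else {
    colSums(sweep(Modnt, 2, mu) > 0) / Tn
  }
  p <- apply(Modt, 2, max)
  q <- apply(Modnt, 2, max)
  PR <- p / q
  CR <- (N * colSums(Modt)) / (Tn * colSums(Mod))
  loss <- MRs / (PR * CR)
  loss[!is.finite(loss) & !is.na(loss)] <- Inf
  loss
}

.gaInitPopulation <- function(cfg, M, Fn) {
  P <- cfg@population
  if (cfg@chromosomeKind == "hd") {
    matrix(runif(2L * Fn * P, -2, 2), 2L * Fn, P)
  } else {
    an1 <- sample.int(M, P, replace = TRUE)
    ca1 <- vapply(an1, function(a) sample(setdiff(seq_len(M), a), 1L), 1L)
    an2 <- sample.int(M, P, replace = TRUE)
    ca2 <- vapply(an2, function(a) sample(setdiff(seq_len(M), a), 1L), 1L)
    rbind(an1, ca1, runif(P, 0.1, 2), an2, ca2, runif(P, 0.1, 2))
  }
}

.gaMutate <- function(G, cfg, M) {
  P <- ncol(G)
  if (cfg@chromosomeKind == "hd") {
    mask <- matrix(runif(length(G)) < cfg@mutationRate, nrow(G), P)
    G[mask] <- G[mask] + rnorm(sum(mask), 0, cfg@mutationScale * 4)
  } else {
    for (r in c(1L, 2L, 4L, 5L)) {
      hit <- runif(P) < cfg@mutationRate
      if (any(hit)) G[r, hit] <- sample.int(M, sum(hit), replace = TRUE)
    }
    for (r in c(3L, 6L)) {
      hit <- runif(P) < cfg@mutationRate
      if (any(hit)) {
        G[r, hit] <- pmin(2, pmax(0.05, G[r, hit] +
                                    rnorm(sum(hit), 0, cfg@mutationScale * 2)))
      }
    }
    ## repair anode == cathode
    for (pair in list(c(1L, 2L), c(4L, 5L))) {
      same <- G[pair[1], ] == G[pair[2], ]
      if (any(same)) {
        G[pair[2], same] <- vapply(G[pair[1], same], function(a) {
          sample(setdiff(seq_len(M), a), 1L)
        }, numeric(1))
      }
    }
  }
  G
}

#' Genetic-algorithm montage optimization
#'
#' Evolves a population of montages minimizing the same three-ratio loss as
#' the generator network, for two chromosome encodings: the conventional
#' two-pair tTIS arrangement (one anode-cathode pair and a current magnitude
#' per frequency) and the high-definition encoding (all free-electrode
#' currents for both frequencies). Selection is binary tournament, crossover
#' is uniform, mutation Gaussian (index genes of the two-pair encoding are
#' resampled), and the best `eliteCount` individuals are conserved, so the
#' per-generation best loss is non-increasing. Every individual is
#' safety-normalized before evaluation.
#'
#' @param leadfield a [LeadField].
#' @param target a [TargetSpec].
#' @param config a [GaConfig].
#' @return an [OptimizationResult]; `lossHistory` holds the best loss per
#'   generation and `evalCalls` equals `population * generations`.
#' @export
gaOptimize <- function(leadfield, target, config = GaConfig()) {
  stopifnot(is(leadfield, "LeadField"), is(target, "TargetSpec"),
            is(config, "GaConfig"))
  validObject(config)
  E <- lfMatrix(leadfield)
  lay <- electrodeLayout(leadfield)
  M <- nrow(lay@positions)
  Fn <- ncol(E)
  ref <- lay@referenceIndex
  tidx <- targetNodes(target)
  set.seed(config@seed)

  evalPop <- function(G) {
    dec <- .gaDecode(G, config@chromosomeKind, M, Fn, ref)
    n1 <- .gaNormalize(dec$C1)
    n2 <- .gaNormalize(dec$C2)
    loss <- .gaLoss(E, n1$C, n2$C, ref, tidx, config@slope, config@useSmoothMR)
    loss[n1$bad | n2$bad] <- Inf
    loss[is.na(loss)] <- Inf
    loss
  }

  G <- .gaInitPopulation(config, M, Fn)
  P <- config@population
  hist <- numeric(config@generations)
  bestG <- NULL
  bestLoss <- Inf
  for (gen in seq_len(config@generations)) {
    loss <- evalPop(G)
    ord <- order(loss)
    if (loss[ord[1]] < bestLoss) {
      bestLoss <- loss[ord[1]]
      bestG <- G[, ord[1], drop = FALSE]
    }
    hist[gen] <- loss[ord[1]]
    if (gen == config@generations) break
    elites <- G[, ord[seq_len(config@eliteCount)], drop = FALSE]
    nChild <- P - config@eliteCount
    ## binary tournament selection
    pick <- function() {
      cand <- sample.int(P, 2L)
      cand[which.min(loss[cand])]
    }
    children <- matrix(0, nrow(G), nChild)
    for (j in seq_len(nChild)) {
      p1 <- G[, pick()]
      if (runif(1) < config@crossoverRate) {
        p2 <- G[, pick()]
        mask <- runif(nrow(G)) < 0.5
        p1[mask] <- p2[mask]
      }
      children[, j] <- p1
    }
    children <- .gaMutate(children, config, M)
    G <- cbind(elites, children)
  }

  dec <- .gaDecode(bestG, config@chromosomeKind, M, Fn, ref)
  pattern <- normalizeCurrents(CurrentPattern(dec$C1[, 1], dec$C2[, 1]))
  metrics <- evaluatePattern(leadfield, pattern, target, slope = config@slope)
  new("OptimizationResult", pattern = pattern, lossHistory = hist,
      finalMetrics = metrics, seed = config@seed,
      evalCalls = config@population * config@generations,
      wallInfo = sprintf("ga %s: population %d, %d generations",
                         config@chromosomeKind, config@population,
                         config@generations))
}
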