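#' @include AllClasses.R AllGenerics.R usnn.R ga.R
NULL

#' Study design for desk-scale replication experiments
#'
#' Describes one of three study kinds: a depth sweep (targets at increasing
#' fractional depth), multi-target stimulation with partitioned evaluation,
#' or a side-by-side method comparison. Replicates are seeds: each method is
#' re-run once per seed.
#'
#' @slot kind `"depth_sweep"`, `"multi_target"` or `"method_comparison"`.
#' @slot depthIndices subset of 1..5.
#' @slot targetPairs list of length-2 integer vectors of multi-target anchor
#'   indices (defaults `1-2`, `1-3`, `1-4`).
#' @slot partitionAxes one axis per pair, `"y"` (left/right hemispheres) or
#'   `"x"` (anterior/posterior); always explicit, never inferred.
#' @slot methods subset of `lse_tacs`, `usnn_tacs`, `usnn_ttis`, `ga_2pair`,
#'   `ga_hd`.
#' @slot seeds integer seeds; `length(seeds)` is the replicate count.
#' @slot targetSize nodes per target region (default 50).
#' @slot epochs generator training epochs (0 selects the study default:
#'   1000 single-target, 2000 multi-target).
#' @slot gaPopulation,gaGenerations GA budget for the GA methods.
#'
#' @aliases StudyDesign-class
#' @export
setClass("StudyDesign",
  representation(
    kind = "character",
    depthIndices = "integer",
    targetPairs = "list",
    partitionAxes = "character",
    methods = "character",
    seeds = "integer",
    targetSize = "integer",
    epochs = "integer",
    gaPopulation = "integer",
    gaGenerations = "integer"
  ),
  prototype(
    kind = "depth_sweep",
    depthIndices = 1:5,
    targetPairs = list(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
    partitionAxes = c("y", "y", "x"),
    methods = c("lse_tacs", "usnn_tacs", "usnn_ttis"),
    seeds = 1:5,
    targetSize = 50L,
    epochs = 0L,
    gaPopulation = 100L,
    gaGenerations = 50L
  )
)

.STUDY_METHODS <- c("lse_tacs", "usnn_tacs", "usnn_ttis", "ga_2pair", "ga_hd")

setValidity("StudyDesign", function(object) {
  if (!object@kind %in% c("depth_sweep", "multi_target", "method_comparison")) {
    return("kind must be depth_sweep, multi_target or method_comparison")
  }
  if (length(object@methods) == 0L) return("methods must be non-empty")
  if (!all(object@methods %in% .STUDY_METHODS)) {
    return(paste("methods must be among", paste(.STUDY_METHODS, collapse = ", ")))
  }
  if (length(object@seeds) < 1L) return("at least one seed is required")
  if (object@kind == "depth_sweep" &&
      (length(object@depthIndices) == 0L || !all(object@depthIndices %in% 1:5))) {
    return("depthIndices must be a non-empty subset of 1..5")
  }
  if (object@kind == "multi_target") {
    if (length(object@targetPairs) == 0L) return("targetPairs must be non-empty")
    if (length(object@partitionAxes) != length(object@targetPairs)) {
      return("one partitionAxis per target pair is required")
    }
    if (!all(object@partitionAxes %in% c("x", "y"))) {
      return("partitionAxes must be 'x' or 'y'")
    }
  }
  TRUE
})

#' @rdname StudyDesign-class
#' @param kind,depthIndices,targetPairs,partitionAxes,methods,seeds,targetSize,epochs,gaPopulation,gaGenerations
#'   see the corresponding slots.
#' @export
StudyDesign <- function(kind = "depth_sweep",
                        depthIndices = 1:5,
                        targetPairs = list(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                        partitionAxes = c("y", "y", "x"),
                        methods = c("lse_tacs", "usnn_tacs", "usnn_ttis"),
                        seeds = 1:5,
                        targetSize = 50L,
                        epochs = 0L,
                        gaPopulation = 100L,
                        gaGenerations = 50L) {
  new("StudyDesign", kind = kind, depthIndices = as.integer(depthIndices),
      targetPairs = lapply(targetPairs, as.integer),
      partitionAxes = partitionAxes, methods = methods,
      seeds = as.integer(seeds), targetSize = as.integer(targetSize),
      epochs = as.integer(epochs), gaPopulation = as.integer(gaPopulation),
      gaGenerations = as.integer(gaGenerations))
}

## run one method on one target; returns an OptimizationResult-like list
.runStudyMethod <- function(leadfield, target, method, seed, epochs,
                            gaPopulation, gaGenerations, partitions = NULL) {
  pattern <- NULL
  history <- numeric(0)
  calls <- NA_integer_
  if (method == "lse_tacs") {
    pattern <- lseOptimize(leadfield, target)
    calls <- 1L
  } else if (method %in% c("usnn_tacs", "usnn_ttis")) {
    cfg <- UsnnConfig(epochs = epochs, seed = seed,
                      mode = if (method == "usnn_tacs") "tACS" else "tTIS")
    res <- usnnOptimize(leadfield, target, cfg)
    pattern <- bestPattern(res)
    history <- lossHistory(res)
    calls <- evalCalls(res)
  } else {
    cfg <- GaConfig(population = gaPopulation, generations = gaGenerations,
                    chromosomeKind = if (method == "ga_2pair") "two_pair" else "hd",
                    eliteCount = max(1L, min(10L, gaPopulation %/% 10L)),
                    seed = seed)
    res <- gaOptimize(leadfield, target, cfg)
    pattern <- bestPattern(res)
    history <- lossHistory(res)
    calls <- evalCalls(res)
  }
  metrics <- evaluatePattern(leadfield, pattern, target, partitions = partitions)
  f1 <- computeField(leadfield, pattern@f1Currents)
  f2 <- computeField(leadfield, pattern@f2Currents)
  mod <- modulation(f1, f2, form = "envelope_min")
  list(pattern = pattern, metrics = metrics, history = history,
       calls = calls, modulation = mod)
}

.metricsRow <- function(metrics, modVec, target) {
  idx <- targetNodes(target)
  row <- data.frame(PR = metrics@PR, CR = metrics@CR,
                    MRexact = metrics@MRexact, MRsmooth = metrics@MRsmooth,
                    loss = metrics@loss, peakTargetMod = max(modVec[idx]))
  pr <- metrics@perRegion
  if (nrow(pr) > 0L) {
    for (i in seq_len(nrow(pr))) {
      row[[paste0("PR_region", pr$region[i])]] <- pr$PR[i]
      row[[paste0("CR_region", pr$region[i])]] <- pr$CR[i]
      row[[paste0("MR_region", pr$region[i])]] <- pr$MRexact[i]
    }
  }
  row
}

.emptyMetricsRow <- function() {
  data.frame(PR = NA_real_, CR = NA_real_, MRexact = NA_real_,
             MRsmooth = NA_real_, loss = NA_real_, peakTargetMod = NA_real_)
}

#' Depth-sweep study
#'
#' For each depth index, builds the 50-node target at the corresponding
#' fractional depth, runs every requested method with every seed, and
#' returns a tidy table of metrics plus per-method linear trends of PR
#' against depth. Optimizer failures are recorded per cell (the `error`
#' column), not fatal to the sweep.
#'
#' @param leadfield a [LeadField].
#' @param design a [StudyDesign] with `kind = "depth_sweep"`.
#' @return a list with `results` (one row per depth x method x seed:
#'   metrics, peak target modulation, error message or NA) and `trends`
#'   (per-method least-squares slope of PR versus depth index).
#' @export
runDepthStudy <- function(leadfield, design = StudyDesign()) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  if (design@kind != "depth_sweep") stop("design kind must be depth_sweep")
  epochs <- if (design@epochs > 0L) design@epochs else 1000L
  rows <- list()
  for (d in design@depthIndices) {
    target <- selectDepthTarget(leadfield, d, k = design@targetSize)
    for (method in design@methods) {
      for (seed in design@seeds) {
        cell <- tryCatch({
          r <- .runStudyMethod(leadfield, target, method, seed, epochs,
                               design@gaPopulation, design@gaGenerations)
          cbind(data.frame(depth = d, method = method, seed = seed),
                .metricsRow(r$metrics, r$modulation, target),
                data.frame(error = NA_character_))
        }, error = function(e) {
          cbind(data.frame(depth = d, method = method, seed = seed),
                .emptyMetricsRow(), data.frame(error = conditionMessage(e)))
        })
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  results <- do.call(rbind, rows)
  trends <- do.call(rbind, lapply(unique(results$method), function(m) {
    sub <- results[results$method == m & is.na(results$error), ]
    slope <- if (nrow(sub) >= 2L && length(unique(sub$depth)) >= 2L) {
      unname(coef(lm(PR ~ depth, data = sub))[2])
    } else NA_real_
    data.frame(method = m, slopePRvsDepth = slope)
  }))
  list(results = results, trends = trends)
}

#' Multi-target study with partitioned evaluation
#'
#' For each anchor pair, the target is the union of two 50-node regions
#' around the corresponding [multiTargetAnchors] locations; evaluation
#' splits the nodes into two parts by the pair's stated plane (left/right
#' hemispheres for a `"y"` axis, anterior/posterior for `"x"`) and reports
#' PR/CR/MR separately per region inside its part.
#'
#' @param leadfield a [LeadField].
#' @param design a [StudyDesign] with `kind = "multi_target"`.
#' @return a data.frame with one row per pair x method x seed, global and
#'   per-region metric columns, and an `error` column.
#' @export
runMultiTargetStudy <- function(leadfield, design) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  if (design@kind != "multi_target") stop("design kind must be multi_target")
  epochs <- if (design@epochs > 0L) design@epochs else 2000L
  anchors <- multiTargetAnchors(leadfield)
  nodes <- nodeCoords(leadfield)
  n <- nrow(nodes)
  rows <- list()
  for (pi in seq_along(design@targetPairs)) {
    pair <- design@targetPairs[[pi]]
    r1 <- regions(selectNearestTarget(leadfield, anchors[pair[1], ],
                                      design@targetSize))[[1]]
    r2 <- regions(selectNearestTarget(leadfield, anchors[pair[2], ],
                                      design@targetSize))[[1]]
    if (length(intersect(r1, r2)) > 0L) {
      stop("contract error: target regions of pair ",
           paste(pair, collapse = "-"), " overlap")
    }
    target <- TargetSpec(list(r1, r2), nNodes = n)
    axis <- if (design@partitionAxes[pi] == "y") 2L else 1L
    sideOf1 <- nodes[, axis] >= 0
    if (mean(nodes[r1, axis] >= 0) < 0.5) sideOf1 <- !sideOf1
    p1 <- sort(union(setdiff(which(sideOf1), r2), r1))
    p2 <- sort(union(setdiff(which(!sideOf1), r1), r2))
    partitions <- list(p1, p2)
    for (method in design@methods) {
      for (seed in design@seeds) {
        cell <- tryCatch({
          r <- .runStudyMethod(leadfield, target, method, seed, epochs,
                               design@gaPopulation, design@gaGenerations,
                               partitions = partitions)
          cbind(data.frame(pair = paste(pair, collapse = "-"),
                           method = method, seed = seed),
                .metricsRow(r$metrics, r$modulation, target),
                data.frame(error = NA_character_))
        }, error = function(e) {
          cbind(data.frame(pair = paste(pair, collapse = "-"),
                           method = method, seed = seed),
                .emptyMetricsRow(), data.frame(error = conditionMessage(e)))
        })
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  fill <- function(df, cols) { df[setdiff(cols, names(df))] <- NA_real_; df }
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, fill, cols = cols))[, cols]
}

#' Side-by-side method comparison on one target
#'
#' Runs every requested method on a single target and collects the metrics,
#' per-iteration loss curves, per-node modulation vectors (for plotting) and
#' loss-evaluation call counts (epochs for the generator network,
#' population x generations for the GA, 1 for the closed-form LSE).
#'
#' @param leadfield a [LeadField].
#' @param target a [TargetSpec].
#' @param design a [StudyDesign] with `kind = "method_comparison"` and at
#'   least two methods.
#' @return a list with `metrics` (method x seed rows), `lossHistories`
#'   (named list of numeric vectors for the iterative methods) and
#'   `modulations` (named list of per-node vectors, last seed of each
#'   method).
#' @export
compareMethods <- function(leadfield, target, design) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  if (design@kind != "method_comparison") {
    stop("design kind must be method_comparison")
  }
  if (length(design@methods) < 2L) stop("at least two methods are required")
  epochs <- if (design@epochs > 0L) design@epochs else 1000L
  rows <- list()
  histories <- list()
  modulations <- list()
  for (method in design@methods) {
    for (seed in design@seeds) {
      cell <- tryCatch({
        r <- .runStudyMethod(leadfield, target, method, seed, epochs,
                             design@gaPopulation, design@gaGenerations)
        if (length(r$history) > 0L) {
          histories[[paste0(method, "_seed", seed)]] <- r$history
        }
        modulations[[method]] <- r$modulation
        cbind(data.frame(method = method, seed = seed, evalCalls = r$calls),
              .metricsRow(r$metrics, r$modulation, target),
              data.frame(error = NA_character_))
      }, error = function(e) {
        cbind(data.frame(method = method, seed = seed, evalCalls = NA_integer_),
              .emptyMetricsRow(), data.frame(error = conditionMessage(e)))
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  list(metrics = do.call(rbind, rows), lossHistories = histories,
       modulations = modulations)
}
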