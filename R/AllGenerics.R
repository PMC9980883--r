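#' @include AllClasses.R
NULL

#' Accessors for lead-field objects
#'
#' `lfMatrix` returns the N x (M-1) lead-field matrix (V/m per mA),
#' `nodeCoords` the N x 3 node coordinates in mm, `nodeNormals` the N x 3
#' unit surface normals, `electrodeLayout` the [ElectrodeLayout], and
#' `provenance` a string describing how the lead field was produced.
#' `nNodes` and `nElectrodes` give N and the total electrode count M
#' (including the reference).
#'
#' @param object a [LeadField].
#' @return See the description; matrices are base numeric matrices.
#' @name leadfield-accessors
#' @aliases lfMatrix nodeCoords nodeNormals electrodeLayout provenance
#'   nNodes nElectrodes
#' @examples
#' lf <- generateRandomLeadField(n_nodes = 20, n_electrodes = 4, seed = 1)
#' dim(lfMatrix(lf))      # 20 x 3
#' nElectrodes(lf)        # 4
NULL

#' @rdname leadfield-accessors
#' @export
setGeneric("lfMatrix", function(object) standardGeneric("lfMatrix"))

#' @rdname leadfield-accessors
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))

#' @rdname leadfield-accessors
#' @export
setGeneric("nodeNormals", function(object) standardGeneric("nodeNormals"))

#' @rdname leadfield-accessors
#' @export
setGeneric("electrodeLayout", function(object) standardGeneric("electrodeLayout"))

#' @rdname leadfield-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname leadfield-accessors
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @rdname leadfield-accessors
#' @export
setGeneric("nElectrodes", function(object) standardGeneric("nElectrodes"))

#' @rdname leadfield-accessors
setMethod("lfMatrix", "LeadField", function(object) {
  m <- SummarizedExperiment::assay(object, "leadfield")
  m <- as.matrix(m)
  m
})

#' @rdname leadfield-accessors
setMethod("nodeCoords", "LeadField", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cbind(x = rd$x, y = rd$y, z = rd$z)
})

#' @rdname leadfield-accessors
setMethod("nodeNormals", "LeadField", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cbind(nx = rd$nx, ny = rd$ny, nz = rd$nz)
})

#' @rdname leadfield-accessors
setMethod("electrodeLayout", "LeadField", function(object) {
  S4Vectors::metadata(object)$layout
})

#' @rdname leadfield-accessors
setMethod("provenance", "LeadField", function(object) {
  S4Vectors::metadata(object)$provenance
})

#' @rdname leadfield-accessors
setMethod("nNodes", "LeadField", function(object) nrow(object))

#' @rdname leadfield-accessors
setMethod("nElectrodes", "LeadField", function(object) {
  nrow(electrodeLayout(object)@positions)
})

#' Accessors for target specifications
#'
#' `regions` returns the list of 1-based node-index sets; `targetNodes` the
#' union of all regions; `targetField` the per-node ideal field vector
#' (binary default when none was given).
#'
#' @param object a [TargetSpec].
#' @name targetspec-accessors
#' @aliases regions targetNodes targetField
NULL

#' @rdname targetspec-accessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))

#' @rdname targetspec-accessors
#' @export
setGeneric("targetNodes", function(object) standardGeneric("targetNodes"))

#' @rdname targetspec-accessors
#' @export
setGeneric("targetField", function(object) standardGeneric("targetField"))

#' @rdname targetspec-accessors
setMethod("regions", "TargetSpec", function(object) object@regions)

#' @rdname targetspec-accessors
setMethod("targetNodes", "TargetSpec", function(object) {
  sort(unlist(object@regions, use.names = FALSE))
})

#' @rdname targetspec-accessors
setMethod("targetField", "TargetSpec", function(object) {
  if (length(object@targetField) > 0L) return(object@targetField)
  tf <- numeric(object@nNodes)
  tf[targetNodes(object)] <- 1
  tf
})

#' Accessors for current patterns
#'
#' `f1Currents` / `f2Currents` return the per-electrode mA vectors of the two
#' frequency channels; `currentStage` the normalization stage.
#'
#' @param object a [CurrentPattern].
#' @name currentpattern-accessors
#' @aliases f1Currents f2Currents currentStage
NULL

#' @rdname currentpattern-accessors
#' @export
setGeneric("f1Currents", function(object) standardGeneric("f1Currents"))

#' @rdname currentpattern-accessors
#' @export
setGeneric("f2Currents", function(object) standardGeneric("f2Currents"))

#' @rdname currentpattern-accessors
#' @export
setGeneric("currentStage", function(object) standardGeneric("currentStage"))

#' @rdname currentpattern-accessors
setMethod("f1Currents", "CurrentPattern", function(object) object@f1Currents)

#' @rdname currentpattern-accessors
setMethod("f2Currents", "CurrentPattern", function(object) object@f2Currents)

#' @rdname currentpattern-accessors
setMethod("currentStage", "CurrentPattern", function(object) object@stage)

#' Accessors for optimization results
#'
#' @param object an [OptimizationResult].
#' @name optresult-accessors
#' @aliases bestPattern lossHistory finalMetrics evalCalls
NULL

#' @rdname optresult-accessors
#' @export
setGeneric("bestPattern", function(object) standardGeneric("bestPattern"))

#' @rdname optresult-accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname optresult-accessors
#' @export
setGeneric("finalMetrics", function(object) standardGeneric("finalMetrics"))

#' @rdname optresult-accessors
#' @export
setGeneric("evalCalls", function(object) standardGeneric("evalCalls"))

#' @rdname optresult-accessors
setMethod("bestPattern", "OptimizationResult", function(object) object@pattern)

#' @rdname optresult-accessors
setMethod("lossHistory", "OptimizationResult", function(object) object@lossHistory)

#' @rdname optresult-accessors
setMethod("finalMetrics", "OptimizationResult", function(object) object@finalMetrics)

#' @rdname optresult-accessors
setMethod("evalCalls", "OptimizationResult", function(object) object@evalCalls)

setMethod("show", "SphereModel", function(object) {
  cat("SphereModel with", length(object@shellRadii), "shells\n")
  cat("  radii (mm):        ", paste(format(object@shellRadii), collapse = " "), "\n")
  cat("  conductivity (S/m):", paste(format(object@shellConductivities), collapse = " "), "\n")
  cat("  series order L =", object@seriesOrder, "\n")
})

setMethod("show", "ElectrodeLayout", function(object) {
  cat("ElectrodeLayout with", nrow(object@positions), "electrodes",
      sprintf("(reference: %s)\n", object@labels[object@referenceIndex]))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d nodes x %d free electrodes (%d incl. reference)\n",
              nrow(object), ncol(object), nElectrodes(object)))
  cat("  provenance:", provenance(object), "\n")
  m <- lfMatrix(object)
  cat(sprintf("  |E| range: [%.3g, %.3g] V/m per mA\n", min(abs(m)), max(abs(m))))
})

setMethod("show", "TargetSpec", function(object) {
  sizes <- vapply(object@regions, length, integer(1))
  cat(sprintf("TargetSpec: %d region(s) of size %s over %d nodes\n",
              length(sizes), paste(sizes, collapse = ", "), object@nNodes))
})

setMethod("show", "CurrentPattern", function(object) {
  cat(sprintf("CurrentPattern (stage %s), %d electrodes\n",
              object@stage, length(object@f1Currents)))
  for (ch in c("f1", "f2")) {
    v <- slot(object, paste0(ch, "Currents"))
    cat(sprintf("  %s: max |I| = %.4g mA, sum |I| = %.4g mA\n", ch, max(abs(v)), sum(abs(v))))
  }
})

setMethod("show", "StimMetrics", function(object) {
  cat(sprintf("StimMetrics: PR = %.4g, CR = %.4g, MR = %.4g (smooth %.4g), loss = %.4g\n",
              object@PR, object@CR, object@MRexact, object@MRsmooth, object@loss))
  if (nrow(object@perRegion) > 0L) {
    cat("  per-region:\n")
    print(object@perRegion)
  }
})

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf("OptimizationResult (seed %d, %d loss evaluations)\n",
              object@seed, object@evalCalls))
  cat(sprintf("  best loss %.6g after %d iterations\n",
              min(object@lossHistory), length(object@lossHistory)))
  show(object@finalMetrics)
})
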