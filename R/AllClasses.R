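#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rnorm runif sd cor coef lm setNames
#' @importFrom utils write.table read.table head tail
NULL

#' Multishell spherical head model
#'
#' Concentric-shell volume-conductor model of the head. Shells are listed from
#' the outside in (scalp first); each shell is assigned a homogeneous isotropic
#' conductivity. The electric potential for a point-current source on the
#' scalp is expanded in Legendre series truncated at `seriesOrder`.
#'
#' Default shells are scalp / skull / CSF / brain (gray matter) at radii
#' 92 / 86 / 80 / 78 mm with conductivities 0.465 / 0.010 / 1.654 / 0.276 S/m;
#' white matter (0.126 S/m) can be added as an optional innermost shell.
#'
#' @slot shellRadii numeric, outer radius of each shell in mm, strictly
#'   decreasing; the first entry is the scalp radius.
#' @slot shellConductivities numeric, conductivity of each shell in S/m.
#' @slot seriesOrder integer, truncation degree L of the Legendre expansion.
#'
#' @aliases SphereModel-class
#' @export
setClass("SphereModel",
  representation(
    shellRadii = "numeric",
    shellConductivities = "numeric",
    seriesOrder = "integer"
  ),
  prototype(
    shellRadii = c(92, 86, 80, 78),
    shellConductivities = c(0.465, 0.010, 1.654, 0.276),
    seriesOrder = 80L
  )
)

setValidity("SphereModel", function(object) {
  r <- object@shellRadii
  s <- object@shellConductivities
  if (length(r) < 1L) return("at least one shell is required")
  if (length(r) != length(s)) return("shellRadii and shellConductivities lengths differ")
  if (any(!is.finite(r)) || any(r <= 0)) return("shell radii must be finite and positive")
  if (length(r) > 1L && any(diff(r) >= 0)) return("shell radii must be strictly decreasing (outermost first)")
  if (any(!is.finite(s)) || any(s <= 0)) return("shell conductivities must be finite and positive")
  if (object@seriesOrder < 1L) return("seriesOrder must be >= 1")
  TRUE
})

#' Scalp electrode layout
#'
#' Positions and labels of the stimulation electrodes. Positions are unit
#' vectors (direction from the head center) for spherical models, or 3D points
#' in mm for imported head models. Electrodes are treated as point current
#' sources; the nominal 1 cm disc diameter of HD electrodes is metadata only.
#'
#' @slot positions numeric matrix, one row per electrode (3 columns).
#' @slot labels character, unique electrode labels.
#' @slot referenceIndex integer, 1-based index of the reference electrode
#'   (default 1). Lead-field column m corresponds to the pair
#'   (+1 mA at electrode m+1, -1 mA at the reference).
#'
#' @aliases ElectrodeLayout-class
#' @export
setClass("ElectrodeLayout",
  representation(
    positions = "matrix",
    labels = "character",
    referenceIndex = "integer"
  ),
  prototype(referenceIndex = 1L)
)

setValidity("ElectrodeLayout", function(object) {
  p <- object@positions
  if (!is.numeric(p) || ncol(p) != 3L) return("positions must be a numeric matrix with 3 columns")
  if (nrow(p) < 2L) return("at least 2 electrodes are required")
  if (length(object@labels) != nrow(p)) return("one label per electrode is required")
  if (anyDuplicated(object@labels)) return("electrode labels must be unique")
  ri <- object@referenceIndex
  if (length(ri) != 1L || ri < 1L || ri > nrow(p)) return("referenceIndex out of range")
  if (any(!is.finite(p))) return("electrode positions must be finite")
  TRUE
})

#' Lead-field matrix with node geometry
#'
#' A `LeadField` extends [SummarizedExperiment::SummarizedExperiment]: rows
#' are cortical nodes, columns are free (non-reference) electrodes, and the
#' single assay `"leadfield"` holds the normal component of the electric
#' field, in V/m per mA, produced at each node by +1 mA at that column's
#' electrode and -1 mA at the reference electrode. Node coordinates (mm) and
#' unit surface normals live in `rowData`; the electrode layout, provenance
#' string and (when applicable) the generating [SphereModel] live in
#' `metadata`.
#'
#' By linear superposition the total normal field for a zero-sum current
#' vector I (mA) over all M electrodes is `assay %*% I[-reference]`.
#'
#' @aliases LeadField-class
#' @export
setClass("LeadField", contains = "SummarizedExperiment")

setValidity("LeadField", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (!("leadfield" %in% names(a))) return("assay 'leadfield' is required")
  m <- a[["leadfield"]]
  if (any(!is.finite(m))) return("lead-field entries must be finite")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("x", "y", "z", "nx", "ny", "nz")
  if (!all(need %in% colnames(rd))) {
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  }
  lay <- S4Vectors::metadata(object)$layout
  if (!is(lay, "ElectrodeLayout")) return("metadata$layout must be an ElectrodeLayout")
  if (ncol(m) != nrow(lay@positions) - 1L) {
    return("column count must equal electrode count - 1")
  }
  nrm <- sqrt(rd$nx^2 + rd$ny^2 + rd$nz^2)
  if (any(abs(nrm - 1) > 1e-6)) return("node normals must be unit length within 1e-6")
  prov <- S4Vectors::metadata(object)$provenance
  if (!is.character(prov) || length(prov) != 1L) return("metadata$provenance must be a string")
  TRUE
})

#' Stimulation target specification
#'
#' One or more disjoint sets of node indices defining target region(s) on the
#' cortical surface, with an optional per-node ideal field vector used by the
#' least-squares (tACS) solver. When `targetField` is empty the ideal field
#' defaults to 1 on target nodes and 0 elsewhere. Region areas are
#' approximated by node counts throughout the metrics.
#'
#' @slot regions list of integer vectors, 1-based node indices; regions are
#'   disjoint and non-empty.
#' @slot targetField numeric, length-N ideal normal-field vector, or
#'   `numeric(0)` for the binary default.
#' @slot nNodes integer, total node count N the indices refer to.
#'
#' @aliases TargetSpec-class
#' @export
setClass("TargetSpec",
  representation(
    regions = "list",
    targetField = "numeric",
    nNodes = "integer"
  ),
  prototype(targetField = numeric(0))
)

setValidity("TargetSpec", function(object) {
  rg <- object@regions
  if (length(rg) < 1L) return("at least one region is required")
  all_idx <- unlist(rg, use.names = FALSE)
  if (length(all_idx) == 0L) return("regions must be non-empty")
  for (r in rg) {
    if (length(r) == 0L) return("each region must be non-empty")
    if (any(r != as.integer(r))) return("region indices must be integers")
  }
  if (any(all_idx < 1L) || any(all_idx > object@nNodes)) {
    return("region indices must lie in [1, nNodes]")
  }
  if (anyDuplicated(all_idx)) return("regions must be disjoint")
  tf <- object@targetField
  if (length(tf) > 0L && length(tf) != object@nNodes) {
    return("targetField must have length nNodes (or be empty)")
  }
  TRUE
})

#' Per-frequency electrode current pattern
#'
#' Electrode currents (mA) for the two stimulation frequencies. Each channel
#' is zero-sum (Kirchhoff's law at the head). `stage` records the
#' normalization state: `"I0"` raw generator output, `"I1"` after the 2 mA
#' per-electrode cap, `"I"` after additionally capping the summed absolute
#' current at 8 mA (i.e. 4 mA total anodal current). For single-frequency
#' tACS the two channels are identical.
#'
#' @slot f1Currents numeric, length-M current vector for frequency 1, mA.
#' @slot f2Currents numeric, length-M current vector for frequency 2, mA.
#' @slot stage character, one of `"I0"`, `"I1"`, `"I"`.
#' @slot nominalFrequencies numeric length-2 carrier frequencies in Hz
#'   (metadata only; never used numerically).
#'
#' @aliases CurrentPattern-class
#' @export
setClass("CurrentPattern",
  representation(
    f1Currents = "numeric",
    f2Currents = "numeric",
    stage = "character",
    nominalFrequencies = "numeric"
  ),
  prototype(stage = "I0", nominalFrequencies = c(2000, 2010))
)

setValidity("CurrentPattern", function(object) {
  a <- object@f1Currents
  b <- object@f2Currents
  if (length(a) != length(b)) return("channels must have equal length")
  if (length(a) < 2L) return("at least 2 electrodes are required")
  if (!object@stage %in% c("I0", "I1", "I")) return("stage must be one of I0, I1, I")
  if (any(!is.finite(a)) || any(!is.finite(b))) return("currents must be finite")
  if (abs(sum(a)) > 1e-9 || abs(sum(b)) > 1e-9) {
    return("each channel must be zero-sum within 1e-9 mA")
  }
  if (object@stage == "I") {
    for (ch in list(a, b)) {
      if (max(abs(ch)) > 2 + 1e-9) return("stage I requires max |current| <= 2 mA")
      if (sum(abs(ch)) > 8 + 1e-9) return("stage I requires sum |current| <= 8 mA")
    }
  }
  TRUE
})

#' Fields and beat modulation on the cortical surface
#'
#' Per-node signed normal field for each carrier frequency (V/m) and the
#' canonical non-negative beat-envelope modulation `2*min(|f1|,|f2|)`.
#'
#' @slot fieldF1 numeric, per-node signed normal field at frequency 1, V/m.
#' @slot fieldF2 numeric, same for frequency 2.
#' @slot modulation numeric, per-node envelope modulation (canonical
#'   non-negative form), V/m.
#'
#' @aliases ModulationField-class
#' @export
setClass("ModulationField",
  representation(
    fieldF1 = "numeric",
    fieldF2 = "numeric",
    modulation = "numeric"
  )
)

setValidity("ModulationField", function(object) {
  n <- length(object@fieldF1)
  if (length(object@fieldF2) != n || length(object@modulation) != n) {
    return("fieldF1, fieldF2 and modulation must have equal length")
  }
  if (any(object@modulation < -1e-12)) return("canonical modulation must be non-negative")
  bound <- 2 * pmin(abs(object@fieldF1), abs(object@fieldF2))
  if (any(object@modulation > bound + 1e-9)) {
    return("modulation must not exceed 2*min(|f1|,|f2|)")
  }
  TRUE
})

#' Focality metrics for a stimulation pattern
#'
#' The three evaluation ratios and the scalar loss. PR is the peak ratio
#' (target peak modulation over non-target peak), CR the concentration ratio
#' (target modulation density over whole-surface density), MR the
#' mis-stimulation ratio (non-target nodes whose modulation exceeds the
#' target-mean modulation, divided by the target node count). `MRsmooth` is
#' the sigmoid relaxation of the mis-stimulated area divided by the target
#' area; `loss = MRsmooth / (PR * CR)` by default. `perRegion` optionally
#' holds one row of PR/CR/MRexact per evaluation partition for multi-target
#' runs.
#'
#' @slot PR numeric.
#' @slot CR numeric.
#' @slot MRexact numeric.
#' @slot MRsmooth numeric.
#' @slot loss numeric.
#' @slot perRegion data.frame with columns region, PR, CR, MRexact (may have
#'   zero rows).
#'
#' @aliases StimMetrics-class
#' @export
setClass("StimMetrics",
  representation(
    PR = "numeric",
    CR = "numeric",
    MRexact = "numeric",
    MRsmooth = "numeric",
    loss = "numeric",
    perRegion = "data.frame"
  ),
  prototype(perRegion = data.frame())
)

setValidity("StimMetrics", function(object) {
  for (nm in c("PR", "CR", "MRexact", "MRsmooth", "loss")) {
    v <- slot(object, nm)
    if (length(v) != 1L) return(paste(nm, "must be a scalar"))
    if (!is.na(v) && !is.nan(v) && v < 0) return(paste(nm, "must be non-negative"))
  }
  TRUE
})

#' Configuration of the unsupervised generator network
#'
#' The generator maps a constant unit input through fully connected hidden
#' layers (linear map, ReLU, layer normalization) to an electrode layer with
#' one output per free electrode and frequency channel (2(M-1) for tTIS,
#' M-1 for tACS). All physics downstream of the electrode layer is fixed;
#' only generator weights are trained, with Adam, minimizing the smooth
#' three-ratio loss.
#'
#' @slot hiddenWidths integer vector of hidden-layer sizes.
#' @slot epochs integer, training steps (1000 single-target, 2000 multi-target).
#' @slot learningRate positive real, Adam step size.
#' @slot seed integer RNG seed.
#' @slot mode `"tTIS"` or `"tACS"`.
#' @slot slope sigmoid slope of the smooth mis-area (unit slope default).
#' @slot normalizationMode `"per_frequency"` (two independent stimulators) or
#'   `"joint"` (safety limits on the concatenated channels).
#' @slot modulationForm training modulation form, `"signed_difference"` or
#'   `"envelope_min"`.
#'
#' @aliases UsnnConfig-class
#' @export
setClass("UsnnConfig",
  representation(
    hiddenWidths = "integer",
    epochs = "integer",
    learningRate = "numeric",
    seed = "integer",
    mode = "character",
    slope = "numeric",
    normalizationMode = "character",
    modulationForm = "character"
  ),
  prototype(
    hiddenWidths = c(64L, 64L, 64L),
    epochs = 1000L,
    learningRate = 1e-3,
    seed = 1L,
    mode = "tTIS",
    slope = 1,
    normalizationMode = "per_frequency",
    modulationForm = "envelope_min"
  )
)

setValidity("UsnnConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (length(object@hiddenWidths) < 1L || any(object@hiddenWidths < 1L)) {
    return("hidden widths must be >= 1")
  }
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (!object@mode %in% c("tTIS", "tACS")) return("mode must be tTIS or tACS")
  if (object@slope <= 0) return("slope must be positive")
  if (!object@normalizationMode %in% c("per_frequency", "joint")) {
    return("normalizationMode must be per_frequency or joint")
  }
  if (!object@modulationForm %in% c("signed_difference", "envelope_min")) {
    return("modulationForm must be signed_difference or envelope_min")
  }
  TRUE
})

#' Configuration of the genetic-algorithm baselines
#'
#' Two chromosome encodings are supported: `"two_pair"` (one anode-cathode
#' pair plus a current magnitude per frequency, the conventional tTIS
#' arrangement) and `"hd"` (a list of all free-electrode currents for both
#' frequencies). Individuals are selected by binary tournament, recombined by
#' uniform crossover, perturbed by Gaussian mutation, and the best
#' `eliteCount` are conserved each generation. Fitness is the same
#' three-ratio loss minimized by the generator network.
#'
#' @slot population integer, population size (default 1000).
#' @slot generations integer.
#' @slot chromosomeKind `"two_pair"` or `"hd"`.
#' @slot crossoverRate real in \[0, 1\].
#' @slot mutationRate real in \[0, 1\].
#' @slot mutationScale positive real, Gaussian mutation s.d. as a fraction of
#'   the current range.
#' @slot eliteCount integer, individuals copied unchanged each generation.
#' @slot seed integer RNG seed.
#' @slot slope sigmoid slope for the smooth mis-area.
#' @slot useSmoothMR logical; `TRUE` matches the network's training loss.
#'
#' @aliases GaConfig-class
#' @export
setClass("GaConfig",
  representation(
    population = "integer",
    generations = "integer",
    chromosomeKind = "character",
    crossoverRate = "numeric",
    mutationRate = "numeric",
    mutationScale = "numeric",
    eliteCount = "integer",
    seed = "integer",
    slope = "numeric",
    useSmoothMR = "logical"
  ),
  prototype(
    population = 1000L,
    generations = 100L,
    chromosomeKind = "hd",
    crossoverRate = 0.9,
    mutationRate = 0.1,
    mutationScale = 0.2,
    eliteCount = 10L,
    seed = 1L,
    slope = 1,
    useSmoothMR = TRUE
  )
)

setValidity("GaConfig", function(object) {
  if (object@population < 2L) return("population must be >= 2")
  if (object@generations < 1L) return("generations must be >= 1")
  if (!object@chromosomeKind %in% c("two_pair", "hd")) {
    return("chromosomeKind must be two_pair or hd")
  }
  if (object@crossoverRate < 0 || object@crossoverRate > 1) return("crossoverRate must be in [0, 1]")
  if (object@mutationRate < 0 || object@mutationRate > 1) return("mutationRate must be in [0, 1]")
  if (object@mutationScale <= 0) return("mutationScale must be positive")
  if (object@eliteCount < 0L) return("eliteCount must be >= 0")
  if (object@eliteCount >= object@population) return("eliteCount must be < population")
  if (object@population < 2L * object@eliteCount) return("population must be >= 2 * eliteCount")
  TRUE
})

#' Result of a montage optimization
#'
#' Holds the safety-normalized (stage I) current pattern of the best iterate,
#' the per-epoch (or per-generation) loss trace, final exact-MR metrics, the
#' seed, the number of loss-function evaluations, and free-text metadata.
#'
#' @slot pattern [CurrentPattern] at stage `"I"`.
#' @slot lossHistory numeric, one value per epoch or generation.
#' @slot finalMetrics [StimMetrics] of `pattern` on the evaluation pipeline.
#' @slot seed integer.
#' @slot evalCalls integer, loss-evaluation call count (epochs for the
#'   network, population x generations for the GA).
#' @slot wallInfo character free text.
#'
#' @aliases OptimizationResult-class
#' @export
setClass("OptimizationResult",
  representation(
    pattern = "CurrentPattern",
    lossHistory = "numeric",
    finalMetrics = "StimMetrics",
    seed = "integer",
    evalCalls = "integer",
    wallInfo = "character"
  )
)
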