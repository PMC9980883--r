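#' @include AllClasses.R AllGenerics.R
NULL

## resolve a target argument (TargetSpec or integer indices) to sorted indices
.targetIdx <- function(target, n) {
  idx <- if (is(target, "TargetSpec")) targetNodes(target) else as.integer(target)
  if (length(idx) == 0L) stop("contract error: empty target")
  if (any(idx < 1L) || any(idx > n)) stop("target indices out of range")
  sort(unique(idx))
}

#' Construct a current pattern
#'
#' @param f1Currents per-electrode currents (mA) of the first frequency
#'   channel; must sum to zero.
#' @param f2Currents currents of the second channel; defaults to `f1Currents`
#'   (single-frequency tACS).
#' @param stage normalization stage, `"I0"`, `"I1"` or `"I"`.
#' @param nominalFrequencies length-2 carrier frequencies in Hz (metadata).
#' @return a validated [CurrentPattern].
#' @export
CurrentPattern <- function(f1Currents, f2Currents = f1Currents,
                           stage = "I0", nominalFrequencies = c(2000, 2010)) {
  new("CurrentPattern", f1Currents = as.numeric(f1Currents),
      f2Currents = as.numeric(f2Currents), stage = stage,
      nominalFrequencies = as.numeric(nominalFrequencies))
}

#' Expand free-electrode currents to a full zero-sum vector
#'
#' The reference electrode carries the negative sum of the free currents, so
#' Kirchhoff's law holds exactly by construction.
#'
#' @param freeCurrents length M-1 currents of the non-reference electrodes,
#'   in lead-field column order.
#' @param referenceIndex 1-based position of the reference electrode in the
#'   full vector (default 1).
#' @return a length-M zero-sum current vector.
#' @export
expandCurrents <- function(freeCurrents, referenceIndex = 1L) {
  M <- length(freeCurrents) + 1L
  full <- numeric(M)
  full[-referenceIndex] <- freeCurrents
  full[referenceIndex] <- -sum(freeCurrents)
  full
}

#' Normal electric field from a lead field and electrode currents
#'
#' Linear superposition: the total normal field is the lead-field matrix
#' applied to the free (non-reference) currents; the reference electrode's
#' current is implied by the zero-sum constraint and is not multiplied in.
#'
#' @param leadfield a [LeadField].
#' @param currents length-M zero-sum current vector in mA (all electrodes,
#'   reference included).
#' @param tol zero-sum tolerance in mA (default 1e-9).
#' @return length-N per-node normal field in V/m.
#' @export
computeField <- function(leadfield, currents, tol = 1e-9) {
  lay <- electrodeLayout(leadfield)
  M <- nrow(lay@positions)
  if (length(currents) != M) {
    stop("contract error: expected ", M, " currents, got ", length(currents))
  }
  if (abs(sum(currents)) > tol * max(1, max(abs(currents)))) {
    stop("contract error: currents must sum to zero (net ",
         format(sum(currents)), " mA)")
  }
  as.numeric(lfMatrix(leadfield) %*% currents[-lay@referenceIndex])
}

#' Beat-envelope modulation of two interfering fields
#'
#' For two sinusoidal fields of nearby frequencies with per-node signed
#' amplitudes `a` and `b` along the surface normal, the low-frequency beat
#' envelope has amplitude `2 * min(|a|, |b|)`. Two algebraic forms are
#' provided: `"signed_difference"` returns `|a + b| - |a - b|` (the form used
#' inside gradient training; negative where the two fields have opposite
#' signs) and `"envelope_min"` returns the canonical non-negative envelope
#' `2 * min(|a|, |b|)`. The forms agree exactly wherever `a * b >= 0`.
#'
#' @param a,b equal-length per-node signed field amplitudes (V/m).
#' @param form `"signed_difference"` (default) or `"envelope_min"`.
#' @return per-node modulation amplitude (V/m).
#' @export
#' @examples
#' modulation(1, -0.5)                       # -1
#' modulation(1, -0.5, "envelope_min")       # 1
modulation <- function(a, b, form = c("signed_difference", "envelope_min")) {
  form <- match.arg(form)
  if (length(a) != length(b)) stop("contract error: length mismatch")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("fields must be finite")
  if (form == "signed_difference") abs(a + b) - abs(a - b) else 2 * pmin(abs(a), abs(b))
}

#' Modulation of single-frequency tACS
#'
#' The peak-to-peak signal: twice the field amplitude per node. Equals
#' `modulation(field, field)` in either form.
#'
#' @param field per-node signed field amplitude (V/m).
#' @return per-node peak-to-peak modulation (V/m).
#' @export
tacsModulation <- function(field) 2 * abs(field)

#' Focality ratios of a modulation distribution
#'
#' `peakRatio` (PR) is the peak modulation over the target divided by the
#' peak over the non-target area. `concentrationRatio` (CR) is the target
#' modulation density divided by the whole-surface density, areas
#' approximated by node counts. `misStimulationRatio` (exact MR) counts
#' non-target nodes whose modulation strictly exceeds the target-mean
#' modulation, divided by the target node count. `misAreaSmooth` is the
#' differentiable sigmoid relaxation of the mis-stimulated area,
#' `sum over non-target of 1 / (1 + exp(-slope * (Mod_i - target mean)))`.
#'
#' All three ratios are invariant under positive rescaling of the
#' modulation; the smooth mis-area is not (the sigmoid has a fixed slope in
#' V/m), which is why the slope is exposed.
#'
#' @param modulation per-node non-negative modulation vector.
#' @param target a [TargetSpec] or integer vector of 1-based target node
#'   indices; must be a non-empty strict subset of the nodes for `peakRatio`.
#' @param slope sigmoid slope (default 1, in (V/m)^-1).
#' @return a scalar.
#' @name focality-ratios
#' @export
peakRatio <- function(modulation, target) {
  n <- length(modulation)
  idx <- .targetIdx(target, n)
  if (length(idx) >= n) stop("contract error: empty non-target area")
  pt <- max(modulation[idx])
  pn <- max(modulation[-idx])
  if (pn == 0) {
    if (pt == 0) {
      warning("modulation identically zero: PR = 0/0 reported as 0")
      return(0)
    }
    return(Inf)
  }
  pt / pn
}

#' @rdname focality-ratios
#' @export
concentrationRatio <- function(modulation, target) {
  n <- length(modulation)
  idx <- .targetIdx(target, n)
  total <- sum(modulation)
  if (total == 0) return(0)
  (sum(modulation[idx]) / length(idx)) / (total / n)
}

#' @rdname focality-ratios
#' @export
misStimulationRatio <- function(modulation, target) {
  n <- length(modulation)
  idx <- .targetIdx(target, n)
  thr <- mean(modulation[idx])
  sum(modulation[-idx] > thr) / length(idx)
}

#' @rdname focality-ratios
#' @export
misAreaSmooth <- function(modulation, target, slope = 1) {
  if (slope <= 0) stop("slope must be positive")
  n <- length(modulation)
  idx <- .targetIdx(target, n)
  thr <- mean(modulation[idx])
  sum(1 / (1 + exp(-slope * (modulation[-idx] - thr))))
}

#' Three-ratio stimulation loss
#'
#' `Loss = MR^a / (PR^b * CR^c)` with all exponents 1 by default; training
#' uses the smooth mis-stimulation ratio (sigmoid mis-area over target size)
#' so the loss is differentiable, while evaluation reports the exact count.
#' The loss decreases as the target modulation grows relative to the
#' non-target area.
#'
#' @param modulation per-node modulation vector.
#' @param target a [TargetSpec] or integer indices.
#' @param slope sigmoid slope of the smooth mis-area.
#' @param exponents length-3 positive exponents for (MR, PR, CR).
#' @param smooth use the smooth MR (default) or the exact count.
#' @return scalar loss; `+Inf` with a warning when `PR * CR` is 0
#'   (degenerate montage).
#' @export
stimLoss <- function(modulation, target, slope = 1, exponents = c(1, 1, 1),
                     smooth = TRUE) {
  idx <- .targetIdx(target, length(modulation))
  PR <- peakRatio(modulation, target)
  CR <- concentrationRatio(modulation, target)
  MR <- if (smooth) {
    misAreaSmooth(modulation, target, slope) / length(idx)
  } else {
    misStimulationRatio(modulation, target)
  }
  if (PR * CR == 0) {
    warning("degenerate montage: PR * CR = 0, loss is +Inf")
    return(Inf)
  }
  MR^exponents[1] / (PR^exponents[2] * CR^exponents[3])
}

## normalize one zero-sum channel: cap max |I| at 2 mA, then cap sum |I| at
## 8 mA (equivalently 4 mA total anodal current)
.normalizeChannel <- function(v) {
  m <- max(abs(v))
  if (m == 0) stop("degenerate montage: all-zero currents cannot be normalized")
  I1 <- v * (2 / m)
  s <- sum(abs(I1))
  if (s > 8) I1 * (8 / s) else I1
}

#' Safety normalization of electrode currents
#'
#' Scales each frequency channel so the largest electrode current is exactly
#' 2 mA (`I1 = I0 / max|I0| * 2`), then, if the summed absolute current
#' exceeds 8 mA, rescales so it is exactly 8 mA (`I = I1 / sum|I1| * 8`;
#' since each channel is zero-sum this caps the total anodal current at
#' 4 mA). With `mode = "per_frequency"` (default) the two channels are
#' normalized independently, matching two independent stimulators;
#' `mode = "joint"` applies both limits to the concatenated channels.
#' Zero-sum is preserved because both steps are positive rescalings.
#'
#' @param pattern a [CurrentPattern] (any stage).
#' @param mode `"per_frequency"` or `"joint"`.
#' @return the pattern at stage `"I"`.
#' @export
#' @examples
#' p <- CurrentPattern(c(4, -4))
#' f1Currents(normalizeCurrents(p))   # 2, -2
normalizeCurrents <- function(pattern, mode = c("per_frequency", "joint")) {
  mode <- match.arg(mode)
  a <- pattern@f1Currents
  b <- pattern@f2Currents
  if (mode == "per_frequency") {
    a <- .normalizeChannel(a)
    b <- .normalizeChannel(b)
  } else {
    m <- max(abs(c(a, b)))
    if (m == 0) stop("degenerate montage: all-zero currents cannot be normalized")
    a <- a * (2 / m); b <- b * (2 / m)
    s <- sum(abs(c(a, b)))
    if (s > 8) { a <- a * (8 / s); b <- b * (8 / s) }
  }
  new("CurrentPattern", f1Currents = a, f2Currents = b, stage = "I",
      nominalFrequencies = pattern@nominalFrequencies)
}

#' Evaluate a stimulation pattern against a target
#'
#' Computes both per-frequency fields by linear superposition, the canonical
#' non-negative envelope modulation, and the global focality metrics (PR, CR,
#' exact and smooth MR, loss). When `partitions` is given (a list of node
#' index vectors, one per target region, jointly covering all nodes), metrics
#' are additionally computed per partition, restricting the nodes to the
#' partition and the target to that partition's region — the separate
#' two-hemisphere evaluation of the multi-target design.
#'
#' @param leadfield a [LeadField].
#' @param pattern a [CurrentPattern] at stage `"I"`.
#' @param target a [TargetSpec].
#' @param partitions optional list of integer vectors covering all nodes,
#'   parallel to `regions(target)`.
#' @param slope sigmoid slope for the smooth mis-area.
#' @return a [StimMetrics].
#' @export
evaluatePattern <- function(leadfield, pattern, target, partitions = NULL,
                            slope = 1) {
  stopifnot(is(leadfield, "LeadField"), is(pattern, "CurrentPattern"),
            is(target, "TargetSpec"))
  if (pattern@stage != "I") {
    stop("contract error: pattern must be safety-normalized (stage I); ",
         "call normalizeCurrents() first")
  }
  f1 <- computeField(leadfield, pattern@f1Currents)
  f2 <- computeField(leadfield, pattern@f2Currents)
  mod <- modulation(f1, f2, form = "envelope_min")
  computeMetrics(mod, target, partitions = partitions, slope = slope)
}

#' Focality metrics of a modulation vector
#'
#' The evaluation core shared by the tTIS and tACS pipelines: global PR, CR,
#' exact and smooth MR and loss of a per-node modulation distribution, plus
#' optional per-partition splits.
#'
#' @inheritParams evaluatePattern
#' @param modulation per-node non-negative modulation vector.
#' @return a [StimMetrics].
#' @export
computeMetrics <- function(modulation, target, partitions = NULL, slope = 1) {
  stopifnot(is(target, "TargetSpec"))
  n <- length(modulation)
  idx <- .targetIdx(target, n)
  PR <- peakRatio(modulation, target)
  CR <- concentrationRatio(modulation, target)
  MRe <- misStimulationRatio(modulation, target)
  MRs <- misAreaSmooth(modulation, target, slope) / length(idx)
  loss <- if (PR * CR == 0) {
    warning("degenerate montage: PR * CR = 0, loss is +Inf")
    Inf
  } else {
    MRs / (PR * CR)
  }
  per <- data.frame()
  if (!is.null(partitions)) {
    rg <- regions(target)
    if (length(partitions) != length(rg)) {
      stop("contract error: one partition per target region is required")
    }
    covered <- sort(unique(unlist(partitions)))
    if (!identical(covered, seq_len(n))) {
      stop("contract error: partitions must cover all nodes")
    }
    per <- do.call(rbind, lapply(seq_along(partitions), function(i) {
      part <- sort(unique(as.integer(partitions[[i]])))
      local_target <- match(rg[[i]], part)
      if (any(is.na(local_target))) {
        stop("contract error: region ", i, " not contained in its partition")
      }
      sub <- modulation[part]
      data.frame(region = i,
                 PR = peakRatio(sub, local_target),
                 CR = concentrationRatio(sub, local_target),
                 MRexact = misStimulationRatio(sub, local_target))
    }))
  }
  new("StimMetrics", PR = PR, CR = CR, MRexact = MRe, MRsmooth = MRs,
      loss = loss, perRegion = per)
}

#' Metrics reports
#'
#' `metricsAsList` flattens a [StimMetrics] for serialization;
#' `writeMetrics` writes it as JSON or as a one-row TSV (per-region columns
#' appended as `PR_region1`, ...).
#'
#' @param metrics a [StimMetrics].
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @name metrics-io
#' @export
metricsAsList <- function(metrics) {
  out <- list(PR = metrics@PR, CR = metrics@CR, MR_exact = metrics@MRexact,
              MR_smooth = metrics@MRsmooth, loss = metrics@loss)
  pr <- metrics@perRegion
  if (nrow(pr) > 0L) {
    for (i in seq_len(nrow(pr))) {
      out[[paste0("PR_region", pr$region[i])]] <- pr$PR[i]
      out[[paste0("CR_region", pr$region[i])]] <- pr$CR[i]
      out[[paste0("MR_region", pr$region[i])]] <- pr$MRexact[i]
    }
  }
  out
}

#' @rdname metrics-io
#' @export
writeMetrics <- function(metrics, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  lst <- metricsAsList(metrics)
  if (format == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(as.data.frame(lst), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
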