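#' @include AllClasses.R AllGenerics.R stimulation.R
NULL

#' Least-squares montage for single-frequency tACS
#'
#' Solves the linear targeting problem: free-electrode currents are the
#' minimum-norm least-squares solution `pinv(E) %*% E_target`, where `E` is
#' the lead-field matrix and `E_target` the ideal normal-field vector (1 on
#' target nodes, 0 elsewhere, unless the target carries an explicit field).
#' The solution is expanded to a zero-sum full current vector, safety
#' normalized, and returned with both frequency channels equal
#' (single-frequency stimulation). Valid only for the linear tACS problem;
#' beat modulation is nonlinear in the currents and needs the gradient or
#' genetic optimizers.
#'
#' @param leadfield a [LeadField].
#' @param target a [TargetSpec].
#' @param conditionWarn warn when the finite condition number of `E` exceeds
#'   this (default 1e8).
#' @return a [CurrentPattern] at stage `"I"`.
#' @export
#' @examples
#' lf <- generateRandomLeadField(n_nodes = 30, n_electrodes = 6, seed = 7)
#' tg <- selectNearestTarget(lf, c(70, 0, 0), k = 3)
#' p <- lseOptimize(lf, tg)
#' max(abs(f1Currents(p)))  # 2 mA by construction
lseOptimize <- function(leadfield, target, conditionWarn = 1e8) {
  stopifnot(is(leadfield, "LeadField"), is(target, "TargetSpec"))
  E <- lfMatrix(leadfield)
  et <- targetField(target)
  if (length(et) != nrow(E)) stop("target field length must equal the node count")
  s <- svd(E)
  tol <- max(dim(E)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) stop("lead-field matrix is numerically zero")
  if (sum(pos) < length(s$d)) {
    warning("rank-deficient lead field: minimum-norm pseudo-inverse solution returned")
  }
  cond <- max(s$d) / min(s$d[pos])
  if (cond > conditionWarn) {
    warning(sprintf("ill-conditioned lead field (condition number %.3g)", cond))
  }
  free <- as.numeric(s$v[, pos, drop = FALSE] %*%
                       ((t(s$u[, pos, drop = FALSE]) %*% et) / s$d[pos]))
  ref <- electrodeLayout(leadfield)@referenceIndex
  full <- expandCurrents(free, ref)
  normalizeCurrents(CurrentPattern(full, full))
}

#' Training-form loss of a normalized pattern
#'
#' The scalar minimized by the gradient and genetic optimizers: fields by
#' linear superposition, modulation in the requested form (training default
#' `"envelope_min"`, the non-negative beat envelope), smooth (or exact)
#' mis-stimulation ratio over peak ratio times concentration ratio.
#'
#' @param leadfield a [LeadField].
#' @param pattern a [CurrentPattern] at stage `"I"`.
#' @param target a [TargetSpec].
#' @param slope sigmoid slope of the smooth mis-area.
#' @param form modulation form (see [modulation]).
#' @param smooth use the sigmoid mis-area (default) or the exact count.
#' @return scalar loss.
#' @export
patternLoss <- function(leadfield, pattern, target, slope = 1,
                        form = "envelope_min", smooth = TRUE) {
  f1 <- computeField(leadfield, pattern@f1Currents)
  f2 <- computeField(leadfield, pattern@f2Currents)
  mod <- modulation(f1, f2, form = form)
  stimLoss(mod, target, slope = slope, smooth = smooth)
}
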