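#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a multishell spherical head model
#'
#' @param shellRadii outer radius of each shell in mm, strictly decreasing,
#'   scalp first. Default 92/86/80/78 (scalp, skull, CSF, brain).
#' @param shellConductivities conductivity of each shell in S/m. Defaults to
#'   0.465 (scalp), 0.010 (skull), 1.654 (CSF), 0.276 (gray matter).
#' @param seriesOrder truncation degree of the Legendre expansion (default 80).
#' @param whiteMatter if `TRUE`, append an innermost white-matter shell
#'   (radius `whiteMatterRadius`, 0.126 S/m).
#' @param whiteMatterRadius outer radius in mm of the optional white-matter
#'   shell (default 65, below the default 70 mm cortex sampling radius so
#'   cortex nodes stay in gray matter).
#' @return a validated [SphereModel].
#' @export
#' @examples
#' SphereModel()
#' SphereModel(whiteMatter = TRUE)
SphereModel <- function(shellRadii = c(92, 86, 80, 78),
                        shellConductivities = c(0.465, 0.010, 1.654, 0.276),
                        seriesOrder = 80L,
                        whiteMatter = FALSE,
                        whiteMatterRadius = 65) {
  if (whiteMatter) {
    shellRadii <- c(shellRadii, whiteMatterRadius)
    shellConductivities <- c(shellConductivities, 0.126)
  }
  new("SphereModel",
      shellRadii = as.numeric(shellRadii),
      shellConductivities = as.numeric(shellConductivities),
      seriesOrder = as.integer(seriesOrder))
}

#' Construct an electrode layout
#'
#' @param positions numeric M x 3 matrix of electrode directions (unit
#'   vectors) or 3D points.
#' @param labels character vector of unique labels; defaults to
#'   `E01, E02, ...`.
#' @param referenceIndex 1-based index of the reference electrode (default 1).
#' @return a validated [ElectrodeLayout].
#' @export
ElectrodeLayout <- function(positions, labels = NULL, referenceIndex = 1L) {
  positions <- as.matrix(positions)
  if (is.null(labels)) {
    labels <- sprintf("E%02d", seq_len(nrow(positions)))
  }
  new("ElectrodeLayout", positions = positions, labels = as.character(labels),
      referenceIndex = as.integer(referenceIndex))
}

#' Deterministic point sets on spheres
#'
#' `fibonacciSphere` places `n` points on a full sphere of radius `radius`
#' by the Fibonacci (golden-angle) lattice, the standard low-discrepancy
#' covering. `scalpLayout` builds an HD electrode layout of `n` positions:
#' a Fibonacci lattice restricted to the upper spherical cap (polar angle up
#' to `capAngle` degrees) plus a ring of `nRing` electrodes near the equator,
#' mimicking how an HD cap covers the head. `sampleCortexNodes` samples
#' cortex nodes quasi-uniformly on a sphere of radius `radius` mm.
#'
#' @param n number of points.
#' @param radius sphere radius (mm); electrode positions are returned as unit
#'   vectors regardless.
#' @param nRing electrodes on the lower ring (default 12).
#' @param capAngle polar half-angle of the cap in degrees (default 75).
#' @param ringAngle polar angle of the ring in degrees (default 82).
#' @param referenceIndex reference electrode index passed through.
#' @return `fibonacciSphere`/`sampleCortexNodes`: an n x 3 matrix;
#'   `scalpLayout`: an [ElectrodeLayout].
#' @name sphere-points
#' @export
fibonacciSphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  rho <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' @rdname sphere-points
#' @export
scalpLayout <- function(n = 69L, nRing = min(12L, max(0L, n - 5L)),
                        capAngle = 75, ringAngle = 82,
                        referenceIndex = 1L) {
  stopifnot(n >= 2L, nRing >= 0L, nRing < n)
  nCap <- n - nRing
  zmin <- cos(capAngle * pi / 180)
  i <- seq_len(nCap) - 0.5
  z <- 1 - (1 - zmin) * i / nCap
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  rho <- sqrt(pmax(0, 1 - z^2))
  cap <- cbind(rho * cos(phi), rho * sin(phi), z)
  pos <- cap
  if (nRing > 0L) {
    zr <- cos(ringAngle * pi / 180)
    rr <- sqrt(1 - zr^2)
    a <- 2 * pi * (seq_len(nRing) - 1) / nRing
    ring <- cbind(rr * cos(a), rr * sin(a), rep(zr, nRing))
    pos <- rbind(cap, ring)
  }
  colnames(pos) <- c("x", "y", "z")
  ElectrodeLayout(pos, referenceIndex = referenceIndex)
}

#' @rdname sphere-points
#' @param innerRadius if given, nodes fill the spherical shell
#'   `[innerRadius, radius]` with uniform volume density (radii from a
#'   low-discrepancy cube-root sequence, directions from the Fibonacci
#'   lattice). A single sphere has no structures at depth; the filled shell
#'   stands in for cortical folds reaching different depths, which the
#'   depth-sweep and multi-target designs require. Default `NULL`: all nodes
#'   on the `radius` sphere.
#' @export
sampleCortexNodes <- function(n, radius = 70, innerRadius = NULL) {
  pts <- fibonacciSphere(n, 1)
  if (is.null(innerRadius)) return(radius * pts)
  stopifnot(innerRadius > 0, innerRadius < radius)
  i <- seq_len(n) - 0.5
  r <- (innerRadius^3 + i / n * (radius^3 - innerRadius^3))^(1 / 3)
  ## decorrelate radius from the lattice's latitude sweep (fixed permutation)
  r <- r[order(sin(seq_len(n) * 12.9898))]
  pts * r
}

## Per-degree shell coefficients for a unit point-current source on the scalp.
## Potential in shell k is scale * (A_k (r/R)^l + B_k (R/r)^(l+1)) P_l(cos g);
## coefficients propagate outward from the innermost shell (B = 0 there) by
## enforcing continuity of V and of sigma * dV/dr at every interface, then the
## overall scale is fixed by the surface current-density condition
## sigma_1 dV/dr(R) = I (2l+1) / (4 pi R^2) for each degree l >= 1.
## Explicit 2x2 inverses are used; for equal conductivities the coefficients
## pass through interfaces unchanged, recovering the homogeneous solution.
.shellCoefficients <- function(model, l, currentA = 1e-3) {
  R <- model@shellRadii[1] * 1e-3            # m
  sig <- model@shellConductivities
  K <- length(sig)
  A <- numeric(K); B <- numeric(K)
  A[K] <- 1; B[K] <- 0
  if (K > 1L) {
    for (k in seq(K - 1L, 1L)) {
      s <- model@shellRadii[k + 1L] * 1e-3   # interface radius
      p <- (s / R)^l
      q <- (R / s)^(l + 1)
      rhs1 <- A[k + 1L] * p + B[k + 1L] * q
      rhs2 <- sig[k + 1L] * (A[k + 1L] * l * p - B[k + 1L] * (l + 1) * q)
      A[k] <- ((l + 1) * rhs1 + rhs2 / sig[k]) / (p * (2 * l + 1))
      B[k] <- (l * rhs1 - rhs2 / sig[k]) / (q * (2 * l + 1))
    }
  }
  dVdr_unit <- (A[1] * l - B[1] * (l + 1)) / R
  scale <- currentA * (2 * l + 1) / (4 * pi * R^2 * sig[1] * dVdr_unit)
  list(A = A * scale, B = B * scale)
}

## Radial-field coefficient per node and degree: E_r = -dV/dr evaluated at the
## node radius in its containing shell, without the P_l factor.
.radialCoefMatrix <- function(model, nodeRadii) {
  R <- model@shellRadii[1] * 1e-3
  radiiM <- model@shellRadii * 1e-3
  L <- model@seriesOrder
  r <- nodeRadii * 1e-3
  K <- length(radiiM)
  ## shell index per node: smallest shell whose span contains the radius
  shell <- rep(K, length(r))
  if (K > 1L) {
    for (k in seq_len(K - 1L)) {
      shell[r <= radiiM[k] & r > radiiM[k + 1L]] <- k
    }
  }
  coef <- matrix(0, nrow = length(r), ncol = L)
  for (l in seq_len(L)) {
    cf <- .shellCoefficients(model, l)
    Ak <- cf$A[shell]; Bk <- cf$B[shell]
    coef[, l] <- -(Ak * l * (r / R)^l - Bk * (l + 1) * (R / r)^(l + 1)) / r
  }
  coef
}

## Sum_{l=1..L} coef[, l] * P_l(x) by the three-term Legendre recurrence,
## vectorized over nodes.
.legendreSum <- function(coef, x) {
  L <- ncol(coef)
  Pm1 <- rep(1, length(x))   # P_0
  P <- x                     # P_1
  acc <- coef[, 1] * P
  if (L >= 2L) {
    for (l in 2:L) {
      Pn <- ((2 * l - 1) * x * P - (l - 1) * Pm1) / l
      acc <- acc + coef[, l] * Pn
      Pm1 <- P
      P <- Pn
    }
  }
  acc
}

.newLeadField <- function(matrix, nodeCoords, nodeNormals, layout, provenance,
                          sphereModel = NULL) {
  rd <- S4Vectors::DataFrame(
    x = nodeCoords[, 1], y = nodeCoords[, 2], z = nodeCoords[, 3],
    nx = nodeNormals[, 1], ny = nodeNormals[, 2], nz = nodeNormals[, 3]
  )
  free <- setdiff(seq_len(nrow(layout@positions)), layout@referenceIndex)
  cd <- S4Vectors::DataFrame(label = layout@labels[free])
  colnames(matrix) <- layout@labels[free]
  md <- list(layout = layout, provenance = provenance)
  if (!is.null(sphereModel)) md$sphereModel <- sphereModel
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(leadfield = matrix), rowData = rd, colData = cd,
    metadata = md
  )
  new("LeadField", se)
}

#' Analytic lead field of a multishell spherical head
#'
#' Solves the quasi-static volume-conduction problem for point current
#' sources on the scalp of a concentric-shell sphere by Legendre series and
#' assembles the lead-field matrix: column m is the radial (surface-normal)
#' electric field at each cortex node for +1 mA at electrode m+1 and -1 mA at
#' the reference electrode. The radial component is the normal component on
#' the spherical cortex surface, the direction cortical pyramidal neurons are
#' most sensitive to.
#'
#' @param model a [SphereModel].
#' @param layout an [ElectrodeLayout]; positions are projected onto the scalp
#'   sphere.
#' @param cortexNodes either an integer node count (nodes are then sampled
#'   quasi-uniformly on a sphere of radius `cortexRadius`) or an N x 3 matrix
#'   of node coordinates in mm, all strictly inside the scalp.
#' @param cortexRadius sampling radius in mm used when `cortexNodes` is a
#'   count (default 70).
#' @param tailTolerance relative series-tail size above which a truncation
#'   warning (carrying the tail estimate) is raised (default 1e-4).
#' @return a [LeadField]; entries are in V/m per mA.
#' @export
#' @examples
#' lf <- computeSphericalLeadField(SphereModel(), scalpLayout(16), cortexNodes = 100)
#' dim(lfMatrix(lf))  # 100 x 15
computeSphericalLeadField <- function(model, layout,
                                      cortexNodes = 2000L,
                                      cortexRadius = 70,
                                      tailTolerance = 1e-4) {
  stopifnot(is(model, "SphereModel"), is(layout, "ElectrodeLayout"))
  validObject(model); validObject(layout)
  if (length(cortexNodes) == 1L && is.numeric(cortexNodes)) {
    nodes <- sampleCortexNodes(as.integer(cortexNodes), cortexRadius)
  } else {
    nodes <- as.matrix(cortexNodes)
    stopifnot(ncol(nodes) == 3L)
  }
  R <- model@shellRadii[1]
  nodeRadii <- sqrt(rowSums(nodes^2))
  if (any(nodeRadii >= R)) {
    stop("geometry error: cortex node at or outside the scalp radius (",
         format(R), " mm)")
  }
  if (any(nodeRadii <= 0)) stop("geometry error: node at the sphere center")
  ## electrodes as unit directions on the scalp sphere
  epos <- layout@positions
  epos <- epos / sqrt(rowSums(epos^2))
  M <- nrow(epos)
  nodeUnit <- nodes / nodeRadii

  coef <- .radialCoefMatrix(model, nodeRadii)

  ## series-tail estimate: terms decay at worst geometrically with ratio
  ## max(r)/R; |P_l| <= 1 so the last coefficient bounds the tail
  ratio <- max(nodeRadii) / R
  tail <- max(abs(coef[, ncol(coef)])) * ratio / (1 - ratio)
  scaleRef <- max(abs(coef[, 1]))
  if (tail > tailTolerance * scaleRef) {
    warning(sprintf(
      "Legendre series may not have converged at order L = %d: tail estimate %.3g V/m (%.2g relative); increase seriesOrder",
      model@seriesOrder, tail, tail / scaleRef))
  }

  ## radial field at every node for a unit source at each electrode
  fields <- matrix(0, nrow = nrow(nodes), ncol = M)
  for (m in seq_len(M)) {
    cosg <- pmin(1, pmax(-1, nodeUnit %*% epos[m, , drop = FALSE][1, ]))
    fields[, m] <- .legendreSum(coef, as.numeric(cosg))
  }
  ref <- layout@referenceIndex
  free <- setdiff(seq_len(M), ref)
  lfm <- fields[, free, drop = FALSE] - fields[, ref]

  normals <- nodeUnit
  colnames(normals) <- c("nx", "ny", "nz")
  colnames(nodes) <- c("x", "y", "z")
  .newLeadField(lfm, nodes, normals, layout,
                provenance = sprintf(
                  "spherical model: %d shells, L = %d, %d nodes, %d electrodes",
                  length(model@shellRadii), model@seriesOrder, nrow(nodes), M),
                sphereModel = model)
}
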