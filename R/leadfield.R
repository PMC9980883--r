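#' @include AllClasses.R AllGenerics.R sphere.R
NULL

#' Random smooth lead-field fixture
#'
#' Generates a reproducible synthetic lead field emulating the qualitative
#' structure of an FEM-derived head model: each column is a spatially smooth
#' field over the cortex nodes whose expected magnitude decays with distance
#' from that column's electrode. Nodes are sampled on a 70 mm sphere and
#' electrodes on a 92 mm scalp sphere so distances are in realistic mm.
#'
#' Columns are built as `exp(-depth_decay * d) * g(node)` where `d` is the
#' node-to-electrode distance (mm) and `g` a random smooth field obtained
#' from a Gaussian radial-basis expansion with length scale
#' `smoothness_length` mm. With `depth_decay = 0` the magnitude carries no
#' distance trend.
#'
#' @param n_nodes number of cortex nodes (>= 1).
#' @param n_electrodes total electrode count including the reference (>= 2).
#' @param smoothness_length spatial correlation length in mm (default 30).
#' @param depth_decay magnitude decay rate per mm of node-electrode distance
#'   (default 0.03; 0 disables the trend).
#' @param seed integer RNG seed (required: fixtures are reproducible).
#' @param amplitude field scale in V/m per mA (default 0.1).
#' @return a [LeadField].
#' @export
#' @examples
#' lf <- generateRandomLeadField(n_nodes = 50, n_electrodes = 8, seed = 42)
generateRandomLeadField <- function(n_nodes, n_electrodes,
                                    smoothness_length = 30,
                                    depth_decay = 0.03,
                                    seed,
                                    amplitude = 0.1) {
  if (n_nodes < 1L) stop("n_nodes must be >= 1")
  if (n_electrodes < 2L) stop("n_electrodes must be >= 2")
  if (missing(seed)) stop("seed is required")
  if (smoothness_length <= 0) stop("smoothness_length must be positive")
  if (depth_decay < 0) stop("depth_decay must be >= 0")
  set.seed(as.integer(seed))

  nodes <- sampleCortexNodes(as.integer(n_nodes), radius = 70)
  layout <- scalpLayout(as.integer(n_electrodes),
                        nRing = min(12L, max(0L, as.integer(n_electrodes) - 2L)))
  epos <- 92 * layout@positions
  ref <- layout@referenceIndex
  free <- setdiff(seq_len(n_electrodes), ref)

  nBasis <- 50L
  centers <- fibonacciSphere(nBasis, 70)
  ## squared node-to-center distances, reused for every column
  d2 <- outer(rowSums(nodes^2), rowSums(centers^2), "+") -
    2 * nodes %*% t(centers)
  basis <- exp(-pmax(d2, 0) / (2 * smoothness_length^2))

  lfm <- matrix(0, nrow = n_nodes, ncol = length(free))
  for (j in seq_along(free)) {
    w <- rnorm(nBasis)
    g <- as.numeric(basis %*% w)
    d <- sqrt(rowSums((nodes - matrix(epos[free[j], ], n_nodes, 3,
                                      byrow = TRUE))^2))
    lfm[, j] <- amplitude * exp(-depth_decay * d) * g
  }

  normals <- nodes / sqrt(rowSums(nodes^2))
  colnames(normals) <- c("nx", "ny", "nz")
  .newLeadField(lfm, nodes, normals, layout,
                provenance = sprintf(
                  "random smooth fixture: seed %d, length %g mm, decay %g /mm",
                  as.integer(seed), smoothness_length, depth_decay))
}

#' Construct a target specification
#'
#' @param regions list of integer vectors of 1-based node indices (a single
#'   vector is also accepted); regions must be disjoint and non-empty.
#' @param nNodes total node count the indices refer to.
#' @param targetField optional length-`nNodes` ideal normal-field vector;
#'   defaults to 1 on target nodes and 0 elsewhere.
#' @return a validated [TargetSpec].
#' @export
TargetSpec <- function(regions, nNodes, targetField = numeric(0)) {
  if (!is.list(regions)) regions <- list(regions)
  regions <- lapply(regions, function(r) as.integer(sort(r)))
  new("TargetSpec", regions = regions, targetField = as.numeric(targetField),
      nNodes = as.integer(nNodes))
}

#' Depth-indexed target selection on the spherical cortex
#'
#' Builds the depth-study target: an anchor point at fractional depth
#' `1 - 0.12 * depth_index` of the cortex radius along a fixed anterior
#' meridian (depth index 1 is shallow, 5 deepest), then the `k` cortex nodes
#' nearest the anchor. This preserves the monotone shallow-to-deep ordering
#' of the depth-sweep design on the spherical stand-in geometry.
#'
#' @param leadfield a [LeadField] with node coordinates.
#' @param depth_index integer in 1..5.
#' @param k target size in nodes (default 50).
#' @return a [TargetSpec] with one region of `k` nodes.
#' @export
selectDepthTarget <- function(leadfield, depth_index, k = 50L) {
  if (length(depth_index) != 1L || !depth_index %in% 1:5) {
    stop("depth_index must be an integer in 1..5")
  }
  nodes <- nodeCoords(leadfield)
  if (k > nrow(nodes)) stop("k must not exceed the node count")
  anchor <- depthAnchor(leadfield, depth_index)
  selectNearestTarget(leadfield, anchor, k)
}

#' @rdname selectDepthTarget
#' @export
depthAnchor <- function(leadfield, depth_index) {
  nodes <- nodeCoords(leadfield)
  rc <- mean(sqrt(rowSums(nodes^2)))
  c((1 - 0.12 * depth_index) * rc, 0, 0)
}

#' Target of the k nodes nearest a point
#'
#' @param leadfield a [LeadField].
#' @param point length-3 anchor coordinates in mm.
#' @param k target size in nodes.
#' @return a [TargetSpec] with one region.
#' @export
selectNearestTarget <- function(leadfield, point, k = 50L) {
  nodes <- nodeCoords(leadfield)
  if (k > nrow(nodes)) stop("k must not exceed the node count")
  d <- sqrt(rowSums((nodes - matrix(point, nrow(nodes), 3, byrow = TRUE))^2))
  idx <- order(d)[seq_len(k)]
  TargetSpec(list(as.integer(idx)), nNodes = nrow(nodes))
}

#' Default anchors for multi-target stimulation
#'
#' Four fixed, well-separated deep cortex locations standing in for the
#' folded prefrontal (anchors 1, 3: anterior left/right) and
#' parieto-temporo-occipital (anchors 2, 4: posterior right/left) regions of
#' the multi-target design, at 0.75 of the cortex radius. +x is anterior,
#' +y is left.
#'
#' @param leadfield a [LeadField].
#' @return a 4 x 3 matrix of anchor coordinates in mm.
#' @export
multiTargetAnchors <- function(leadfield) {
  nodes <- nodeCoords(leadfield)
  rc <- mean(sqrt(rowSums(nodes^2)))
  dirs <- rbind(
    c(0.7, 0.6, 0.4),    # 1: anterior left
    c(-0.7, -0.6, 0.4),  # 2: posterior right
    c(0.7, -0.6, 0.4),   # 3: anterior right
    c(-0.7, 0.6, 0.4)    # 4: posterior left
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  0.75 * rc * dirs
}

.LEADFIELD_FORMAT_VERSION <- "1"

#' Persist and restore lead fields
#'
#' `saveLeadField` writes a single-file container of named arrays
#' (`leadfield`, `node_coords`, `node_normals`, `electrode_positions`,
#' `electrode_labels`, `reference_index`, `provenance`, `format_version`,
#' plus `shell_radii`/`shell_conductivities` for spherical models) via RDS;
#' the round trip is bit-exact. `loadLeadField` validates the schema and
#' format version before reconstructing the object. `exportLeadFieldTSV`
#' writes one node per row (coordinates, normals, then one column per free
#' electrode) for interoperability with external tools; lead fields computed
#' by an external FEM pipeline can be imported by assembling the same
#' container.
#'
#' @param leadfield a [LeadField].
#' @param path file path.
#' @return `loadLeadField` returns a [LeadField]; the writers return `path`
#'   invisibly.
#' @name leadfield-io
#' @export
saveLeadField <- function(leadfield, path) {
  stopifnot(is(leadfield, "LeadField"))
  lay <- electrodeLayout(leadfield)
  obj <- list(
    format_version = .LEADFIELD_FORMAT_VERSION,
    leadfield = unname(lfMatrix(leadfield)),
    node_coords = unname(nodeCoords(leadfield)),
    node_normals = unname(nodeNormals(leadfield)),
    electrode_positions = unname(lay@positions),
    electrode_labels = lay@labels,
    reference_index = lay@referenceIndex,
    provenance = provenance(leadfield)
  )
  sm <- S4Vectors::metadata(leadfield)$sphereModel
  if (!is.null(sm)) {
    obj$shell_radii <- sm@shellRadii
    obj$shell_conductivities <- sm@shellConductivities
    obj$series_order <- sm@seriesOrder
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname leadfield-io
#' @export
loadLeadField <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj)) stop("schema error: container is not a named list")
  if (is.null(obj$format_version)) stop("schema error: missing field 'format_version'")
  if (!identical(obj$format_version, .LEADFIELD_FORMAT_VERSION)) {
    stop("lead-field container version mismatch: found '", obj$format_version,
         "', expected '", .LEADFIELD_FORMAT_VERSION, "'")
  }
  need <- c("leadfield", "node_coords", "node_normals",
            "electrode_positions", "electrode_labels")
  for (nm in need) {
    if (is.null(obj[[nm]])) stop("schema error: missing field '", nm, "'")
  }
  ref <- if (is.null(obj$reference_index)) 1L else as.integer(obj$reference_index)
  layout <- ElectrodeLayout(obj$electrode_positions, obj$electrode_labels, ref)
  sm <- NULL
  if (!is.null(obj$shell_radii)) {
    sm <- SphereModel(obj$shell_radii, obj$shell_conductivities,
                      if (is.null(obj$series_order)) 80L else obj$series_order)
  }
  prov <- if (is.null(obj$provenance)) "imported container" else obj$provenance
  .newLeadField(obj$leadfield, obj$node_coords, obj$node_normals, layout,
                provenance = prov, sphereModel = sm)
}

#' @rdname leadfield-io
#' @export
exportLeadFieldTSV <- function(leadfield, path) {
  stopifnot(is(leadfield, "LeadField"))
  m <- lfMatrix(leadfield)
  df <- data.frame(nodeCoords(leadfield), nodeNormals(leadfield),
                   m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Target specifications as JSON
#'
#' Serialized as `{"regions": [[indices...], ...], "n_nodes": N}` with
#' optional `"target_field"`; indices are 1-based.
#'
#' @param target a [TargetSpec].
#' @param path file path.
#' @name targetspec-io
#' @export
writeTargetSpec <- function(target, path) {
  stopifnot(is(target, "TargetSpec"))
  obj <- list(regions = lapply(target@regions, as.integer),
              n_nodes = target@nNodes)
  if (length(target@targetField) > 0L) obj$target_field <- target@targetField
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname targetspec-io
#' @export
readTargetSpec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$regions)) stop("schema error: missing field 'regions'")
  if (is.null(obj$n_nodes)) stop("schema error: missing field 'n_nodes'")
  rg <- obj$regions
  if (is.matrix(rg)) rg <- lapply(seq_len(nrow(rg)), function(i) rg[i, ])
  if (!is.list(rg)) rg <- list(rg)
  tf <- if (is.null(obj$target_field)) numeric(0) else as.numeric(obj$target_field)
  TargetSpec(rg, nNodes = as.integer(obj$n_nodes), targetField = tf)
}
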