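#' @import methods
NULL

#' Canonical marker panel
#'
#' The 20-marker multiplex immunofluorescence panel the default gating
#' taxonomy expects. RORgt denotes the Th17/Tc17 transcription factor
#' (written ASCII). CD45RA is carried in the panel but no default gate
#' depends on it, so tables lacking a CD45RA column are still accepted by
#' [readCellTable()] when a reduced panel is supplied.
#'
#' @return Character vector of marker names, in canonical order.
#' @export
#' @examples
#' defaultPanel()
defaultPanel <- function() {
  c("CD3", "CD8", "CD4", "FOXP3", "T-bet", "GATA3", "RORgt", "BCL6",
    "CD27", "CD56", "CD11c", "TIM-3", "PD-1", "CTLA-4", "panCK", "Ki67",
    "CD31", "GranzymeB", "HLA-DR", "CD45RA")
}

## Functional-state markers whose positivity is copied verbatim onto
## phenotype assignments (checkpoints, effector, proliferation, memory).
.functionalMarkers <- function() {
  c("TIM-3", "PD-1", "CTLA-4", "GranzymeB", "Ki67", "HLA-DR", "CD27",
    "CD45RA")
}

.regionLevels <- function() c("CT", "IM_TUMOR", "IM_STROMA", "OUTSIDE", "UNASSIGNED")

.validPanel <- function(panel) {
  if (length(panel) == 0L) return("marker panel must be non-empty")
  if (anyDuplicated(panel)) return("marker panel names must be unique")
  if (any(is.na(panel) | panel == "")) return("marker panel names must be non-missing")
  TRUE
}

#' Tumor-stroma borderline geometry
#'
#' An open polyline separating tumor from stroma in a large tissue
#' section, together with which side of the line (relative to the vertex
#' order) is tumor and the half-width of the invasive-margin band.
#'
#' @slot vertices Numeric matrix (>= 2 rows, 2 columns) of polyline
#'   vertex coordinates in micrometers.
#' @slot tumorSide Either "left" or "right": the side of the directed
#'   polyline (first vertex towards last) occupied by tumor.
#' @slot marginWidthUm Half-width of the invasive-margin band in
#'   micrometers (360 by default: the band extends 360 um into the stroma
#'   and 360 um into the tumor).
#' @export
setClass("RegionGeometry",
  representation(vertices = "matrix", tumorSide = "character",
                 marginWidthUm = "numeric"),
  prototype(marginWidthUm = 360))

setValidity("RegionGeometry", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 2L)
    return("vertices must be a numeric matrix with 2 columns and >= 2 rows")
  if (any(!is.finite(v))) return("vertices must be finite")
  if (!(object@tumorSide %in% c("left", "right")))
    return("tumorSide must be 'left' or 'right'")
  if (length(object@marginWidthUm) != 1L || !is.finite(object@marginWidthUm) ||
      object@marginWidthUm <= 0)
    return("marginWidthUm must be a single positive number")
  TRUE
})

#' Construct a RegionGeometry
#'
#' @param vertices Two-column numeric matrix of borderline vertices (um).
#' @param tumorSide "left" or "right" of the directed polyline.
#' @param marginWidthUm Invasive-margin band half-width in um.
#' @return A [RegionGeometry-class] object.
#' @export
#' @examples
#' RegionGeometry(cbind(c(0, 0), c(0, 1000)), tumorSide = "right")
RegionGeometry <- function(vertices, tumorSide = c("left", "right"),
                           marginWidthUm = 360) {
  tumorSide <- match.arg(tumorSide)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  new("RegionGeometry", vertices = vertices, tumorSide = tumorSide,
      marginWidthUm = as.numeric(marginWidthUm))
}

setMethod("show", "RegionGeometry", function(object) {
  cat("RegionGeometry:", nrow(object@vertices), "vertices; tumor on the",
      object@tumorSide, "side; margin +/-", object@marginWidthUm, "um\n")
})

#' Single-cell table for one tissue sample
#'
#' The pipeline's universal currency: one row per segmented cell with
#' coordinates in micrometers, one positivity flag per panel marker and
#' (optionally) one 0-255 intensity per marker, plus per-sample metadata
#' (tissue area in mm^2, tumor-stroma geometry).
#'
#' @slot cellId Character vector of cell identifiers (unique per sample).
#' @slot sampleId Character vector of sample identifiers.
#' @slot coords Numeric n x 2 matrix of (x, y) positions in micrometers.
#' @slot positivity Logical n x p matrix, one column per panel marker.
#' @slot intensity Numeric n x p matrix in [0, 255], or a 0 x 0 matrix
#'   when intensities are absent.
#' @slot panel Character vector of marker names (columns of positivity).
#' @slot areaMM2 Tissue area in mm^2 (NA when unknown).
#' @slot geometry A [RegionGeometry-class] or NULL.
#' @slot region Factor of region labels (CT / IM_TUMOR / IM_STROMA /
#'   OUTSIDE / UNASSIGNED), filled by [zoneCells()].
#' @export
setClass("CellTable",
  representation(cellId = "character", sampleId = "character",
                 coords = "matrix", positivity = "matrix",
                 intensity = "matrix", panel = "character",
                 areaMM2 = "numeric", geometry = "ANY",
                 region = "factor"))

setValidity("CellTable", function(object) {
  msg <- .validPanel(object@panel)
  if (!isTRUE(msg)) return(msg)
  n <- length(object@cellId)
  if (length(object@sampleId) != n) return("sampleId length mismatch")
  if (nrow(object@coords) != n || ncol(object@coords) != 2L)
    return("coords must be an n x 2 matrix")
  if (n > 0 && any(!is.finite(object@coords)))
    return("cell coordinates must be finite")
  if (nrow(object@positivity) != n)
    return("positivity must have one row per cell")
  if (ncol(object@positivity) != length(object@panel))
    return("positivity vector length must equal panel length")
  if (n > 0 && any(is.na(object@positivity)))
    return("positivity flags must be non-missing")
  if (nrow(object@intensity) > 0) {
    if (nrow(object@intensity) != n || ncol(object@intensity) != length(object@panel))
      return("intensity must be n x length(panel) when present")
    if (any(!is.na(object@intensity) &
            (object@intensity < 0 | object@intensity > 255)))
      return("intensity values must lie within [0, 255]")
  }
  if (anyDuplicated(paste(object@sampleId, object@cellId, sep = "\r")))
    return("cell_id must be unique within sample")
  if (!is.na(object@areaMM2) && object@areaMM2 <= 0)
    return("area_mm2 must be > 0 when present")
  if (!is.null(object@geometry) && !is(object@geometry, "RegionGeometry"))
    return("geometry must be a RegionGeometry or NULL")
  if (length(object@region) != n) return("region length mismatch")
  TRUE
})

#' Construct a CellTable
#'
#' @param cellId,sampleId Identifier vectors (recycled sampleId allowed).
#' @param x,y Coordinates in micrometers.
#' @param positivity Logical (or 0/1) matrix, columns named by `panel`.
#' @param panel Marker panel; defaults to the positivity column names.
#' @param intensity Optional numeric matrix in [0, 255], same shape.
#' @param areaMM2 Tissue area in mm^2 (NA if unknown).
#' @param geometry Optional [RegionGeometry-class].
#' @param region Optional region factor (defaults to UNASSIGNED).
#' @return A [CellTable-class].
#' @export
#' @examples
#' pos <- matrix(FALSE, 2, 20, dimnames = list(NULL, defaultPanel()))
#' pos[, "CD3"] <- TRUE
#' CellTable(cellId = c("c1", "c2"), sampleId = "s1",
#'           x = c(0, 10), y = c(0, 0), positivity = pos)
CellTable <- function(cellId, sampleId, x, y, positivity,
                      panel = colnames(positivity), intensity = NULL,
                      areaMM2 = NA_real_, geometry = NULL, region = NULL) {
  n <- length(cellId)
  positivity <- as.matrix(positivity)
  if (is.null(dim(positivity)) || nrow(positivity) != n)
    stop("positivity must be a matrix with one row per cell")
  mode(positivity) <- "logical"
  colnames(positivity) <- panel
  if (is.null(intensity)) {
    intensity <- matrix(numeric(0), 0, 0)
  } else {
    intensity <- as.matrix(intensity)
    storage.mode(intensity) <- "double"
    colnames(intensity) <- panel
  }
  if (is.null(region)) {
    region <- factor(rep("UNASSIGNED", n), levels = .regionLevels())
  } else {
    region <- factor(as.character(region), levels = .regionLevels())
  }
  new("CellTable",
      cellId = as.character(cellId),
      sampleId = rep_len(as.character(sampleId), n),
      coords = cbind(x = as.numeric(x), y = as.numeric(y)),
      positivity = positivity, intensity = intensity,
      panel = as.character(panel), areaMM2 = as.numeric(areaMM2),
      geometry = geometry, region = region)
}

setMethod("show", "CellTable", function(object) {
  cat("CellTable:", length(object@cellId), "cells,",
      length(unique(object@sampleId)), "sample(s),",
      length(object@panel), "markers\n")
  if (!is.na(object@areaMM2))
    cat("  area:", signif(object@areaMM2, 4), "mm^2\n")
  if (!is.null(object@geometry))
    cat("  tumor-stroma borderline attached\n")
  if (nrow(object@intensity) > 0) cat("  per-marker intensities present\n")
})

#' @describeIn CellTable Number of cells.
#' @param x A CellTable.
#' @export
nCells <- function(x) length(x@cellId)

#' Accessors for CellTable
#'
#' `cellIds`, `sampleIds`, `cellCoords`, `positivity`, `intensities`,
#' `markerPanel`, `areaMM2`, `cellRegions` extract the corresponding
#' per-cell columns or metadata without touching slots directly.
#'
#' @param x A [CellTable-class].
#' @return The requested component.
#' @name cellTableAccessors
NULL

#' @rdname cellTableAccessors
#' @export
cellIds <- function(x) x@cellId

#' @rdname cellTableAccessors
#' @export
sampleIds <- function(x) x@sampleId

#' @rdname cellTableAccessors
#' @export
cellCoords <- function(x) x@coords

#' @rdname cellTableAccessors
#' @export
positivity <- function(x) x@positivity

#' @rdname cellTableAccessors
#' @export
intensities <- function(x) if (nrow(x@intensity)) x@intensity else NULL

#' @rdname cellTableAccessors
#' @export
markerPanel <- function(x) x@panel

#' @rdname cellTableAccessors
#' @export
areaMM2 <- function(x) x@areaMM2

#' @rdname cellTableAccessors
#' @export
regionGeometry <- function(x) x@geometry

#' @rdname cellTableAccessors
#' @export
cellRegions <- function(x) x@region

#' Subset a CellTable by cell index
#'
#' @param x A [CellTable-class].
#' @param i Integer or logical cell index.
#' @param j,drop,... Ignored.
#' @return A [CellTable-class] with the selected cells.
#' @export
setMethod("[", "CellTable", function(x, i, j, ..., drop = FALSE) {
  new("CellTable",
      cellId = x@cellId[i], sampleId = x@sampleId[i],
      coords = x@coords[i, , drop = FALSE],
      positivity = x@positivity[i, , drop = FALSE],
      intensity = if (nrow(x@intensity)) x@intensity[i, , drop = FALSE]
                  else x@intensity,
      panel = x@panel, areaMM2 = x@areaMM2, geometry = x@geometry,
      region = x@region[i])
})

#' Cell-cell contact graph
#'
#' Symmetric adjacency over the cells of one sample: an (unordered) edge
#' joins two cells whose center-to-center Euclidean distance is less than
#' or equal to the contact threshold (8 um by default, boundary
#' inclusive).
#'
#' @slot cellId Character vector of node identifiers.
#' @slot edgeI,edgeJ Integer endpoint indices (edgeI < edgeJ).
#' @slot edgeDist Numeric edge distances in micrometers.
#' @slot thresholdUm Contact radius in micrometers.
#' @export
setClass("ContactGraph",
  representation(cellId = "character", edgeI = "integer", edgeJ = "integer",
                 edgeDist = "numeric", thresholdUm = "numeric"))

setValidity("ContactGraph", function(object) {
  ne <- length(object@edgeI)
  if (length(object@edgeJ) != ne || length(object@edgeDist) != ne)
    return("edge vectors must have equal length")
  if (ne > 0) {
    if (any(object@edgeI >= object@edgeJ)) return("edges must satisfy i < j (no self-edges)")
    if (max(object@edgeJ) > length(object@cellId)) return("edge index out of range")
    if (any(object@edgeDist > object@thresholdUm + 1e-9))
      return("every edge distance must be <= thresholdUm")
  }
  TRUE
})

setMethod("show", "ContactGraph", function(object) {
  cat("ContactGraph:", length(object@cellId), "cells,",
      length(object@edgeI), "contacts (threshold",
      object@thresholdUm, "um)\n")
})

#' @describeIn ContactGraph Number of contact edges.
#' @param x A ContactGraph.
#' @export
numEdges <- function(x) length(x@edgeI)

#' Edge list of a contact graph
#'
#' @param x A [ContactGraph-class].
#' @return data.frame with columns cell_a, cell_b, distance_um.
#' @export
edgeTable <- function(x) {
  data.frame(cell_a = x@cellId[x@edgeI], cell_b = x@cellId[x@edgeJ],
             distance_um = x@edgeDist, stringsAsFactors = FALSE)
}

#' DBSCAN nest labeling
#'
#' Per-cell nest assignment for one population (typically all T cells),
#' plus the DBSCAN parameters and a per-nest composition summary.
#'
#' @slot cellId Character vector of cells the labeling covers.
#' @slot nestId Integer nest id per cell; NA for noise cells.
#' @slot epsUm,minPts DBSCAN reachability radius (um) and minimum
#'   self-inclusive neighborhood size.
#' @slot nestSizes Integer vector of nest sizes, named by nest id.
#' @slot composition Numeric matrix nests x subpopulations of member
#'   fractions (rows sum to 1), or 0 x 0 when no assignment was given.
#' @export
setClass("NestLabeling",
  representation(cellId = "character", nestId = "integer",
                 epsUm = "numeric", minPts = "integer",
                 nestSizes = "integer", composition = "matrix"))

setValidity("NestLabeling", function(object) {
  if (length(object@nestId) != length(object@cellId))
    return("nestId length mismatch")
  TRUE
})

setMethod("show", "NestLabeling", function(object) {
  cat("NestLabeling:", length(object@cellId), "cells,",
      length(object@nestSizes), "nest(s); eps =", object@epsUm,
      "um, MinPts =", object@minPts, "\n")
})

#' @describeIn NestLabeling Number of nests found.
#' @param x A NestLabeling.
#' @export
numNests <- function(x) length(x@nestSizes)

#' @describeIn NestLabeling Per-cell nest ids (NA = noise).
#' @export
nestIds <- function(x) structure(x@nestId, names = x@cellId)

#' @describeIn NestLabeling Nest sizes.
#' @export
nestSizes <- function(x) x@nestSizes

#' @describeIn NestLabeling Per-nest subpopulation composition.
#' @export
nestComposition <- function(x) x@composition

#' KNN-density (X-shift-style) patient clustering
#'
#' @slot sampleId Character vector of clustered samples.
#' @slot clusterId Integer cluster id per sample (1..nClusters).
#' @slot K Number of nearest neighbors used for the density estimate.
#' @slot modes Integer indices of the density modes (cluster roots).
#' @slot density Numeric KNN density per sample.
#' @slot centroids Numeric matrix clusters x features of mean profiles
#'   (on the standardized scale used for clustering).
#' @export
setClass("PatientClustering",
  representation(sampleId = "character", clusterId = "integer",
                 K = "integer", modes = "integer", density = "numeric",
                 centroids = "matrix"))

setValidity("PatientClustering", function(object) {
  if (length(object@clusterId) != length(object@sampleId))
    return("clusterId length mismatch")
  if (length(object@sampleId) > 0 &&
      (any(is.na(object@clusterId)) || max(object@clusterId) < 1L))
    return("every patient must belong to exactly one cluster")
  TRUE
})

setMethod("show", "PatientClustering", function(object) {
  cat("PatientClustering:", length(object@sampleId), "samples in",
      length(object@modes), "cluster(s); K =", object@K, "\n")
})

#' @describeIn PatientClustering Cluster ids named by sample.
#' @param x A PatientClustering.
#' @export
clusterIds <- function(x) structure(x@clusterId, names = x@sampleId)

#' @describeIn PatientClustering Number of clusters.
#' @export
numClusters <- function(x) length(x@modes)
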