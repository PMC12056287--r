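## Classic DBSCAN with self-inclusive neighbor counting and a
## deterministic, order-independent border rule: core points are points
## with >= minPts cells (themselves included) within eps; clusters are
## the connected components of the core-core eps-graph; a non-core cell
## with at least one core neighbor joins the cluster of its
## smallest-index core neighbor; remaining cells are noise. Cluster ids
## are numbered by smallest member index.
.dbscan <- function(x, y, epsUm, minPts) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  pr <- .radiusPairs(x, y, epsUm)
  deg <- tabulate(c(pr$i, pr$j), nbins = n)
  core <- (deg + 1L) >= minPts
  cl <- rep(NA_integer_, n)
  if (!any(core)) return(cl)
  ## union-find over core-core edges
  parent <- seq_len(n)
  findRoot <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  cc <- which(core[pr$i] & core[pr$j])
  for (e in cc) {
    ri <- findRoot(pr$i[e]); rj <- findRoot(pr$j[e])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(which(core), findRoot, integer(1))
  ids <- match(roots, sort(unique(roots)))
  cl[core] <- ids
  ## border cells: smallest-index core neighbor decides
  bi <- pr$i; bj <- pr$j
  borderEdge <- xor(core[bi], core[bj])
  if (any(borderEdge)) {
    b <- ifelse(core[bi[borderEdge]], bj[borderEdge], bi[borderEdge])
    cr <- ifelse(core[bi[borderEdge]], bi[borderEdge], bj[borderEdge])
    o <- order(b, cr)
    b <- b[o]; cr <- cr[o]
    first <- !duplicated(b)
    cl[b[first]] <- cl[cr[first]]
  }
  cl
}

#' Detect T-cell nests by DBSCAN
#'
#' Runs DBSCAN on the (x, y) positions of the selected population
#' (default: all T cells). A nest is a density cluster with at least
#' `minPts` members at reachability `epsUm`; neighbor counts include the
#' point itself, matching the convention of the standard R DBSCAN
#' implementations. Defaults eps = 40 um, MinPts = 27 (the calibrated
#' nest definition).
#'
#' @param table A [CellTable-class].
#' @param assignment Output of [assignPhenotypes()], or NULL to cluster
#'   every cell of the table.
#' @param epsUm Reachability radius in micrometers (> 0).
#' @param minPts Minimum self-inclusive neighborhood size (>= 1).
#' @param population Subpopulation labels to cluster; NULL selects all
#'   cells of the T-cell lineages.
#' @return A [NestLabeling-class] over the selected cells.
#' @export
detectNests <- function(table, assignment = NULL, epsUm = 40, minPts = 27,
                        population = NULL) {
  stopifnot(is(table, "CellTable"))
  if (!is.numeric(epsUm) || epsUm <= 0) stop("eps must be > 0")
  if (!is.numeric(minPts) || minPts < 1) stop("minPts must be >= 1")
  if (is.null(assignment)) {
    sel <- seq_len(nCells(table))
    subpop <- NULL
  } else {
    stopifnot(nrow(assignment) == nCells(table))
    sel <- if (is.null(population))
      which(as.character(assignment$lineage) %in% .tLineages())
    else which(assignment$subpopulation %in% population)
    subpop <- as.character(assignment$subpopulation[sel])
  }
  cl <- .dbscan(table@coords[sel, 1], table@coords[sel, 2], epsUm, minPts)
  sizes <- if (all(is.na(cl))) integer(0) else as.integer(table(cl))
  comp <- matrix(numeric(0), 0, 0)
  if (length(sizes) > 0 && !is.null(subpop)) {
    tab <- table(factor(cl, levels = seq_along(sizes)), subpop)
    comp <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  }
  new("NestLabeling", cellId = table@cellId[sel], nestId = cl,
      epsUm = as.numeric(epsUm), minPts = as.integer(minPts),
      nestSizes = sizes, composition = comp)
}

#' Calibrate the DBSCAN reachability radius
#'
#' Given cells with ground-truth nest membership (e.g. manually annotated
#' accumulations), runs [detectNests()] at every candidate eps and
#' computes sensitivity (fraction of true nest cells labeled in-nest) and
#' specificity (fraction of true non-nest cells labeled noise). Returns
#' the grid value at the crossing point of the two curves, i.e. the eps
#' minimizing |sensitivity - specificity|; ties resolve to the smaller
#' eps.
#'
#' @param table A [CellTable-class] of the annotated population.
#' @param truthInNest Logical per cell: TRUE for true nest cells.
#' @param epsGrid Ascending numeric grid of candidate eps values (>= 2).
#' @param minPts DBSCAN MinPts (default 27).
#' @return The selected eps; attributes `sensitivity` and `specificity`
#'   carry the full curves.
#' @export
calibrateEps <- function(table, truthInNest, epsGrid, minPts = 27) {
  stopifnot(is(table, "CellTable"), length(truthInNest) == nCells(table))
  if (length(epsGrid) < 2L)
    stop("eps calibration requires a grid of at least two values")
  if (is.unsorted(epsGrid, strictly = TRUE))
    stop("epsGrid must be strictly ascending")
  if (!any(truthInNest) || all(truthInNest))
    stop("annotation must contain both nest and non-nest cells ",
         "(sensitivity/specificity curves undefined otherwise)")
  sens <- spec <- numeric(length(epsGrid))
  for (g in seq_along(epsGrid)) {
    lab <- detectNests(table, assignment = NULL, epsUm = epsGrid[g],
                       minPts = minPts)
    inNest <- !is.na(lab@nestId)
    sens[g] <- mean(inNest[truthInNest])
    spec[g] <- mean(!inNest[!truthInNest])
  }
  best <- which.min(abs(sens - spec))  # which.min takes the first = smaller eps
  structure(epsGrid[best], sensitivity = sens, specificity = spec)
}
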