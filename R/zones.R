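## Signed distance from points to an open polyline: nearest-segment
## projection; the side is the sign of the cross product on the nearest
## segment (ties at shared vertices resolved towards the segment with
## the larger |cross|, which is the more robust witness of the side).
.polylineSignedDistance <- function(px, py, verts) {
  nseg <- nrow(verts) - 1L
  n <- length(px)
  bestD2 <- rep(Inf, n)
  bestCross <- rep(0, n)
  degenerate <- TRUE
  for (s in seq_len(nseg)) {
    ax <- verts[s, 1]; ay <- verts[s, 2]
    dx <- verts[s + 1L, 1] - ax; dy <- verts[s + 1L, 2] - ay
    L2 <- dx * dx + dy * dy
    if (L2 == 0) next
    degenerate <- FALSE
    t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    # perpendicular offset (cross product / segment length): sign gives
    # the side, magnitude is comparable across segments at vertex ties
    cross <- (dx * (py - ay) - dy * (px - ax)) / sqrt(L2)
    upd <- d2 < bestD2 - 1e-9 |
           (abs(d2 - bestD2) <= 1e-9 & abs(cross) > abs(bestCross))
    bestD2[upd] <- d2[upd]
    bestCross[upd] <- cross[upd]
  }
  if (degenerate)
    stop("degenerate borderline: all vertices identical")
  list(dist = sqrt(bestD2), leftSide = bestCross)
}

#' Zone cells into tumor center and invasive margin
#'
#' Computes the signed distance of every cell to the tumor-stroma
#' borderline and labels it CT (tumor side beyond the margin band),
#' IM_TUMOR / IM_STROMA (within the band of half-width
#' `marginWidthUm`, 360 um by default, boundary inclusive) or OUTSIDE
#' (stroma side beyond the band). Cells lying exactly on the borderline
#' are treated as tumor-side.
#'
#' @param table A [CellTable-class].
#' @param geometry A [RegionGeometry-class]; defaults to the table's own.
#' @return The table with its `region` factor filled; the signed
#'   distances (positive towards tumor) are attached as attribute
#'   `signedDistanceUm`.
#' @export
zoneCells <- function(table, geometry = regionGeometry(table)) {
  stopifnot(is(table, "CellTable"))
  if (is.null(geometry)) stop("no region geometry supplied or attached")
  stopifnot(is(geometry, "RegionGeometry"))
  validObject(geometry)
  sd <- .polylineSignedDistance(table@coords[, 1], table@coords[, 2],
                                geometry@vertices)
  tumorSign <- if (geometry@tumorSide == "left") 1 else -1
  signed <- ifelse(sign(sd$leftSide) == 0, 1,
                   tumorSign * sign(sd$leftSide)) * sd$dist
  w <- geometry@marginWidthUm
  region <- ifelse(abs(signed) <= w,
                   ifelse(signed >= 0, "IM_TUMOR", "IM_STROMA"),
                   ifelse(signed > 0, "CT", "OUTSIDE"))
  out <- table
  out@region <- factor(region, levels = .regionLevels())
  out@geometry <- geometry
  attr(out, "signedDistanceUm") <- signed
  out
}

#' Randomly split a section into spatially contiguous regions
#'
#' Partitions the cells of a large section into k spatially contiguous
#' tiles of near-equal cell count for heterogeneity analysis: k-means on
#' the cell coordinates with a fixed seed (default k = 48), followed by a
#' capacity-balanced assignment to the fitted centers so that region
#' counts differ by at most one.
#'
#' @param table A [CellTable-class].
#' @param k Number of regions (1 <= k <= number of cells).
#' @param seed RNG seed making the partition reproducible.
#' @return Integer region index (1..k) per cell, named by cell id.
#' @export
randomRegionSplit <- function(table, k = 48, seed = 1) {
  stopifnot(is(table, "CellTable"))
  n <- nCells(table)
  if (!is.numeric(k) || k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  if (k > n) stop("k exceeds the number of cells (", n, ")")
  if (k == 1L || n == 1L)
    return(structure(rep(1L, n), names = table@cellId))
  set.seed(seed)
  km <- stats::kmeans(table@coords, centers = k, nstart = 5L,
                      iter.max = 100L)
  ## capacity-balanced assignment to the k-means centers: cells are
  ## processed by distance to their preferred center and each region
  ## accepts at most ceil(n/k) cells, so counts differ by at most one
  cap <- ceiling(n / k)
  d2 <- outer(table@coords[, 1], km$centers[, 1], "-")^2 +
        outer(table@coords[, 2], km$centers[, 2], "-")^2
  assign <- integer(n)
  load <- integer(k)
  ord <- order(apply(d2, 1L, min))
  for (i in ord) {
    pref <- order(d2[i, ])
    g <- pref[load[pref] < cap][1]
    assign[i] <- g
    load[g] <- load[g] + 1L
  }
  structure(assign, names = table@cellId)
}
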