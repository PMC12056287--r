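## Fixed-radius pair search via grid binning: bins of side r, each point
## compared with points in its own and the 8 adjacent bins (each
## unordered bin pair visited once). Returns i < j pairs with d <= r
## (boundary inclusive). Defined by, and tested against, the O(n^2)
## all-pairs rule.
.radiusPairs <- function(x, y, r) {
  n <- length(x)
  empty <- list(i = integer(0), j = integer(0), d = numeric(0))
  if (n < 2L) return(empty)
  cw <- max(r, 1e-9)
  ix <- as.integer(floor(x / cw)); iy <- as.integer(floor(y / cw))
  ix <- ix - min(ix); iy <- iy - min(iy)
  stride <- max(ix) + 2L
  key <- ix + iy * stride
  o <- order(key, method = "radix")
  members <- split(o, key[o])
  ukey <- as.integer(names(members))
  iOut <- list(); jOut <- list()
  ## within-bin pairs
  len <- lengths(members)
  multi <- which(len >= 2L)
  if (length(multi)) {
    iOut[[1]] <- unlist(lapply(members[multi], function(m) {
      k <- length(m); rep(m[-k], times = (k - 1L):1L)
    }), use.names = FALSE)
    jOut[[1]] <- unlist(lapply(members[multi], function(m) {
      k <- length(m)
      m[unlist(lapply(2:k, function(a) a:k), use.names = FALSE)]
    }), use.names = FALSE)
  }
  ## cross-bin pairs: offsets E, NW, N, NE relative to each bin
  for (off in c(1L, stride - 1L, stride, stride + 1L)) {
    hit <- match(ukey + off, ukey)
    src <- which(!is.na(hit))
    if (!length(src)) next
    a <- members[src]; b <- members[hit[src]]
    la <- lengths(a); lb <- lengths(b)
    ii <- unlist(mapply(function(m, k) rep(m, each = k), a, lb[seq_along(a)],
                        SIMPLIFY = FALSE), use.names = FALSE)
    jj <- unlist(mapply(function(m, k) rep(m, times = k), b, la[seq_along(b)],
                        SIMPLIFY = FALSE), use.names = FALSE)
    iOut[[length(iOut) + 1L]] <- ii
    jOut[[length(jOut) + 1L]] <- jj
  }
  if (!length(iOut)) return(empty)
  i <- unlist(iOut, use.names = FALSE)
  j <- unlist(jOut, use.names = FALSE)
  d2 <- (x[i] - x[j])^2 + (y[i] - y[j])^2
  keep <- d2 <= r * r
  i <- i[keep]; j <- j[keep]
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  list(i = i, j = j, d = sqrt(d2[keep]))
}

#' Build the cell-cell contact graph
#'
#' Two cells are in contact when the Euclidean distance between their
#' center points is eight or fewer micrometers (threshold inclusive,
#' configurable). Uses a grid spatial index, so it scales subquadratically,
#' but the result is defined by (and tested against) the all-pairs rule.
#'
#' @param table A [CellTable-class].
#' @param thresholdUm Contact radius in micrometers (default 8).
#' @return A [ContactGraph-class].
#' @export
#' @examples
#' tab <- CellTable(cellId = c("a", "b"), sampleId = "s",
#'                  x = c(0, 8), y = c(0, 0),
#'                  positivity = matrix(FALSE, 2, 20,
#'                                      dimnames = list(NULL, defaultPanel())))
#' numEdges(buildContactGraph(tab))  # 1: the 8-um boundary is inclusive
buildContactGraph <- function(table, thresholdUm = 8) {
  stopifnot(is(table, "CellTable"))
  if (!is.numeric(thresholdUm) || length(thresholdUm) != 1L ||
      !is.finite(thresholdUm) || thresholdUm < 0)
    stop("contact threshold must be a single non-negative number")
  pr <- .radiusPairs(table@coords[, 1], table@coords[, 2], thresholdUm)
  ord <- order(pr$i, pr$j)
  new("ContactGraph", cellId = table@cellId,
      edgeI = as.integer(pr$i[ord]), edgeJ = as.integer(pr$j[ord]),
      edgeDist = pr$d[ord], thresholdUm = thresholdUm)
}

#' Nearest-neighbor distances between subpopulations
#'
#' For every cell of subpopulation `from`, the minimum Euclidean distance
#' to any cell of subpopulation `to` (excluding the cell itself when
#' `from == to`). When no valid target exists the value is NA, following
#' the zero-denominator exclusion rule.
#'
#' @param table A [CellTable-class].
#' @param assignment Output of [assignPhenotypes()] for the same cells.
#' @param from,to Subpopulation labels.
#' @return Named numeric vector (um), one entry per `from` cell.
#' @export
nearestDistances <- function(table, assignment, from, to) {
  stopifnot(is(table, "CellTable"), nrow(assignment) == nCells(table))
  fi <- which(assignment$subpopulation == from)
  ti <- which(assignment$subpopulation == to)
  out <- rep(NA_real_, length(fi))
  names(out) <- table@cellId[fi]
  if (!length(fi)) return(out)
  if (!length(ti) || (from == to && length(ti) == 1L)) return(out)
  fx <- table@coords[fi, 1]; fy <- table@coords[fi, 2]
  tx <- table@coords[ti, 1]; ty <- table@coords[ti, 2]
  self <- if (from == to) match(fi, ti) else rep(NA_integer_, length(fi))
  block <- max(1L, floor(2e6 / length(ti)))
  for (s in seq(1L, length(fi), by = block)) {
    idx <- s:min(s + block - 1L, length(fi))
    d2 <- outer(fx[idx], tx, "-")^2 + outer(fy[idx], ty, "-")^2
    if (from == to)
      d2[cbind(seq_along(idx), self[idx])] <- Inf
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}
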