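# Independent brute-force oracles and fixture builders used across the
# suite. The oracles deliberately avoid the package's spatial index and
# union-find code paths.

# all-pairs contact oracle: i < j with d <= r (inclusive)
bruteContacts <- function(x, y, r) {
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  idx <- which(upper.tri(d2) & d2 <= r * r, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

# classic DBSCAN oracle via dense matrix + min-label propagation over
# core points; border points take the cluster of their smallest-index
# core neighbor; clusters renumbered by smallest core index
bruteDbscan <- function(x, y, eps, minPts) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  adj <- d2 <= eps * eps
  diag(adj) <- FALSE
  core <- (rowSums(adj) + 1L) >= minPts
  lab <- ifelse(core, seq_len(n), NA_integer_)
  if (any(core)) {
    repeat {
      changed <- FALSE
      for (i in which(core)) {
        nb <- which(adj[i, ] & core)
        m <- min(lab[c(i, nb)])
        if (m < lab[i]) { lab[i] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    for (i in which(!core)) {
      nb <- which(adj[i, ] & core)
      if (length(nb)) lab[i] <- lab[min(nb)]
    }
    seen <- sort(unique(lab[!is.na(lab)]))
    lab <- match(lab, seen)
  }
  lab
}

# bare CellTable from coordinates (no marker structure needed)
pointTable <- function(x, y, sampleId = "s", markerOn = NULL) {
  pos <- matrix(FALSE, length(x), 20,
                dimnames = list(NULL, defaultPanel()))
  if (!is.null(markerOn)) pos[, markerOn] <- TRUE
  CellTable(cellId = sprintf("c%05d", seq_along(x)), sampleId = sampleId,
            x = x, y = y, positivity = pos)
}

# CellTable with explicit subpopulation labels (markers set so that the
# default gates reproduce `labels` exactly)
labeledTable <- function(x, y, labels, sampleId = "s") {
  pm <- spatialTME:::.populationMarkers()
  pos <- matrix(FALSE, length(x), 20,
                dimnames = list(NULL, defaultPanel()))
  for (lab in unique(labels)) {
    rows <- labels == lab
    for (m in pm[[lab]]) pos[rows, m] <- TRUE
  }
  CellTable(cellId = sprintf("c%05d", seq_along(x)), sampleId = sampleId,
            x = x, y = y, positivity = pos)
}

# label-exchangeable null configuration: five immune subpopulations at
# equal density on a standard core, no attraction, no nests
nullConfig <- function(densityEach = 600) {
  simulationConfig(intensities = c(Tc1 = densityEach, Th1 = densityEach,
                                   Treg = densityEach, Th17 = densityEach,
                                   `Tc-other` = densityEach))
}

# composition-recovery configuration: the MSI preset with the spatial
# attractions removed (multinomial sampling of the planted fractions)
recoveryConfig <- function() {
  cfg <- preset("MSI")
  cfg@attractions <- cfg@attractions[0, ]
  cfg
}

# dense planted-nest configuration over a sparse background
nestConfig <- function(nNests = 3, cellsPerNest = 60, radiusUm = 50,
                       background = 150) {
  simulationConfig(
    intensities = c(`Tc-other` = background),
    nests = data.frame(population = "Tc-other", count = nNests,
                       radiusUm = radiusUm, cellsPerNest = cellsPerNest,
                       stringsAsFactors = FALSE))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
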