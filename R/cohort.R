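#' Group comparison across immune features (volcano logic)
#'
#' Per feature: Welch two-sided t-test between the two groups, log2
#' fold-change of group means (numerator / denominator), and
#' Benjamini-Hochberg adjustment across the evaluable feature family
#' (Bonferroni selectable). Samples excluded for a feature (NA, the
#' zero-denominator rule) are dropped per feature; a feature with fewer
#' than two values in either group is reported as not evaluable.
#'
#' @param features Numeric matrix samples x features (NA = excluded).
#' @param groups Factor (two levels) of group membership per sample.
#' @param numerator Group level used as the fold-change numerator
#'   (default: the second level).
#' @param adjust "BH" (default) or "bonferroni".
#' @return data.frame per feature: mean/SEM per group, log2fc (finite
#'   only when both means are positive), p, p_adj, evaluable.
#' @export
compareGroups <- function(features, groups,
                          numerator = levels(groups)[2],
                          adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (!numerator %in% levels(groups)) stop("unknown numerator level")
  features <- as.matrix(features)
  if (nrow(features) != length(groups))
    stop("features must have one row per sample")
  denominator <- setdiff(levels(groups), numerator)
  num <- groups == numerator
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  res <- lapply(seq_len(ncol(features)), function(j) {
    v <- features[, j]
    a <- v[num & !is.na(v)]; b <- v[!num & !is.na(v)]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(mean_num = NA_real_, sem_num = NA_real_,
                        mean_den = NA_real_, sem_den = NA_real_,
                        log2fc = NA_real_, p = NA_real_, evaluable = FALSE))
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    }
    fc <- if (mean(a) > 0 && mean(b) > 0) log2(mean(a) / mean(b)) else NA_real_
    data.frame(mean_num = mean(a), sem_num = sem(a), mean_den = mean(b),
               sem_den = sem(b), log2fc = fc, p = p, evaluable = TRUE)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(feature = colnames(features) %||%
                            as.character(seq_len(ncol(features))),
                          stringsAsFactors = FALSE), out)
  out$p_adj <- NA_real_
  ev <- out$evaluable
  out$p_adj[ev] <- stats::p.adjust(out$p[ev],
                                   method = if (adjust == "BH") "BH"
                                            else "bonferroni")
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  out
}

#' KNN-density (X-shift-style) clustering of patient profiles
#'
#' Simplified re-implementation of X-shift density ascent: (1) the
#' density of each point is the inverse mean Euclidean distance to its K
#' nearest neighbors; (2) each point links to the highest-density point
#' within its K-neighborhood whose density exceeds its own (exact density
#' ties broken towards the smaller index, so that coincident points form
#' one cluster); (3) points with no denser neighbor are modes; (4)
#' clusters are the ascent trees rooted at the modes. Features are
#' z-scored per column before clustering unless `standardize = FALSE`.
#' No neighborhood-merging refinement is applied.
#'
#' @param features Numeric matrix samples x features (no NA).
#' @param K Number of nearest neighbors (default 20; must be < n).
#' @param standardize Z-score columns first (constant columns left at 0).
#' @return A [PatientClustering-class].
#' @export
knnDensityCluster <- function(features, K = 20, standardize = TRUE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (!is.numeric(K) || K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  if (K >= n) stop("K must be smaller than the number of patients (", n, ")")
  if (anyNA(features)) stop("feature matrix must not contain NA")
  if (standardize) {
    mu <- colMeans(features)
    sdv <- apply(features, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    features <- sweep(sweep(features, 2L, mu), 2L, sdv, "/")
  }
  d <- as.matrix(stats::dist(features))
  nbr <- matrix(0L, n, K)
  knnMean <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(d[i, ])
    o <- o[o != i][seq_len(K)]  # drop self explicitly (ties!)
    nbr[i, ] <- o
    knnMean[i] <- mean(d[i, o])
  }
  density <- ifelse(knnMean == 0, Inf, 1 / knnMean)
  denser <- function(a, b) {  # is a denser than b (with index tie-break)?
    density[a] > density[b] | (density[a] == density[b] & a < b)
  }
  parent <- integer(n)
  for (i in seq_len(n)) {
    cand <- nbr[i, denser(nbr[i, ], i)]
    if (!length(cand)) {
      parent[i] <- i  # mode
    } else {
      best <- cand[order(-density[cand], cand)[1]]
      parent[i] <- best
    }
  }
  root <- seq_len(n)
  repeat {
    nxt <- parent[root]
    if (all(nxt == root)) break
    root <- nxt
  }
  modes <- sort(unique(root))
  cid <- match(root, modes)
  cent <- do.call(rbind, lapply(seq_along(modes), function(cc)
    colMeans(features[cid == cc, , drop = FALSE])))
  colnames(cent) <- colnames(features)
  new("PatientClustering",
      sampleId = rownames(features) %||% as.character(seq_len(n)),
      clusterId = as.integer(cid), K = K, modes = as.integer(modes),
      density = density, centroids = cent)
}

#' Select K by the elbow of the cluster-count curve
#'
#' Runs [knnDensityCluster()] for every K in the grid, records the
#' cluster count, and returns the K at the point of maximum discrete
#' curvature of the cluster-count-versus-K curve (second differences
#' normalized by the local slope, central differences over the grid
#' spacing; endpoints are not eligible). Ties resolve to the smaller K;
#' a flat curve returns the smallest K with a warning.
#'
#' @param features Numeric matrix samples x features.
#' @param KGrid Ascending integer grid with at least three values, all
#'   below the number of samples.
#' @param standardize Passed to [knnDensityCluster()].
#' @return Selected K; attribute `clusterCounts` carries the curve.
#' @export
elbowSelectK <- function(features, KGrid, standardize = TRUE) {
  if (length(KGrid) < 3L) stop("K grid must contain at least three values")
  if (is.unsorted(KGrid, strictly = TRUE)) stop("K grid must be ascending")
  counts <- vapply(KGrid, function(K)
    numClusters(knnDensityCluster(features, K = K,
                                  standardize = standardize)), numeric(1))
  structure(.elbowFromCurve(KGrid, counts), clusterCounts = counts)
}

## elbow = maximum discrete curvature |y''| / (1 + y'^2)^(3/2) over the
## interior grid points (central differences on the K axis)
.elbowFromCurve <- function(K, y) {
  if (length(unique(y)) == 1L) {
    warning("cluster-count curve is flat; returning the smallest K")
    return(K[1])
  }
  interior <- 2:(length(K) - 1L)
  h1 <- K[interior] - K[interior - 1L]
  h2 <- K[interior + 1L] - K[interior]
  d1 <- (y[interior + 1L] - y[interior - 1L]) / (h1 + h2)
  d2 <- 2 * (h1 * y[interior + 1L] - (h1 + h2) * y[interior] +
             h2 * y[interior - 1L]) / (h1 * h2 * (h1 + h2))
  curv <- abs(d2) / (1 + d1^2)^1.5
  K[interior[which.max(curv)]]  # which.max: first maximum = smaller K
}

#' Flag the MSI-like patient cluster
#'
#' Among the clusters of an (MSS) patient clustering, flags the members
#' of the cluster whose mean composition profile is nearest (Euclidean,
#' restricted to the supplied profile columns) to a reference MSI mean
#' profile. Ties resolve to the smaller cluster id. With a single
#' cluster the flag is all-or-nothing and a warning is raised.
#'
#' @param clustering A [PatientClustering-class] over the MSS patients.
#' @param profiles Numeric matrix samples x features (same samples, raw
#'   scale; typically subpopulation fractions from [profileMatrix()]).
#' @param reference Numeric vector: the MSI mean profile on the same
#'   features.
#' @return Named logical vector per patient.
#' @export
flagMsiLike <- function(clustering, profiles, reference) {
  stopifnot(is(clustering, "PatientClustering"))
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != length(clustering@sampleId))
    stop("profiles and clustering must cover the same patients")
  if (length(reference) != ncol(profiles))
    stop("reference profile must match the profile columns")
  nc <- numClusters(clustering)
  if (nc == 1L)
    warning("single cluster: MSI-like flag is all-or-nothing")
  dists <- vapply(seq_len(nc), function(cc) {
    mu <- colMeans(profiles[clustering@clusterId == cc, , drop = FALSE])
    sqrt(sum((mu - reference)^2))
  }, numeric(1))
  best <- which.min(dists)  # first minimum = smaller cluster id
  structure(clustering@clusterId == best, names = clustering@sampleId)
}
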