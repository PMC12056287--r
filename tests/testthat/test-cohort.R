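test_that("group comparison handles identical groups, NAs and small groups", {
  set.seed(71)
  m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  m <- rbind(m, m)  # two identical groups
  grp <- factor(rep(c("MSS", "MSI"), each = 20), levels = c("MSS", "MSI"))
  cmp <- compareGroups(abs(m) + 1, grp, numerator = "MSI")
  expect_equal(cmp$log2fc, c(0, 0))
  expect_equal(cmp$p, c(1, 1))
  # adjusted p never below raw p
  m2 <- matrix(rnorm(200), 40, 5)
  m2[1:3, 1] <- NA
  cmp2 <- compareGroups(m2, grp)
  expect_true(all(cmp2$p_adj >= cmp2$p - 1e-12, na.rm = TRUE))
  # a feature with < 2 values in one group is not evaluable
  m2[grp == "MSI", 2] <- NA
  m2[which(grp == "MSI")[1], 2] <- 0
  cmp3 <- compareGroups(m2, grp)
  expect_false(cmp3$evaluable[2])
  expect_true(is.na(cmp3$p[2]))
  expect_error(compareGroups(m2, factor(rep("A", 40))), "two levels")
})

test_that("fold changes are finite only for positive group means", {
  m <- cbind(allzero = c(rep(0, 10), rep(0, 10)),
             ok = c(rnorm(10, 5), rnorm(10, 10)))
  grp <- factor(rep(c("MSS", "MSI"), each = 10), levels = c("MSS", "MSI"))
  cmp <- compareGroups(m, grp, numerator = "MSI")
  expect_true(is.na(cmp$log2fc[1]))
  expect_true(is.finite(cmp$log2fc[2]))
})

test_that("BH rejections under the global null stay at the nominal rate", {
  set.seed(72)
  anyRej <- replicate(200, {
    m <- matrix(rnorm(30 * 12), 30, 12)
    grp <- factor(rep(c("A", "B"), 15))
    cmp <- compareGroups(m, grp)
    any(cmp$p_adj < 0.05, na.rm = TRUE)
  })
  # under the complete null FDR = FWER; allow two binomial SEs of MC error
  expect_lte(mean(anyRej), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("KNN-density clustering separates well-separated blobs", {
  set.seed(73)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  m <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(100, centers[k, 1], 0.5), rnorm(100, centers[k, 2], 0.5))))
  truth <- rep(1:3, each = 100)
  # within the stability window the planted count is recovered exactly
  for (K in c(40, 50, 60)) {
    cl <- knnDensityCluster(m, K = K)
    expect_equal(numClusters(cl), 3L)
    expect_false(anyNA(clusterIds(cl)))
    # and the partition coincides with the planted blobs
    expect_equal(length(unique(clusterIds(cl)[truth == 1])), 1L)
    expect_equal(length(unique(truth[clusterIds(cl) == clusterIds(cl)[1]])),
                 1L)
  }
  # at smaller K the ascent may split a blob but never mixes two blobs
  cl20 <- knnDensityCluster(m, K = 20)
  for (cc in unique(clusterIds(cl20)))
    expect_equal(length(unique(truth[clusterIds(cl20) == cc])), 1L)
})

test_that("degenerate clustering inputs behave as documented", {
  m <- matrix(1, 10, 3)
  cl <- knnDensityCluster(m, K = 3, standardize = FALSE)
  expect_equal(numClusters(cl), 1L)  # all points identical
  expect_error(knnDensityCluster(m, K = 10), "smaller")
  expect_error(knnDensityCluster(m, K = 0), ">= 1")
  # unimodal data with K = n-1: single cluster, against an exhaustive
  # density-ascent oracle
  set.seed(74)
  u <- matrix(rnorm(60 * 2), 60, 2)
  cl2 <- knnDensityCluster(u, K = 59)
  d <- as.matrix(dist(scale(u)))
  dens <- 1 / vapply(1:60, function(i) mean(sort(d[i, ])[2:60]), numeric(1))
  expect_equal(numClusters(cl2), sum(vapply(1:60, function(i)
    all(dens[i] >= dens[-i]) || !any(dens[-i] > dens[i]), logical(1))))
  expect_equal(numClusters(cl2), 1L)
})

test_that("clustering is invariant to point order", {
  set.seed(75)
  m <- matrix(rnorm(200), 100, 2)
  rownames(m) <- sprintf("p%03d", 1:100)
  cl1 <- knnDensityCluster(m, K = 15)
  perm <- sample(100)
  cl2 <- knnDensityCluster(m[perm, ], K = 15)
  ids1 <- clusterIds(cl1); ids2 <- clusterIds(cl2)[rownames(m)]
  # same partition up to relabeling
  expect_equal(length(unique(ids1)), length(unique(ids2)))
  expect_true(all(outer(ids1, ids1, "==") == outer(ids2, ids2, "==")))
})

test_that("the elbow rule picks the flattening point of the count curve", {
  # curve 50,20,8,6,5,5 over K grid 5..30: maximum curvature at the
  # 8 -> 6 flattening (K = 15)
  expect_equal(spatialTME:::.elbowFromCurve(seq(5, 30, by = 5),
                                            c(50, 20, 8, 6, 5, 5)), 15)
  expect_warning(
    flat <- spatialTME:::.elbowFromCurve(seq(5, 30, by = 5), rep(4, 6)),
    "flat")
  expect_equal(flat, 5)
})

test_that("elbow selection lands at the flattening of the count curve", {
  set.seed(76)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  m <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(40, centers[k, 1], 0.5), rnorm(40, centers[k, 2], 0.5))))
  grid <- c(5, 8, 12, 16, 20, 24, 30)
  KSel <- elbowSelectK(m, KGrid = grid)
  counts <- attr(KSel, "clusterCounts")
  # an interior K near the steep-to-flat transition, with a count close
  # to the planted 3 (the simplified ascent has no merge step, so the
  # elbow can sit one grid step before full stabilization)
  expect_true(KSel %in% grid[2:(length(grid) - 1)])
  expect_lte(counts[match(as.numeric(KSel), grid)], 6)
  # the curve itself stabilizes at the planted count
  expect_equal(counts[length(grid)], 3)
  expect_true(all(diff(counts) <= 0))  # decreasing on clean blobs
  expect_error(elbowSelectK(m, KGrid = c(5, 10)), "three")
})

test_that("MSI-like flagging picks the cluster nearest the reference", {
  set.seed(77)
  # two clusters: one around the reference profile, one far away
  prof <- rbind(matrix(rnorm(40, 10, 0.5), 20, 2),
                matrix(rnorm(40, 0, 0.5), 20, 2))
  rownames(prof) <- sprintf("s%02d", 1:40)
  cl <- knnDensityCluster(prof, K = 10)
  expect_equal(numClusters(cl), 2L)
  fl <- flagMsiLike(cl, prof, reference = c(10, 10))
  expect_identical(unname(fl), rep(c(TRUE, FALSE), each = 20))
  # tie between identical clusters resolves to the smaller id
  dup <- new("PatientClustering", sampleId = rownames(prof),
             clusterId = rep(c(1L, 2L), each = 20), K = 5L,
             modes = c(1L, 21L), density = rep(1, 40),
             centroids = matrix(0, 2, 2))
  same <- rbind(matrix(5, 20, 2), matrix(5, 20, 2))
  fl2 <- flagMsiLike(dup, same, reference = c(5, 5))
  expect_identical(unname(fl2), rep(c(TRUE, FALSE), each = 20))
  # single cluster: all-or-nothing with a warning
  one <- new("PatientClustering", sampleId = rownames(prof)[1:20],
             clusterId = rep(1L, 20), K = 5L, modes = 1L,
             density = rep(1, 20), centroids = matrix(0, 1, 2))
  expect_warning(fl3 <- flagMsiLike(one, prof[1:20, ], c(0, 0)),
                 "single cluster")
  expect_true(all(fl3))
})
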