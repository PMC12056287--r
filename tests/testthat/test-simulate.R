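test_that("generation is reproducible for a fixed seed", {
  g1 <- generateSample(preset("MSI"), seed = 101)
  g2 <- generateSample(preset("MSI"), seed = 101)
  expect_identical(cellCoords(g1$table), cellCoords(g2$table))
  expect_identical(positivity(g1$table), positivity(g2$table))
  expect_identical(g1$truth, g2$truth)
})

test_that("homogeneous Poisson counts match the planted intensity", {
  cfg <- simulationConfig(intensities = c(`Tc-other` = 1000))
  set.seed(102)
  counts <- replicate(100, nCells(generateSample(cfg)$table))
  lambda <- 1000 * coreArea(0.6)  # 282.7 expected cells per core
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 100))
  expect_true(all(counts >= qpois(1e-6, lambda) &
                  counts <= qpois(1 - 1e-6, lambda)))
})

test_that("positivity is exactly consistent with the ground truth", {
  for (name in c("MSI", "MSS")) {
    g <- generateSample(preset(name), seed = 103)
    a <- assignPhenotypes(g$table)
    expect_identical(as.character(a$subpopulation),
                     g$truth$true_subpopulation)
  }
})

test_that("presets plant the reported cohort density parameters", {
  expect_equal(sum(preset("MSI")@intensities[tSubpopulations()]), 1628)
  expect_equal(sum(preset("MSS")@intensities[tSubpopulations()]), 1028)
  expect_identical(preset("MSI_LIKE")@intensities, preset("MSI")@intensities)
  expect_error(preset("BOGUS"), "unknown preset")
})

test_that("functional positivity rates are recovered within sampling error", {
  set.seed(104)
  cfg <- recoveryConfig()
  nPos <- 0; nTot <- 0
  for (r in 1:20) {
    g <- generateSample(cfg)
    a <- assignPhenotypes(g$table)
    tcells <- a$lineage %in% c("CYTOTOXIC_T", "HELPER_T", "OTHER_T")
    nPos <- nPos + sum(a[["PD-1"]][tcells])
    nTot <- nTot + sum(tcells)
  }
  rate <- attr(generateSample(cfg)$truth, "functionalRates")["Tc1", "PD-1"]
  ci <- binom.test(nPos, nTot)$conf.int
  expect_true(rate >= ci[1] && rate <= ci[2])
})

test_that("attraction couples offspring to parents at the planted scale", {
  set.seed(105)
  g <- generateSample(preset("MSI"))
  a <- assignPhenotypes(g$table)
  d <- nearestDistances(g$table, a, "Th1", "Tc1")
  # a substantial share of Th1 cells sit within a few sigma of a Tc1 cell
  expect_gt(mean(d < 15, na.rm = TRUE), 0.3)
  # with attraction stripped the same share is much smaller
  g0 <- generateSample(recoveryConfig())
  a0 <- assignPhenotypes(g0$table)
  d0 <- nearestDistances(g0$table, a0, "Th1", "Tc1")
  expect_lt(mean(d0 < 15, na.rm = TRUE), mean(d < 15, na.rm = TRUE))
})

test_that("cohort generation covers the degenerate and planted cases", {
  coh0 <- generateCohort(0, 0, 0)
  expect_length(coh0$tables, 0L)
  expect_equal(nrow(coh0$labels), 0L)
  coh <- generateCohort(3, 5, fracMsiLike = 0.4, seed = 106)
  coh2 <- generateCohort(3, 5, fracMsiLike = 0.4, seed = 106)
  expect_identical(coh$labels, coh2$labels)
  expect_equal(sum(coh$labels$msi_like_true), 2)  # round(0.4 * 5)
  expect_true(all(coh$labels$group[coh$labels$msi_like_true] == "MSS"))
  expect_identical(names(coh$tables), coh$labels$sample_id)
})

test_that("large sections honor region factors and record region truth", {
  border <- RegionGeometry(cbind(c(1500, 1500), c(0, 2000)),
                           tumorSide = "right", marginWidthUm = 360)
  pops <- c(Tc1 = 400, `Th-other` = 400)
  mkRF <- function(ctFactor) {
    rf <- matrix(1, 2, 4, dimnames = list(names(pops),
                                          c("CT", "IM_TUMOR", "IM_STROMA",
                                            "OUTSIDE")))
    rf["Tc1", "CT"] <- ctFactor
    rf
  }
  cfg <- simulationConfig(pops, geometryType = "rect",
                          rectWidthUm = 3000, rectHeightUm = 2000,
                          borderline = border, regionFactors = mkRF(2.5))
  set.seed(107)
  cts <- sapply(1:8, function(i) {
    g <- generateLargeSection(cfg)
    tc1 <- g$truth$true_subpopulation == "Tc1"
    c(ct = sum(tc1 & g$truth$region == "CT"),
      outside = sum(tc1 & g$truth$region == "OUTSIDE"))
  })
  # CT spans x in (1860, 3000], OUTSIDE x in [0, 1140): areas 2.28 and
  # 2.28 mm^2, so the count ratio estimates the planted factor 2.5
  ratio <- sum(cts["ct", ]) / sum(cts["outside", ])
  expect_equal(ratio, 2.5, tolerance = 0.15)
  # factor 1.0 -> homogeneous field
  cfg1 <- simulationConfig(pops, geometryType = "rect",
                           rectWidthUm = 3000, rectHeightUm = 2000,
                           borderline = border, regionFactors = mkRF(1))
  g1 <- generateLargeSection(cfg1, seed = 108)
  tc1 <- g1$truth$true_subpopulation == "Tc1"
  r1 <- sum(tc1 & g1$truth$region == "CT") /
        sum(tc1 & g1$truth$region == "OUTSIDE")
  expect_equal(r1, 1, tolerance = 0.35)
  # region truth matches zoning of the emitted table
  z <- zoneCells(g1$table)
  expect_identical(as.character(cellRegions(z)), g1$truth$region)
  expect_error(generateLargeSection(preset("MSI")), "rect")
})

test_that("the resource guard rejects absurd configurations", {
  cfg <- simulationConfig(intensities = c(Tc1 = 1e8))
  expect_error(generateSample(cfg), "resource guard")
})

test_that("truth sidecars align row-for-row with the emitted table", {
  g <- generateSample(preset("MSS"), seed = 109)
  expect_equal(nrow(g$truth), nCells(g$table))
  expect_identical(g$truth$cell_id, cellIds(g$table))
  expect_true(all(g$truth$true_subpopulation %in%
                  names(preset("MSS")@intensities)))
})
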