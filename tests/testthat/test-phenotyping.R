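mkCell <- function(markers) {
  pos <- matrix(FALSE, 1, 20, dimnames = list(NULL, defaultPanel()))
  pos[, markers] <- TRUE
  CellTable(cellId = "c1", sampleId = "s", x = 0, y = 0, positivity = pos)
}

test_that("canonical gates assign the expected subpopulations", {
  cases <- list(
    list(c("CD3", "CD8", "T-bet"), "Tc1", "CYTOTOXIC_T"),
    list(c("CD3", "CD8", "GATA3"), "Tc2", "CYTOTOXIC_T"),
    list(c("CD3", "CD8", "RORgt"), "Tc17", "CYTOTOXIC_T"),
    list(c("CD3", "CD8", "FOXP3"), "Tcreg", "CYTOTOXIC_T"),
    list(c("CD3", "CD8", "BCL6"), "Tcf", "CYTOTOXIC_T"),
    list(c("CD3", "CD8", "CD56"), "Tc-NKT", "CYTOTOXIC_T"),
    list(c("CD3", "CD8"), "Tc-other", "CYTOTOXIC_T"),
    list(c("CD3", "CD4", "T-bet"), "Th1", "HELPER_T"),
    list(c("CD3", "CD4", "FOXP3"), "Treg", "HELPER_T"),
    list(c("CD3", "CD4", "BCL6"), "Tfh", "HELPER_T"),
    list(c("CD3", "CD4"), "Th-other", "HELPER_T"),
    list(c("CD3"), "T-other", "OTHER_T"),
    list(c("CD3", "CD4", "CD8"), "T-other", "OTHER_T"),  # double positive
    list(c("CD11c"), "DC", "DC"),
    list(c("CD56"), "NK", "NK"),
    list(c("CD56", "CD11c"), "DC", "DC"),  # CD11c+ dominates NK gate
    list(c("panCK"), "Tumor", "TUMOR"),
    list(c("CD31"), "Endothelial", "ENDOTHELIAL"),
    list(character(0), "Other", "OTHER"))
  for (cs in cases) {
    a <- assignPhenotypes(mkCell(cs[[1]]))
    expect_identical(as.character(a$subpopulation), cs[[2]])
    expect_identical(as.character(a$lineage), cs[[3]])
  }
})

test_that("multi-TF cells resolve by the FOXP3-first priority", {
  a <- assignPhenotypes(mkCell(c("CD3", "CD8", "FOXP3", "T-bet")))
  expect_identical(as.character(a$subpopulation), "Tcreg")
  a <- assignPhenotypes(mkCell(c("CD3", "CD4", "T-bet", "GATA3")))
  expect_identical(as.character(a$subpopulation), "Th1")
  a <- assignPhenotypes(mkCell(c("CD3", "CD4", "GATA3", "RORgt", "CD56")))
  expect_identical(as.character(a$subpopulation), "Th2")
})

test_that("gating is order-independent and exhaustive", {
  set.seed(21)
  g <- generateSample(preset("MSI"), seed = 77)
  a1 <- assignPhenotypes(g$table)
  perm <- sample(nCells(g$table))
  a2 <- assignPhenotypes(g$table[perm])
  expect_identical(as.character(a2$subpopulation),
                   as.character(a1$subpopulation)[perm])
  expect_false(anyNA(a1$subpopulation))
})

test_that("rules referencing markers absent from the panel error", {
  rules <- defaultGatingRules()
  rules$pos[[1]] <- c(rules$pos[[1]], "CD999")
  expect_error(assignPhenotypes(mkCell("CD3"), rules), "CD999")
})

test_that("composition fractions partition T cells and match hand counts", {
  # 50 Tc1 + 150 Th-other = 200 T cells on a 0.6 mm core
  labels <- c(rep("Tc1", 50), rep("Th-other", 150))
  tab <- labeledTable(runif(200, -250, 250), runif(200, -250, 250), labels)
  tab@areaMM2 <- coreArea(0.6)
  a <- assignPhenotypes(tab)
  prof <- composition(tab, a)
  expect_equal(prof$frac_Tc1, 25)
  expect_equal(prof$frac_Th_other, 75)
  expect_equal(prof$t_density, 200 / coreArea(0.6), tolerance = 1e-12)
  expect_equal(round(prof$t_density, 1), 707.4)
  fr <- unlist(prof[grep("^frac_", names(prof))])
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  expect_false(prof$excluded)
})

test_that("samples with zero T cells are excluded, not NaN", {
  tab <- labeledTable(c(0, 10), c(0, 10), c("Tumor", "DC"))
  tab@areaMM2 <- 0.28
  prof <- composition(tab, assignPhenotypes(tab))
  expect_true(prof$excluded)
  expect_true(all(is.na(unlist(prof[grep("^frac_", names(prof))]))))
  expect_false(any(is.nan(unlist(prof[sapply(prof, is.numeric)]))))
  expect_equal(prof$dens_DC, 1 / 0.28, tolerance = 1e-12)
})

test_that("functional fractions match hand counts and exclude empty subsets", {
  labels <- rep(c("Tc1", "Treg"), c(10, 5))
  tab <- labeledTable(seq_along(labels) * 20, rep(0, 15), labels)
  # make 4 of 10 Tc1 PD-1+ and all 5 Treg CTLA-4+
  pos <- positivity(tab)
  pos[1:4, "PD-1"] <- TRUE
  pos[11:15, "CTLA-4"] <- TRUE
  tab@positivity <- pos
  ff <- functionalFractions(assignPhenotypes(tab))
  val <- function(s, m) ff$fraction[ff$subpopulation == s & ff$marker == m]
  expect_equal(val("Tc1", "PD-1"), 40)
  expect_equal(val("Treg", "CTLA-4"), 100)
  expect_equal(val("Treg", "PD-1"), 0)
  expect_true(all(ff$excluded[ff$subpopulation == "Th2"]))
  expect_true(all(is.na(ff$fraction[ff$excluded])))
  expect_error(functionalFractions(assignPhenotypes(tab), markers = "CD999"),
               "CD999")
})

test_that("gating rules round-trip through their text config format", {
  p <- tempfile()
  writeGatingRules(defaultGatingRules(), p)
  back <- readGatingRules(p)
  ref <- defaultGatingRules()
  expect_identical(back$label, ref$label)
  expect_identical(back$priority, ref$priority)
  for (k in seq_len(nrow(ref))) {
    expect_identical(back$pos[[k]], as.character(ref$pos[[k]]))
    expect_identical(back$neg[[k]], as.character(ref$neg[[k]]))
  }
  # a reloaded rule set gates identically
  g <- generateSample(preset("MSS"), seed = 13)
  expect_identical(assignPhenotypes(g$table, back)$subpopulation,
                   assignPhenotypes(g$table, ref)$subpopulation)
  bad <- tempfile()
  writeLines(c("label\tfoo", "x\ty"), bad)
  expect_error(readGatingRules(bad), "missing column")
  unlink(c(p, bad))
})

test_that("recovered fractions track planted frequencies within binomial error", {
  set.seed(31)
  cfg <- recoveryConfig()
  cover <- logical(0)
  for (r in 1:40) {
    g <- generateSample(cfg)
    a <- assignPhenotypes(g$table)
    prof <- composition(g$table, a)
    expT <- attr(g$truth, "expectedFractions")
    nT <- prof$n_t_cells
    for (s in names(expT)) {
      k <- round(prof[[paste0("frac_", spatialTME:::.san(s))]] * nT / 100)
      ci <- stats::binom.test(k, nT)$conf.int
      cover <- c(cover, expT[[s]] / 100 >= ci[1] & expT[[s]] / 100 <= ci[2])
    }
  }
  expect_gt(mean(cover), 0.9)
})
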