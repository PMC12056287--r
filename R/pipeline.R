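.pipelineStages <- function() {
  c("simulate", "phenotype", "contacts", "interactions", "nests", "zones",
    "cohort")
}

.writeStamped <- function(df, path, seed, params = "") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# spatialTME %s\tseed=%d\t%s",
                     as.character(utils::packageVersion("spatialTME")),
                     seed, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Orchestrates simulate -> phenotype -> contacts -> interactions ->
#' nests -> zones -> cohort over a synthetic MSI/MSS cohort, writing
#' tab-separated tables (each stamped with package version, seed and
#' parameters) into an output directory. Deterministic for a fixed seed;
#' existing outputs are never overwritten unless `overwrite = TRUE`. On a
#' stage failure a `FAILED` marker naming the stage is left in the
#' output directory and the error is re-thrown.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param stages Subset of the stage list to run (dependencies of later
#'   stages are computed in memory regardless).
#' @param nMsi,nMss,fracMsiLike Cohort composition.
#' @param nPerm Permutations for the interaction null.
#' @param thresholdUm,epsUm,minPts,marginUm Spatial parameters.
#' @param overwrite Allow overwriting an existing output directory.
#' @return Invisibly, the output directory.
#' @export
runPipeline <- function(outDir, seed = 1L, stages = .pipelineStages(),
                        nMsi = 8, nMss = 8, fracMsiLike = 0,
                        nPerm = 200, thresholdUm = 8, epsUm = 40,
                        minPts = 27, marginUm = 360, overwrite = FALSE) {
  unknown <- setdiff(stages, .pipelineStages())
  if (length(unknown))
    stop("unknown pipeline stage(s): ", paste(sQuote(unknown), collapse = ", "))
  if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite)
    stop("output directory not empty; pass overwrite = TRUE to replace")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  stage <- "simulate"
  tryCatch({
    set.seed(seed)
    coh <- generateCohort(nMsi, nMss, fracMsiLike)
    if ("simulate" %in% stages) {
      dir.create(file.path(outDir, "samples"), showWarnings = FALSE)
      for (sid in names(coh$tables))
        writeCellTable(coh$tables[[sid]],
                       file.path(outDir, "samples", paste0(sid, ".tsv")))
      .writeStamped(coh$labels, file.path(outDir, "labels.tsv"), seed,
                    sprintf("nMsi=%d nMss=%d fracMsiLike=%g",
                            nMsi, nMss, fracMsiLike))
    }

    stage <- "phenotype"
    rules <- defaultGatingRules()
    assignments <- lapply(coh$tables, assignPhenotypes, rules = rules)
    profiles <- do.call(rbind, lapply(names(coh$tables), function(sid)
      composition(coh$tables[[sid]], assignments[[sid]], rules)))
    if ("phenotype" %in% stages)
      .writeStamped(profiles, file.path(outDir, "composition.tsv"), seed, "")

    stage <- "contacts"
    graphs <- lapply(coh$tables, buildContactGraph, thresholdUm = thresholdUm)
    if ("contacts" %in% stages) {
      summary <- data.frame(
        sample_id = names(graphs),
        n_cells = vapply(coh$tables, nCells, integer(1)),
        n_contacts = vapply(graphs, numEdges, integer(1)),
        row.names = NULL, stringsAsFactors = FALSE)
      .writeStamped(summary, file.path(outDir, "contacts.tsv"), seed,
                    sprintf("threshold_um=%g", thresholdUm))
    }

    stage <- "interactions"
    inter <- NULL
    if (any(c("interactions", "cohort") %in% stages)) {
      inter <- do.call(rbind, lapply(names(graphs), function(sid) {
        res <- interactionStatistics(graphs[[sid]], assignments[[sid]],
                                     nPerm = nPerm,
                                     areaMM2 = areaMM2(coh$tables[[sid]]))
        cbind(sample_id = sid, res)
      }))
      if ("interactions" %in% stages)
        .writeStamped(inter, file.path(outDir, "interactions.tsv"), seed,
                      sprintf("n_perm=%d threshold_um=%g", nPerm, thresholdUm))
    }

    stage <- "nests"
    if ("nests" %in% stages) {
      nestRows <- do.call(rbind, lapply(names(coh$tables), function(sid) {
        nl <- detectNests(coh$tables[[sid]], assignments[[sid]],
                          epsUm = epsUm, minPts = minPts)
        data.frame(sample_id = sid, n_t_cells = length(nl@cellId),
                   n_nests = numNests(nl),
                   frac_in_nest = if (length(nl@cellId))
                     mean(!is.na(nl@nestId)) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
      .writeStamped(nestRows, file.path(outDir, "nests.tsv"), seed,
                    sprintf("eps_um=%g min_pts=%d", epsUm, minPts))
    }

    stage <- "zones"
    if ("zones" %in% stages) {
      zoneRows <- do.call(rbind, lapply(names(coh$tables), function(sid) {
        tab <- coh$tables[[sid]]
        if (!is.null(regionGeometry(tab))) tab <- zoneCells(tab)
        counts <- table(cellRegions(tab))
        cbind(data.frame(sample_id = sid, stringsAsFactors = FALSE),
              as.data.frame(t(as.matrix(counts))))
      }))
      .writeStamped(zoneRows, file.path(outDir, "zones.tsv"), seed,
                    sprintf("margin_um=%g", marginUm))
    }

    stage <- "cohort"
    if ("cohort" %in% stages) {
      feat <- profileMatrix(profiles, "fractions")
      cmp <- compareGroups(feat, coh$labels$group, numerator = "MSI")
      .writeStamped(cmp, file.path(outDir, "volcano.tsv"), seed, "")
      n <- nrow(feat)
      K <- min(20L, n - 2L)
      if (K >= 1L && n > K) {
        cl <- knnDensityCluster(feat, K = K)
        msiMean <- colMeans(feat[coh$labels$group == "MSI", , drop = FALSE])
        # flagging is only meaningful with >= 2 clusters and an MSI arm
        flags <- if (any(coh$labels$group == "MSI") && numClusters(cl) > 1)
          flagMsiLike(cl, feat, msiMean) else rep(NA, n)
        .writeStamped(data.frame(sample_id = rownames(feat),
                                 cluster = clusterIds(cl),
                                 msi_like = flags,
                                 stringsAsFactors = FALSE),
                      file.path(outDir, "clustering.tsv"), seed,
                      sprintf("K=%d", K))
      }
    }
    invisible(outDir)
  }, error = function(e) {
    writeLines(c(stage, conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop("pipeline stage ", sQuote(stage), " failed: ",
         conditionMessage(e), call. = FALSE)
  })
}
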