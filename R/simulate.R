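#' Synthetic tissue simulation configuration
#'
#' Describes one synthetic sample: geometry (a TMA-core disc or a
#' rectangular large section with a tumor-stroma borderline), expected
#' per-population densities (cells/mm^2), pairwise spatial attraction
#' (parent-offspring Neyman-Scott coupling: a fraction kappa of parent
#' cells each spawn one offspring at an isotropic Gaussian displacement
#' of scale sigma), planted uniform-disc nests, per-(population, marker)
#' functional positivity rates, patient-level heterogeneity (lognormal
#' jitter of immune densities), and per-region density factors for large
#' sections. Points are generated on a 10\% enlarged region and clipped,
#' so intensities are unbiased near the border.
#'
#' @slot geometryType "disc" or "rect".
#' @slot discRadiusUm Core radius in um (disc geometry; 300 by default,
#'   the 0.6 mm TMA format).
#' @slot rectWidthUm,rectHeightUm Section extent in um (rect geometry).
#' @slot borderline A [RegionGeometry-class] (rect geometry) or NULL.
#' @slot intensities Named numeric vector of expected densities
#'   (cells/mm^2) per population label.
#' @slot attractions data.frame(parent, offspring, kappa, sigmaUm).
#' @slot nests data.frame(population, count, radiusUm, cellsPerNest).
#' @slot functionalRates Numeric matrix populations x functional markers
#'   of Bernoulli positivity probabilities.
#' @slot regionFactors Numeric matrix populations x regions (CT,
#'   IM_TUMOR, IM_STROMA, OUTSIDE) scaling densities per zone (rect
#'   geometry; 0 x 0 = homogeneous).
#' @slot heterogeneitySdLog Lognormal sd of the per-subpopulation density
#'   jitter between patients.
#' @slot densitySdLog Lognormal sd of the global immune-infiltration
#'   factor between patients.
#' @slot withIntensity Emit synthetic 0-255 marker intensities.
#' @export
setClass("SimulationConfig",
  representation(geometryType = "character", discRadiusUm = "numeric",
                 rectWidthUm = "numeric", rectHeightUm = "numeric",
                 borderline = "ANY", intensities = "numeric",
                 attractions = "data.frame", nests = "data.frame",
                 functionalRates = "matrix", regionFactors = "matrix",
                 heterogeneitySdLog = "numeric", densitySdLog = "numeric",
                 withIntensity = "logical"))

setValidity("SimulationConfig", function(object) {
  if (!(object@geometryType %in% c("disc", "rect")))
    return("geometryType must be 'disc' or 'rect'")
  if (object@geometryType == "disc" &&
      (!is.finite(object@discRadiusUm) || object@discRadiusUm <= 0))
    return("disc radius must be > 0")
  if (object@geometryType == "rect" &&
      (object@rectWidthUm <= 0 || object@rectHeightUm <= 0))
    return("rectangle extent must be > 0")
  if (any(object@intensities < 0) || is.null(names(object@intensities)))
    return("intensities must be named and >= 0")
  at <- object@attractions
  if (nrow(at) > 0) {
    if (any(at$kappa < 0 | at$kappa > 1)) return("kappa must lie in [0, 1]")
    if (any(at$sigmaUm <= 0)) return("sigmaUm must be > 0")
    if (!all(c(at$parent, at$offspring) %in% names(object@intensities)))
      return("attraction populations must appear in intensities")
  }
  if (nrow(object@nests) > 0 && any(object@nests$radiusUm <= 0))
    return("nest radius must be > 0")
  fr <- object@functionalRates
  if (length(fr) > 0 && any(fr < 0 | fr > 1))
    return("functional rates must be probabilities in [0, 1]")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@geometryType, "geometry,",
      length(object@intensities), "populations,",
      nrow(object@attractions), "attraction(s),",
      nrow(object@nests), "planted nest spec(s)\n")
})

#' @rdname SimulationConfig-class
#' @param intensities,attractions,nests,functionalRates,regionFactors,geometryType,discRadiusUm,rectWidthUm,rectHeightUm,borderline,heterogeneitySdLog,densitySdLog,withIntensity
#'   See the class slots.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(intensities,
                             geometryType = c("disc", "rect"),
                             discRadiusUm = 300,
                             rectWidthUm = 2000, rectHeightUm = 1500,
                             borderline = NULL,
                             attractions = NULL, nests = NULL,
                             functionalRates = NULL, regionFactors = NULL,
                             heterogeneitySdLog = 0, densitySdLog = 0,
                             withIntensity = FALSE) {
  geometryType <- match.arg(geometryType)
  if (is.null(attractions))
    attractions <- data.frame(parent = character(0), offspring = character(0),
                              kappa = numeric(0), sigmaUm = numeric(0),
                              stringsAsFactors = FALSE)
  if (is.null(nests))
    nests <- data.frame(population = character(0), count = integer(0),
                        radiusUm = numeric(0), cellsPerNest = integer(0),
                        stringsAsFactors = FALSE)
  if (is.null(functionalRates)) {
    functionalRates <- matrix(0, length(intensities),
                              length(.functionalMarkers()),
                              dimnames = list(names(intensities),
                                              .functionalMarkers()))
  }
  if (is.null(regionFactors)) regionFactors <- matrix(numeric(0), 0, 0)
  new("SimulationConfig", geometryType = geometryType,
      discRadiusUm = discRadiusUm, rectWidthUm = rectWidthUm,
      rectHeightUm = rectHeightUm, borderline = borderline,
      intensities = intensities, attractions = attractions, nests = nests,
      functionalRates = functionalRates, regionFactors = regionFactors,
      heterogeneitySdLog = heterogeneitySdLog, densitySdLog = densitySdLog,
      withIntensity = withIntensity)
}

## lineage-defining positive markers per population label
.populationMarkers <- function() {
  subset <- c(Tcreg = "FOXP3", Tc1 = "T-bet", Tc2 = "GATA3", Tc17 = "RORgt",
              Tcf = "BCL6", `Tc-NKT` = "CD56")
  hsubset <- c(Treg = "FOXP3", Th1 = "T-bet", Th2 = "GATA3", Th17 = "RORgt",
               Tfh = "BCL6", `Th-NKT` = "CD56")
  out <- list()
  for (k in seq_along(subset))
    out[[names(subset)[k]]] <- c("CD3", "CD8", subset[[k]])
  out[["Tc-other"]] <- c("CD3", "CD8")
  for (k in seq_along(hsubset))
    out[[names(hsubset)[k]]] <- c("CD3", "CD4", hsubset[[k]])
  out[["Th-other"]] <- c("CD3", "CD4")
  out[["T-other"]] <- "CD3"
  out[["DC"]] <- "CD11c"
  out[["NK"]] <- "CD56"
  out[["Tumor"]] <- "panCK"
  out[["Endothelial"]] <- "CD31"
  out
}

.nonImmunePops <- function() c("Tumor", "Endothelial")

#' Cohort presets
#'
#' Simulation configurations emulating the qualitative immune structure
#' of microsatellite-instable (MSI) and -stable (MSS) colorectal cancer
#' TMA cores: planted total T-cell densities of 1,628 (MSI) and 1,028
#' (MSS) cells/mm^2; a Tc1/Th1-dominant composition with Tc1-Th1 and
#' Tc1-DC spatial attraction and elevated checkpoint (TIM-3/PD-1/CTLA-4)
#' rates for MSI; a Treg/Th17/Th2-enriched composition with Treg-Th17
#' and Treg-DC attraction for MSS. MSI_LIKE is the MSI configuration
#' (used for patients carried in an MSS arm).
#'
#' @param name One of "MSI", "MSS", "MSI_LIKE".
#' @return A [SimulationConfig-class] (disc geometry, 0.6 mm core).
#' @export
#' @examples
#' cfg <- preset("MSI")
#' sum(cfg@intensities[tSubpopulations()])  # 1628 cells/mm^2
preset <- function(name = c("MSI", "MSS", "MSI_LIKE")) {
  if (!is.character(name) || !(name[1] %in% c("MSI", "MSS", "MSI_LIKE")))
    stop("unknown preset: ", sQuote(name[1]))
  name <- match.arg(name)
  tFrac <- if (name %in% c("MSI", "MSI_LIKE")) {
    c(Tc1 = 0.24, Tc2 = 0.02, Tc17 = 0.02, Tcreg = 0.02, Tcf = 0.01,
      `Tc-NKT` = 0.01, `Tc-other` = 0.14,
      Th1 = 0.15, Th2 = 0.04, Th17 = 0.03, Treg = 0.07, Tfh = 0.02,
      `Th-NKT` = 0.01, `Th-other` = 0.21, `T-other` = 0.01)
  } else {
    c(Tc1 = 0.07, Tc2 = 0.04, Tc17 = 0.03, Tcreg = 0.02, Tcf = 0.01,
      `Tc-NKT` = 0.01, `Tc-other` = 0.10,
      Th1 = 0.07, Th2 = 0.09, Th17 = 0.08, Treg = 0.13, Tfh = 0.02,
      `Th-NKT` = 0.01, `Th-other` = 0.31, `T-other` = 0.01)
  }
  tTotal <- if (name %in% c("MSI", "MSI_LIKE")) 1628 else 1028
  intens <- c(tFrac * tTotal,
              DC = if (name == "MSS") 100 else 120,
              NK = if (name == "MSS") 60 else 80,
              Tumor = 1500, Endothelial = 150)
  attr <- if (name %in% c("MSI", "MSI_LIKE")) {
    data.frame(parent = c("Tc1", "Tc1"), offspring = c("Th1", "DC"),
               kappa = c(0.4, 0.1), sigmaUm = c(5, 5),
               stringsAsFactors = FALSE)
  } else {
    data.frame(parent = c("Treg", "Treg"), offspring = c("Th17", "DC"),
               kappa = c(0.4, 0.15), sigmaUm = c(5, 5),
               stringsAsFactors = FALSE)
  }
  rates <- if (name %in% c("MSI", "MSI_LIKE")) {
    c(`TIM-3` = 0.30, `PD-1` = 0.35, `CTLA-4` = 0.25, GranzymeB = 0.25,
      Ki67 = 0.20, `HLA-DR` = 0.30, CD27 = 0.40, CD45RA = 0.30)
  } else {
    c(`TIM-3` = 0.12, `PD-1` = 0.15, `CTLA-4` = 0.10, GranzymeB = 0.15,
      Ki67 = 0.10, `HLA-DR` = 0.25, CD27 = 0.35, CD45RA = 0.30)
  }
  fr <- matrix(rep(rates, each = length(intens)), length(intens),
               dimnames = list(names(intens), names(rates)))
  fr[.nonImmunePops(), ] <- 0
  fr["Tumor", "Ki67"] <- 0.3
  simulationConfig(intensities = intens, geometryType = "disc",
                   discRadiusUm = 300, attractions = attr,
                   functionalRates = fr,
                   heterogeneitySdLog = 0.25, densitySdLog = 0.6)
}

## uniform points in the generation region (enlarged by `expand`)
.genPoints <- function(n, config, expand = 1.1) {
  if (config@geometryType == "disc") {
    r <- config@discRadiusUm * expand * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  } else {
    padW <- config@rectWidthUm * (expand - 1) / 2
    padH <- config@rectHeightUm * (expand - 1) / 2
    cbind(stats::runif(n, -padW, config@rectWidthUm + padW),
          stats::runif(n, -padH, config@rectHeightUm + padH))
  }
}

.genAreaMM2 <- function(config, expand = 1.1) {
  if (config@geometryType == "disc")
    pi * (config@discRadiusUm * expand)^2 / 1e6
  else
    (config@rectWidthUm * expand) * (config@rectHeightUm * expand) / 1e6
}

.insideGeometry <- function(xy, config) {
  if (config@geometryType == "disc")
    xy[, 1]^2 + xy[, 2]^2 <= config@discRadiusUm^2
  else
    xy[, 1] >= 0 & xy[, 1] <= config@rectWidthUm &
    xy[, 2] >= 0 & xy[, 2] <= config@rectHeightUm
}

.regionOf <- function(xy, config) {
  if (config@geometryType != "rect" || is.null(config@borderline))
    return(rep("UNASSIGNED", nrow(xy)))
  sd <- .polylineSignedDistance(xy[, 1], xy[, 2], config@borderline@vertices)
  tumorSign <- if (config@borderline@tumorSide == "left") 1 else -1
  signed <- ifelse(sign(sd$leftSide) == 0, 1,
                   tumorSign * sign(sd$leftSide)) * sd$dist
  w <- config@borderline@marginWidthUm
  ifelse(abs(signed) <= w, ifelse(signed >= 0, "IM_TUMOR", "IM_STROMA"),
         ifelse(signed > 0, "CT", "OUTSIDE"))
}

#' Generate one synthetic tissue sample
#'
#' Unattracted populations follow a homogeneous Poisson process at their
#' (jittered) planted intensity; for each attraction (A, B, kappa,
#' sigma), a fraction kappa of A cells each spawn one B offspring at a
#' Gaussian(sigma) displacement, and B's independent base intensity is
#' reduced by kappa times A's intensity (floored at zero) so that B's
#' total planted density is preserved. Planted nests are uniform discs
#' of extra cells. Positivity flags are generated consistently with the
#' default gating rules, so [assignPhenotypes()] recovers the true
#' subpopulations exactly; functional flags are Bernoulli draws at the
#' configured rates. For rectangular geometry with region factors,
#' densities are scaled per zone by thinning.
#'
#' @param config A [SimulationConfig-class].
#' @param seed Optional RNG seed; NULL continues the current stream.
#' @param sampleId Sample identifier stamped on every cell.
#' @return List with `table` (a [CellTable-class]) and `truth`: a
#'   data.frame row-per-cell (cell_id, true_subpopulation, true_nest,
#'   region, is_offspring) plus attributes `expectedFractions` (the
#'   realized per-sample expected T-subpopulation fractions, after
#'   heterogeneity jitter) and `functionalRates`.
#' @export
generateSample <- function(config, seed = NULL, sampleId = "sample1") {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  pops <- names(config@intensities)
  areaGen <- .genAreaMM2(config)
  immune <- setdiff(pops, .nonImmunePops())

  eff <- config@intensities
  if (config@densitySdLog > 0) {
    g <- stats::rlnorm(1, -config@densitySdLog^2 / 2, config@densitySdLog)
    eff[immune] <- eff[immune] * g
  }
  if (config@heterogeneitySdLog > 0) {
    h <- config@heterogeneitySdLog
    eff[immune] <- eff[immune] * stats::rlnorm(length(immune), -h^2 / 2, h)
  }

  at <- config@attractions
  base <- eff
  for (r in seq_len(nrow(at)))
    base[at$offspring[r]] <- max(base[at$offspring[r]] -
                                   at$kappa[r] * eff[at$parent[r]], 0)

  ## per-region thinning factors (rect geometry)
  rf <- config@regionFactors
  useRegions <- length(rf) > 0 && config@geometryType == "rect"
  maxF <- if (useRegions) apply(rf, 1L, max)[pops] else rep(1, length(pops))
  names(maxF) <- pops

  expTotal <- sum(base * maxF) * areaGen +
    sum(config@nests$count * config@nests$cellsPerNest)
  if (expTotal > 1e6)
    stop("resource guard: expected cell count exceeds 1e6")

  xy <- matrix(numeric(0), 0, 2)
  popLab <- character(0)
  nestLab <- integer(0)
  offspringFlag <- logical(0)

  addCells <- function(pts, pop, nest = NA_integer_, off = FALSE) {
    xy <<- rbind(xy, pts)
    popLab <<- c(popLab, rep(pop, nrow(pts)))
    nestLab <<- c(nestLab, rep(nest, nrow(pts)))
    offspringFlag <<- c(offspringFlag, rep(off, nrow(pts)))
  }

  thin <- function(pts, pop) {
    if (!useRegions || nrow(pts) == 0L) return(pts)
    reg <- .regionOf(pts, config)
    pKeep <- rf[pop, ][match(reg, colnames(rf))] / maxF[pop]
    pKeep[is.na(pKeep)] <- 1
    pts[stats::runif(nrow(pts)) < pKeep, , drop = FALSE]
  }

  basePoints <- list()
  for (pop in pops) {
    n <- stats::rpois(1, base[pop] * maxF[pop] * areaGen)
    pts <- thin(.genPoints(n, config), pop)
    basePoints[[pop]] <- pts
    addCells(pts, pop)
  }
  for (r in seq_len(nrow(at))) {
    parents <- basePoints[[at$parent[r]]]
    if (nrow(parents) == 0L) next
    sel <- stats::runif(nrow(parents)) < at$kappa[r]
    if (!any(sel)) next
    pts <- parents[sel, , drop = FALSE] +
      matrix(stats::rnorm(2 * sum(sel), 0, at$sigmaUm[r]), ncol = 2)
    addCells(thin(pts, at$offspring[r]), at$offspring[r], off = TRUE)
  }
  nextNest <- 1L
  for (r in seq_len(nrow(config@nests))) {
    nr <- config@nests$radiusUm[r]
    for (cc in seq_len(config@nests$count[r])) {
      center <- if (config@geometryType == "disc") {
        rr <- max(config@discRadiusUm - nr, 0) * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        c(rr * cos(th), rr * sin(th))
      } else {
        c(stats::runif(1, nr, max(config@rectWidthUm - nr, nr)),
          stats::runif(1, nr, max(config@rectHeightUm - nr, nr)))
      }
      m <- config@nests$cellsPerNest[r]
      rad <- nr * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      pts <- cbind(center[1] + rad * cos(th), center[2] + rad * sin(th))
      addCells(pts, config@nests$population[r], nest = nextNest)
      nextNest <- nextNest + 1L
    }
  }

  keep <- .insideGeometry(xy, config)
  xy <- xy[keep, , drop = FALSE]
  popLab <- popLab[keep]; nestLab <- nestLab[keep]
  offspringFlag <- offspringFlag[keep]
  n <- nrow(xy)

  panel <- defaultPanel()
  pos <- matrix(FALSE, n, length(panel), dimnames = list(NULL, panel))
  pm <- .populationMarkers()
  for (pop in unique(popLab)) {
    rows <- popLab == pop
    for (m in pm[[pop]]) pos[rows, m] <- TRUE
  }
  fr <- config@functionalRates
  for (pop in unique(popLab)) {
    rows <- which(popLab == pop)
    if (!(pop %in% rownames(fr))) next
    for (m in intersect(colnames(fr), panel)) {
      rate <- fr[pop, m]
      if (rate > 0) pos[rows, m] <- pos[rows, m] |
          stats::runif(length(rows)) < rate
    }
  }

  intensity <- NULL
  if (config@withIntensity) {
    intensity <- matrix(pmin(pmax(stats::rnorm(n * length(panel), 30, 15), 0),
                             255), n, length(panel),
                        dimnames = list(NULL, panel))
    hi <- pmin(pmax(stats::rnorm(sum(pos), 180, 30), 0), 255)
    intensity[pos] <- hi
  }

  areaMM2 <- if (config@geometryType == "disc")
    pi * config@discRadiusUm^2 / 1e6
  else config@rectWidthUm * config@rectHeightUm / 1e6
  cellId <- sprintf("%s_c%06d", sampleId, seq_len(n))
  region <- .regionOf(xy, config)
  table <- CellTable(cellId = cellId, sampleId = sampleId,
                     x = xy[, 1], y = xy[, 2], positivity = pos,
                     panel = panel, intensity = intensity,
                     areaMM2 = areaMM2,
                     geometry = if (config@geometryType == "rect")
                       config@borderline else NULL,
                     region = region)
  tLab <- intersect(names(eff), tSubpopulations())
  expT <- eff[tLab]
  truth <- data.frame(cell_id = cellId, true_subpopulation = popLab,
                      true_nest = nestLab, region = region,
                      is_offspring = offspringFlag,
                      stringsAsFactors = FALSE)
  attr(truth, "expectedFractions") <- 100 * expT / sum(expT)
  attr(truth, "functionalRates") <- fr
  list(table = table, truth = truth)
}

#' Generate a synthetic large section
#'
#' Rectangular geometry with a tumor-stroma borderline; per-region
#' densities are obtained by thinning against the configuration's
#' region factors (CT, IM_TUMOR, IM_STROMA, OUTSIDE). The true region of
#' every cell is recorded in the ground-truth sidecar.
#'
#' @inheritParams generateSample
#' @return As [generateSample()].
#' @export
generateLargeSection <- function(config, seed = NULL,
                                 sampleId = "section1") {
  stopifnot(is(config, "SimulationConfig"))
  if (config@geometryType != "rect" || is.null(config@borderline))
    stop("large-section generation needs rect geometry with a borderline")
  generateSample(config, seed = seed, sampleId = sampleId)
}

#' Generate a synthetic patient cohort
#'
#' Independent TMA-core samples from the MSI and MSS presets; a fraction
#' of the MSS arm (rounded to a whole number of patients, positions
#' drawn at random) is substituted with the MSI_LIKE configuration while
#' keeping the MSS group label, planting the MSI-like subgroup scenario.
#'
#' @param nMsi,nMss Arm sizes (>= 0).
#' @param fracMsiLike Fraction of the MSS arm substituted with MSI-like
#'   patients (default 0).
#' @param seed Optional RNG seed.
#' @return List: `tables` (named list of [CellTable-class]), `labels`
#'   (data.frame sample_id, group, msi_like_true), `truths` (named list
#'   of ground-truth sidecars).
#' @export
generateCohort <- function(nMsi, nMss, fracMsiLike = 0, seed = NULL) {
  stopifnot(nMsi >= 0, nMss >= 0, fracMsiLike >= 0, fracMsiLike <= 1)
  if (!is.null(seed)) set.seed(seed)
  cfgMsi <- preset("MSI"); cfgMss <- preset("MSS")
  cfgLike <- preset("MSI_LIKE")
  nLike <- round(fracMsiLike * nMss)
  likeIdx <- if (nLike > 0) sample.int(nMss, nLike) else integer(0)
  tables <- list(); truths <- list()
  ids <- character(0); grp <- character(0); likeFlag <- logical(0)
  for (i in seq_len(nMsi)) {
    sid <- sprintf("MSI_%03d", i)
    g <- generateSample(cfgMsi, sampleId = sid)
    tables[[sid]] <- g$table; truths[[sid]] <- g$truth
    ids <- c(ids, sid); grp <- c(grp, "MSI"); likeFlag <- c(likeFlag, FALSE)
  }
  for (i in seq_len(nMss)) {
    sid <- sprintf("MSS_%03d", i)
    isLike <- i %in% likeIdx
    g <- generateSample(if (isLike) cfgLike else cfgMss, sampleId = sid)
    tables[[sid]] <- g$table; truths[[sid]] <- g$truth
    ids <- c(ids, sid); grp <- c(grp, "MSS"); likeFlag <- c(likeFlag, isLike)
  }
  list(tables = tables,
       labels = data.frame(sample_id = ids,
                           group = factor(grp, levels = c("MSS", "MSI")),
                           msi_like_true = likeFlag,
                           stringsAsFactors = FALSE),
       truths = truths)
}
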