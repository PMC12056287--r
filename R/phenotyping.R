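.lineageLevels <- function() {
  c("CYTOTOXIC_T", "HELPER_T", "OTHER_T", "DC", "NK", "TUMOR",
    "ENDOTHELIAL", "OTHER")
}

.tLineages <- function() c("CYTOTOXIC_T", "HELPER_T", "OTHER_T")

## sanitize a subpopulation label for use as a column name
.san <- function(s) gsub("[^A-Za-z0-9]+", "_", s)

.makeRules <- function(label, lineage, pos, neg, priority) {
  data.frame(label = label, lineage = lineage, priority = priority,
             pos = I(pos), neg = I(neg), stringsAsFactors = FALSE)
}

#' Default gating taxonomy
#'
#' The marker-based decision list that assigns every cell to exactly one
#' subpopulation. T cells are CD3+; cytotoxic (Tc) cells are CD3+CD8+CD4-
#' and helper (Th) cells CD3+CD4+CD8-; within each, the sublineage is the
#' highest-priority positive subset transcription factor with priority
#' FOXP3 > T-bet > GATA3 > RORgt > BCL6 > CD56 (regulatory identity
#' dominates), else "-other". CD4+CD8+ double positives (and
#' double-negative CD3+ cells) fall into the OTHER_T lineage ("T-other"),
#' keeping the T-cell partition free of double counting. Non-T gates:
#' DC = CD3-CD11c+; NK = CD3-CD56+CD11c-; tumor = CD3-panCK+;
#' endothelium = CD3-CD31+. Rules are evaluated in priority order and
#' the first match wins; unmatched cells are "Other".
#'
#' @return data.frame with columns label, lineage, priority and
#'   list-columns pos / neg (required-positive / required-negative marker
#'   sets). Editable and re-loadable via [readGatingRules()].
#' @export
#' @examples
#' head(defaultGatingRules())
defaultGatingRules <- function() {
  if (is.null(.cache$rules)) .cache$rules <- .buildDefaultRules()
  .cache$rules
}

.cache <- new.env(parent = emptyenv())

.buildDefaultRules <- function() {
  subset <- c(Tcreg = "FOXP3", Tc1 = "T-bet", Tc2 = "GATA3",
              Tc17 = "RORgt", Tcf = "BCL6", `Tc-NKT` = "CD56")
  hsubset <- c(Treg = "FOXP3", Th1 = "T-bet", Th2 = "GATA3",
               Th17 = "RORgt", Tfh = "BCL6", `Th-NKT` = "CD56")
  rules <- list()
  pr <- 0L
  for (k in seq_along(subset)) {
    pr <- pr + 1L
    rules[[length(rules) + 1L]] <- .makeRules(
      names(subset)[k], "CYTOTOXIC_T",
      list(c("CD3", "CD8", subset[[k]])), list("CD4"), pr)
  }
  pr <- pr + 1L
  rules[[length(rules) + 1L]] <- .makeRules(
    "Tc-other", "CYTOTOXIC_T", list(c("CD3", "CD8")), list("CD4"), pr)
  for (k in seq_along(hsubset)) {
    pr <- pr + 1L
    rules[[length(rules) + 1L]] <- .makeRules(
      names(hsubset)[k], "HELPER_T",
      list(c("CD3", "CD4", hsubset[[k]])), list("CD8"), pr)
  }
  pr <- pr + 1L
  rules[[length(rules) + 1L]] <- .makeRules(
    "Th-other", "HELPER_T", list(c("CD3", "CD4")), list("CD8"), pr)
  rules[[length(rules) + 1L]] <- .makeRules(
    "T-other", "OTHER_T", list("CD3"), list(character(0)), pr + 1L)
  rules[[length(rules) + 1L]] <- .makeRules(
    "DC", "DC", list("CD11c"), list("CD3"), pr + 2L)
  rules[[length(rules) + 1L]] <- .makeRules(
    "NK", "NK", list("CD56"), list(c("CD3", "CD11c")), pr + 3L)
  rules[[length(rules) + 1L]] <- .makeRules(
    "Tumor", "TUMOR", list("panCK"), list("CD3"), pr + 4L)
  rules[[length(rules) + 1L]] <- .makeRules(
    "Endothelial", "ENDOTHELIAL", list("CD31"), list("CD3"), pr + 5L)
  out <- do.call(rbind, rules)
  rownames(out) <- NULL
  out
}

#' Read / write a gating rule set as tab-separated text
#'
#' One rule per line: `label<TAB>lineage<TAB>pos<TAB>neg<TAB>priority`,
#' where pos / neg are comma-separated marker lists (neg may be empty).
#' Rules are applied in ascending priority order, first match wins.
#'
#' @param path File path.
#' @return [readGatingRules()] returns a rule data.frame as described in
#'   [defaultGatingRules()]; [writeGatingRules()] returns `path`
#'   invisibly.
#' @export
#' @examples
#' p <- tempfile()
#' writeGatingRules(defaultGatingRules(), p)
#' identical(readGatingRules(p)$label, defaultGatingRules()$label)
readGatingRules <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("label", "lineage", "pos", "neg", "priority")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("gating rule file missing column(s): ",
         paste(sQuote(missing), collapse = ", "))
  splitMarkers <- function(s) {
    s <- trimws(strsplit(ifelse(is.na(s), "", s), ",", fixed = TRUE)[[1]])
    s[nzchar(s)]
  }
  data.frame(label = df$label, lineage = df$lineage,
             priority = as.integer(df$priority),
             pos = I(lapply(df$pos, splitMarkers)),
             neg = I(lapply(df$neg, splitMarkers)),
             stringsAsFactors = FALSE)
}

#' @rdname readGatingRules
#' @param rules A gating rule data.frame.
#' @export
writeGatingRules <- function(rules, path) {
  df <- data.frame(label = rules$label, lineage = rules$lineage,
                   pos = vapply(rules$pos, paste, "", collapse = ","),
                   neg = vapply(rules$neg, paste, "", collapse = ","),
                   priority = rules$priority, stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validateRules <- function(rules, panel) {
  if (anyDuplicated(rules$label)) stop("gating rule labels must be unique")
  for (k in seq_len(nrow(rules))) {
    pos <- rules$pos[[k]]; neg <- rules$neg[[k]]
    if (length(intersect(pos, neg)))
      stop("rule ", sQuote(rules$label[k]),
           ": required_pos and required_neg overlap")
    unknown <- setdiff(c(pos, neg), panel)
    if (length(unknown))
      stop("gating rule ", sQuote(rules$label[k]),
           " references marker(s) absent from the panel: ",
           paste(sQuote(unknown), collapse = ", "))
  }
  invisible(TRUE)
}

#' Subpopulation labels of the T-cell partition
#'
#' @param rules A gating rule set (see [defaultGatingRules()]).
#' @return Character vector of subpopulation labels whose lineage is a
#'   T-cell lineage; together these partition the CD3+ compartment.
#' @export
tSubpopulations <- function(rules = defaultGatingRules()) {
  rules$label[rules$lineage %in% .tLineages()]
}

#' Gate cells into lineages and subpopulations
#'
#' Applies a gating rule set (first match in priority order wins) to
#' every cell and copies the functional-state marker flags (TIM-3, PD-1,
#' CTLA-4, GranzymeB, Ki67, HLA-DR, CD27, CD45RA) onto the assignment.
#' Gating is deterministic and independent of cell order.
#'
#' @param table A [CellTable-class].
#' @param rules Gating rules as returned by [defaultGatingRules()].
#' @return data.frame with one row per cell: cell_id, sample_id, lineage
#'   (factor), subpopulation (factor; "Other" for unmatched cells) and
#'   one logical column per functional marker present in the panel.
#' @export
assignPhenotypes <- function(table, rules = defaultGatingRules()) {
  stopifnot(is(table, "CellTable"))
  .validateRules(rules, table@panel)
  n <- nCells(table)
  pos <- table@positivity
  ord <- order(rules$priority)
  subpop <- rep.int("Other", n)
  lineage <- rep.int("OTHER", n)
  unassigned <- rep.int(TRUE, n)
  for (k in ord) {
    need <- rules$pos[[k]]; forbid <- rules$neg[[k]]
    hit <- unassigned
    for (m in need) hit <- hit & pos[, m]
    for (m in forbid) hit <- hit & !pos[, m]
    if (any(hit)) {
      subpop[hit] <- rules$label[k]
      lineage[hit] <- rules$lineage[k]
      unassigned[hit] <- FALSE
    }
  }
  out <- data.frame(cell_id = table@cellId, sample_id = table@sampleId,
                    lineage = factor(lineage, levels = .lineageLevels()),
                    subpopulation = factor(
                      subpop, levels = c(rules$label[ord], "Other")),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (m in intersect(.functionalMarkers(), table@panel))
    out[[m]] <- pos[, m]
  out
}

#' Per-sample composition and density profile
#'
#' Subpopulation fractions are percentages of all CD3+ T cells (they sum
#' to 100 over the T-cell partition); densities are cells/mm^2 using, in
#' order of preference, the supplied area, the table's `areaMM2`, or the
#' convex-hull area of all cells. A sample with zero T cells has no
#' defined fractions and is flagged `excluded` (the zero-denominator
#' rule); its densities are still reported.
#'
#' @param table A [CellTable-class].
#' @param assignment Output of [assignPhenotypes()] for the same cells.
#' @param rules The gating rules defining the label set.
#' @param areaMM2 Optional area override in mm^2.
#' @return One-row data.frame: sample_id, n_cells, n_t_cells, area_mm2,
#'   t_density, `frac_<subpop>` (%, T-cell partition), `dens_<subpop>`
#'   (cells/mm^2, T subpopulations plus DC and NK), excluded.
#' @export
composition <- function(table, assignment, rules = defaultGatingRules(),
                        areaMM2 = NULL) {
  stopifnot(is(table, "CellTable"), nrow(assignment) == nCells(table))
  area <- if (!is.null(areaMM2)) areaMM2 else table@areaMM2
  if (is.na(area))
    area <- .convexHullAreaMM2(table@coords[, 1], table@coords[, 2])
  if (is.na(area) || area <= 0)
    stop("composition: no tissue area available (supply areaMM2, set it ",
         "on the table, or provide >= 3 cells for a convex hull)")
  tLabels <- tSubpopulations(rules)
  densLabels <- c(tLabels, intersect(c("DC", "NK"), rules$label))
  counts <- table(assignment$subpopulation)
  nT <- sum(counts[tLabels])
  frac <- if (nT > 0) 100 * as.numeric(counts[tLabels]) / nT
          else rep(NA_real_, length(tLabels))
  dens <- as.numeric(counts[densLabels]) / area
  out <- data.frame(sample_id = table@sampleId[1] %||% NA_character_,
                    n_cells = nCells(table), n_t_cells = as.integer(nT),
                    area_mm2 = area, t_density = nT / area,
                    stringsAsFactors = FALSE)
  for (k in seq_along(tLabels)) out[[paste0("frac_", .san(tLabels[k]))]] <- frac[k]
  for (k in seq_along(densLabels)) out[[paste0("dens_", .san(densLabels[k]))]] <- dens[k]
  out$excluded <- nT == 0
  out
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Functional-marker positive fractions per subpopulation
#'
#' Fraction (%) of marker-positive cells within each immune
#' subpopulation. Subpopulations with zero cells are flagged excluded
#' (no value) rather than producing NaN.
#'
#' @param assignment Output of [assignPhenotypes()].
#' @param markers Functional markers to tabulate (default: all carried on
#'   the assignment).
#' @param rules Gating rules defining the immune label set.
#' @return Long data.frame: subpopulation, marker, n, n_pos, fraction
#'   (%, NA when excluded), excluded.
#' @export
functionalFractions <- function(assignment,
                                markers = intersect(.functionalMarkers(),
                                                    names(assignment)),
                                rules = defaultGatingRules()) {
  unknown <- setdiff(markers, names(assignment))
  if (length(unknown))
    stop("unknown functional marker(s): ", paste(sQuote(unknown), collapse = ", "))
  labels <- c(tSubpopulations(rules), intersect(c("DC", "NK"), rules$label))
  res <- expand.grid(subpopulation = labels, marker = markers,
                     stringsAsFactors = FALSE)
  res$n <- 0L; res$n_pos <- 0L
  for (k in seq_len(nrow(res))) {
    inS <- assignment$subpopulation == res$subpopulation[k]
    res$n[k] <- sum(inS)
    res$n_pos[k] <- sum(assignment[[res$marker[k]]][inS])
  }
  res$excluded <- res$n == 0L
  res$fraction <- ifelse(res$excluded, NA_real_, 100 * res$n_pos / res$n)
  res[, c("subpopulation", "marker", "n", "n_pos", "fraction", "excluded")]
}

#' Stack per-sample profiles into a feature matrix
#'
#' @param profiles data.frame of stacked [composition()] rows (one per
#'   sample).
#' @param features Which column families to keep: fractions
#'   (`frac_*`), densities (`dens_*`), and/or total (`t_density`).
#' @return Numeric matrix samples x features with sample_id rownames;
#'   excluded samples carry NA fractions.
#' @export
profileMatrix <- function(profiles,
                          features = c("fractions", "densities", "total")) {
  features <- match.arg(features, several.ok = TRUE)
  cols <- character(0)
  if ("fractions" %in% features)
    cols <- c(cols, grep("^frac_", names(profiles), value = TRUE))
  if ("densities" %in% features)
    cols <- c(cols, grep("^dens_", names(profiles), value = TRUE))
  if ("total" %in% features) cols <- c(cols, "t_density")
  m <- as.matrix(profiles[, cols, drop = FALSE])
  rownames(m) <- profiles$sample_id
  m
}
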