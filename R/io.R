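#' Area of a circular TMA core
#'
#' Tissue microarray spots are punched discs; the density denominator for
#' a core of diameter d mm is pi * (d/2)^2.
#'
#' @param diameterMm Core diameter in millimeters (0.6 for the standard
#'   TMA format).
#' @return Area in mm^2.
#' @export
#' @examples
#' coreArea(0.6)  # 0.2827 mm^2
coreArea <- function(diameterMm) {
  if (!is.numeric(diameterMm) || any(!is.finite(diameterMm)) ||
      any(diameterMm <= 0))
    stop("core diameter must be a positive finite number")
  pi * (diameterMm / 2)^2
}

## Convex-hull area (mm^2) of a point set -- the default density
## denominator for large sections, where no tissue mask is available.
.convexHullAreaMM2 <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  # shoelace formula, um^2 -> mm^2
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2 / 1e6
}

.mandatoryColumns <- c("cell_id", "sample_id", "x_um", "y_um")

#' Read a tab-separated cell table
#'
#' Expects a UTF-8, tab-separated file with header columns `cell_id`,
#' `sample_id`, `x_um`, `y_um`, one 0/1 positivity column per panel
#' marker, and optionally one `<marker>_int` intensity column (0-255)
#' per marker. Row order is preserved.
#'
#' @param path File path.
#' @param panel Marker panel the positivity columns must cover; defaults
#'   to [defaultPanel()].
#' @param areaMM2,geometry Optional per-sample metadata attached to the
#'   returned table.
#' @return A [CellTable-class].
#' @export
readCellTable <- function(path, panel = defaultPanel(),
                          areaMM2 = NA_real_, geometry = NULL) {
  msg <- .validPanel(panel)
  if (!isTRUE(msg)) stop(msg)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", comment.char = "#")
  missing <- setdiff(c(.mandatoryColumns, panel), names(df))
  if (length(missing))
    stop("cell table format error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "))
  pos <- as.matrix(df[, panel, drop = FALSE])
  bad <- which(matrix(!(pos %in% c(0, 1)), nrow(pos)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-binary positivity value for marker ",
         sQuote(panel[bad[1, 2]]), " at row ", bad[1, 1])
  intCols <- paste0(panel, "_int")
  intensity <- NULL
  if (all(intCols %in% names(df))) {
    intensity <- as.matrix(df[, intCols, drop = FALSE])
    storage.mode(intensity) <- "double"
  } else if (any(intCols %in% names(df))) {
    stop("cell table format error: intensity columns present for only ",
         "part of the panel")
  }
  region <- if ("region" %in% names(df)) df$region else NULL
  CellTable(cellId = df$cell_id, sampleId = df$sample_id,
            x = df$x_um, y = df$y_um,
            positivity = pos == 1, panel = panel, intensity = intensity,
            areaMM2 = areaMM2, geometry = geometry, region = region)
}

#' Write a cell table to tab-separated text
#'
#' Emits the format read by [readCellTable()]: tab separation, UTF-8,
#' "." decimal, coordinates at full double precision so that a
#' write/read round trip is the identity up to print precision. Output is
#' byte-stable for a fixed input.
#'
#' @param table A [CellTable-class].
#' @param path Output file path.
#' @param writeRegion Emit the `region` column when any cell is zoned.
#' @return Invisibly, `path`.
#' @export
writeCellTable <- function(table, path, writeRegion = TRUE) {
  stopifnot(is(table, "CellTable"))
  validObject(table)
  df <- data.frame(cell_id = table@cellId, sampleId = table@sampleId,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[2] <- "sample_id"
  df$x_um <- format(table@coords[, 1], digits = 15, trim = TRUE,
                    scientific = FALSE)
  df$y_um <- format(table@coords[, 2], digits = 15, trim = TRUE,
                    scientific = FALSE)
  for (m in table@panel) df[[m]] <- as.integer(table@positivity[, m])
  if (nrow(table@intensity) > 0 || (nCells(table) == 0 && ncol(table@intensity) > 0))
    for (m in table@panel)
      df[[paste0(m, "_int")]] <- format(table@intensity[, m], digits = 15,
                                        trim = TRUE, scientific = FALSE)
  if (writeRegion && any(table@region != "UNASSIGNED"))
    df$region <- as.character(table@region)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read / write a tumor-stroma borderline file
#'
#' Plain-text geometry interchange: a one-line header
#' `tumor_side=<left|right>\tmargin_um=<w>` followed by a two-column
#' tab-separated vertex list (x_um, y_um).
#'
#' @param path File path.
#' @return [readRegionGeometry()] returns a [RegionGeometry-class];
#'   [writeRegionGeometry()] returns `path` invisibly.
#' @export
readRegionGeometry <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) stop("geometry file must contain a header and >= 2 vertices")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  side <- vals[match("tumor_side", keys)]
  width <- as.numeric(vals[match("margin_um", keys)])
  if (is.na(side)) stop("geometry header must declare tumor_side")
  body <- do.call(rbind, lapply(strsplit(lines[-1], "\t", fixed = TRUE),
                                function(p) as.numeric(p[1:2])))
  RegionGeometry(body, tumorSide = side,
                 marginWidthUm = if (is.na(width)) 360 else width)
}

#' @rdname readRegionGeometry
#' @param geometry A [RegionGeometry-class].
#' @export
writeRegionGeometry <- function(geometry, path) {
  stopifnot(is(geometry, "RegionGeometry"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("tumor_side=%s\tmargin_um=%s", geometry@tumorSide,
                     format(geometry@marginWidthUm, digits = 15)), con)
  writeLines(sprintf("%s\t%s",
                     format(geometry@vertices[, 1], digits = 15, trim = TRUE),
                     format(geometry@vertices[, 2], digits = 15, trim = TRUE)),
             con)
  invisible(path)
}

#' Threshold continuous marker intensities into positivity flags
#'
#' Convenience for synthetic or exported data carrying 0-255 intensities
#' without upstream positivity calls; real pipelines call markers
#' upstream and this utility is not part of the default gating path.
#'
#' @param intensity Numeric matrix in [0, 255].
#' @param cutoff Positivity threshold (inclusive above).
#' @return Logical matrix of the same shape.
#' @export
thresholdPositivity <- function(intensity, cutoff = 100) {
  if (any(intensity < 0 | intensity > 255, na.rm = TRUE))
    stop("intensities must lie within [0, 255]")
  intensity >= cutoff
}
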