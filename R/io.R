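#' Read a bivariate point set from delimited text
#'
#' Parses a CSV or TSV file with two numeric columns (x, y).  The
#' delimiter is auto-detected (comma or tab) unless given, and a header
#' line is auto-detected by attempting a numeric parse of the first row.
#' Rows containing non-numeric cells are dropped with a warning listing
#' their line numbers; fewer than 3 valid rows is an error.
#'
#' @param path Path to the file.
#' @param delimiter Optional delimiter character; \code{NULL} (default)
#'   auto-detects.
#' @return An n x 2 point matrix (see [as_points()]).
#' @export
read_points <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("file is empty")
  if (is.null(delimiter)) {
    has_tab <- grepl("\t", lines[1L], fixed = TRUE)
    has_comma <- grepl(",", lines[1L], fixed = TRUE)
    if (has_tab && has_comma)
      stop("mixed delimiters on the first line; pass `delimiter` explicitly")
    delimiter <- if (has_tab) "\t" else ","
  }
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  if (any(lengths(cells) < 2L))
    stop("every row must have at least two delimited columns",
         " (mixed delimiters? pass `delimiter` explicitly)")
  parse_row <- function(row)
    suppressWarnings(as.numeric(trimws(row[1:2])))
  vals <- t(vapply(cells, parse_row, numeric(2)))
  bad <- which(!is.finite(vals[, 1L]) | !is.finite(vals[, 2L]))
  start <- 1L
  if (length(bad) > 0L && bad[1L] == 1L) {
    ## non-numeric first row: a header
    start <- 2L
    bad <- bad[-1L]
  }
  if (length(bad) > 0L)
    warning(sprintf("dropped %d row(s) with non-numeric cells (lines: %s)",
                    length(bad), paste(bad, collapse = ", ")))
  keep <- setdiff(seq(start, length(lines)), bad)
  if (length(keep) < 3L)
    stop(sprintf("need at least 3 valid rows, found %d", length(keep)))
  as_points(vals[keep, , drop = FALSE])
}

#' Write a point set to CSV
#'
#' @param points A point set.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_points <- function(points, path) {
  points <- as_points(points)
  ## %.17g keeps doubles exact through the round-trip
  writeLines(c("x,y",
               sprintf("%.17g,%.17g", points[, 1L], points[, 2L])),
             path)
  invisible(path)
}

#' Write a convex region to CSV or WKT
#'
#' CSV output has columns \code{vertex_index}, \code{x}, \code{y} in the
#' region's canonical counter-clockwise vertex order; WKT output is a
#' single \code{POLYGON} with the first vertex repeated to close the
#' ring.
#'
#' @param region A \code{"convex_region"} with at least 3 vertices.
#' @param path Output path.
#' @param format \code{"csv"} (default) or \code{"wkt"}.
#' @return Invisibly, the path.
#' @export
write_region <- function(region, path, format = c("csv", "wkt")) {
  stopifnot(inherits(region, "convex_region"))
  format <- match.arg(format)
  v <- region$vertices
  if (is.null(v) || nrow(v) < 3L)
    stop("region is empty or degenerate; refusing to write")
  if (format == "csv") {
    writeLines(c("vertex_index,x,y",
                 sprintf("%d,%.17g,%.17g", seq_len(nrow(v)),
                         v[, 1L], v[, 2L])),
               path)
  } else {
    writeLines(region_wkt(region), path)
  }
  invisible(path)
}

#' WKT POLYGON representation of a convex region
#'
#' @param region A \code{"convex_region"}.
#' @param digits Significant digits for coordinates (default 15).
#' @return Single WKT \code{POLYGON} string (ring closed).
#' @export
region_wkt <- function(region, digits = 15L) {
  stopifnot(inherits(region, "convex_region"))
  v <- region$vertices
  if (is.null(v) || nrow(v) < 3L) stop("region is empty or degenerate")
  ring <- rbind(v, v[1L, , drop = FALSE])
  coords <- apply(ring, 1L, function(p)
    paste(format(p[1L], digits = digits), format(p[2L], digits = digits)))
  sprintf("POLYGON((%s))", paste(coords, collapse = ", "))
}

#' Read a convex region written by [write_region()] (CSV form)
#'
#' @param path Path to a vertex CSV with columns
#'   \code{vertex_index}, \code{x}, \code{y}.
#' @return A \code{"convex_region"} (polygon membership only; the
#'   half-plane representation is not reconstructed).
#' @export
read_region <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("vertex CSV must have columns x and y")
  verts <- canonical_vertices(cbind(df$x, df$y))
  new_convex_region(vertices = verts, method = "imported")
}
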