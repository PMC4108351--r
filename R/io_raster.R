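#' Read a raster layer from an ESRI ASCII grid
#'
#' Reads the plain-text ESRI ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`nodata_value` header followed by rows of values,
#' north row first). Values equal to the file's nodata marker become `NA`.
#' Kind-specific range checks are applied after reading, so e.g. an
#' exclusion layer containing 150 is rejected with the offending cell named.
#'
#' @param path Path to a `.asc` / `.txt` ESRI ASCII grid.
#' @param expected_kind The raster kind to validate against (see
#'   [raster_layer()]).
#' @param legend Optional legend for `landcover_class` layers.
#' @param crs_tag Coordinate-system tag to attach (the ASCII format does not
#'   carry one).
#' @return A [raster_layer()].
#' @export
read_raster <- function(path, expected_kind, legend = NULL,
                        crs_tag = "local-planar") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ESRI ASCII header missing ", paste(setdiff(need, names(hdr)),
         collapse = ", "), " in ", path, call. = FALSE)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " values, found ", length(vals), " in ", path,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  spec <- grid_spec(nr, nc, cell_size = hdr$cellsize,
                    origin_x = xll, origin_y = yll + nr * hdr$cellsize,
                    crs_tag = crs_tag)
  raster_layer(spec, m, kind = expected_kind, legend = legend)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param x A [raster_layer()].
#' @param path Output path.
#' @param nodata Value written for `NA` cells.
#' @param digits Significant digits for cell values; the default 17
#'   round-trips doubles exactly.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, nodata = -9999, digits = 17) {
  stopifnot(inherits(x, "raster_layer"))
  s <- x$spec
  hdr <- c(sprintf("ncols %d", s$ncols),
           sprintf("nrows %d", s$nrows),
           sprintf("xllcorner %.10g", s$origin_x),
           sprintf("yllcorner %.10g", s$origin_y - s$nrows * s$cell_size),
           sprintf("cellsize %.10g", s$cell_size),
           sprintf("nodata_value %.10g", nodata))
  m <- x$values
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
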