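#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' cell values, top row first. The format carries no coordinate reference
#' system, so the CRS is supplied by the caller (and recorded in workflow
#' manifests).
#'
#' @param path file path (`.asc`).
#' @param crs CRS label for the resulting [GridSpec-class] (`"local"` or
#'   `"eckert4"`).
#' @param name layer name for the resulting [RasterGrid-class].
#' @return `readAsciiGrid`: a [RasterGrid-class]. `writeAsciiGrid`: the path,
#'   invisibly.
#' @export
readAsciiGrid <- function(path, crs = "local", name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ASCII grid header, missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$nrows * hdr$ncols, call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  spec <- GridSpec(hdr$nrows, hdr$ncols, hdr$cellsize,
                   xmin = hdr$xllcorner,
                   ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                   crs = crs)
  if (is.null(name)) name <- sub("\\.asc$", "", basename(path))
  rasterGrid(m, spec, name = name)
}

#' @rdname readAsciiGrid
#' @param grid a [RasterGrid-class] to write.
#' @param digits significant digits written per cell.
#' @export
writeAsciiGrid <- function(grid, path, digits = 10) {
  spec <- grid@spec
  v <- grid@values
  v[is.na(v)] <- -9999
  hdr <- c(sprintf("ncols %d", spec@ncols),
           sprintf("nrows %d", spec@nrows),
           sprintf("xllcorner %.10g", spec@xmin),
           sprintf("yllcorner %.10g", spec@ymin),
           sprintf("cellsize %.10g", spec@cellSize),
           "NODATA_value -9999")
  body <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
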