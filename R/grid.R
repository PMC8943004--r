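#' ESRI ASCII grid rasters
#'
#' A minimal in-memory raster: header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) plus a numeric matrix in map orientation (row 1 =
#' northernmost row). Reads and writes the plain-text ESRI ASCII `.asc`
#' interchange format used for the biome, terrain and land/sea grids.
#'
#' @name ascii_grid
NULL

#' Construct an ascii_grid
#'
#' @param values numeric matrix, row 1 = north.
#' @param xllcorner,yllcorner lower-left corner of the grid, degrees.
#' @param cellsize cell size in degrees (square cells).
#' @param nodata NODATA code (default -9999).
#' @return object of class `ascii_grid`.
#' @export
ascii_grid <- function(values, xllcorner, yllcorner, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(
    ncols = ncol(values), nrows = nrow(values),
    xllcorner = xllcorner, yllcorner = yllcorner,
    cellsize = cellsize, nodata = nodata, values = values
  ), class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("ascii_grid: %d x %d cells, cellsize %g deg, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Accepts the standard header keys in any order and case; NODATA_value is
#' optional (default -9999).
#'
#' @param path file path.
#' @return an `ascii_grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(nodata_value = -9999)
  i <- 1
  while (grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("missing ESRI ASCII header fields: ", paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("grid body has ", length(vals), " values, expected ", hdr$ncols * hdr$nrows)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  ascii_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' @param grid an `ascii_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  hdr <- c(
    sprintf("ncols %d", grid$ncols), sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$xllcorner),
    sprintf("yllcorner %.10g", grid$yllcorner),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  body <- apply(vals, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Column/row index of the cell containing (lon, lat), half-open
# [west, east) x [south, north) convention: a point on a shared edge belongs
# to the cell to its east/north. Returns NA outside the extent.
.grid_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xllcorner) / grid$cellsize) + 1
  row_from_south <- floor((lat - grid$yllcorner) / grid$cellsize) + 1
  row <- grid$nrows - row_from_south + 1
  bad <- col < 1 | col > grid$ncols | row < 1 | row > grid$nrows
  col[bad] <- NA; row[bad] <- NA
  list(row = row, col = col)
}

#' Sample a raster at points
#'
#' Nearest-cell (containing-cell) lookup with the half-open edge convention;
#' points outside the extent or on NODATA return NA with a warning.
#'
#' @param grid an `ascii_grid`.
#' @param lon,lat point coordinates, degrees; vectorised.
#' @return numeric vector of cell values.
#' @export
sample_point <- function(grid, lon, lat) {
  ix <- .grid_index(grid, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(ix$row)
  out[ok] <- grid$values[cbind(ix$row[ok], ix$col[ok])]
  if (any(!ok)) warning(sum(!ok), " point(s) outside raster extent")
  out
}

#' Cell-centre coordinates of a grid
#'
#' @param grid an `ascii_grid`.
#' @return list of vectors `lon` (by column) and `lat` (by row, row 1 = north).
#' @export
grid_cell_centres <- function(grid) {
  lon <- grid$xllcorner + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  lat_south <- grid$yllcorner + (seq_len(grid$nrows) - 0.5) * grid$cellsize
  list(lon = lon, lat = rev(lat_south))
}

#' Zonal majority of a categorical raster within a box
#'
#' Counts cells whose centres fall in the axis-aligned box, weighting each
#' cell by its spherical area (proportional to cos of the centre latitude),
#' and returns the modal code with its area fraction. Ties break to the
#' lower code, flagged. Used to assign a biome to the 97.5% credible-interval
#' box of a geolocation position estimate.
#'
#' @param grid categorical `ascii_grid`.
#' @param lon_min,lon_max,lat_min,lat_max box bounds, degrees.
#' @param area_weighted cosine-latitude weighting (default TRUE); FALSE
#'   gives plain cell counts.
#' @return list with majority (code), fraction, tie (logical), and
#'   `fractions` (named vector of per-code area fractions summing to 1), or
#'   NULL-like list with majority NA if the box misses the raster.
#' @export
zonal_majority <- function(grid, lon_min, lon_max, lat_min, lat_max,
                           area_weighted = TRUE) {
  cc <- grid_cell_centres(grid)
  cols <- which(cc$lon >= lon_min & cc$lon <= lon_max)
  rows <- which(cc$lat >= lat_min & cc$lat <= lat_max)
  if (!length(cols) || !length(rows)) {
    return(list(majority = NA_real_, fraction = NA_real_, tie = FALSE,
                fractions = numeric(0)))
  }
  sub <- grid$values[rows, cols, drop = FALSE]
  w <- if (area_weighted) cos(.deg2rad(cc$lat[rows])) else rep(1, length(rows))
  wmat <- matrix(w, nrow = length(rows), ncol = length(cols))
  ok <- !is.na(sub)
  if (!any(ok)) {
    return(list(majority = NA_real_, fraction = NA_real_, tie = FALSE,
                fractions = numeric(0)))
  }
  tot <- tapply(wmat[ok], sub[ok], sum)
  fractions <- stats::setNames(as.numeric(tot / sum(tot)), names(tot))
  best <- max(fractions)
  winners <- names(fractions)[fractions >= best - 1e-12]
  majority <- min(as.numeric(winners))
  list(majority = majority, fraction = unname(fractions[as.character(majority)]),
       tie = length(winners) > 1,
       fractions = fractions[order(as.numeric(names(fractions)))])
}
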