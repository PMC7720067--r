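#' Gridded population raster
#'
#' A single-band, north-up, square-pixel population grid: per-pixel person
#' counts plus the affine information needed to map pixel indices to
#' geographic coordinates. This is the in-memory form of a high-resolution
#' settlement layer tile.
#'
#' @param values numeric matrix, row 1 = northernmost row; entries are
#'   persons per pixel, `NA` or `nodata` where unpopulated/unknown.
#' @param xll,yll coordinates of the lower-left corner of the grid (degrees).
#' @param cellsize pixel size in degrees.
#' @param crs coordinate reference system label (default WGS84).
#' @param nodata sentinel value marking missing pixels.
#' @return an object of class `population_grid`.
#' @export
population_grid <- function(values, xll, yll, cellsize,
                            crs = "EPSG:4326", nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (!is.numeric(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  v <- values
  v[v == nodata] <- NA_real_
  if (any(v[!is.na(v)] < 0)) stop("negative population values")
  structure(
    list(values = v, xll = xll, yll = yll, cellsize = cellsize,
         crs = crs, nodata = nodata),
    class = "population_grid"
  )
}

#' @export
print.population_grid <- function(x, ...) {
  cat("population_grid:", nrow(x$values), "x", ncol(x$values),
      "pixels @", x$cellsize, "deg (", x$crs, ")\n")
  cat("  populated pixels:", sum(!is.na(x$values) & x$values > 0),
      " total persons:", round(sum(x$values, na.rm = TRUE), 1), "\n")
  invisible(x)
}

# pixel centres under the north-up affine (0-based row/col from top-left)
pixel_center <- function(grid, row, col) {
  n_rows <- nrow(grid$values)
  list(
    lon = grid$xll + (col - 0.5) * grid$cellsize,
    lat = grid$yll + (n_rows - row + 0.5) * grid$cellsize
  )
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text `.asc` single-band raster format (header keys
#' ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value followed by the
#' value matrix, northernmost row first).
#'
#' @param path file path.
#' @return a [population_grid].
#' @export
read_asc_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path,
         " (need ncols, nrows, cellsize)")
  }
  if (is.null(hdr$xllcorner) || is.null(hdr$yllcorner)) {
    stop("missing georeference (xllcorner/yllcorner) in ", path)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("expected ", hdr$ncols * hdr$nrows, " values, got ", length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  population_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                  nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [population_grid].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_asc_grid <- function(grid, path) {
  stopifnot(inherits(grid, "population_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$xll, digits = 12)),
    paste("yllcorner", format(grid$yll, digits = 12)),
    paste("cellsize", format(grid$cellsize, digits = 12)),
    paste("NODATA_value", grid$nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract households from a population raster
#'
#' Treats every sufficiently populated pixel as one household: the household
#' sits at the pixel centre, its family size is the pixel's person count
#' rounded to the nearest integer (minimum 1), and under-5 children are
#' allocated across the village by the largest-remainder rule so the village
#' total matches the rounded `under5_fraction` share of the population.
#'
#' @param grid a [population_grid].
#' @param min_persons minimum pixel value for a pixel to count as a
#'   household (default 1).
#' @param under5_fraction fraction of the population under 5 (default 0.18).
#' @param name village label.
#' @return an [smc_village]; empty (with a warning) when no pixel qualifies.
#' @export
extract_households <- function(grid, min_persons = 1,
                               under5_fraction = 0.18, name = "raster") {
  stopifnot(inherits(grid, "population_grid"))
  if (!is.numeric(min_persons) || min_persons <= 0) {
    stop("min_persons must be > 0")
  }
  keep <- which(!is.na(grid$values) & grid$values >= min_persons,
                arr.ind = TRUE)
  if (nrow(keep) == 0) {
    warning("no pixel holds >= ", min_persons, " persons; empty village")
    hh <- data.frame(household_id = character(0), lon = numeric(0),
                     lat = numeric(0), family_size = integer(0),
                     n_under5 = integer(0), stringsAsFactors = FALSE)
    return(smc_village(name, hh))
  }
  # row-major order (top-left to bottom-right) for stable household ids
  keep <- keep[order(keep[, "row"], keep[, "col"]), , drop = FALSE]
  ctr <- pixel_center(grid, keep[, "row"], keep[, "col"])
  family_size <- pmax(1L, as.integer(round(grid$values[keep])))
  hh <- data.frame(
    household_id = sprintf("%s_%04d", name, seq_len(nrow(keep))),
    lon = ctr$lon,
    lat = ctr$lat,
    family_size = family_size,
    n_under5 = allocate_under5(family_size, under5_fraction),
    stringsAsFactors = FALSE
  )
  smc_village(name, hh)
}

#' Rasterize a village into a population grid
#'
#' Bins household family sizes into pixels of the given size over the
#' village's bounding box (plus a half-pixel margin). The inverse of
#' [extract_households()] up to pixel quantisation; used for round-trip
#' validation of the extraction step.
#'
#' @param village an [smc_village].
#' @param cellsize pixel size in degrees (default ~30 m).
#' @return a [population_grid].
#' @export
rasterize_village <- function(village, cellsize = 0.00027) {
  stopifnot(inherits(village, "smc_village"))
  hh <- village$households
  if (nrow(hh) == 0) stop("cannot rasterize an empty village")
  xll <- min(hh$lon) - cellsize / 2
  yll <- min(hh$lat) - cellsize / 2
  ncols <- ceiling((max(hh$lon) - xll) / cellsize) + 1
  nrows <- ceiling((max(hh$lat) - yll) / cellsize) + 1
  col <- pmin(floor((hh$lon - xll) / cellsize) + 1, ncols)
  row <- pmin(nrows - floor((hh$lat - yll) / cellsize), nrows)
  m <- matrix(NA_real_, nrow = nrows, ncol = ncols)
  for (i in seq_len(nrow(hh))) {
    cur <- m[row[i], col[i]]
    m[row[i], col[i]] <- if (is.na(cur)) hh$family_size[i] else
      cur + hh$family_size[i]
  }
  population_grid(m, xll, yll, cellsize)
}
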