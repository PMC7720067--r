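#' Village of households
#'
#' An `smc_village` holds one village's households: coordinates (WGS84
#' lon/lat, plus local km coordinates when available), family sizes and
#' numbers of under-5 children. It is the common input of the routing,
#' clustering and campaign-simulation steps.
#'
#' @param name village label.
#' @param households data.frame with columns `household_id`, `lon`, `lat`,
#'   `family_size`, `n_under5` (optionally `x_km`, `y_km`).
#' @return an object of class `smc_village`: a list with elements `name`,
#'   `households` and `total_children` (the eligible-population denominator
#'   N of the coverage formula).
#' @export
smc_village <- function(name, households) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.data.frame(households)) {
    stop("`households` must be a data.frame")
  }
  required <- c("household_id", "lon", "lat", "family_size", "n_under5")
  missing <- setdiff(required, names(households))
  if (length(missing)) {
    stop("households table lacks column(s): ", paste(missing, collapse = ", "))
  }
  households$household_id <- as.character(households$household_id)
  if (anyDuplicated(households$household_id)) {
    stop("duplicate household_id values")
  }
  if (nrow(households) > 0) {
    fs <- households$family_size
    u5 <- households$n_under5
    if (any(!is.finite(fs)) || any(fs < 1) || any(fs != round(fs))) {
      bad <- which(!is.finite(fs) | fs < 1 | fs != round(fs))[1]
      stop("family_size must be a positive integer (row ", bad, ")")
    }
    if (any(!is.finite(u5)) || any(u5 < 0) || any(u5 > fs) || any(u5 != round(u5))) {
      bad <- which(!is.finite(u5) | u5 < 0 | u5 > fs | u5 != round(u5))[1]
      stop("n_under5 must be an integer in [0, family_size] (row ", bad, ")")
    }
    if (any(!is.finite(households$lon)) || any(!is.finite(households$lat))) {
      stop("non-finite coordinates")
    }
  }
  rownames(households) <- NULL
  structure(
    list(
      name = name,
      households = households,
      total_children = as.integer(sum(households$n_under5))
    ),
    class = "smc_village"
  )
}

#' @export
print.smc_village <- function(x, ...) {
  cat("smc_village:", x$name, "\n")
  cat("  households:    ", nrow(x$households), "\n")
  cat("  population:    ", sum(x$households$family_size), "\n")
  cat("  under-5 (N):   ", x$total_children, "\n")
  invisible(x)
}

#' @export
length.smc_village <- function(x) nrow(x$households)

#' Allocate under-5 children to households by largest remainder
#'
#' Each household's expected under-5 count is `fraction * family_size`; these
#' are converted to integers so the village total equals
#' `round(fraction * sum(family_size))`: floors first, then one extra child
#' to the households with the largest fractional remainders (ties broken by
#' household order). Counts are capped at family size.
#'
#' @param family_size vector of positive integer family sizes.
#' @param fraction fraction of the population under 5 (default 0.18).
#' @return integer vector of under-5 counts, same length as `family_size`.
#' @export
allocate_under5 <- function(family_size, fraction = 0.18) {
  stopifnot(fraction > 0, fraction < 1)
  if (length(family_size) == 0L) return(integer(0))
  q <- fraction * family_size
  target <- round(sum(q))
  base <- floor(q)
  extra <- target - sum(base)
  if (extra > 0) {
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(pmin(base, family_size))
}

#' Read a household table into a village
#'
#' @param path CSV file (columns household_id, lon, lat, family_size,
#'   n_under5) or a GeoJSON FeatureCollection of Point features with those
#'   properties.
#' @param format `"csv"` or `"geojson"`; default inferred from the file
#'   extension.
#' @param name village label; defaults to the file base name.
#' @return an [smc_village].
#' @export
read_households <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv",
      geojson = , json = "geojson",
      stop("cannot infer format from extension '", ext, "'")
    )
  }
  format <- match.arg(format, c("csv", "geojson"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  hh <- switch(format,
    csv = read_households_csv(path),
    geojson = read_households_geojson(path)
  )
  smc_village(name, hh)
}

read_households_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("household_id", "lon", "lat", "family_size", "n_under5")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(df$family_size) | df$family_size < 1)
  if (length(bad)) {
    stop("non-positive or missing family_size at row ", bad[1])
  }
  df
}

read_households_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  feats <- gj$features
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (is.null(f$geometry) || f$geometry$type != "Point") {
      stop("feature ", i, " is not a Point")
    }
    p <- f$properties
    if (is.null(p$family_size) || p$family_size < 1) {
      stop("non-positive or missing family_size at feature ", i)
    }
    data.frame(
      household_id = as.character(p$household_id),
      lon = as.numeric(f$geometry$coordinates[[1]]),
      lat = as.numeric(f$geometry$coordinates[[2]]),
      family_size = as.integer(p$family_size),
      n_under5 = as.integer(if (is.null(p$n_under5)) 0L else p$n_under5),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a village to CSV or GeoJSON
#'
#' CSV columns are household_id, lon, lat, family_size, n_under5 (plus
#' x_km/y_km when present); GeoJSON is a FeatureCollection of Point features
#' with those attributes as properties.
#'
#' @param village an [smc_village].
#' @param path output file.
#' @param format `"csv"` or `"geojson"`; default inferred from extension.
#' @return `path`, invisibly.
#' @export
write_households <- function(village, path, format = NULL) {
  stopifnot(inherits(village, "smc_village"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", geojson = , json = "geojson",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  format <- match.arg(format, c("csv", "geojson"))
  hh <- village$households
  if (format == "csv") {
    utils::write.csv(hh, path, row.names = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(hh)), function(i) {
      list(
        type = "Feature",
        geometry = list(
          type = "Point",
          coordinates = c(hh$lon[i], hh$lat[i])
        ),
        properties = list(
          household_id = hh$household_id[i],
          family_size = hh$family_size[i],
          n_under5 = hh$n_under5[i]
        )
      )
    })
    gj <- list(type = "FeatureCollection",
               name = village$name,
               features = feats)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  }
  invisible(path)
}
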