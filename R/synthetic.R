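#' Specification of a synthetic village
#'
#' Describes a village to be generated by [generate_village()]: number of
#' households, spatial dispersion regime, footprint, family-size law and
#' under-5 fraction. The three dispersion regimes mirror the settlement
#' patterns seen in rural Burkina Faso villages: evenly spaced compounds
#' (`uniform`), irregular spacing (`random`) and settlement clumps separated
#' by barriers such as water streams (`clumped`).
#'
#' @param name village label.
#' @param n_households number of households (>= 1).
#' @param dispersion one of `"uniform"`, `"random"`, `"clumped"`.
#' @param n_clumps number of settlement clumps (used when `dispersion =
#'   "clumped"`; must be >= 2 there).
#' @param extent_km side of the square village footprint in km.
#' @param mean_family_size mean of the zero-truncated Poisson family-size
#'   law (persons per household).
#' @param under5_fraction fraction of the population under 5 years old,
#'   default 0.18.
#' @param seed integer seed; the same spec and seed always generate the same
#'   village.
#' @param origin_lon,origin_lat WGS84 anchor of the local km frame (the
#'   village's south-west corner); defaults are in the centre-west of
#'   Burkina Faso.
#' @return an object of class `village_spec`.
#' @export
village_spec <- function(name = "synthetic",
                         n_households,
                         dispersion = c("uniform", "random", "clumped"),
                         n_clumps = 3L,
                         extent_km = 2,
                         mean_family_size = 6,
                         under5_fraction = 0.18,
                         seed = 1L,
                         origin_lon = -2.19,
                         origin_lat = 12.68) {
  dispersion <- match.arg(dispersion)
  if (!is.numeric(n_households) || length(n_households) != 1L ||
      n_households < 1 || n_households != round(n_households)) {
    stop("invalid spec: n_households must be a positive integer")
  }
  if (!is.numeric(extent_km) || extent_km <= 0) {
    stop("invalid spec: extent_km must be > 0")
  }
  if (!is.numeric(under5_fraction) ||
      under5_fraction <= 0 || under5_fraction >= 1) {
    stop("invalid spec: under5_fraction must be in (0, 1)")
  }
  if (!is.numeric(mean_family_size) || mean_family_size <= 0) {
    stop("invalid spec: mean_family_size must be > 0")
  }
  if (dispersion == "clumped" &&
      (!is.numeric(n_clumps) || n_clumps < 2 || n_clumps != round(n_clumps))) {
    stop("invalid spec: n_clumps must be >= 2 when dispersion is clumped")
  }
  structure(
    list(
      name = name,
      n_households = as.integer(n_households),
      dispersion = dispersion,
      n_clumps = as.integer(n_clumps),
      extent_km = extent_km,
      mean_family_size = mean_family_size,
      under5_fraction = under5_fraction,
      seed = as.integer(seed),
      origin_lon = origin_lon,
      origin_lat = origin_lat
    ),
    class = "village_spec"
  )
}

#' @export
print.village_spec <- function(x, ...) {
  cat("village_spec:", x$name, "-", x$n_households, "households,",
      x$dispersion, "dispersion over", x$extent_km, "km\n")
  invisible(x)
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# zero-truncated Poisson by inverse CDF: exact, no rejection loop
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Generate a synthetic village
#'
#' Places `n_households` dwellings in a square footprint according to the
#' spec's dispersion regime:
#' * `uniform`: a jittered grid (near-even spacing);
#' * `random`: homogeneous (Poisson-like) placement;
#' * `clumped`: households drawn around `n_clumps` widely separated clump
#'   centres (Gaussian spread of 8% of the extent), emulating settlement
#'   groups split by a barrier.
#'
#' Family sizes are zero-truncated Poisson draws; under-5 counts follow the
#' village-wide largest-remainder allocation of [allocate_under5()], so the
#' village total equals the rounded `under5_fraction` share of the
#' population. Coordinates are produced in a local metric frame (km) and as
#' WGS84 lon/lat anchored at the spec's origin.
#'
#' @param spec a [village_spec].
#' @return an [smc_village] whose `households` table also carries `x_km` and
#'   `y_km` columns.
#' @export
generate_village <- function(spec) {
  stopifnot(inherits(spec, "village_spec"))
  n <- spec$n_households
  ext <- spec$extent_km
  with_seed(spec$seed, {
    xy <- switch(spec$dispersion,
      uniform = place_uniform(n, ext),
      random = matrix(stats::runif(2 * n, 0, ext), ncol = 2),
      clumped = place_clumped(n, ext, spec$n_clumps)
    )
    family_size <- rztpois(n, spec$mean_family_size)
    n_under5 <- allocate_under5(family_size, spec$under5_fraction)
    ll <- km_to_lonlat(xy[, 1], xy[, 2], spec$origin_lon, spec$origin_lat)
    hh <- data.frame(
      household_id = sprintf("%s_%04d", spec$name, seq_len(n)),
      lon = ll$lon,
      lat = ll$lat,
      x_km = xy[, 1],
      y_km = xy[, 2],
      family_size = as.integer(family_size),
      n_under5 = n_under5,
      stringsAsFactors = FALSE
    )
    smc_village(spec$name, hh)
  })
}

place_uniform <- function(n, ext) {
  side <- ceiling(sqrt(n))
  cell <- ext / side
  ij <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(n), ]
  jit <- matrix(stats::runif(2 * n, -0.15 * cell, 0.15 * cell), ncol = 2)
  cbind((ij$i - 0.5) * cell + jit[, 1],
        (ij$j - 0.5) * cell + jit[, 2])
}

place_clumped <- function(n, ext, k) {
  # clump centres on a ring of radius 0.35*extent: guaranteed far apart,
  # standing in for groups separated by rivers or other barriers
  ang <- 2 * pi * (seq_len(k) - 1) / k + stats::runif(1, 0, 2 * pi)
  cx <- ext / 2 + 0.35 * ext * cos(ang)
  cy <- ext / 2 + 0.35 * ext * sin(ang)
  assign_to <- sort(rep_len(seq_len(k), n))
  sd <- 0.08 * ext
  x <- pmin(pmax(stats::rnorm(n, cx[assign_to], sd), 0), ext)
  y <- pmin(pmax(stats::rnorm(n, cy[assign_to], sd), 0), ext)
  cbind(x, y)
}

# equirectangular anchor: km offsets from a lon/lat origin
EARTH_RADIUS_KM <- 6371.0088

km_to_lonlat <- function(x_km, y_km, origin_lon, origin_lat) {
  lat <- origin_lat + (y_km / EARTH_RADIUS_KM) * 180 / pi
  lon <- origin_lon +
    (x_km / (EARTH_RADIUS_KM * cos(origin_lat * pi / 180))) * 180 / pi
  list(lon = lon, lat = lat)
}
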