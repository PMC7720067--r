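#' @useDynLib smcplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# itinerary constructor: order is an id vector, dm the matrix it indexes
new_itinerary <- function(order, dm, exact) {
  n <- length(order)
  leg_km <- if (n >= 2) dm$d[cbind(order[-n], order[-1])] else numeric(0)
  structure(
    list(order = order, total_km = sum(leg_km), leg_km = unname(leg_km),
         exact = exact, metric = dm$metric),
    class = "smc_itinerary"
  )
}

#' @export
print.smc_itinerary <- function(x, ...) {
  cat("smc_itinerary:", length(x$order), "households,",
      sprintf("%.2f km", x$total_km),
      if (x$exact) "(exact)" else "(heuristic)", "\n")
  invisible(x)
}

# lexicographically smaller of a path and its reverse (equal length)
canonical_direction <- function(order) {
  rev_order <- rev(order)
  cmp <- which(order != rev_order)
  if (length(cmp) && rev_order[cmp[1]] < order[cmp[1]]) rev_order else order
}

#' Exact shortest open visit path (Held-Karp)
#'
#' Solves the open-path travelling salesman problem exactly by the
#' Held-Karp dynamic program over vertex subsets: the itinerary visits every
#' household exactly once, does not return to the start, and both endpoints
#' are free (the cost is minimised over all endpoint pairs). Exponential in
#' the number of households, so refused above `exact_limit`; use
#' [heuristic_path()] beyond that.
#'
#' @param dm an `smc_dist` from [build_distance_matrix()].
#' @param exact_limit largest instance solved exactly (default 15).
#' @return an `smc_itinerary` with `exact = TRUE`: the visit `order`,
#'   per-leg and total distance in km. Equal-cost ties resolve to the
#'   lexicographically smallest direction.
#' @export
held_karp_path <- function(dm, exact_limit = 15) {
  stopifnot(inherits(dm, "smc_dist"))
  n <- length(dm$labels)
  if (n == 1) {
    return(structure(list(order = dm$labels, total_km = 0,
                          leg_km = numeric(0), exact = TRUE,
                          metric = dm$metric),
                     class = "smc_itinerary"))
  }
  if (n > exact_limit) {
    stop("instance has ", n, " households, above the exact limit of ",
         exact_limit, "; use heuristic_path()")
  }
  sol <- held_karp_cpp(unname(dm$d))
  order <- canonical_direction(dm$labels[sol$order])
  new_itinerary(order, dm, exact = TRUE)
}

#' Heuristic open visit path (nearest neighbour + 2-opt)
#'
#' Multi-start nearest-neighbour construction followed by 2-opt segment
#' reversal to a local optimum, for instances too large for the exact
#' solver. Deterministic given `seed`. The result is never shorter than the
#' exact optimum and is typically within a few percent of it.
#'
#' @param dm an `smc_dist`.
#' @param seed integer seed controlling the choice of start households.
#' @param n_starts number of nearest-neighbour starts (default 10, capped
#'   at the number of households).
#' @return an `smc_itinerary` with `exact = FALSE`.
#' @export
heuristic_path <- function(dm, seed = 1L, n_starts = 10L) {
  stopifnot(inherits(dm, "smc_dist"))
  n <- length(dm$labels)
  if (n < 2) stop("need at least 2 households")
  d <- unname(dm$d)
  starts <- with_seed(seed, {
    if (n <= n_starts) seq_len(n) else sort(sample.int(n, n_starts))
  })
  best <- NULL
  best_cost <- Inf
  for (s in starts) {
    p <- nearest_neighbour_order(d, s)
    p <- two_opt(p, d)
    cost <- path_cost(p, d)
    if (cost < best_cost - 1e-12) {
      best <- p
      best_cost <- cost
    }
  }
  order <- canonical_direction(dm$labels[best])
  new_itinerary(order, dm, exact = FALSE)
}

path_cost <- function(p, d) {
  n <- length(p)
  if (n < 2) return(0)
  sum(d[cbind(p[-n], p[-1])])
}

nearest_neighbour_order <- function(d, start) {
  n <- nrow(d)
  visited <- logical(n)
  p <- integer(n)
  p[1] <- start
  visited[start] <- TRUE
  for (i in seq_len(n - 1)) {
    cand <- d[p[i], ]
    cand[visited] <- Inf
    p[i + 1] <- which.min(cand)  # ties: smallest index
    visited[p[i + 1]] <- TRUE
  }
  p
}

# first-improvement 2-opt for an OPEN path: reversing p[i..j] replaces the
# boundary edges (i-1,i) and (j,j+1); a missing boundary edge (path end)
# contributes zero.
two_opt <- function(p, d) {
  n <- length(p)
  if (n < 3) return(p)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      before <- if (i > 1) d[p[i - 1], p[i]] else 0
      for (j in seq(i + 1, n)) {
        after <- if (j < n) d[p[j], p[j + 1]] else 0
        new_before <- if (i > 1) d[p[i - 1], p[j]] else 0
        new_after <- if (j < n) d[p[i], p[j + 1]] else 0
        if (new_before + new_after < before + after - 1e-12) {
          p[i:j] <- p[j:i]
          improved <- TRUE
          before <- if (i > 1) d[p[i - 1], p[i]] else 0
        }
      }
    }
  }
  p
}

#' Write an itinerary as GeoJSON and/or CSV
#'
#' GeoJSON output is a LineString following the visit order; CSV lists
#' rank, household_id, leg_km (distance from the previous stop) and
#' cumulative_km.
#'
#' @param itinerary an `smc_itinerary`.
#' @param village the [smc_village] it routes (supplies coordinates).
#' @param path output file; format chosen by extension (`.geojson`/`.csv`).
#' @return `path`, invisibly.
#' @export
write_itinerary <- function(itinerary, village, path) {
  stopifnot(inherits(itinerary, "smc_itinerary"),
            inherits(village, "smc_village"))
  hh <- village$households
  idx <- match(itinerary$order, hh$household_id)
  if (anyNA(idx)) stop("itinerary references households absent from village")
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    leg <- c(0, itinerary$leg_km)
    utils::write.csv(data.frame(
      rank = seq_along(itinerary$order),
      household_id = itinerary$order,
      leg_km = round(leg, 6),
      cumulative_km = round(cumsum(leg), 6)
    ), path, row.names = FALSE)
  } else if (ext %in% c("geojson", "json")) {
    gj <- list(
      type = "FeatureCollection",
      features = list(list(
        type = "Feature",
        geometry = list(
          type = "LineString",
          coordinates = lapply(idx, function(i) c(hh$lon[i], hh$lat[i]))
        ),
        properties = list(
          village = village$name,
          total_km = itinerary$total_km,
          exact = itinerary$exact
        )
      ))
    )
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  } else {
    stop("unsupported itinerary format: ", ext)
  }
  invisible(path)
}
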