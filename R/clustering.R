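#' Minimum-size constrained assignment of points to centres
#'
#' The assignment step of constrained k-means: with centres fixed, minimise
#' `sum_i T[i,h] * 0.5 * ||x_i - C_h||^2` subject to every point belonging
#' to exactly one cluster and cluster `h` receiving at least `tau[h]`
#' points. The linear program has transportation structure, so its optimum
#' is integral; it is solved exactly as a min-cost transportation problem by
#' successive shortest augmenting paths. Points not needed to fill a quota
#' go to their nearest centre (ties to the lowest cluster index).
#'
#' @param points numeric matrix (m x d) of coordinates.
#' @param centers numeric matrix (k x d) of cluster centres.
#' @param tau integer vector of k minimum cluster sizes, `sum(tau) <= m`.
#' @return integer vector of length m of cluster labels in `1..k`, attaining
#'   the minimum constrained assignment cost.
#' @export
solve_assignment <- function(points, centers, tau) {
  points <- as.matrix(points)
  centers <- as.matrix(centers)
  m <- nrow(points)
  k <- nrow(centers)
  if (length(tau) != k) stop("tau must have one entry per cluster")
  if (any(tau < 0)) stop("tau must be non-negative")
  if (sum(tau) > m) {
    stop("infeasible: sum(tau) = ", sum(tau), " exceeds m = ", m)
  }
  # half squared Euclidean cost to each centre
  cost <- 0.5 * outer(rowSums(points^2), rep(1, k)) -
    points %*% t(centers) + 0.5 * outer(rep(1, m), rowSums(centers^2))
  cost <- pmax(cost, 0)

  # transportation columns: one quota column per cluster (capacity tau_h)
  # plus a free column (capacity m - sum(tau)) whose cost for point i is the
  # nearest-centre cost; free points map back to that nearest centre.
  nearest <- max.col(-cost, ties.method = "first")
  cc <- cbind(cost, cost[cbind(seq_len(m), nearest)])
  cap <- c(tau, m - sum(tau))
  ncol_t <- k + 1

  assign_col <- integer(m)        # 0 = not yet assigned
  col_count <- integer(ncol_t)
  rows_in <- vector("list", ncol_t)

  for (i in seq_len(m)) {
    # Bellman-Ford over column states in the residual graph: moving from
    # column j to j2 re-routes one of j's rows; its cheapest re-route is
    # min over rows r in j of cc[r, j2] - cc[r, j].
    dist <- cc[i, ]
    prev_col <- rep(0L, ncol_t)   # 0 = reached directly from row i
    prev_row <- rep(0L, ncol_t)
    for (iter in seq_len(ncol_t)) {
      changed <- FALSE
      for (j in seq_len(ncol_t)) {
        if (!is.finite(dist[j]) || col_count[j] == 0) next
        rows_j <- rows_in[[j]]
        delta <- cc[rows_j, , drop = FALSE] - cc[rows_j, j]
        best_r <- apply(delta, 2, which.min)
        best_d <- dist[j] + delta[cbind(best_r, seq_len(ncol_t))]
        improve <- best_d < dist - 1e-12
        if (any(improve)) {
          dist[improve] <- best_d[improve]
          prev_col[improve] <- j
          prev_row[improve] <- rows_j[best_r[improve]]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    open <- which(col_count < cap)
    target <- open[which.min(dist[open])]
    # backtrack: reassign rows along the augmenting path
    j <- target
    while (prev_col[j] != 0L) {
      r <- prev_row[j]
      jp <- prev_col[j]
      rows_in[[jp]] <- setdiff(rows_in[[jp]], r)
      rows_in[[j]] <- c(rows_in[[j]], r)
      assign_col[r] <- j
      col_count[j] <- col_count[j] + 1L
      col_count[jp] <- col_count[jp] - 1L
      j <- jp
    }
    assign_col[i] <- j
    rows_in[[j]] <- c(rows_in[[j]], i)
    col_count[j] <- col_count[j] + 1L
  }

  labels <- ifelse(assign_col == ncol_t, nearest, assign_col)
  as.integer(labels)
}

# objective of a hard assignment: sum of half squared distances to centres
assignment_objective <- function(points, centers, labels) {
  diff <- points - centers[labels, , drop = FALSE]
  0.5 * sum(diff^2)
}

# seeded k-means++ initial centres
kmeanspp_init <- function(points, k) {
  m <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1, ] <- points[sample.int(m, 1), ]
  if (k > 1) {
    for (h in 2:k) {
      d2 <- apply(points, 1, function(p) {
        min(colSums((t(centers[seq_len(h - 1), , drop = FALSE]) - p)^2))
      })
      if (sum(d2) <= 0) {
        centers[h, ] <- points[sample.int(m, 1), ]
      } else {
        centers[h, ] <- points[sample.int(m, 1, prob = d2), ]
      }
    }
  }
  centers
}

#' Constrained k-means clustering of a village
#'
#' Partitions households into `k` clusters, each of at least `tau[h]`
#' households, by alternating (1) the exact minimum-cost constrained
#' assignment of [solve_assignment()] with centres fixed and (2) the
#' centroid update (a cluster that ends up empty keeps its centre). Both
#' steps weakly decrease the objective `sum_i 0.5 * ||x_i - C_{h(i)}||^2`,
#' so the iteration converges to a local optimum; it stops when no centre
#' moves by more than `tol` or after `max_iter` iterations. With all
#' `tau = 0` this is exactly Lloyd's k-means. Used to split hard-to-reach
#' villages (settlement groups separated by rivers or other barriers) into
#' separately routed catchments.
#'
#' @param village an [smc_village].
#' @param k number of clusters, `1 <= k <=` number of households.
#' @param tau minimum cluster sizes; a single value is recycled. Default
#'   `floor(0.8 * m / k)` — clusters of roughly equal size.
#' @param seed seed for the k-means++ initialisation.
#' @param max_iter,tol iteration cap and centre-displacement tolerance (km).
#' @return an `smc_cluster_plan`: cluster labels per household, centres,
#'   minimum sizes, final objective and iteration count.
#' @export
constrained_kmeans <- function(village, k, tau = NULL, seed = 1L,
                               max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(village, "smc_village"))
  m <- nrow(village$households)
  if (!is.numeric(k) || k < 1 || k != round(k)) {
    stop("k must be a positive integer")
  }
  if (k > m) stop("k = ", k, " exceeds the number of households ", m)
  if (is.null(tau)) tau <- floor(0.8 * m / k)
  if (length(tau) == 1L) tau <- rep(tau, k)
  if (length(tau) != k) stop("tau must have length 1 or k")
  if (sum(tau) > m) stop("infeasible: sum(tau) > number of households")
  points <- village_coords_km(village)

  with_seed(seed, {
    centers <- kmeanspp_init(points, k)
    labels <- NULL
    obj_trace <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      labels <- solve_assignment(points, centers, tau)
      obj_trace <- c(obj_trace, assignment_objective(points, centers, labels))
      new_centers <- centers
      for (h in seq_len(k)) {
        members <- labels == h
        if (any(members)) {
          new_centers[h, ] <- colMeans(points[members, , drop = FALSE])
        }
      }
      shift <- max(sqrt(rowSums((new_centers - centers)^2)))
      centers <- new_centers
      if (shift < tol || iter >= max_iter) break
    }
    final_obj <- assignment_objective(points, centers, labels)
    structure(
      list(
        k = as.integer(k),
        centers = centers,
        assignment = stats::setNames(labels, village$households$household_id),
        tau = as.integer(tau),
        objective = final_obj,
        objective_trace = obj_trace,
        n_iterations = iter,
        village = village$name
      ),
      class = "smc_cluster_plan"
    )
  })
}

#' @export
print.smc_cluster_plan <- function(x, ...) {
  cat("smc_cluster_plan:", x$village, "-", x$k, "clusters, sizes",
      paste(tabulate(x$assignment, x$k), collapse = "/"),
      sprintf("(objective %.4f, %d iterations)\n", x$objective,
              x$n_iterations))
  invisible(x)
}

# household coordinates in a local km frame (uses x_km/y_km when present)
village_coords_km <- function(village) {
  hh <- village$households
  if (all(c("x_km", "y_km") %in% names(hh))) {
    return(cbind(x = hh$x_km, y = hh$y_km))
  }
  lat0 <- mean(hh$lat) * pi / 180
  cbind(x = EARTH_RADIUS_KM * cos(lat0) * hh$lon * pi / 180,
        y = EARTH_RADIUS_KM * hh$lat * pi / 180)
}

#' Split a village along a cluster plan
#'
#' @param village an [smc_village].
#' @param plan an `smc_cluster_plan` for that village.
#' @return list of k [smc_village] objects named `<village>_<cluster>`.
#' @export
split_village <- function(village, plan) {
  stopifnot(inherits(village, "smc_village"),
            inherits(plan, "smc_cluster_plan"))
  labels <- plan$assignment[village$households$household_id]
  if (anyNA(labels)) stop("cluster plan does not cover this village")
  lapply(seq_len(plan$k), function(h) {
    smc_village(paste0(village$name, "_", LETTERS[h]),
                village$households[labels == h, , drop = FALSE])
  })
}

#' Write a cluster plan as GeoJSON or CSV
#'
#' GeoJSON holds the households as Points with a `cluster` property plus the
#' centres as Points with `role = "center"`; CSV lists household_id and
#' cluster.
#'
#' @param plan an `smc_cluster_plan`.
#' @param village the clustered [smc_village].
#' @param path output file (`.geojson` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_cluster_plan <- function(plan, village, path) {
  stopifnot(inherits(plan, "smc_cluster_plan"))
  hh <- village$households
  labels <- plan$assignment[hh$household_id]
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(data.frame(household_id = hh$household_id,
                                cluster = unname(labels)),
                     path, row.names = FALSE)
  } else if (ext %in% c("geojson", "json")) {
    pts <- lapply(seq_len(nrow(hh)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(hh$lon[i], hh$lat[i])),
           properties = list(household_id = hh$household_id[i],
                             cluster = unname(labels[i])))
    })
    # centres live in the local km frame; report them back in lon/lat when
    # the village carries the km frame anchored at its own origin
    gj <- list(type = "FeatureCollection", features = pts)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  } else {
    stop("unsupported cluster-plan format: ", ext)
  }
  invisible(path)
}
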