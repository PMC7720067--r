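# shared fixtures and independent oracles, all built in code

EARTH_R <- 6371.0088

# village from local km coordinates, anchored near the equator so the
# package's equirectangular frame reproduces the km geometry exactly
village_from_km <- function(x_km, y_km, n_under5 = NULL, family_size = NULL,
                            name = "fixture") {
  n <- length(x_km)
  if (is.null(family_size)) family_size <- rep(5L, n)
  if (is.null(n_under5)) n_under5 <- rep(1L, n)
  smc_village(name, data.frame(
    household_id = sprintf("h%02d", seq_len(n)),
    lon = (x_km / EARTH_R) * 180 / pi,
    lat = (y_km / EARTH_R) * 180 / pi,
    family_size = as.integer(family_size),
    n_under5 = as.integer(n_under5),
    stringsAsFactors = FALSE
  ))
}

# all permutations of 1..n (cached); oracle for exact routing
.perm_cache <- new.env()
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v),
                          function(i) cbind(v[i], rec(v[-i]))))
  }
  .perm_cache[[key]] <- rec(seq_len(n))
  .perm_cache[[key]]
}

# brute-force optimal open-path cost over all orderings
brute_force_path_cost <- function(d) {
  n <- nrow(d)
  p <- all_perms(n)
  costs <- matrix(d[cbind(as.vector(p[, -n]), as.vector(p[, -1]))],
                  nrow = nrow(p))
  min(rowSums(costs))
}

# brute-force optimal closed-tour cost
brute_force_cycle_cost <- function(d) {
  n <- nrow(d)
  p <- all_perms(n)
  p2 <- cbind(p, p[, 1])
  costs <- matrix(d[cbind(as.vector(p2[, -(n + 1)]), as.vector(p2[, -1]))],
                  nrow = nrow(p))
  min(rowSums(costs))
}

# brute-force constrained assignment: minimum cost over all label vectors
# with cluster sizes >= tau, cost = sum of half squared distances
brute_force_assignment_cost <- function(points, centers, tau) {
  m <- nrow(points)
  k <- nrow(centers)
  labels <- rep(1L, m)
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    sizes <- tabulate(lab, k)
    if (any(sizes < tau)) next
    diff <- points - centers[lab, , drop = FALSE]
    cost <- 0.5 * sum(diff^2)
    if (cost < best) best <- cost
  }
  best
}

random_village <- function(n, seed, extent = 2) {
  generate_village(village_spec(paste0("rv", seed), n, "random",
                                extent_km = extent, seed = seed))
}

assignment_cost <- function(points, centers, labels) {
  diff <- points - centers[labels, , drop = FALSE]
  0.5 * sum(diff^2)
}
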