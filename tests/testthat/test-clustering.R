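test_that("unconstrained assignment sends each point to its nearest centre", {
  set.seed(1)
  pts <- matrix(runif(40), ncol = 2)
  ctr <- matrix(c(0.2, 0.2, 0.8, 0.8), 2, 2, byrow = TRUE)
  lab <- solve_assignment(pts, ctr, tau = c(0, 0))
  d1 <- rowSums((pts - matrix(ctr[1, ], 20, 2, byrow = TRUE))^2)
  d2 <- rowSums((pts - matrix(ctr[2, ], 20, 2, byrow = TRUE))^2)
  expect_equal(lab, ifelse(d1 <= d2, 1L, 2L))
})

test_that("a binding quota moves the cheapest point", {
  # both points nearer centre 1; tau forces one to centre 2, and the LP
  # moves the one with the smaller reassignment penalty
  pts <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  ctr <- matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE)
  lab <- solve_assignment(pts, ctr, tau = c(1, 1))
  expect_equal(lab, c(1L, 2L))  # moving point 2 costs less
})

test_that("assignment cost equals brute-force enumeration", {
  for (seed in 1:20) {
    set.seed(4000 + seed)
    m <- 5 + seed %% 4          # 5..8 points
    pts <- matrix(runif(2 * m), ncol = 2)
    ctr <- matrix(runif(4), 2, 2)
    tau <- c(2, 2)
    lab <- solve_assignment(pts, ctr, tau)
    expect_true(all(tabulate(lab, 2) >= tau))
    expect_equal(assignment_cost(pts, ctr, lab),
                 brute_force_assignment_cost(pts, ctr, tau),
                 tolerance = 1e-9)
  }
})

test_that("assignment matches an independent linear-program solution", {
  set.seed(77)
  m <- 12; k <- 3
  pts <- matrix(runif(2 * m), ncol = 2)
  ctr <- matrix(runif(2 * k), ncol = 2)
  tau <- c(2, 3, 4)
  lab <- solve_assignment(pts, ctr, tau)
  cost <- sapply(seq_len(k), function(h)
    0.5 * rowSums((pts - matrix(ctr[h, ], m, 2, byrow = TRUE))^2))
  script <- paste(
    "import sys, json",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "d = json.load(sys.stdin)",
    "c = np.array(d['cost']).reshape(d['m'], d['k'])",
    "m, k = d['m'], d['k']",
    "A_eq = np.zeros((m, m * k)); b_eq = np.ones(m)",
    "for i in range(m): A_eq[i, i * k:(i + 1) * k] = 1",
    "A_ub = np.zeros((k, m * k)); b_ub = -np.array(d['tau'], float)",
    "for h in range(k):",
    "    for i in range(m): A_ub[h, i * k + h] = -1",
    "r = linprog(c.ravel(), A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,",
    "            bounds=(0, None))",
    "print(r.fun)",
    sep = "\n")
  lp_out <- system2("python", c("-c", shQuote(script)),
                    input = jsonlite::toJSON(
                      list(cost = as.vector(t(cost)), m = m, k = k,
                           tau = tau),
                      auto_unbox = TRUE, digits = NA),
                    stdout = TRUE)
  lp_cost <- as.numeric(tail(lp_out, 1))
  expect_equal(assignment_cost(pts, ctr, lab), lp_cost, tolerance = 1e-6)
})

test_that("infeasible quotas and bad k are rejected", {
  v <- random_village(5, seed = 2)
  expect_error(constrained_kmeans(v, k = 2, tau = c(3, 3)), "nfeasible")
  expect_error(constrained_kmeans(v, k = 0), "positive integer")
  expect_error(constrained_kmeans(v, k = 6), "exceeds")
})

test_that("k = 1 gives the coordinate mean and the closed-form objective", {
  v <- random_village(12, seed = 3)
  plan <- constrained_kmeans(v, k = 1, tau = 0)
  pts <- cbind(v$households$x_km, v$households$y_km)
  expect_equal(as.vector(plan$centers), colMeans(pts), tolerance = 1e-9)
  expect_equal(plan$objective,
               0.5 * sum(sweep(pts, 2, colMeans(pts))^2), tolerance = 1e-9)
})

test_that("well-separated triplets are recovered as clusters", {
  v <- village_from_km(c(0, 0.1, 0.05, 10, 10.1, 10.05),
                       c(0, 0.05, 0.1, 5, 5.05, 5.1))
  plan <- constrained_kmeans(v, k = 2, tau = c(3, 3), seed = 1)
  lab <- unname(plan$assignment)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[2], lab[3])
  expect_equal(lab[4], lab[5])
  expect_false(lab[1] == lab[4])
})

test_that("objective is non-increasing and quotas hold at every iteration", {
  for (seed in c(1, 7, 19)) {
    v <- generate_village(village_spec("c", 60, "clumped", n_clumps = 3,
                                       seed = seed))
    plan <- constrained_kmeans(v, k = 3, tau = 15, seed = seed)
    expect_true(all(diff(plan$objective_trace) <= 1e-9))
    expect_true(all(tabulate(plan$assignment, 3) >= 15))
    expect_lte(plan$n_iterations, 100)
  }
})

test_that("with tau = 0 the iteration matches Lloyd's k-means", {
  v <- random_village(40, seed = 31)
  pts <- cbind(v$households$x_km, v$households$y_km)
  plan <- constrained_kmeans(v, k = 3, tau = 0, seed = 5, tol = 1e-10)
  # Lloyd from the same converged centres must not improve the objective
  km <- stats::kmeans(pts, centers = plan$centers, algorithm = "Lloyd",
                      iter.max = 100)
  expect_equal(0.5 * km$tot.withinss, plan$objective, tolerance = 1e-6)
  expect_equal(unname(plan$assignment), unname(km$cluster))
})

test_that("constrained solution equals exhaustive partition search", {
  for (seed in 1:5) {
    v <- random_village(7, seed = 5000 + seed)
    plan <- constrained_kmeans(v, k = 2, tau = c(2, 2), seed = seed)
    pts <- cbind(v$households$x_km, v$households$y_km)
    # with the final centres fixed, the assignment must be optimal over all
    # label vectors meeting the quotas
    expect_equal(assignment_cost(pts, plan$centers,
                                 unname(plan$assignment)),
                 brute_force_assignment_cost(pts, plan$centers, c(2, 2)),
                 tolerance = 1e-9)
  }
})

test_that("split_village partitions households by cluster", {
  v <- generate_village(village_spec("s", 30, "clumped", n_clumps = 2,
                                     seed = 12))
  plan <- constrained_kmeans(v, k = 2, tau = 10, seed = 1)
  parts <- split_village(v, plan)
  expect_length(parts, 2)
  expect_equal(sum(sapply(parts, function(p) nrow(p$households))), 30)
  expect_equal(sum(sapply(parts, function(p) p$total_children)),
               v$total_children)
})
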