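cfg_current <- campaign_config(treatment_model = "current_fixed")
cfg_optimal <- campaign_config(treatment_model = "optimal_fixed")

test_that("fixed treatment models give the published per-child durations", {
  expect_equal(treatment_minutes(1, cfg_current), 12.5)
  expect_equal(treatment_minutes(3, cfg_optimal), 25.5)
  expect_equal(treatment_minutes(0, cfg_current), 0)
  expect_equal(treatment_minutes(c(1, 2, 4), cfg_optimal),
               c(8.5, 17, 34))
})

test_that("stochastic draws respect the per-bracket ranges and means", {
  cfg <- campaign_config(treatment_model = "optimal_draws", seed = 2)
  set.seed(2)
  d1 <- treatment_minutes(rep(1, 2000), cfg)
  d2 <- treatment_minutes(rep(2, 2000), cfg)
  d3 <- treatment_minutes(rep(3, 10000), cfg)
  expect_true(all(d1 >= 10 & d1 <= 15))
  expect_true(all(d2 >= 15 & d2 <= 20))
  expect_true(all(d3 >= 20 & d3 <= 25))
  expect_gt(mean(d3), 22.3)
  expect_lt(mean(d3), 22.7)
  # beyond 3 children: 8.5 min per extra child on top of the 3-child draw
  d5 <- treatment_minutes(rep(5, 1000), cfg)
  expect_true(all(d5 >= 20 + 17 & d5 <= 25 + 17))
})

test_that("time conversions reproduce the published day counts", {
  expect_equal(round(km_to_days(20, cfg_current), 2), 0.83)
  expect_equal(round(km_to_days(31, cfg_current), 2), 1.29)
  expect_equal(km_to_days(0, cfg_current), 0)
  expect_error(km_to_days(-1, cfg_current), "non-negative")
  expect_equal(round(children_to_treatment_days(121, 12.5, cfg_current), 2),
               3.15)
  expect_equal(round(children_to_treatment_days(324, 8.5, cfg_optimal), 2),
               5.74)
  expect_equal(children_to_treatment_days(0, config = cfg_optimal), 0)
})

test_that("unmet-needs formula scales time into CHWs", {
  expect_equal(unmet_needs(2, 2, cfg_optimal), 2)       # t = T: one pair
  expect_equal(round(unmet_needs(5.74, 1.29, cfg_optimal), 1), 3.5)
  expect_equal(round(unmet_needs(2.58, 1.16, cfg_optimal), 2), 1.87)
  expect_error(unmet_needs(-1, 0, cfg_optimal), "non-negative")
})

test_that("coverage formula and bounds", {
  expect_equal(round(coverage_from_counts(121, 324), 1), 37.3)
  expect_equal(round(coverage_from_counts(189, 324), 1), 58.3)
  expect_equal(coverage_from_counts(0, 50), 0)
  expect_error(coverage_from_counts(1, 0), "total")
  expect_error(coverage_from_counts(5, 4), "treated")
})

test_that("ample budget treats everyone along the full itinerary", {
  v <- random_village(10, seed = 17)
  it <- held_karp_path(build_distance_matrix(v))
  cfg <- campaign_config(chw_pairs = 1, campaign_days = 1000,
                         treatment_model = "optimal_fixed")
  res <- simulate_campaign(v, it, cfg)
  expect_equal(res$coverage_pct, 100)
  expect_equal(res$treated_children, v$total_children)
  expect_equal(res$walking_km, it$total_km)
  expect_equal(res$visited_households, 10)
})

test_that("a hand-computed budget cuts the walk mid-itinerary", {
  # 4 households on a line, 1 km legs, 1 child each, 8.5 min/child:
  # budget = 2 treatments + 1 km of walking => exactly 2 households visited
  v <- village_from_km(c(0, 1, 2, 3), rep(0, 4))
  it <- held_karp_path(build_distance_matrix(v))
  budget_days <- (2 * 8.5 + 20) / 480
  cfg <- campaign_config(chw_pairs = 1, campaign_days = budget_days,
                         treatment_model = "optimal_fixed")
  res <- simulate_campaign(v, it, cfg)
  expect_equal(res$visited_households, 2)
  expect_equal(res$treated_children, 2L)
  expect_equal(res$coverage_pct, 50)
  expect_equal(res$walking_km, 1)
})

test_that("zero (negligible) budget visits nothing", {
  v <- village_from_km(c(0, 1), c(0, 0))
  it <- held_karp_path(build_distance_matrix(v))
  cfg <- campaign_config(chw_pairs = 1e-9, campaign_days = 1e-9,
                         treatment_model = "optimal_fixed")
  res <- simulate_campaign(v, it, cfg)
  expect_equal(res$visited_households, 0)
  expect_equal(res$coverage_pct, 0)
})

test_that("time spent never exceeds budget plus the skipped household", {
  v <- random_village(20, seed = 23)
  it <- heuristic_path(build_distance_matrix(v), seed = 1)
  for (days in c(0.05, 0.1, 0.3)) {
    cfg <- campaign_config(chw_pairs = 1, campaign_days = days,
                           treatment_model = "optimal_fixed")
    res <- simulate_campaign(v, it, cfg)
    spent <- res$treatment_days + res$travel_days
    expect_lte(spent, res$budget_days + 1e-9)
    expect_gte(res$coverage_pct, 0)
    expect_lte(res$coverage_pct, 100)
  }
})

test_that("coverage is monotone in the budget parameters", {
  v <- random_village(15, seed = 29)
  it <- held_karp_path(build_distance_matrix(v))
  cov <- function(pairs = 1, days = 0.5, minpc = 8.5, pace = 20) {
    cfg <- campaign_config(chw_pairs = pairs, campaign_days = days,
                           walk_min_per_km = pace,
                           treatment_model = "optimal_fixed",
                           fixed_min_per_child = minpc)
    simulate_campaign(v, it, cfg)$coverage_pct
  }
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4), function(p)
    cov(pairs = p))) >= 0))
  expect_true(all(diff(sapply(c(0.2, 0.5, 1, 2), function(d)
    cov(days = d))) >= 0))
  expect_true(all(diff(sapply(c(8.5, 12.5, 20), function(m)
    cov(minpc = m))) <= 0))
  expect_true(all(diff(sapply(c(10, 20, 40), function(w)
    cov(pace = w))) <= 0))
})

test_that("staffing at the unmet-needs level reaches full coverage", {
  for (seed in c(3, 11)) {
    v <- random_village(25, seed = seed)
    it <- heuristic_path(build_distance_matrix(v), seed = 1)
    cfg1 <- campaign_config(chw_pairs = 1, treatment_model = "optimal_fixed")
    need <- simulate_campaign(v, it, cfg1)$unmet_chws
    cfg2 <- campaign_config(chw_pairs = need / 2,
                            treatment_model = "optimal_fixed")
    expect_gte(simulate_campaign(v, it, cfg2)$coverage_pct, 99)
  }
})

test_that("campaigns with stochastic draws are reproducible by seed", {
  v <- random_village(12, seed = 41)
  it <- held_karp_path(build_distance_matrix(v))
  cfg <- campaign_config(treatment_model = "optimal_draws", seed = 8)
  expect_identical(simulate_campaign(v, it, cfg),
                   simulate_campaign(v, it, cfg))
})

test_that("chi-square scenario comparison reproduces published contrasts", {
  hh <- compare_scenarios(87, 242, 136, 242,
                          labels = c("current", "microplan_a"))
  expect_equal(hh$chi2, 19.15, tolerance = 0.01)
  expect_lt(hh$p_value, 0.001)
  ch <- compare_scenarios(121, 324, 189, 324)
  expect_equal(ch$chi2, 27.76, tolerance = 0.01)
  expect_lt(ch$p_value, 0.001)
  # identical proportions: the corrected statistic vanishes
  expect_equal(compare_scenarios(50, 100, 50, 100)$chi2, 0)
  # uncorrected option differs (and is larger here)
  expect_gt(compare_scenarios(87, 242, 136, 242, correct = FALSE)$chi2,
            19.9)
  expect_error(compare_scenarios(1, 0, 1, 2), "positive")
})

test_that("t-based confidence interval matches the closed form", {
  ci <- mean_t_ci(c(1, 2, 3))
  expect_equal(unname(ci["mean"]), 2)
  expect_equal(unname(ci["upper"] - ci["mean"]), 2.484138, tolerance = 1e-5)
  expect_equal(unname(ci["mean"] - ci["lower"]),
               unname(ci["upper"] - ci["mean"]))
  const <- mean_t_ci(rep(4, 5))
  expect_equal(unname(const["lower"]), 4)
  expect_equal(unname(const["upper"]), 4)
  expect_error(mean_t_ci(1), "at least 2")
})
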