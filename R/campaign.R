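#' Campaign configuration
#'
#' Parameters of a door-to-door SMC delivery round by community health
#' worker (CHW) pairs. One pair of CHWs is the serving unit: a budget of
#' `chw_pairs * campaign_days` workdays is available, each workday lasting
#' `workday_hours` hours. Walking converts to time at `walk_min_per_km`
#' (wet-season default 20 min/km). Treatment time per household follows one
#' of three models:
#' * `current_fixed` — 12.5 min per child, the average observed under the
#'   current unplanned deployment mode;
#' * `optimal_fixed` — 8.5 min per child, the optimised duration (25 min
#'   for a 3-child household / 3);
#' * `optimal_draws` — stochastic: U(10,15) min for a 1-child household,
#'   U(15,20) for 2 children, U(20,25) for 3, plus 8.5 min per child beyond
#'   the third.
#'
#' @param chw_pairs number of CHW pairs (fractional values scale the time
#'   budget linearly).
#' @param campaign_days campaign duration in days (default 4).
#' @param workday_hours working hours per day (default 8).
#' @param walk_min_per_km walking pace in minutes per km (default 20).
#' @param treatment_model one of `"current_fixed"`, `"optimal_draws"`,
#'   `"optimal_fixed"`.
#' @param fixed_min_per_child per-child minutes for the fixed models;
#'   defaults to 12.5 under `current_fixed` and 8.5 otherwise.
#' @param seed seed for the stochastic treatment draws.
#' @return an object of class `campaign_config`.
#' @export
campaign_config <- function(chw_pairs = 1,
                            campaign_days = 4,
                            workday_hours = 8,
                            walk_min_per_km = 20,
                            treatment_model = c("optimal_fixed",
                                                "current_fixed",
                                                "optimal_draws"),
                            fixed_min_per_child = NULL,
                            seed = 1L) {
  treatment_model <- match.arg(treatment_model)
  if (is.null(fixed_min_per_child)) {
    fixed_min_per_child <- if (treatment_model == "current_fixed") 12.5
                           else 8.5
  }
  vals <- c(chw_pairs = chw_pairs, campaign_days = campaign_days,
            workday_hours = workday_hours, walk_min_per_km = walk_min_per_km,
            fixed_min_per_child = fixed_min_per_child)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad)) stop("config values must be positive: ",
                        paste(bad, collapse = ", "))
  structure(
    list(chw_pairs = chw_pairs, campaign_days = campaign_days,
         workday_hours = workday_hours, walk_min_per_km = walk_min_per_km,
         treatment_model = treatment_model,
         fixed_min_per_child = fixed_min_per_child, seed = as.integer(seed)),
    class = "campaign_config"
  )
}

#' @export
print.campaign_config <- function(x, ...) {
  cat(sprintf(
    "campaign_config: %.3g CHW pair(s), %g days x %g h, %g min/km, %s\n",
    x$chw_pairs, x$campaign_days, x$workday_hours, x$walk_min_per_km,
    x$treatment_model))
  invisible(x)
}

#' Treatment duration for one household
#'
#' Minutes a CHW pair spends treating a household's under-5 children, under
#' the config's treatment model. Households with no eligible child take
#' zero minutes (they are still walked past). Stochastic draws use the
#' current RNG state; seed it (or use [simulate_campaign()], which seeds
#' from the config) for reproducibility.
#'
#' @param n_under5 number of under-5 children (vectorised).
#' @param config a [campaign_config].
#' @return treatment duration(s) in minutes.
#' @export
treatment_minutes <- function(n_under5, config) {
  stopifnot(inherits(config, "campaign_config"))
  n <- as.integer(n_under5)
  if (any(n < 0)) stop("n_under5 must be non-negative")
  out <- numeric(length(n))
  if (config$treatment_model %in% c("current_fixed", "optimal_fixed")) {
    out <- config$fixed_min_per_child * n
  } else {
    pos <- which(n > 0)
    for (i in pos) {
      out[i] <- switch(min(n[i], 3L),
        stats::runif(1, 10, 15),
        stats::runif(1, 15, 20),
        stats::runif(1, 20, 25) + 8.5 * (n[i] - 3L)
      )
    }
  }
  out
}

#' Convert walking distance to workdays
#'
#' `km * walk_min_per_km / (workday_hours * 60)`: e.g. 20 km at 20 min/km
#' with 8-hour days is 0.83 days.
#'
#' @param km distance in km (vectorised).
#' @param config a [campaign_config].
#' @return travel time in workdays.
#' @export
km_to_days <- function(km, config) {
  stopifnot(inherits(config, "campaign_config"))
  if (any(km < 0)) stop("km must be non-negative")
  km * config$walk_min_per_km / (config$workday_hours * 60)
}

#' Convert a child count to treatment workdays
#'
#' `n_children * min_per_child / (workday_hours * 60)`: e.g. 121 children
#' at 12.5 min each with 8-hour days is 3.15 days.
#'
#' @param n_children number of children treated.
#' @param min_per_child per-child treatment minutes; defaults to the
#'   config's `fixed_min_per_child`.
#' @param config a [campaign_config].
#' @return treatment time in workdays.
#' @export
children_to_treatment_days <- function(n_children, min_per_child = NULL,
                                       config = campaign_config()) {
  stopifnot(inherits(config, "campaign_config"))
  if (any(n_children < 0)) stop("n_children must be non-negative")
  if (is.null(min_per_child)) min_per_child <- config$fixed_min_per_child
  n_children * min_per_child / (config$workday_hours * 60)
}

#' Unmet CHW needs to reach full coverage
#'
#' Total CHWs required to complete treatment and travel within the campaign
#' window: `(t / T) * 2`, with `t` the total time invested (treatment +
#' travel, days), `T` the campaign duration and 2 the CHWs per pair.
#'
#' @param treatment_days,travel_days time components in workdays.
#' @param config a [campaign_config] supplying `campaign_days`.
#' @return total number of CHWs needed (possibly fractional).
#' @export
unmet_needs <- function(treatment_days, travel_days,
                        config = campaign_config()) {
  stopifnot(inherits(config, "campaign_config"))
  if (config$campaign_days <= 0) stop("campaign_days must be > 0")
  if (any(treatment_days < 0) || any(travel_days < 0)) {
    stop("time components must be non-negative")
  }
  (treatment_days + travel_days) / config$campaign_days * 2
}

#' Coverage from treated and total child counts
#'
#' `100 * treated / total`: the percentage of eligible under-5 children
#' reached during the round.
#'
#' @param treated number of children treated.
#' @param total total eligible children (> 0).
#' @return coverage percentage.
#' @export
coverage_from_counts <- function(treated, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(treated < 0) || any(treated > total)) {
    stop("treated must lie in [0, total]")
  }
  100 * treated / total
}

#' Simulate a door-to-door campaign along an itinerary
#'
#' Walks the itinerary household by household against a time budget of
#' `chw_pairs * campaign_days` workdays. A household is visited only if the
#' leg to reach it plus its full treatment fits the remaining budget
#' (treatment is all-or-nothing — SMC doses cannot be split); the walk
#' stops at the first household that does not fit. Households with no
#' under-5 children cost walking time only.
#'
#' The result also reports the full-village time ledger (every household,
#' whole itinerary) and the unmet CHW needs derived from it, i.e. the total
#' workforce that would reach 100% coverage within the window.
#'
#' @param village an [smc_village].
#' @param itinerary an `smc_itinerary` covering the village.
#' @param config a [campaign_config].
#' @return an `smc_campaign_result` with visited/treated counts, time
#'   components, walking km, coverage percentage and unmet CHW needs.
#' @export
simulate_campaign <- function(village, itinerary, config) {
  stopifnot(inherits(village, "smc_village"),
            inherits(itinerary, "smc_itinerary"),
            inherits(config, "campaign_config"))
  hh <- village$households
  if (nrow(hh) == 0) stop("empty village")
  idx <- match(itinerary$order, hh$household_id)
  if (anyNA(idx) || length(idx) != nrow(hh)) {
    stop("itinerary does not cover the village")
  }
  n <- length(idx)
  u5 <- hh$n_under5[idx]
  treat_min <- with_seed(config$seed, treatment_minutes(u5, config))
  treat_days <- treat_min / (config$workday_hours * 60)
  leg_days <- c(0, km_to_days(itinerary$leg_km, config))
  leg_km <- c(0, itinerary$leg_km)

  budget <- config$chw_pairs * config$campaign_days
  remaining <- budget
  visited <- 0L
  for (i in seq_len(n)) {
    cost_i <- leg_days[i] + treat_days[i]
    if (cost_i <= remaining + 1e-12) {
      remaining <- remaining - cost_i
      visited <- i
    } else {
      break
    }
  }
  vis <- seq_len(visited)
  treated <- sum(u5[vis])
  total <- village$total_children
  structure(
    list(
      village = village$name,
      visited_households = visited,
      total_households = n,
      treated_children = as.integer(treated),
      total_children = total,
      treatment_days = sum(treat_days[vis]),
      travel_days = sum(leg_days[vis]),
      walking_km = sum(leg_km[vis]),
      coverage_pct = if (total > 0)
        min(100, coverage_from_counts(treated, total)) else 0,
      full_treatment_days = sum(treat_days),
      full_travel_days = sum(leg_days),
      full_walking_km = itinerary$total_km,
      unmet_chws = unmet_needs(sum(treat_days), sum(leg_days), config),
      budget_days = budget,
      config = config
    ),
    class = "smc_campaign_result"
  )
}

#' @export
print.smc_campaign_result <- function(x, ...) {
  cat("smc_campaign_result:", x$village, "\n")
  cat(sprintf("  visited %d/%d households, treated %d/%d children (%.1f%%)\n",
              x$visited_households, x$total_households,
              x$treated_children, x$total_children, x$coverage_pct))
  cat(sprintf("  treatment %.2f d + travel %.2f d (%.2f km) of %.2f d budget\n",
              x$treatment_days, x$travel_days, x$walking_km, x$budget_days))
  cat(sprintf("  CHWs needed for 100%%: %.2f\n", x$unmet_chws))
  invisible(x)
}

#' Chi-square comparison of two deployment scenarios
#'
#' Compares success proportions (treated children, or visited households)
#' between two scenarios with the 2x2 chi-square test, Yates-corrected by
#' default — the correction matters at these sample sizes and is the form
#' under which the published village contrasts reproduce.
#'
#' @param a_success,a_total counts for scenario A.
#' @param b_success,b_total counts for scenario B.
#' @param labels length-2 character vector naming the scenarios.
#' @param correct apply Yates continuity correction (default TRUE).
#' @return an `smc_comparison`: the 2x2 table, chi-square statistic and
#'   p-value (1 df).
#' @export
compare_scenarios <- function(a_success, a_total, b_success, b_total,
                              labels = c("A", "B"), correct = TRUE) {
  if (a_total <= 0 || b_total <= 0) stop("totals must be positive")
  if (a_success < 0 || a_success > a_total ||
      b_success < 0 || b_success > b_total) {
    stop("successes must lie in [0, total]")
  }
  tab <- matrix(c(a_success, a_total - a_success,
                  b_success, b_total - b_success),
                nrow = 2, byrow = TRUE,
                dimnames = list(labels, c("success", "failure")))
  if (any(colSums(tab) == 0)) {
    # degenerate table (e.g. both scenarios at 100%): no association
    chi2 <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    chi2 <- unname(ct$statistic)
    p <- ct$p.value
  }
  structure(
    list(label_a = labels[1], label_b = labels[2], counts = tab,
         chi2 = chi2, p_value = p,
         corrected = correct),
    class = "smc_comparison"
  )
}

#' @export
print.smc_comparison <- function(x, ...) {
  cat(sprintf("smc_comparison: %s (%d/%d) vs %s (%d/%d)\n",
              x$label_a, x$counts[1, 1], sum(x$counts[1, ]),
              x$label_b, x$counts[2, 1], sum(x$counts[2, ])))
  cat(sprintf("  chi2 = %.2f%s, p = %.3g\n", x$chi2,
              if (x$corrected) " (Yates)" else "", x$p_value))
  invisible(x)
}

#' t-distribution confidence interval for a mean
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` — used for uncertainty
#' around per-day optima such as children treated per day or km walked per
#' day.
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric vector `(mean, lower, upper)`.
#' @export
mean_t_ci <- function(values, level = 0.95) {
  if (length(values) < 2) stop("need at least 2 values")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, length(values) - 1) *
    stats::sd(values) / sqrt(length(values))
  c(mean = m, lower = m - half, upper = m + half)
}
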