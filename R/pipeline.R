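#' Run the end-to-end microplanning pipeline
#'
#' Ingests or generates a village, optionally subdivides it with
#' constrained k-means, routes each (sub)village, simulates the requested
#' deployment scenarios and writes a deployment report, pairwise
#' scenario comparisons and GeoJSON map layers.
#'
#' Scenarios:
#' * `current` — the unplanned deployment mode: a seeded random visit order
#'   emulating an un-mapped door-to-door walk (an emulation of, not a claim
#'   about, real CHW behaviour), 12.5 min per child;
#' * `microplan_a` — optimised itinerary and treatment duration (8.5
#'   min/child), workforce unchanged (1 CHW pair);
#' * `microplan_b` — as A, with the number of CHW pairs raised to the
#'   unmet-needs level so the whole village fits the campaign window.
#'
#' The config is a YAML file or an equivalent nested list:
#' ```yaml
#' seed: 1
#' village:
#'   synthetic: {name: demo, n_households: 40, dispersion: random}
#'   # or: csv: path.csv | geojson: path.geojson | asc: path.asc
#' clustering: {k: 3}            # optional
#' campaign: {campaign_days: 4, workday_hours: 8, walk_min_per_km: 20}
#' scenarios: [current, microplan_a, microplan_b]
#' exact_limit: 13
#' ```
#'
#' @param config path to a YAML config or a list with the fields above.
#' @param out_dir output directory (created if needed); `NULL` writes no
#'   files and only returns the results.
#' @return invisibly, a list with `report` (one row per village x
#'   scenario), `comparisons` (pairwise statistics), `results` (the
#'   `smc_campaign_result` objects) and `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  seed <- as.integer(cfg$seed %||% 1L)
  scenarios <- unlist(cfg$scenarios %||% list("current", "microplan_a"))
  bad <- setdiff(scenarios, c("current", "microplan_a", "microplan_b"))
  if (length(bad)) stop("config field 'scenarios': unknown scenario(s) ",
                        paste(bad, collapse = ", "))
  exact_limit <- cfg$exact_limit %||% 13L

  village <- load_pipeline_village(cfg, seed)
  message("pipeline: village '", village$name, "' with ",
          nrow(village$households), " households, seed ", seed)

  villages <- list(village)
  plan <- NULL
  if (!is.null(cfg$clustering)) {
    cl <- cfg$clustering
    plan <- constrained_kmeans(village, k = cl$k,
                               tau = cl$tau %||% NULL,
                               seed = seed)
    villages <- split_village(village, plan)
    message("pipeline: split into ", plan$k, " clusters (sizes ",
            paste(tabulate(plan$assignment, plan$k), collapse = "/"), ")")
  }

  camp <- cfg$campaign %||% list()
  base_config <- function(model, pairs, seed_offset = 0L) {
    campaign_config(
      chw_pairs = pairs,
      campaign_days = camp$campaign_days %||% 4,
      workday_hours = camp$workday_hours %||% 8,
      walk_min_per_km = camp$walk_min_per_km %||% 20,
      treatment_model = model,
      seed = seed + seed_offset
    )
  }

  results <- list()
  rows <- list()
  layers <- list()
  for (v in villages) {
    dm <- build_distance_matrix(v)
    n <- nrow(v$households)
    optimized <- if (n == 1) held_karp_path(dm)
                 else if (n <= exact_limit) held_karp_path(dm, exact_limit)
                 else heuristic_path(dm, seed = seed)
    for (sc in scenarios) {
      res <- run_scenario(v, dm, optimized, sc, base_config, seed)
      key <- paste(v$name, sc, sep = ":")
      results[[key]] <- res
      rows[[key]] <- report_row(v$name, sc, res)
      layers[[key]] <- attr(res, "itinerary")
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  comparisons <- pipeline_comparisons(results, villages, scenarios)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    if (nrow(comparisons)) {
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    write_households(village, file.path(out_dir, "village.geojson"))
    if (!is.null(plan)) {
      write_cluster_plan(plan, village, file.path(out_dir,
                                                  "clusters.geojson"))
    }
    for (v in villages) {
      for (sc in scenarios) {
        key <- paste(v$name, sc, sep = ":")
        write_itinerary(layers[[key]], v,
                        file.path(out_dir, paste0("itinerary_", v$name,
                                                  "_", sc, ".geojson")))
      }
    }
    jsonlite::write_json(
      list(seed = seed, scenarios = as.list(scenarios),
           village = village$name,
           n_households = nrow(village$households),
           total_children = village$total_children,
           report = report),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = 10, dataframe = "rows"
    )
    message("pipeline: wrote report for ", nrow(report), " scenario runs to ",
            out_dir)
  }
  invisible(list(report = report, comparisons = comparisons,
                 results = results, cluster_plan = plan, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_pipeline_village <- function(cfg, seed) {
  vc <- cfg$village
  if (is.null(vc)) stop("config field 'village' is required")
  if (!is.null(vc$synthetic)) {
    s <- vc$synthetic
    spec <- village_spec(
      name = s$name %||% "synthetic",
      n_households = s$n_households,
      dispersion = s$dispersion %||% "random",
      n_clumps = s$n_clumps %||% 3L,
      extent_km = s$extent_km %||% 2,
      mean_family_size = s$mean_family_size %||% 6,
      under5_fraction = s$under5_fraction %||% 0.18,
      seed = s$seed %||% seed
    )
    generate_village(spec)
  } else if (!is.null(vc$csv)) {
    read_households(vc$csv, "csv")
  } else if (!is.null(vc$geojson)) {
    read_households(vc$geojson, "geojson")
  } else if (!is.null(vc$asc)) {
    extract_households(read_asc_grid(vc$asc),
                       min_persons = vc$min_persons %||% 1)
  } else {
    stop("config field 'village' must name one of: synthetic, csv, ",
         "geojson, asc")
  }
}

run_scenario <- function(village, dm, optimized, scenario, base_config,
                         seed) {
  n <- nrow(village$households)
  if (scenario == "current") {
    order <- with_seed(seed,
                       sample(village$households$household_id, n))
    itin <- new_itinerary(order, dm, exact = FALSE)
    config <- base_config("current_fixed", pairs = 1)
  } else {
    itin <- optimized
    config <- base_config("optimal_fixed", pairs = 1)
    if (scenario == "microplan_b") {
      probe <- simulate_campaign(village, itin, config)
      config <- base_config("optimal_fixed",
                            pairs = max(1, probe$unmet_chws / 2))
    }
  }
  res <- simulate_campaign(village, itin, config)
  attr(res, "itinerary") <- itin
  attr(res, "scenario") <- scenario
  res
}

report_row <- function(village, scenario, res) {
  data.frame(
    village = village,
    scenario = scenario,
    chws_needed = round(res$config$chw_pairs * 2, 2),
    visited_households = res$visited_households,
    total_households = res$total_households,
    treated_children = res$treated_children,
    total_children = res$total_children,
    treatment_days = round(res$treatment_days, 2),
    walking_km = round(res$walking_km, 2),
    travel_days = round(res$travel_days, 2),
    coverage_pct = round(res$coverage_pct, 1),
    unmet_chws = round(res$unmet_chws, 2),
    stringsAsFactors = FALSE
  )
}

pipeline_comparisons <- function(results, villages, scenarios) {
  if (length(scenarios) < 2) {
    return(data.frame())
  }
  out <- list()
  for (v in villages) {
    res_v <- lapply(scenarios, function(sc) {
      results[[paste(v$name, sc, sep = ":")]]
    })
    names(res_v) <- scenarios
    out[[v$name]] <- scenario_compare_report(res_v, village = v$name)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pairwise comparison table for scenario results
#'
#' For every scenario pair on the same village: Yates-corrected chi-square
#' tests on visited households and on treated children, the walking-distance
#' change, and the coverage change both in percentage points and relative.
#'
#' @param results named list (scenario name -> `smc_campaign_result`) for
#'   one village.
#' @param village village label for the output rows.
#' @return data.frame, one row per scenario pair.
#' @export
scenario_compare_report <- function(results, village = NULL) {
  if (length(results) < 2) stop("need at least 2 scenario results")
  tot_hh <- vapply(results, function(r) r$total_households, numeric(1))
  tot_ch <- vapply(results, function(r) r$total_children, numeric(1))
  if (length(unique(tot_hh)) != 1 || length(unique(tot_ch)) != 1) {
    stop("scenario results are not on the same village")
  }
  if (is.null(village)) village <- results[[1]]$village
  pairs <- utils::combn(names(results), 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    a <- results[[p[1]]]
    b <- results[[p[2]]]
    ch_hh <- compare_scenarios(a$visited_households, a$total_households,
                               b$visited_households, b$total_households,
                               labels = p)
    ch_tr <- compare_scenarios(a$treated_children, a$total_children,
                               b$treated_children, b$total_children,
                               labels = p)
    data.frame(
      village = village,
      scenario_a = p[1], scenario_b = p[2],
      chi2_households = round(ch_hh$chi2, 2),
      p_households = ch_hh$p_value,
      chi2_children = round(ch_tr$chi2, 2),
      p_children = ch_tr$p_value,
      walking_change_pct = if (a$walking_km > 0)
        round(100 * (b$walking_km - a$walking_km) / a$walking_km, 1)
        else NA_real_,
      coverage_change_points = round(b$coverage_pct - a$coverage_pct, 1),
      coverage_change_rel_pct = if (a$coverage_pct > 0)
        round(100 * (b$coverage_pct - a$coverage_pct) / a$coverage_pct, 1)
        else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
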