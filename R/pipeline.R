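# Orchestration of the two-stage redesign: nationwide relocation scenarios,
# within-town grid optimisation for the selected scenario, and simulation
# comparison of the current vs redesigned deployment.

# static indicators of an arbitrary deployment (not necessarily optimal)
static_of_sites <- function(tmat, b, sites, als_sites, threshold_min = 15) {
  tmin <- apply(tmat[as.character(sort(unique(sites))), , drop = FALSE], 2, min)
  tals <- apply(tmat[as.character(sort(unique(als_sites))), , drop = FALSE], 2, min)
  tot <- sum(b)
  list(avg_time_closest = sum(b * tmin) / tot,
       avg_time_closest_als = sum(b * tals) / tot,
       coverage_pct = 100 * sum(b[tmin <= threshold_min]) / tot)
}

#' Run the full two-stage redesign pipeline
#'
#' Stage 1 (nationwide): derives demand weights from the K+N calls of a
#' historical record, applies the station-fixing rules, and solves the
#' hierarchical pq-median model once per relocation-budget scenario
#' (fractions of the station count plus an unrestricted scenario). Stage 2
#' (towns): for the selected scenario, re-optimises the stations inside
#' each town on a 250 m grid with an unrestricted budget, the town's
#' station counts and types being fixed by stage 1. Finally the current and
#' the redesigned deployments are simulated and compared.
#'
#' @param country an [generate_country()] result (or an
#'   `ems_country_config`, which is generated first).
#' @param fractions relocation fractions for the scenario sweep.
#' @param unrestricted also evaluate the unrestricted scenario.
#' @param select_fraction scenario fed into stage 2 (default 0.4, the
#'   compromise between improvement and reorganisation effort).
#' @param history_days length of the synthetic historical record that
#'   provides the demand weights.
#' @param sm speed model (default [speed_model()]).
#' @param sim_config simulation configuration; `NULL` skips simulation.
#' @param grid_cell_km stage-2 grid resolution (default 0.25 km).
#' @param seed master seed for the historical record.
#' @param out_dir optional directory; when given, solution tables and a
#'   manifest are written there.
#' @return A result bundle (list) with the scenario table, per-scenario
#'   solutions, stage-2 town solutions, the final deployment, indicator
#'   reports and the comparison table.
#' @export
run_pipeline <- function(country, fractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                         unrestricted = TRUE, select_fraction = 0.4,
                         history_days = 120, sm = speed_model(),
                         sim_config = simulation_config(),
                         grid_cell_km = 0.25, seed = 1L, out_dir = NULL) {
  if (inherits(country, "ems_country_config"))
    country <- generate_country(country)
  stopifnot(inherits(country, "ems_country"))
  fractions <- sort(unique(fractions))
  net <- country$network
  muni <- country$municipalities
  stations <- country$stations
  zones <- country$zones

  history <- generate_call_history(country, history_days, seed = seed)
  b <- aggregate_demand(history, zones)

  fixing <- apply_fixing_rules(stations, muni)
  scale <- setNames(fixing$report$demand_scale, fixing$report$municipality)
  sc <- scale[names(b)]
  b_scaled <- b * ifelse(is.na(sc), 1, sc)

  # candidate sites are the municipality central nodes; the static matrix
  # uses the single off-peak urgent-driving open-road context
  cand <- muni$central_node
  tmat <- travel_time_matrix(net, sm, cand, zones$anchor_node,
                             priority = "K", time_bucket = "offpeak",
                             ignore_built_up = TRUE)
  colnames(tmat) <- zones$zone_id

  fixed_st <- stations[as.character(stations$station_id) %in%
                         fixing$fixed_ids, , drop = FALSE]
  fixed <- NULL
  if (nrow(fixed_st)) {
    nf <- table(fixed_st$municipality)
    na_ <- table(factor(fixed_st$municipality[fixed_st$type == "ALS"],
                        levels = names(nf)))
    fixed <- data.frame(
      site = muni$central_node[match(names(nf), muni$municipality)],
      n_fixed = as.integer(nf), n_fixed_als = as.integer(na_))
  }
  free_st <- stations[as.character(stations$station_id) %in%
                        fixing$free_ids, , drop = FALSE]
  current_free_sites <- unique(free_st$node)
  p <- nrow(stations)
  q <- sum(stations$type == "ALS")

  labels <- c(sprintf("%d%%", round(100 * fractions)),
              if (unrestricted) "unrestricted")
  budgets <- c(vapply(fractions, build_scenario, numeric(1),
                      total_station_count = p),
               if (unrestricted) build_scenario(p, "unrestricted",
                                                length(fixing$free_ids)))
  scenarios <- vector("list", length(labels))
  names(scenarios) <- labels
  for (i in seq_along(labels)) {
    inst <- location_instance(tmat, b_scaled, p, q, fixed,
                              current_free_sites, budgets[i])
    sol <- solve_pq_median(inst)
    post <- postprocess_solution(sol, stations, muni, fixing)
    scenarios[[i]] <- list(label = labels[i], budget = budgets[i],
                           instance = inst, solution = sol,
                           placements = post$placements,
                           summary = post$summary,
                           static = static_indicators(sol, inst))
  }
  current_static <- static_of_sites(
    tmat, b_scaled, unique(stations$node),
    unique(stations$node[stations$type == "ALS"]))

  sel_label <- if (identical(select_fraction, "unrestricted")) "unrestricted"
    else sprintf("%d%%", round(100 * select_fraction))
  if (!sel_label %in% labels)
    stop("select_fraction does not match any evaluated scenario")
  selected <- scenarios[[sel_label]]

  # stage 2: within-town grids, unrestricted relocation, town station
  # counts and types fixed by the nationwide solution
  towns <- muni$municipality[muni$town]
  stage2 <- list()
  final <- selected$placements
  for (tw in towns) {
    rows <- which(final$municipality == tw)
    p_town <- length(rows)
    if (p_town == 0) next
    q_town <- sum(final$type[rows] == "ALS")
    tn <- net$nodes[net$nodes$node_id %in% zones$nodes[[match(tw, zones$zone_id)]], ]
    extent <- c(min(tn$x_km) - 0.1, max(tn$x_km) + 0.1,
                min(tn$y_km) - 0.1, max(tn$y_km) + 0.1)
    gz <- make_grid_zones(extent, net, cell_size = grid_cell_km, parent = tw)
    town_calls <- history[history$node %in% tn$node_id, , drop = FALSE]
    town_calls$zone_id <- NULL
    gb <- aggregate_demand(town_calls, gz)
    anchors <- sort(unique(gz$anchor_node))
    if (sum(gb) == 0 || length(anchors) < p_town) next
    gt <- travel_time_matrix(net, sm, anchors, gz$anchor_node,
                             priority = "K", time_bucket = "offpeak",
                             ignore_built_up = TRUE)
    colnames(gt) <- gz$zone_id
    ginst <- location_instance(gt, gb, p_town, q_town, budget = p_town)
    gsol <- solve_pq_median(ginst)
    stage2[[tw]] <- list(town = tw, p = p_town, q = q_town, zones = gz,
                         instance = ginst, solution = gsol,
                         static = static_indicators(gsol, ginst))
    # rewrite the town's stations onto the grid sites
    sites <- sort(gsol$y)
    als <- sites %in% gsol$u
    ord <- rows[order(final$type[rows] != "ALS", final$station_id[rows])]
    sites <- c(sites[als], sites[!als])
    for (k in seq_along(ord)) {
      final$node[ord[k]] <- as.integer(sites[k])
      final$type[ord[k]] <- if (k <= sum(als)) "ALS" else "BLS"
    }
  }

  sim_current <- sim_final <- comparison <- NULL
  if (!is.null(sim_config)) {
    dep_cur <- stations[c("station_id", "node", "type")]
    dep_fin <- final[c("station_id", "node", "type")]
    logs_cur <- run_replications(dep_cur, country$dist, sim_config, net, sm,
                                 country$hospitals, zones)
    logs_fin <- run_replications(dep_fin, country$dist, sim_config, net, sm,
                                 country$hospitals, zones)
    sim_current <- compute_indicators(logs_cur)
    sim_final <- compute_indicators(logs_fin)
    comparison <- compare_deployments(sim_current, sim_final)
  }

  scenario_table <- data.frame(
    scenario = labels, budget = budgets,
    n_relocated = vapply(scenarios, function(s) s$summary$n_relocated, numeric(1)),
    bls_to_als = vapply(scenarios, function(s) s$summary$bls_to_als, numeric(1)),
    als_to_bls = vapply(scenarios, function(s) s$summary$als_to_bls, numeric(1)),
    avg_time_closest = vapply(scenarios, function(s)
      s$static$avg_time_closest, numeric(1)),
    avg_time_closest_als = vapply(scenarios, function(s)
      s$static$avg_time_closest_als, numeric(1)),
    coverage_pct = vapply(scenarios, function(s) s$static$coverage_pct,
                          numeric(1)),
    stringsAsFactors = FALSE)

  bundle <- list(country = country, history_days = history_days,
                 fixing = fixing, current_static = current_static,
                 scenario_table = scenario_table, scenarios = scenarios,
                 selected = sel_label, stage2 = stage2,
                 final_deployment = final, sim_current = sim_current,
                 sim_final = sim_final, comparison = comparison,
                 seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stations_csv(final[c("station_id", "municipality", "node", "type")],
                       file.path(out_dir, "final_deployment.csv"))
    write.csv(scenario_table, file.path(out_dir, "scenario_table.csv"),
              row.names = FALSE)
    if (!is.null(comparison))
      write.csv(comparison, file.path(out_dir, "comparison.csv"),
                row.names = FALSE)
    manifest <- list(seed = seed, history_days = history_days,
                     selected = sel_label,
                     country_seed = country$config$seed,
                     n_stations = p, n_als = q,
                     budgets = setNames(as.list(budgets), labels),
                     sim = if (!is.null(sim_config))
                       list(horizon_days = sim_config$horizon_days,
                            replications = sim_config$replications,
                            seed = sim_config$seed))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}
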