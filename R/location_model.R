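# Hierarchical pq-median location model: station-fixing rules, relocation
# budgets, exact lower/upper level optimisation, post-processing and static
# indicators.
#
# Both levels are uncapacitated median problems, so any optimal solution
# assigns every demand zone to its nearest open site. That collapses the
# binary location/assignment program to a site-subset selection problem,
# which is solved to proven optimality by an exact branch-and-bound
# (src/pmedian.cpp) with deterministic lowest-id tie-breaks.

#' Construct a location-model instance
#'
#' Houses every ingredient of the two-level median model: candidate sites I
#' (rows of `tmat`), demand zones J (columns), travel times \eqn{t_{ij}},
#' demand weights \eqn{b_j}, the station counts p (all stations) and q (ALS
#' stations), the stations fixed at their current sites by the pre-processing
#' rules, the sites currently hosting relocatable stations, and the
#' relocation budget.
#'
#' @param tmat numeric travel-time matrix (minutes), rows named by candidate
#'   site node ids, columns by zone ids.
#' @param weights demand weights \eqn{b_j \ge 0}, one per column of `tmat`.
#' @param p total number of stations.
#' @param q number of ALS stations, `q <= p`.
#' @param fixed data.frame with columns `site`, `n_fixed`, `n_fixed_als`:
#'   per-site counts of stations fixed by the fixing rules (`NULL` for
#'   none). Fixed sites are forced open; sites with `n_fixed_als > 0` are
#'   forced to carry an ALS.
#' @param current_free_sites node ids of sites currently hosting free
#'   (relocatable) stations; the relocation budget counts how many of these
#'   may be abandoned.
#' @param budget relocation budget r: maximum number of free stations moved
#'   to a new municipality (`Inf` = unrestricted).
#' @return An object of class `ems_location_instance`.
#' @export
location_instance <- function(tmat, weights, p, q, fixed = NULL,
                              current_free_sites = integer(0),
                              budget = Inf) {
  stopifnot(is.matrix(tmat), !is.null(rownames(tmat)), !is.null(colnames(tmat)))
  if (any(!is.finite(tmat)) || any(tmat < 0))
    stop("travel times must be finite and >= 0")
  if (length(weights) != ncol(tmat)) stop("one weight per demand zone needed")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (!(q <= p)) stop("q must not exceed p")
  if (p > nrow(tmat)) {
    # p counts stations; multiple fixed stations may share a site, so the
    # site requirement is checked after netting out fixed multiplicity
    if (is.null(fixed) || p - sum(fixed$n_fixed) + nrow(fixed) > nrow(tmat))
      stop("more station sites required than candidate sites available")
  }
  if (budget < 0) stop("budget must be >= 0")
  ord <- order(as.numeric(rownames(tmat)))
  tmat <- tmat[ord, , drop = FALSE]
  if (is.null(fixed)) {
    fixed <- data.frame(site = integer(0), n_fixed = integer(0),
                        n_fixed_als = integer(0))
  } else {
    stopifnot(all(c("site", "n_fixed", "n_fixed_als") %in% names(fixed)))
    if (any(fixed$n_fixed_als > fixed$n_fixed))
      stop("fixed ALS count exceeds fixed count")
    if (!all(as.character(fixed$site) %in% rownames(tmat)))
      stop("fixed site not among candidates")
    if (sum(fixed$n_fixed) > p) stop("more fixed stations than p")
    if (sum(fixed$n_fixed_als) > q) stop("more fixed ALS stations than q")
  }
  structure(list(tmat = tmat, weights = setNames(weights, colnames(tmat)),
                 p = p, q = q, fixed = fixed,
                 current_free_sites = as.integer(current_free_sites),
                 budget = budget),
            class = "ems_location_instance")
}

#' Apply the station-fixing rules
#'
#' Pre-processing that keeps the uncapacitated model realistic in
#' high-demand towns. The capacity of a station is the average population
#' per station, C = total population / total station count. Rule 1: a town
#' with k stations and population P keeps all k fixed when P > kC;
#' otherwise n = floor(P/C) stations are fixed and the town's demand weight
#' is scaled by 1 - nC/P (the share served by the fixed stations). Rule 2:
#' a town with exactly two stations and P < C (so Rule 1 fixed none) keeps
#' one. Within a town, ALS stations are fixed before BLS, lowest id first.
#'
#' @param stations data.frame with columns `station_id`, `municipality`,
#'   `type` (`"ALS"`/`"BLS"`), `node`.
#' @param towns data.frame with columns `municipality`, `population`.
#' @param total_population defaults to the sum over `towns`.
#' @return An object of class `ems_fixing` with the capacity, a per-town
#'   report (`municipality`, `population`, `n_stations`, `n_fixed`, `rule`,
#'   `demand_scale`) and the fixed / free station ids.
#' @export
apply_fixing_rules <- function(stations, towns,
                               total_population = sum(towns$population)) {
  stopifnot(all(c("station_id", "municipality", "type") %in% names(stations)),
            all(c("municipality", "population") %in% names(towns)))
  unknown <- setdiff(stations$municipality, towns$municipality)
  if (length(unknown))
    stop("station in unknown town: ", paste(unknown, collapse = ", "))
  capacity <- total_population / nrow(stations)
  munis <- unique(stations$municipality)
  rows <- vector("list", length(munis))
  fixed_ids <- character(0)
  for (m in seq_along(munis)) {
    mu <- munis[m]
    st <- stations[stations$municipality == mu, , drop = FALSE]
    st <- st[order(st$type != "ALS", st$station_id), , drop = FALSE]
    k <- nrow(st)
    P <- towns$population[match(mu, towns$municipality)]
    if (P > k * capacity) {
      n <- k; rule <- 1L; scale <- 1
    } else {
      n <- floor(P / capacity)
      if (n > 0) {
        rule <- 1L; scale <- 1 - n * capacity / P
      } else if (k == 2 && P < capacity) {
        n <- 1L; rule <- 2L; scale <- 1
      } else {
        rule <- 0L; scale <- 1
      }
    }
    if (n > 0) fixed_ids <- c(fixed_ids, as.character(st$station_id[seq_len(n)]))
    rows[[m]] <- data.frame(municipality = mu, population = P, n_stations = k,
                            n_fixed = as.integer(n), rule = rule,
                            demand_scale = scale, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  stopifnot(all(report$demand_scale >= -1e-12))
  structure(list(capacity = capacity, report = report,
                 fixed_ids = fixed_ids,
                 free_ids = setdiff(as.character(stations$station_id),
                                    fixed_ids)),
            class = "ems_fixing")
}

#' @export
print.ems_fixing <- function(x, ...) {
  cat("<ems_fixing> capacity ", round(x$capacity, 1), " inhabitants/station; ",
      length(x$fixed_ids), " fixed, ", length(x$free_ids), " free\n", sep = "")
  invisible(x)
}

#' Relocation budget for a redesign scenario
#'
#' @param total_station_count total number of stations in the system.
#' @param fraction share of stations allowed to move (in (0, 1]), or the
#'   string `"unrestricted"`.
#' @param free_station_count number of non-fixed stations; required for the
#'   unrestricted scenario.
#' @return Integer relocation budget r (nearest integer of
#'   `fraction * total_station_count`, or `free_station_count`).
#' @export
build_scenario <- function(total_station_count, fraction,
                           free_station_count = NULL) {
  if (identical(fraction, "unrestricted")) {
    if (is.null(free_station_count))
      stop("unrestricted scenario needs free_station_count")
    return(as.integer(free_station_count))
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1] or be \"unrestricted\"")
  as.integer(floor(fraction * total_station_count + 0.5))
}

# map an instance to the branch-and-bound arguments shared by both levels
solve_site_subset <- function(tmat, weights, forced_sites, pool_sites,
                              pool_is_current, pick, min_keep) {
  sites <- as.numeric(rownames(tmat))
  fi <- match(forced_sites, sites) - 1L
  pi <- match(pool_sites, sites) - 1L
  res <- pmedian_bb_cpp(tmat, weights, as.integer(fi), as.integer(pi),
                        as.logical(pool_is_current), as.integer(pick),
                        as.integer(min_keep))
  if (!isTRUE(res$feasible)) return(NULL)
  open <- sort(c(forced_sites, sites[res$chosen + 1L]))
  list(objective = res$objective, open = open,
       chosen = sort(sites[res$chosen + 1L]))
}

# nearest-open assignment with lowest-site-id tie-break
assign_nearest <- function(tmat, open_sites) {
  sub <- tmat[as.character(open_sites), , drop = FALSE]
  ord <- order(as.numeric(rownames(sub)))
  sub <- sub[ord, , drop = FALSE]
  idx <- apply(sub, 2, which.min)
  setNames(as.numeric(rownames(sub))[idx], colnames(sub))
}

#' Solve the lower level of the hierarchical median model
#'
#' Chooses the sites of all p stations minimising the demand-weighted total
#' travel time, with fixed sites forced open and at most r free stations
#' abandoning their current sites. The optimum is proven (exact
#' branch-and-bound); zones are assigned to their nearest open site, ties
#' broken by lowest site id.
#'
#' @param instance an [location_instance()].
#' @return List with `y` (open sites), `x` (zone to site assignment),
#'   `Z_low` (optimal objective), `chosen_free_sites` and `p_free`.
#' @export
solve_lower_level <- function(instance) {
  stopifnot(inherits(instance, "ems_location_instance"))
  tm <- instance$tmat
  sites <- as.numeric(rownames(tm))
  forced <- as.numeric(instance$fixed$site)
  p_free <- instance$p - sum(instance$fixed$n_fixed)
  pool <- setdiff(sites, forced)
  is_cur <- pool %in% instance$current_free_sites
  base_keep <- sum(instance$current_free_sites %in% forced)
  min_keep <- max(0, p_free - instance$budget - base_keep)
  res <- solve_site_subset(tm, instance$weights, forced, pool, is_cur,
                           p_free, min_keep)
  if (is.null(res))
    stop("lower level infeasible: budget r = ", instance$budget,
         " requires keeping ", min_keep, " current sites but only ",
         sum(is_cur), " are available")
  x <- assign_nearest(tm, res$open)
  list(y = res$open, x = x, Z_low = res$objective,
       chosen_free_sites = res$chosen, p_free = p_free)
}

#' Solve the upper level: ALS siting among the open stations
#'
#' Selects q of the p open sites for ALS ambulances, minimising the
#' demand-weighted total travel time from the ALS tier. Sites carrying a
#' fixed ALS station are forced in; fixed BLS stations may be upgraded, and
#' all other types are free.
#'
#' @param instance an [location_instance()].
#' @param y open sites from [solve_lower_level()].
#' @return List with `u` (ALS sites), `v` (zone to ALS-site assignment) and
#'   `Z_up`.
#' @export
solve_upper_level <- function(instance, y) {
  stopifnot(inherits(instance, "ems_location_instance"))
  if (instance$q > length(y) + sum(pmax(instance$fixed$n_fixed_als - 1, 0)))
    stop("q exceeds the number of open sites")
  tm <- instance$tmat[as.character(sort(y)), , drop = FALSE]
  fixed_als_sites <- as.numeric(instance$fixed$site[instance$fixed$n_fixed_als > 0])
  if (!all(fixed_als_sites %in% y))
    stop("fixed ALS site not open at the lower level")
  q_free <- instance$q - sum(instance$fixed$n_fixed_als)
  if (q_free < 0) stop("more fixed ALS stations than q")
  pool <- setdiff(sort(y), fixed_als_sites)
  res <- solve_site_subset(tm, instance$weights, fixed_als_sites, pool,
                           rep(FALSE, length(pool)), q_free, 0)
  if (is.null(res)) stop("upper level infeasible")
  v <- assign_nearest(tm, res$open)
  list(u = res$open, v = v, Z_up = res$objective)
}

#' Solve both levels of the hierarchical pq-median model
#'
#' @param instance an [location_instance()].
#' @return An object of class `ems_location_solution` with the open sites
#'   `y`, ALS sites `u`, both assignments and both objectives.
#' @export
solve_pq_median <- function(instance) {
  low <- solve_lower_level(instance)
  up <- solve_upper_level(instance, low$y)
  structure(c(low, up), class = "ems_location_solution")
}

#' @export
print.ems_location_solution <- function(x, ...) {
  cat("<ems_location_solution> p = ", length(x$y), " sites (q = ",
      length(x$u), " ALS); Z_low = ", round(x$Z_low, 2), ", Z_up = ",
      round(x$Z_up, 2), "\n", sep = "")
  invisible(x)
}

#' Post-process an optimal solution into station placements
#'
#' Stations that were not relocated by the model stay at their current
#' addresses; the others are placed at the central nodes of their new
#' municipalities. A station counts as relocated iff its final municipality
#' differs from its origin municipality. One station per ALS site is
#' designated ALS (preferring a station that is ALS today, then lowest id);
#' type switches are counted over non-relocated stations.
#'
#' @param solution an `ems_location_solution`.
#' @param stations current stations: `station_id`, `municipality`, `node`,
#'   `type`.
#' @param municipalities data.frame with `municipality` and `central_node`
#'   (the candidate site of each municipality).
#' @param fixing optional [apply_fixing_rules()] result identifying the
#'   fixed stations (all stations are treated as free if omitted).
#' @return List with `placements` (one row per station: final node,
#'   municipality, type, `relocated`, `switched`) and `summary` counts.
#' @export
postprocess_solution <- function(solution, stations, municipalities,
                                 fixing = NULL) {
  site_muni <- setNames(municipalities$municipality,
                        as.character(municipalities$central_node))
  muni_site <- setNames(municipalities$central_node,
                        municipalities$municipality)
  fixed_ids <- if (is.null(fixing)) character(0) else fixing$fixed_ids
  st <- stations
  st$fixed <- as.character(st$station_id) %in% fixed_ids
  st$site <- muni_site[st$municipality]

  pl <- data.frame(station_id = st$station_id,
                   origin_municipality = st$municipality,
                   origin_type = st$type,
                   municipality = NA_character_, node = NA_integer_,
                   site = NA_real_, relocated = FALSE,
                   stringsAsFactors = FALSE)
  # fixed stations never move
  fx <- which(st$fixed)
  pl$municipality[fx] <- st$municipality[fx]
  pl$node[fx] <- st$node[fx]
  pl$site[fx] <- st$site[fx]

  free_sites <- solution$chosen_free_sites
  free_idx <- which(!st$fixed)
  free_idx <- free_idx[order(st$station_id[free_idx])]
  unmatched_sites <- free_sites
  for (s in free_sites) {
    m <- site_muni[as.character(s)]
    cand <- free_idx[st$municipality[free_idx] == m & is.na(pl$node[free_idx])]
    if (length(cand)) {
      i <- cand[1]
      pl$municipality[i] <- m; pl$node[i] <- st$node[i]; pl$site[i] <- s
      unmatched_sites <- setdiff(unmatched_sites, s)
    }
  }
  movers <- free_idx[is.na(pl$node[free_idx])]
  if (length(movers) != length(unmatched_sites))
    stop("internal error: station/site pairing mismatch")
  for (k in seq_along(unmatched_sites)) {
    s <- unmatched_sites[k]; i <- movers[k]
    m <- site_muni[as.character(s)]
    pl$municipality[i] <- m
    pl$node[i] <- as.integer(muni_site[m])
    pl$site[i] <- s
    pl$relocated[i] <- TRUE
  }

  # final types: fixed ALS immutable; one ALS per remaining ALS site,
  # preferring a station that is ALS today, then lowest id
  pl$type <- "BLS"
  fixed_als <- fx[st$type[fx] == "ALS"]
  pl$type[fixed_als] <- "ALS"
  for (s in setdiff(solution$u, unique(pl$site[fixed_als]))) {
    here <- which(pl$site == s & pl$type == "BLS")
    if (!length(here)) next
    here <- here[order(pl$origin_type[here] != "ALS", pl$station_id[here])]
    pl$type[here[1]] <- "ALS"
  }
  pl$switched <- !pl$relocated & pl$type != pl$origin_type
  summary <- list(
    n_relocated = sum(pl$relocated),
    n_relocated_bls = sum(pl$relocated & pl$type == "BLS"),
    n_relocated_als = sum(pl$relocated & pl$type == "ALS"),
    bls_to_als = sum(pl$switched & pl$type == "ALS"),
    als_to_bls = sum(pl$switched & pl$type == "BLS"))
  list(placements = pl, summary = summary)
}

#' Static indicators of a location solution
#'
#' The average travel time of each tier is the objective divided by the
#' total demand; theoretical coverage is the demand share whose nearest open
#' station is within the threshold (inclusive), computed from the static
#' matrix with no congestion.
#'
#' @param solution an `ems_location_solution` (or lower-level list).
#' @param instance the [location_instance()] it solves.
#' @param threshold_min coverage threshold in minutes (default 15).
#' @return List with `avg_time_closest`, `avg_time_closest_als` (`NA` when
#'   no upper level was solved) and `coverage_pct`.
#' @export
static_indicators <- function(solution, instance, threshold_min = 15) {
  b <- instance$weights
  tot <- sum(b)
  if (tot <= 0) stop("total demand is zero; averages undefined")
  tmin <- apply(instance$tmat[as.character(solution$y), , drop = FALSE], 2, min)
  list(avg_time_closest = solution$Z_low / tot,
       avg_time_closest_als = if (is.null(solution$Z_up)) NA_real_ else
         solution$Z_up / tot,
       coverage_pct = 100 * sum(b[tmin <= threshold_min]) / tot)
}
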