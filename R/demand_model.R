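# Two-level spatial demand representation and call-stream distributions.

#' Construct a set of demand zones
#'
#' A demand zone is either a whole municipality (anchored at its central
#' road node) or a 250 m grid cell inside a town. Each zone knows the road
#' nodes it contains, its population and an aggregated demand weight.
#'
#' @param zones data.frame with columns `zone_id`, `level`
#'   (`"municipality"` or `"grid_cell"`), `anchor_node`, `population`,
#'   `parent` (municipality id, `NA` at the municipality level).
#' @param zone_nodes named list mapping `zone_id` to the integer vector of
#'   road nodes belonging to the zone.
#' @param network the road network the anchors live on (validated if given).
#' @return data.frame of class `ems_zones` with a list column `nodes`.
#' @export
demand_zones <- function(zones, zone_nodes, network = NULL) {
  need <- c("zone_id", "level", "anchor_node", "population", "parent")
  if (!all(need %in% names(zones)))
    stop("zones must have columns: ", paste(need, collapse = ", "))
  if (!all(zones$level %in% c("municipality", "grid_cell")))
    stop("unknown zone level")
  if (any(zones$population < 0)) stop("populations must be >= 0")
  if (!all(zones$zone_id %in% names(zone_nodes)))
    stop("every zone needs an entry in zone_nodes")
  if (!is.null(network)) node_index(network, zones$anchor_node)
  zones$nodes <- unname(zone_nodes[zones$zone_id])
  class(zones) <- c("ems_zones", "data.frame")
  zones
}

# node id -> zone id lookup for a zone set
zone_of_node <- function(zones) {
  ids <- rep(zones$zone_id, lengths(zones$nodes))
  setNames(ids, as.character(unlist(zones$nodes)))
}

#' Aggregate historical calls into zone demand weights
#'
#' Demand is derived from the historical calls of the two urgent priorities
#' (K, life-threatening, and N, urgent); the non-urgent M calls are excluded.
#' The weight \eqn{b_j} of a zone is the count of K and N calls located in
#' it.
#'
#' @param calls data.frame with a `priority` column and either a `zone_id`
#'   or a `node` column locating each call.
#' @param zones an [demand_zones()] object.
#' @return Named numeric vector of weights `b_j`, one per zone, in zone
#'   order.
#' @export
aggregate_demand <- function(calls, zones) {
  if (!"priority" %in% names(calls)) stop("calls need a priority column")
  if ("zone_id" %in% names(calls)) {
    zid <- calls$zone_id
  } else if ("node" %in% names(calls)) {
    zid <- zone_of_node(zones)[as.character(calls$node)]
  } else stop("calls need a zone_id or node column")
  bad <- which(is.na(zid) | !(zid %in% zones$zone_id))
  if (length(bad))
    stop("call(s) outside every zone: record ",
         paste(head(bad, 5), collapse = ", "))
  keep <- calls$priority %in% c("K", "N")
  tab <- table(factor(zid[keep], levels = zones$zone_id))
  setNames(as.numeric(tab), zones$zone_id)
}

#' Build grid-cell demand zones over a town extent
#'
#' Tiles the extent with axis-aligned square cells (default 250 m) and
#' anchors each cell at the road node nearest (Euclidean) to its centre.
#' A cell's nodes are the road nodes falling inside its rectangle.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in km.
#' @param network road network covering the town.
#' @param cell_size cell side in km (default 0.25).
#' @param snap_radius maximum anchor distance in km; cells whose nearest
#'   node is farther away are flagged `anchored = FALSE`.
#' @param parent municipality id recorded on the cells.
#' @param drop_empty drop cells with no road node and zero population.
#' @return An `ems_zones` data.frame with extra columns `cx`, `cy`
#'   (cell centres) and `anchored`.
#' @export
make_grid_zones <- function(extent, network, cell_size = 0.25,
                            snap_radius = Inf, parent = NA_character_,
                            drop_empty = TRUE) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  nx <- ceiling((extent[2] - extent[1]) / cell_size - 1e-9)
  ny <- ceiling((extent[4] - extent[3]) / cell_size - 1e-9)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cx <- extent[1] + (grid$ix - 0.5) * cell_size
  cy <- extent[3] + (grid$iy - 0.5) * cell_size
  nodes <- network$nodes
  anchor <- integer(nrow(grid)); adist <- numeric(nrow(grid))
  cell_nodes <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    d2 <- (nodes$x_km - cx[k])^2 + (nodes$y_km - cy[k])^2
    i <- which.min(d2)
    anchor[k] <- nodes$node_id[i]
    adist[k] <- sqrt(d2[i])
    inside <- nodes$node_id[
      nodes$x_km >= cx[k] - cell_size / 2 & nodes$x_km < cx[k] + cell_size / 2 &
        nodes$y_km >= cy[k] - cell_size / 2 & nodes$y_km < cy[k] + cell_size / 2]
    cell_nodes[[k]] <- as.integer(inside)
  }
  zdf <- data.frame(
    zone_id = sprintf("cell_%d_%d", grid$ix, grid$iy),
    level = "grid_cell", anchor_node = anchor, population = 0,
    parent = parent, stringsAsFactors = FALSE)
  zdf$cx <- cx; zdf$cy <- cy
  zdf$anchored <- adist <= snap_radius
  names(cell_nodes) <- zdf$zone_id
  z <- demand_zones(zdf, cell_nodes, network)
  if (drop_empty) {
    keep <- lengths(z$nodes) > 0 | z$population > 0
    z <- z[keep, , drop = FALSE]
  }
  z
}

#' Estimate hourly call arrival rates
#'
#' @param calls data.frame with a `t_min` column (minutes since the start of
#'   the observation window).
#' @param horizon_days length of the observation window in days.
#' @return Numeric vector `lambda[1..24]`: calls per hour-of-day per day.
#' @export
estimate_hourly_rates <- function(calls, horizon_days) {
  stopifnot(horizon_days > 0)
  if (nrow(calls) == 0) return(rep(0, 24))
  h <- floor((calls$t_min %% 1440) / 60)
  as.numeric(table(factor(h, levels = 0:23))) / horizon_days
}

#' Construct a call distribution
#'
#' The temporal and attribute model of emergency calls: arrivals follow a
#' non-homogeneous Poisson process with an hour-of-day specific rate
#' (day-of-week and month effects are flat), and each call independently
#' draws a priority (K/N/M), a diagnosis and an age class.
#'
#' @param hourly_rates numeric vector of 24 rates (calls/hour), hour 0 first.
#' @param priority_mix named probabilities over `c("K", "N", "M")`.
#' @param diagnosis_probs named probabilities over diagnoses; must contain
#'   the First Hour Quintet ([fhq_diagnoses()]) in its support.
#' @param age_probs named probabilities over `c("child", "adult")`.
#' @return An object of class `ems_call_distribution`.
#' @export
call_distribution <- function(hourly_rates, priority_mix, diagnosis_probs,
                              age_probs = c(child = 0.08, adult = 0.92)) {
  stopifnot(length(hourly_rates) == 24)
  if (any(hourly_rates < 0)) stop("hourly rates must be >= 0")
  chk <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8) stop(what, " probabilities must sum to 1")
    if (any(p < 0)) stop(what, " probabilities must be >= 0")
  }
  chk(priority_mix, "priority"); chk(diagnosis_probs, "diagnosis")
  chk(age_probs, "age")
  if (!all(c("K", "N", "M") %in% names(priority_mix)))
    stop("priority mix must cover K, N, M")
  if (!all(fhq_diagnoses() %in% names(diagnosis_probs)))
    stop("diagnosis support must contain the First Hour Quintet")
  structure(list(hourly_rates = as.numeric(hourly_rates),
                 priority_mix = priority_mix,
                 diagnosis_probs = diagnosis_probs, age_probs = age_probs),
            class = "ems_call_distribution")
}

#' Sample a call stream from a call distribution
#'
#' Piecewise-homogeneous Poisson sampling: the number of calls in each hour
#' of each day is Poisson with that hour's rate, and arrival instants inside
#' the hour are uniform order statistics. Each call is then assigned to a
#' zone with probability proportional to zone population, to a road node
#' uniformly inside the zone, and draws its attributes independently.
#'
#' @param dist an [call_distribution()].
#' @param zones an [demand_zones()] set carrying populations and nodes.
#' @param horizon_days number of days to simulate.
#' @param seed optional integer seed; identical seeds reproduce the stream.
#' @return data.frame sorted by `t_min` with columns `call_id`, `t_min`,
#'   `zone_id`, `node`, `priority`, `diagnosis`, `age_class`.
#' @export
sample_call_stream <- function(dist, zones, horizon_days, seed = NULL) {
  stopifnot(inherits(dist, "ems_call_distribution"), horizon_days >= 0)
  if (!is.null(seed)) set.seed(seed)
  pop <- zones$population
  with_nodes <- lengths(zones$nodes) > 0
  if (any(pop > 0 & !with_nodes))
    stop("zones with population must contain road nodes")
  if (sum(pop[with_nodes]) <= 0 && sum(dist$hourly_rates) > 0)
    stop("no populated zone to place calls in")
  slots <- expand.grid(hour = 0:23, day = seq_len(horizon_days))
  counts <- rpois(nrow(slots), dist$hourly_rates[slots$hour + 1])
  n <- sum(counts)
  if (n == 0) {
    return(data.frame(call_id = integer(0), t_min = numeric(0),
                      zone_id = character(0), node = integer(0),
                      priority = character(0), diagnosis = character(0),
                      age_class = character(0), stringsAsFactors = FALSE))
  }
  base <- rep((slots$day - 1) * 1440 + slots$hour * 60, counts)
  t_min <- base + runif(n) * 60
  w <- ifelse(with_nodes, pop, 0)
  zi <- sample.int(nrow(zones), n, replace = TRUE, prob = w)
  node <- vapply(zi, function(i) {
    nd <- zones$nodes[[i]]
    if (length(nd) == 1L) nd else nd[sample.int(length(nd), 1L)]
  }, integer(1))
  draw <- function(p) names(p)[sample.int(length(p), n, replace = TRUE,
                                          prob = p)]
  out <- data.frame(call_id = seq_len(n), t_min = t_min,
                    zone_id = zones$zone_id[zi], node = node,
                    priority = draw(dist$priority_mix),
                    diagnosis = draw(dist$diagnosis_probs),
                    age_class = draw(dist$age_probs),
                    stringsAsFactors = FALSE)
  out <- out[order(out$t_min), , drop = FALSE]
  out$call_id <- seq_len(n)
  rownames(out) <- NULL
  out
}
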