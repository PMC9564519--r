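# Road graph, travel speeds, shortest-time routing and en-route positions.

#' Construct a road network
#'
#' A road network is an (by default undirected) graph whose nodes carry
#' planar coordinates in kilometres and a built-up flag, and whose edges
#' carry a positive length in kilometres and a road category
#' (`highway`, `main` or `local`). Ambulance travel times are derived from
#' edge lengths and a [speed_model()].
#'
#' @param nodes data.frame with columns `node_id` (unique integers),
#'   `x_km`, `y_km`, `built_up` (logical).
#' @param edges data.frame with columns `a`, `b` (node ids), `length_km`
#'   (> 0) and `category` (one of `"highway"`, `"main"`, `"local"`).
#' @param directed logical; ambulance networks are normally undirected.
#' @return An object of class `ems_network`.
#' @export
road_network <- function(nodes, edges, directed = FALSE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("node_id", "x_km", "y_km", "built_up")
  need_e <- c("a", "b", "length_km", "category")
  if (!all(need_n %in% names(nodes)))
    stop("nodes must have columns: ", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop("edges must have columns: ", paste(need_e, collapse = ", "))
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$built_up <- as.logical(nodes$built_up)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids")
  if (nrow(edges)) {
    if (any(edges$length_km <= 0)) stop("edge lengths must be > 0")
    if (!all(edges$category %in% c("highway", "main", "local")))
      stop("unknown edge category")
    miss <- setdiff(c(edges$a, edges$b), nodes$node_id)
    if (length(miss))
      stop("edge endpoints not in node set: ", paste(miss, collapse = ", "))
    edges$a <- as.integer(edges$a)
    edges$b <- as.integer(edges$b)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$a), to = as.character(edges$b)),
    directed = directed,
    vertices = data.frame(name = as.character(nodes$node_id)))
  # edge built-up context: an edge runs through a built-up area when both of
  # its endpoints do
  bu <- nodes$built_up[match(edges$a, nodes$node_id)] &
    nodes$built_up[match(edges$b, nodes$node_id)]
  structure(list(nodes = nodes, edges = edges, edge_built_up = bu,
                 directed = directed, graph = g),
            class = "ems_network")
}

#' @export
print.ems_network <- function(x, ...) {
  cat("<ems_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      if (x$directed) "directed" else "undirected", ")\n", sep = "")
  invisible(x)
}

node_index <- function(network, ids) {
  idx <- match(as.integer(ids), network$nodes$node_id)
  if (anyNA(idx))
    stop("unknown node id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Check that a set of nodes lies in one connected component
#'
#' @param network an [road_network()] object.
#' @param ids node ids to check (default: all nodes).
#' @return `TRUE` invisibly, or an error naming the offending nodes.
#' @export
assert_connected <- function(network, ids = network$nodes$node_id) {
  comp <- igraph::components(network$graph, mode = "weak")$membership
  m <- comp[node_index(network, ids)]
  if (length(unique(m)) > 1L)
    stop("nodes span ", length(unique(m)), " components; e.g. nodes ",
         ids[which(m != m[1])[1]], " and ", ids[1], " are disconnected")
  invisible(TRUE)
}

#' Default travel-speed table
#'
#' Documented default cruising speeds in km/h by road category, built-up
#' context, call priority and time bucket. Off-peak / rush-hour speeds are
#' 90/72 (highway), 60/48 (main) and 40/32 (local); built-up areas scale all
#' speeds by 0.8 and the lowest priority (M) drives at 0.9 of the urgent
#' speed. The values are configuration, not physical constants, and can be
#' replaced wholesale.
#'
#' @return data.frame with columns `category`, `built_up`, `priority`,
#'   `bucket`, `speed_kmh`.
#' @export
default_speed_table <- function() {
  base <- c(highway = 90, main = 60, local = 40)
  grid <- expand.grid(category = names(base), built_up = c(FALSE, TRUE),
                      priority = c("K", "N", "M"),
                      bucket = c("offpeak", "rush"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sp <- base[grid$category]
  sp <- sp * ifelse(grid$bucket == "rush", 0.8, 1)
  sp <- sp * ifelse(grid$built_up, 0.8, 1)
  sp <- sp * ifelse(grid$priority == "M", 0.9, 1)
  grid$speed_kmh <- unname(sp)
  grid
}

#' Construct a travel-speed model
#'
#' Speeds depend on road category, built-up context, call priority and time
#' of day: rush-hour traffic (default windows 06:30--09:00 and 15:00--18:00)
#' slows every road class down, and so do built-up areas.
#'
#' @param table speed table as in [default_speed_table()].
#' @param rush_windows two-column matrix of rush windows in minutes of the
#'   day, `[start, end)`.
#' @return An object of class `ems_speed_model`.
#' @export
speed_model <- function(table = default_speed_table(),
                        rush_windows = rbind(c(390, 540), c(900, 1080))) {
  need <- c("category", "built_up", "priority", "bucket", "speed_kmh")
  if (!all(need %in% names(table)))
    stop("speed table must have columns: ", paste(need, collapse = ", "))
  if (any(table$speed_kmh <= 0)) stop("all speeds must be > 0")
  rush_windows <- matrix(as.numeric(rush_windows), ncol = 2)
  key <- function(cat, bu, pri, bucket)
    paste(cat, bu, pri, bucket, sep = "|")
  lut <- setNames(table$speed_kmh,
                  key(table$category, table$built_up, table$priority,
                      table$bucket))
  full <- expand.grid(category = c("highway", "main", "local"),
                      built_up = c(FALSE, TRUE), priority = c("K", "N", "M"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(full))) {
    off <- lut[key(full$category[i], full$built_up[i], full$priority[i], "offpeak")]
    rush <- lut[key(full$category[i], full$built_up[i], full$priority[i], "rush")]
    if (is.na(off) || is.na(rush))
      stop("speed table is missing the combination ",
           paste(full[i, ], collapse = "/"))
    if (rush > off)
      stop("rush-hour speed exceeds off-peak speed for ",
           paste(full[i, ], collapse = "/"))
    open <- lut[key(full$category[i], FALSE, full$priority[i], "offpeak")]
    bu <- lut[key(full$category[i], TRUE, full$priority[i], "offpeak")]
    if (bu > open)
      stop("built-up speed exceeds open-road speed for ",
           full$category[i], "/", full$priority[i])
  }
  structure(list(table = table, lut = lut, rush_windows = rush_windows),
            class = "ems_speed_model")
}

speed_lookup <- function(sm, category, built_up, priority, bucket) {
  if (length(category) == 0) return(numeric(0))
  v <- sm$lut[paste(category, built_up, priority, bucket, sep = "|")]
  if (anyNA(v)) stop("speed table has no entry for requested context")
  unname(v)
}

# Per-edge off-peak and rush speeds for one priority, in the edge order of
# the network. ignore_built_up = TRUE evaluates every edge as open road (the
# static optimisation-stage context).
edge_speed_vectors <- function(network, sm, priority, ignore_built_up = FALSE) {
  bu <- if (ignore_built_up) rep(FALSE, nrow(network$edges)) else
    network$edge_built_up
  list(off = speed_lookup(sm, network$edges$category, bu, priority, "offpeak"),
       rush = speed_lookup(sm, network$edges$category, bu, priority, "rush"))
}

# Directed expansion of the edge set for the C++ router (0-based indices).
expand_edges <- function(network) {
  e <- network$edges
  ia <- node_index(network, e$a) - 1L
  ib <- node_index(network, e$b) - 1L
  if (network$directed) {
    list(from = ia, to = ib, eid = seq_len(nrow(e)))
  } else {
    list(from = c(ia, ib), to = c(ib, ia),
         eid = c(seq_len(nrow(e)), seq_len(nrow(e))))
  }
}

# Precomputed routing context: directed edge expansion plus per-priority
# off-peak/rush speed vectors. The simulator routes thousands of legs, so
# this is built once per run.
routing_context <- function(network, sm, ignore_built_up = FALSE) {
  ex <- expand_edges(network)
  pri <- c("K", "N", "M")
  sp <- lapply(setNames(pri, pri), function(p) {
    v <- edge_speed_vectors(network, sm, p, ignore_built_up)
    list(off = v$off[ex$eid], rush = v$rush[ex$eid])
  })
  list(network = network, ex = ex,
       len = network$edges$length_km[ex$eid], sp = sp,
       rush = sm$rush_windows,
       idmap = setNames(seq_len(nrow(network$nodes)),
                        as.character(network$nodes$node_id)))
}

route_ctx <- function(ctx, origin, dest, priority, depart_time) {
  net <- ctx$network
  oi <- unname(ctx$idmap[as.character(origin)])
  di <- unname(ctx$idmap[as.character(dest)])
  if (is.na(oi) || is.na(di))
    stop("unknown node id(s): ", origin, " / ", dest)
  if (oi == di) {
    return(structure(list(nodes = as.integer(origin),
                          entry_times = depart_time,
                          total_time = 0, total_length = 0,
                          priority = priority, depart_time = depart_time),
                     class = "ems_route"))
  }
  spv <- ctx$sp[[priority]]
  res <- tdsp_cpp(nrow(net$nodes), ctx$ex$from, ctx$ex$to, ctx$len,
                  spv$off, spv$rush, ctx$rush, oi - 1L, depart_time)
  if (!is.finite(res$arrival[di]))
    stop("no route between nodes ", origin, " and ", dest)
  path <- integer(0); eids <- integer(0); v <- di
  while (v != oi) {
    path <- c(v, path)
    eids <- c(ctx$ex$eid[res$pedge[v] + 1L], eids)
    v <- res$parent[v] + 1L
  }
  path <- c(oi, path)
  structure(list(nodes = net$nodes$node_id[path],
                 entry_times = res$arrival[path],
                 total_time = res$arrival[di] - depart_time,
                 total_length = sum(net$edges$length_km[eids]),
                 priority = priority, depart_time = depart_time),
            class = "ems_route")
}

#' Shortest-time route between two nodes
#'
#' Computes the minimal-travel-time route for an ambulance departing at
#' `depart_time`. The speed of each edge is frozen at the moment the
#' ambulance enters the edge (rush-hour vs off-peak), which makes routes
#' deterministic.
#'
#' @param network an `ems_network`.
#' @param sm an `ems_speed_model`.
#' @param origin,dest node ids.
#' @param priority call priority, `"K"`, `"N"` or `"M"` (selects the speed
#'   context).
#' @param depart_time departure time in minutes (clock time is
#'   `depart_time mod 1440`).
#' @param ignore_built_up evaluate all edges as open road.
#' @return An object of class `ems_route` with fields `nodes` (ordered node
#'   ids), `entry_times` (time the ambulance reaches each node; the first is
#'   `depart_time`), `total_time` (min) and `total_length` (km).
#' @export
shortest_route <- function(network, sm, origin, dest, priority = "K",
                           depart_time = 0, ignore_built_up = FALSE) {
  ctx <- routing_context(network, sm, ignore_built_up)
  route_ctx(ctx, origin, dest, priority, depart_time)
}

#' @export
print.ems_route <- function(x, ...) {
  cat("<ems_route> ", length(x$nodes), " nodes, ",
      round(x$total_time, 2), " min, ", round(x$total_length, 2), " km\n",
      sep = "")
  invisible(x)
}

#' Travel-time matrix under a static speed context
#'
#' The matrix of shortest travel times \eqn{t_{ij}} (minutes) from candidate
#' locations to demand points, computed with a single fixed (priority, time
#' bucket) speed context so that the location model is well defined.
#'
#' @inheritParams shortest_route
#' @param origins,dests node id vectors.
#' @param time_bucket `"offpeak"` or `"rush"`.
#' @return Numeric matrix (minutes) with origin/destination node ids as
#'   dimnames. Unroutable pairs raise an error.
#' @export
travel_time_matrix <- function(network, sm, origins, dests, priority = "K",
                               time_bucket = "offpeak",
                               ignore_built_up = FALSE) {
  sp <- edge_speed_vectors(network, sm, priority, ignore_built_up)
  spd <- if (time_bucket == "rush") sp$rush else sp$off
  w <- network$edges$length_km / spd * 60
  oi <- node_index(network, origins)
  di <- node_index(network, dests)
  m <- igraph::distances(network$graph, v = oi, to = di, weights = w,
                         mode = "out")
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("no route between nodes ", origins[bad[1]], " and ", dests[bad[2]])
  }
  dimnames(m) <- list(as.character(origins), as.character(dests))
  m
}

#' Position of an ambulance along a route
#'
#' Linear interpolation along the frozen per-edge schedule of a route. Used
#' for re-dispatching an ambulance while it is en route to its base station:
#' travel estimates from an en-route position start at the next reachable
#' node.
#'
#' @param route an `ems_route`.
#' @param depart_time departure time of the route (defaults to the one the
#'   route was computed with).
#' @param query_time time at which the position is requested; must be `>=`
#'   `depart_time`.
#' @return A list with `node` (last node reached), `next_node` (`NA` once
#'   arrived), `edge` (`c(a, b)` or `NULL`), `offset` (fraction of the
#'   current edge already covered), `time_to_next` (minutes until the next
#'   node) and `arrived` (logical).
#' @export
position_en_route <- function(route, depart_time = route$depart_time,
                              query_time) {
  if (query_time < depart_time)
    stop("query_time precedes depart_time")
  et <- route$entry_times - route$depart_time + depart_time
  n <- length(route$nodes)
  if (query_time >= et[n] || n == 1L) {
    return(list(node = route$nodes[n], next_node = NA_integer_, edge = NULL,
                offset = 0, time_to_next = 0, arrived = TRUE))
  }
  k <- findInterval(query_time, et, rightmost.closed = FALSE)
  k <- max(1L, min(k, n - 1L))
  frac <- (query_time - et[k]) / (et[k + 1] - et[k])
  if (frac < 1e-12) {
    # exactly at an intermediate node: departures start here, not one
    # edge downstream
    return(list(node = route$nodes[k], next_node = route$nodes[k],
                edge = NULL, offset = 0, time_to_next = 0, arrived = FALSE))
  }
  list(node = route$nodes[k], next_node = route$nodes[k + 1],
       edge = c(route$nodes[k], route$nodes[k + 1]), offset = frac,
       time_to_next = et[k + 1] - query_time, arrived = FALSE)
}

# Length of the route actually driven when a vehicle is diverted at
# `query_time`: every edge up to and including the one in progress is
# completed (the vehicle diverts at the next node).
traversed_length <- function(network, route, query_time) {
  pos <- position_en_route(route, query_time = query_time)
  if (pos$arrived) return(route$total_length)
  upto <- match(pos$next_node, route$nodes)
  s <- 0
  for (k in seq_len(upto - 1L)) {
    a <- route$nodes[k]; b <- route$nodes[k + 1]
    hit <- which((network$edges$a == a & network$edges$b == b) |
                   (!network$directed &
                      network$edges$a == b & network$edges$b == a))[1]
    s <- s + network$edges$length_km[hit]
  }
  s
}
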