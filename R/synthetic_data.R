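# Self-contained synthetic country: road network, municipalities with
# heavy-tailed populations, tiered stations, hospitals and a call
# distribution with the statistical structure the analysis assumes
# (bimodal hour-of-day rate peaking at 9-11 and 18-21, flat day-of-week,
# urgent-call demand weights, Erlang hospital drop-offs).

#' Synthetic-country configuration
#'
#' @param n_municipalities number of municipalities.
#' @param total_population total inhabitants (allocated log-normally, so a
#'   few towns dominate, as in a mixed urban-rural country).
#' @param pop_sdlog log-sd of the municipal population distribution.
#' @param n_stations total stations (one ambulance each).
#' @param als_share share of ALS stations (default 86/274).
#' @param n_hospitals number of hospitals, placed in the largest towns.
#' @param n_towns number of municipalities treated as towns (built-up,
#'   candidates for within-town grid optimisation).
#' @param nodes_per_town,nodes_per_village road nodes per municipality.
#' @param area_km side of the square country in km.
#' @param calls_per_100k_day daily all-priority call rate per 100,000
#'   inhabitants (default 13, a realistic national EMS load).
#' @param priority_mix,diagnosis_probs,age_probs call attribute mixes
#'   (documented configuration; see [call_distribution()]).
#' @param seed integer seed fixing everything downstream.
#' @return An object of class `ems_country_config`.
#' @export
country_config <- function(n_municipalities = 10, total_population = 150000,
                           pop_sdlog = 1.1, n_stations = 8,
                           als_share = 86 / 274, n_hospitals = 2,
                           n_towns = 2, nodes_per_town = 9,
                           nodes_per_village = 3, area_km = 60,
                           calls_per_100k_day = 13,
                           priority_mix = c(K = 0.10, N = 0.45, M = 0.45),
                           diagnosis_probs = c(chest_pain = 0.07,
                                               severe_trauma = 0.05,
                                               stroke = 0.06,
                                               severe_respiratory = 0.05,
                                               cardiac_arrest = 0.02,
                                               other = 0.75),
                           age_probs = c(child = 0.08, adult = 0.92),
                           seed = 1L) {
  stopifnot(n_stations >= 1, als_share > 0, als_share < 1,
            n_municipalities >= 1, n_towns >= 1,
            n_towns <= n_municipalities, n_hospitals >= 1,
            n_hospitals <= n_municipalities, total_population > 0)
  structure(list(n_municipalities = n_municipalities,
                 total_population = total_population, pop_sdlog = pop_sdlog,
                 n_stations = n_stations, als_share = als_share,
                 n_hospitals = n_hospitals, n_towns = n_towns,
                 nodes_per_town = nodes_per_town,
                 nodes_per_village = nodes_per_village, area_km = area_km,
                 calls_per_100k_day = calls_per_100k_day,
                 priority_mix = priority_mix,
                 diagnosis_probs = diagnosis_probs, age_probs = age_probs,
                 seed = as.integer(seed)),
            class = "ems_country_config")
}

#' Desk-scale preset country
#'
#' Ten municipalities, eight stations, two hospitals: a minimal world on
#' which the full two-stage pipeline and the simulator run in seconds.
#'
#' @param seed integer seed.
#' @return An `ems_country_config`.
#' @export
preset_tiny <- function(seed = 1L) country_config(seed = seed)

#' Country-scale preset with the shape of a 5.4-million state
#'
#' 274 stations (86 ALS), 8 towns and 5.4 million inhabitants spread over
#' several hundred municipalities: the shape of the nationwide application
#' this methodology targets. Intended for desk experiments at scale, not
#' for the test suite.
#'
#' @param seed integer seed.
#' @return An `ems_country_config`.
#' @export
preset_country_scale <- function(seed = 1L) {
  country_config(n_municipalities = 300, total_population = 5.4e6,
                 pop_sdlog = 1.4, n_stations = 274, als_share = 86 / 274,
                 n_hospitals = 12, n_towns = 8, nodes_per_town = 16,
                 nodes_per_village = 2, area_km = 220, seed = seed)
}

#' Bimodal hour-of-day arrival profile
#'
#' Hourly rates with a morning peak at 9--11 and an evening peak at 18--21,
#' scaled so the 24 rates sum to `daily_total` calls per day.
#'
#' @param daily_total expected calls per day.
#' @return Numeric vector of 24 rates (calls/hour).
#' @export
bimodal_hourly_profile <- function(daily_total) {
  h <- 0:23
  shape <- 0.45 + 1.0 * exp(-((h - 10)^2) / (2 * 1.5^2)) +
    0.85 * exp(-((h - 19.5)^2) / (2 * 1.8^2))
  shape / sum(shape) * daily_total
}

# largest-remainder proportional allocation of n items by weight w
allocate_proportional <- function(n, w) {
  raw <- n * w / sum(w)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic country
#'
#' Builds a connected road network (local roads inside municipalities, a
#' spanning tree of main roads plus a few highways between them),
#' municipality demand zones, a population-proportional station deployment
#' with the configured ALS share, hospitals in the largest towns, and the
#' call distribution. Everything is reproducible from the configuration
#' seed.
#'
#' @param config an [country_config()].
#' @return An object of class `ems_country`: `network`, `municipalities`,
#'   `zones`, `stations`, `hospitals`, `dist`, `config`.
#' @export
generate_country <- function(config) {
  stopifnot(inherits(config, "ems_country_config"))
  set.seed(config$seed)
  nm <- config$n_municipalities
  L <- config$area_km

  # populations: heavy-tailed, scaled to the configured total
  pop <- rlnorm(nm, meanlog = 0, sdlog = config$pop_sdlog)
  pop <- round(pop / sum(pop) * config$total_population)
  pop[which.max(pop)] <- pop[which.max(pop)] +
    (config$total_population - sum(pop))
  ord <- order(pop, decreasing = TRUE)
  town <- seq_len(nm) %in% ord[seq_len(config$n_towns)]
  muni_names <- sprintf("M%02d", seq_len(nm))

  # municipality centres, then a cluster of road nodes around each
  cx <- runif(nm, 0.1 * L, 0.9 * L)
  cy <- runif(nm, 0.1 * L, 0.9 * L)
  nodes <- list(); next_id <- 1L
  central_node <- integer(nm)
  for (m in seq_len(nm)) {
    k <- if (town[m]) config$nodes_per_town else config$nodes_per_village
    rad <- if (town[m]) 1.8 else 0.7
    xs <- c(cx[m], cx[m] + rnorm(k - 1, sd = rad))
    ys <- c(cy[m], cy[m] + rnorm(k - 1, sd = rad))
    ids <- next_id:(next_id + k - 1L)
    central_node[m] <- ids[1]
    nodes[[m]] <- data.frame(node_id = ids, x_km = xs, y_km = ys,
                             built_up = town[m], municipality = muni_names[m],
                             stringsAsFactors = FALSE)
    next_id <- next_id + k
  }
  nodes <- do.call(rbind, nodes)

  # intra-municipality local roads: star to the central node plus a
  # nearest-neighbour link per node
  circuity <- 1.2
  edges <- list()
  for (m in seq_len(nm)) {
    nd <- nodes[nodes$municipality == muni_names[m], , drop = FALSE]
    if (nrow(nd) < 2) next
    star <- data.frame(a = nd$node_id[1], b = nd$node_id[-1])
    nn <- do.call(rbind, lapply(2:nrow(nd), function(i) {
      d <- sqrt((nd$x_km - nd$x_km[i])^2 + (nd$y_km - nd$y_km[i])^2)
      d[i] <- Inf
      data.frame(a = nd$node_id[i], b = nd$node_id[which.min(d)])
    }))
    e <- rbind(star, nn)
    e$category <- "local"
    edges[[length(edges) + 1L]] <- e
  }
  # inter-municipality roads: Euclidean minimum spanning tree over the
  # central nodes (guarantees one component), longest links upgraded to
  # highways, plus a second-nearest-neighbour link per municipality
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (nm > 1) {
    dmat <- as.matrix(dist(cbind(cx, cy)))
    g <- igraph::graph_from_adjacency_matrix(dmat, weighted = TRUE,
                                             mode = "undirected")
    me <- igraph::as_edgelist(igraph::mst(g))
    inter <- data.frame(a = central_node[as.integer(me[, 1])],
                        b = central_node[as.integer(me[, 2])])
    if (nm > 2) {
      nn2 <- do.call(rbind, lapply(seq_len(nm), function(m) {
        d <- dmat[m, ]; d[m] <- Inf
        data.frame(a = central_node[m],
                   b = central_node[order(d)[min(2, nm - 1)]])
      }))
      inter <- rbind(inter, nn2)
    }
    inter <- inter[!duplicated(key(inter$a, inter$b)), , drop = FALSE]
    xy <- nodes[match(c(inter$a, inter$b), nodes$node_id), c("x_km", "y_km")]
    half <- nrow(inter)
    ilen <- sqrt((xy$x_km[1:half] - xy$x_km[half + 1:half])^2 +
                   (xy$y_km[1:half] - xy$y_km[half + 1:half])^2)
    inter$category <- ifelse(ilen > stats::median(ilen), "highway", "main")
    edges[[length(edges) + 1L]] <- inter
  }
  edges <- do.call(rbind, edges)
  edges <- edges[!duplicated(key(edges$a, edges$b)), , drop = FALSE]
  exy_a <- nodes[match(edges$a, nodes$node_id), c("x_km", "y_km")]
  exy_b <- nodes[match(edges$b, nodes$node_id), c("x_km", "y_km")]
  edges$length_km <- pmax(0.05, circuity *
    sqrt((exy_a$x_km - exy_b$x_km)^2 + (exy_a$y_km - exy_b$y_km)^2))
  network <- road_network(nodes[c("node_id", "x_km", "y_km", "built_up")],
                          edges[c("a", "b", "length_km", "category")])
  assert_connected(network)

  municipalities <- data.frame(municipality = muni_names,
                               central_node = central_node,
                               population = pop, town = town,
                               x_km = cx, y_km = cy, stringsAsFactors = FALSE)

  # one municipality zone per municipality; the zone's road nodes are the
  # municipality's own nodes
  zone_nodes <- split(nodes$node_id, nodes$municipality)
  zdf <- data.frame(zone_id = muni_names, level = "municipality",
                    anchor_node = central_node, population = pop,
                    parent = NA_character_, stringsAsFactors = FALSE)
  zones <- demand_zones(zdf, zone_nodes[muni_names], network)

  # stations proportional to population (each municipality gets at least
  # its fair share by largest remainder); ALS units go to the most
  # populated municipalities first, round-robin
  n_per_muni <- allocate_proportional(config$n_stations, pop)
  if (sum(n_per_muni) != config$n_stations)
    stop("unsatisfiable station allocation")
  st <- list(); sid <- 1L
  for (m in seq_len(nm)) {
    if (n_per_muni[m] == 0) next
    st[[length(st) + 1L]] <- data.frame(
      station_id = sid:(sid + n_per_muni[m] - 1L),
      municipality = muni_names[m], node = central_node[m],
      type = "BLS", stringsAsFactors = FALSE)
    sid <- sid + n_per_muni[m]
  }
  stations <- do.call(rbind, st)
  n_als <- max(1L, as.integer(floor(config$n_stations * config$als_share + 0.5)))
  # round-robin: first station of each municipality by population rank,
  # then second stations, etc.
  rank1 <- unlist(lapply(seq_len(max(n_per_muni)), function(r)
    unlist(lapply(ord, function(m) {
      ids <- stations$station_id[stations$municipality == muni_names[m]]
      if (length(ids) >= r) ids[r] else NULL
    }))))
  stations$type[stations$station_id %in% rank1[seq_len(n_als)]] <- "ALS"

  # hospitals in the largest towns; the largest admits everyone
  hm <- ord[seq_len(config$n_hospitals)]
  hospitals <- data.frame(
    hospital_id = sprintf("H%d", seq_len(config$n_hospitals)),
    node = central_node[hm],
    admits = c("both", rep_len(c("adults", "both"),
                               config$n_hospitals - 1)),
    dropoff_shape = sample(2:5, config$n_hospitals, replace = TRUE),
    dropoff_mean = runif(config$n_hospitals, 14, 38),
    stringsAsFactors = FALSE)
  hospitals$specializations <- rep(list("all"), config$n_hospitals)

  daily <- config$total_population / 1e5 * config$calls_per_100k_day
  dist <- call_distribution(bimodal_hourly_profile(daily),
                            config$priority_mix, config$diagnosis_probs,
                            config$age_probs)

  structure(list(network = network, municipalities = municipalities,
                 zones = zones, stations = stations, hospitals = hospitals,
                 dist = dist, config = config),
            class = "ems_country")
}

#' @export
print.ems_country <- function(x, ...) {
  cat("<ems_country> ", nrow(x$municipalities), " municipalities, ",
      nrow(x$network$nodes), " road nodes, ", nrow(x$stations),
      " stations (", sum(x$stations$type == "ALS"), " ALS), ",
      nrow(x$hospitals), " hospitals, ",
      format(sum(x$municipalities$population), big.mark = ","),
      " inhabitants\n", sep = "")
  invisible(x)
}

#' Generate a synthetic historical call record
#'
#' Draws a call stream from the country's distribution and annotates it
#' with ISO-8601 timestamps so it round-trips through the calls CSV
#' dialect. The K+N subset of this record is what drives the location
#' model.
#'
#' @param country an [generate_country()] result.
#' @param days length of the record in days.
#' @param seed integer seed.
#' @param origin first day of the record.
#' @return Call data.frame with an extra `timestamp` column.
#' @export
generate_call_history <- function(country, days, seed = 1L,
                                  origin = "2020-01-01") {
  calls <- sample_call_stream(country$dist, country$zones, days, seed = seed)
  t0 <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  calls$timestamp <- format(t0 + calls$t_min * 60, "%Y-%m-%dT%H:%M:%S")
  calls
}
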