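# Fixture builders shared across the suite. All fixtures are generated in
# code; nothing is read from disk.

# speed model with rush == off-peak (time-invariant travel times)
static_speed_model <- function() {
  tab <- default_speed_table()
  off <- tab[tab$bucket == "offpeak", ]
  key <- function(d) paste(d$category, d$built_up, d$priority)
  tab$speed_kmh <- off$speed_kmh[match(key(tab), key(off))]
  speed_model(tab)
}

# straight-line road: n nodes, consecutive edges of the given lengths
line_network <- function(lengths_km, category = "main", built_up = FALSE) {
  n <- length(lengths_km) + 1L
  road_network(
    data.frame(node_id = 1:n, x_km = c(0, cumsum(lengths_km)), y_km = 0,
               built_up = built_up),
    data.frame(a = 1:(n - 1), b = 2:n, length_km = lengths_km,
               category = category))
}

# connected random geometric graph for routing tests
random_network <- function(n_nodes, seed, built_up_frac = 0.3) {
  set.seed(seed)
  x <- runif(n_nodes, 0, 20); y <- runif(n_nodes, 0, 20)
  d <- as.matrix(dist(cbind(x, y)))
  g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                           mode = "undirected")
  mst <- igraph::as_edgelist(igraph::mst(g))
  edges <- data.frame(a = as.integer(mst[, 1]), b = as.integer(mst[, 2]))
  for (i in seq_len(n_nodes)) {   # add a 2nd-nearest link per node
    dd <- d[i, ]; dd[i] <- Inf
    j <- order(dd)[2]
    edges <- rbind(edges, data.frame(a = i, b = j))
  }
  key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  edges <- edges[!duplicated(key), ]
  edges$length_km <- pmax(0.1, d[cbind(edges$a, edges$b)])
  edges$category <- sample(c("highway", "main", "local"), nrow(edges),
                           replace = TRUE)
  road_network(
    data.frame(node_id = 1:n_nodes, x_km = x, y_km = y,
               built_up = runif(n_nodes) < built_up_frac),
    edges)
}

# one-municipality world on a line: station at node 1, scene node 2,
# hospital at node 3; all durations controllable
micro_world <- function(types = "BLS",
                        leg1_km = 7, leg2_km = 10) {
  net <- line_network(c(leg1_km, leg2_km))
  zones <- demand_zones(
    data.frame(zone_id = "Z", level = "municipality", anchor_node = 2,
               population = 100, parent = NA_character_,
               stringsAsFactors = FALSE),
    list(Z = 2L), net)
  deployment <- data.frame(station_id = seq_along(types), node = 1,
                           type = types, stringsAsFactors = FALSE)
  hospitals <- data.frame(hospital_id = "H1", node = 3, admits = "both",
                          dropoff_shape = Inf, dropoff_mean = 15,
                          stringsAsFactors = FALSE)
  list(net = net, zones = zones, deployment = deployment,
       hospitals = hospitals, sm = static_speed_model())
}

# call stream data.frame with the columns the simulator expects
manual_stream <- function(t_min, node, priority,
                          diagnosis = "other", age_class = "adult",
                          zone_id = "Z") {
  n <- length(t_min)
  data.frame(call_id = seq_len(n), t_min = t_min,
             zone_id = rep_len(zone_id, n), node = rep_len(node, n),
             priority = rep_len(priority, n),
             diagnosis = rep_len(diagnosis, n),
             age_class = rep_len(age_class, n), stringsAsFactors = FALSE)
}

# deterministic durations: constant on-scene times, fixed transport draws
deterministic_config <- function(horizon_days = 1, onscene = 20,
                                 transport = 0, seed = 1L, ...) {
  means <- default_onscene_means()
  means[] <- onscene
  simulation_config(horizon_days = horizon_days, replications = 1,
                    seed = seed, p_support = 0,
                    transport_prob = c(BLS = transport, ALS = transport),
                    onscene_means = means, onscene_sdlog = 0, ...)
}
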