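# Plain-text interchange: CSV for nodes/edges/calls/zones/stations/
# deployments, YAML for speed tables, JSON for reports.

#' Read and write a road network as CSV
#'
#' Nodes CSV: `node_id, x_km, y_km, built_up`; edges CSV:
#' `a, b, length_km, category`.
#'
#' @param nodes_file,edges_file file paths.
#' @param directed directedness flag.
#' @return [road_network()] object.
#' @export
read_network_csv <- function(nodes_file, edges_file, directed = FALSE) {
  road_network(read.csv(nodes_file, stringsAsFactors = FALSE),
               read.csv(edges_file, stringsAsFactors = FALSE), directed)
}

#' @rdname read_network_csv
#' @param network an `ems_network`.
#' @export
write_network_csv <- function(network, nodes_file, edges_file) {
  write.csv(network$nodes, nodes_file, row.names = FALSE)
  write.csv(network$edges, edges_file, row.names = FALSE)
  invisible(c(nodes_file, edges_file))
}

#' Read and write call records as CSV
#'
#' Dialect: `timestamp` (ISO-8601), `zone_id` or `node`, `priority`
#' (K/N/M), `diagnosis`, `age_class`; internal minute offsets `t_min` are
#' preserved when present.
#'
#' @param file path.
#' @return Call data.frame.
#' @export
read_calls_csv <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname read_calls_csv
#' @param calls call data.frame.
#' @export
write_calls_csv <- function(calls, file) {
  write.csv(calls, file, row.names = FALSE)
  invisible(file)
}

#' Read and write demand zones as CSV
#'
#' Columns `zone_id, level, anchor_node, population, parent, nodes`, where
#' `nodes` holds the zone's road nodes joined by `;`.
#'
#' @param file path.
#' @param network optional network to validate anchors against.
#' @return `ems_zones` object.
#' @export
read_zones_csv <- function(file, network = NULL) {
  z <- read.csv(file, stringsAsFactors = FALSE)
  zone_nodes <- lapply(strsplit(z$nodes, ";", fixed = TRUE), as.integer)
  names(zone_nodes) <- z$zone_id
  z$nodes <- NULL
  if ("parent" %in% names(z)) z$parent <- as.character(z$parent)
  demand_zones(z, zone_nodes, network)
}

#' @rdname read_zones_csv
#' @param zones `ems_zones`.
#' @export
write_zones_csv <- function(zones, file) {
  z <- as.data.frame(zones)
  z$nodes <- vapply(z$nodes, paste, character(1), collapse = ";")
  keep <- c("zone_id", "level", "anchor_node", "population", "parent", "nodes")
  write.csv(z[keep], file, row.names = FALSE)
  invisible(file)
}

#' Read and write station tables as CSV
#'
#' Columns `station_id, municipality, node, type`.
#'
#' @param file path.
#' @return Station data.frame.
#' @export
read_stations_csv <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname read_stations_csv
#' @param stations station data.frame.
#' @export
write_stations_csv <- function(stations, file) {
  write.csv(stations, file, row.names = FALSE)
  invisible(file)
}

#' Read and write a speed model as YAML
#'
#' @param file path.
#' @return `ems_speed_model`.
#' @export
read_speed_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  tab <- do.call(rbind, lapply(y$speeds, as.data.frame))
  tab$built_up <- as.logical(tab$built_up)
  rw <- do.call(rbind, lapply(y$rush_windows, unlist))
  speed_model(tab, rw)
}

#' @rdname read_speed_yaml
#' @param sm `ems_speed_model`.
#' @export
write_speed_yaml <- function(sm, file) {
  yaml::write_yaml(list(
    speeds = lapply(seq_len(nrow(sm$table)), function(i)
      as.list(sm$table[i, ])),
    rush_windows = lapply(seq_len(nrow(sm$rush_windows)), function(i)
      as.numeric(sm$rush_windows[i, ]))), file)
  invisible(file)
}

#' Write an indicator report as JSON
#'
#' @param report an `ems_report` or any list of numbers.
#' @param file path.
#' @export
write_report_json <- function(report, file) {
  if (inherits(report, "ems_report"))
    report <- setNames(as.list(report$mean), report$indicator)
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
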