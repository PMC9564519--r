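# Agent-based discrete-event simulation of tiered ambulance operations.
#
# Every station houses exactly one ambulance. An ambulance is dispatchable
# while idle at base or while returning to base (it can be re-dispatched en
# route); travel uses shortest-time routes with frozen per-edge-entry
# speeds. Calls not dispatchable immediately wait in a strict-priority
# (K > N > M, FIFO within class) queue that is re-examined at every
# ambulance-release event.

#' Default on-scene duration means (minutes)
#'
#' Mean on-scene times by diagnosis and crew type, in the 20--30 minute
#' band, with BLS crews spending at least as long on scene as ALS crews.
#' Rows are diagnoses (the First Hour Quintet plus `other`), columns crew
#' types.
#'
#' @return Numeric matrix with columns `BLS` and `ALS`.
#' @export
default_onscene_means <- function() {
  m <- rbind(chest_pain = c(26, 23),
             severe_trauma = c(30, 26),
             stroke = c(27, 24),
             severe_respiratory = c(25, 22),
             cardiac_arrest = c(30, 27),
             other = c(22, 20))
  colnames(m) <- c("BLS", "ALS")
  m
}

#' Simulation configuration
#'
#' @param horizon_days length of one replication (default 91 days).
#' @param replications number of independent replications (default 10).
#' @param seed master seed; per-replication seeds are derived from it.
#' @param p_support probability that an N-call crew requests a supporting
#'   ALS ambulance when it starts on-scene care.
#' @param tau_M travel-time threshold (minutes) beyond which an M call is
#'   "too far" for the closest BLS and a closer ALS may respond instead.
#' @param transport_prob named probabilities of hospital transport by crew
#'   type (defaults: BLS 0.71, ALS 0.53).
#' @param onscene_means matrix of on-scene means as in
#'   [default_onscene_means()].
#' @param onscene_sdlog log-sd of the lognormal on-scene time (0 makes the
#'   duration deterministic at its mean, which is useful for validation).
#' @return An object of class `ems_sim_config`.
#' @export
simulation_config <- function(horizon_days = 91, replications = 10,
                              seed = 1L, p_support = 0.1, tau_M = 25,
                              transport_prob = c(BLS = 0.71, ALS = 0.53),
                              onscene_means = default_onscene_means(),
                              onscene_sdlog = 0.35) {
  stopifnot(horizon_days > 0, replications >= 1,
            p_support >= 0, p_support <= 1, tau_M >= 0,
            all(transport_prob >= 0), all(transport_prob <= 1),
            all(c("BLS", "ALS") %in% names(transport_prob)),
            is.matrix(onscene_means),
            all(c("BLS", "ALS") %in% colnames(onscene_means)),
            onscene_sdlog >= 0)
  structure(list(horizon_days = horizon_days, replications = replications,
                 seed = as.integer(seed), p_support = p_support,
                 tau_M = tau_M, transport_prob = transport_prob,
                 onscene_means = onscene_means,
                 onscene_sdlog = onscene_sdlog),
            class = "ems_sim_config")
}

# lowest-id tie-break key: numeric when all ids parse as numbers
id_order_key <- function(ids) {
  n <- suppressWarnings(as.numeric(ids))
  if (anyNA(n)) ids else n
}

#' Dispatch policy kernel
#'
#' Pure decision rule applied to the currently available ambulances.
#' Priority K: the closest available ambulance regardless of type; if it is
#' a BLS, the closest available ALS is dispatched concurrently. Priority N:
#' the closest available BLS (ALS support may be requested later, on scene).
#' Priority M: the closest available BLS, unless it is farther than `tau_M`
#' minutes and a closer ALS is available, in which case the ALS responds;
#' with no BLS available at all, the closest ALS responds. Ties are broken
#' by lowest ambulance id.
#'
#' @param priority `"K"`, `"N"` or `"M"`.
#' @param est named numeric vector: estimated travel time (minutes) of each
#'   available ambulance, names are ambulance ids.
#' @param type character vector of the same length: `"BLS"`/`"ALS"`.
#' @param tau_M "too far" threshold for M calls, in minutes.
#' @return List with `primary` (ambulance id, or `NA` to queue the call)
#'   and `dual_als` (`TRUE` when a concurrent ALS dispatch is required).
#' @export
dispatch_policy <- function(priority, est, type, tau_M = 25) {
  pick <- function(sel) {
    if (!any(sel)) return(NA_character_)
    ids <- names(est)[sel]
    ids[order(est[sel], id_order_key(ids))][1]
  }
  if (length(est) == 0) return(list(primary = NA_character_, dual_als = FALSE))
  if (priority == "K") {
    prim <- pick(rep(TRUE, length(est)))
    return(list(primary = prim,
                dual_als = type[match(prim, names(est))] == "BLS"))
  }
  bls <- pick(type == "BLS")
  if (priority == "N") return(list(primary = bls, dual_als = FALSE))
  # priority M
  als <- pick(type == "ALS")
  if (is.na(bls)) return(list(primary = als, dual_als = FALSE))
  if (est[bls] > tau_M && !is.na(als) && est[als] < est[bls])
    return(list(primary = als, dual_als = FALSE))
  list(primary = bls, dual_als = FALSE)
}

validate_deployment <- function(deployment, network) {
  stopifnot(all(c("station_id", "node", "type") %in% names(deployment)))
  if (anyDuplicated(deployment$station_id)) stop("duplicate station ids")
  if (!all(deployment$type %in% c("ALS", "BLS"))) stop("unknown station type")
  node_index(network, deployment$node)
  invisible(TRUE)
}

validate_hospitals <- function(hospitals, network) {
  need <- c("hospital_id", "node", "admits", "dropoff_shape", "dropoff_mean")
  stopifnot(all(need %in% names(hospitals)))
  if (!all(hospitals$admits %in% c("adults", "children", "both")))
    stop("hospital admits must be adults/children/both")
  if (any(hospitals$dropoff_shape < 1)) stop("Erlang shape must be >= 1")
  if (any(hospitals$dropoff_mean <= 0)) stop("drop-off means must be > 0")
  node_index(network, hospitals$node)
  invisible(TRUE)
}

hospital_admissible <- function(hospitals, age_class, diagnosis) {
  age_ok <- if (age_class == "child") hospitals$admits %in% c("children", "both")
    else hospitals$admits %in% c("adults", "both")
  spec_ok <- rep(TRUE, nrow(hospitals))
  if ("specializations" %in% names(hospitals)) {
    spec_ok <- vapply(hospitals$specializations, function(s) {
      is.null(s) || length(s) == 0 || any(is.na(s)) || "all" %in% s ||
        diagnosis %in% s
    }, logical(1))
  }
  which(age_ok & spec_ok)
}

#' Run one simulation replication
#'
#' Simulates tiered ambulance operations under a given station deployment:
#' non-homogeneous Poisson call arrivals (or a pre-drawn stream), the
#' priority-dependent dispatch policy with dual ALS dispatch on K calls,
#' diagnosis/crew-dependent on-scene times, type-dependent hospital
#' transport, Erlang drop-off at the nearest admissible hospital, and
#' en-route re-dispatch of returning ambulances. The run is reproducible
#' from its seed.
#'
#' @param deployment data.frame `station_id`, `node`, `type`; one ambulance
#'   per station.
#' @param demand either a call stream data.frame (as from
#'   [sample_call_stream()]) or an [call_distribution()] (then `zones` is
#'   required).
#' @param config an [simulation_config()].
#' @param network,sm road network and speed model.
#' @param hospitals hospital table (`hospital_id`, `node`, `admits`,
#'   optional `specializations` list column, `dropoff_shape`,
#'   `dropoff_mean`); `dropoff_shape = Inf` gives a deterministic drop-off.
#' @param zones demand zones, required when `demand` is a distribution.
#' @param seed replication seed.
#' @return An object of class `ems_simlog`: the annotated `calls` table,
#'   per-ambulance statistics, the event log, and the horizon.
#' @export
run_replication <- function(deployment, demand, config, network, sm,
                            hospitals, zones = NULL, seed = config$seed) {
  stopifnot(inherits(config, "ems_sim_config"))
  validate_deployment(deployment, network)
  validate_hospitals(hospitals, network)
  set.seed(seed)
  horizon_min <- config$horizon_days * 1440

  stream <- if (is.data.frame(demand)) demand else {
    if (is.null(zones)) stop("zones required when demand is a distribution")
    sample_call_stream(demand, zones, config$horizon_days)
  }
  n_call <- nrow(stream)
  diag_key <- ifelse(stream$diagnosis %in% rownames(config$onscene_means),
                     stream$diagnosis, "other")
  if (!all(diag_key %in% rownames(config$onscene_means)))
    stop("no on-scene distribution for diagnosis ",
         paste(setdiff(unique(stream$diagnosis),
                       rownames(config$onscene_means)), collapse = ", "))

  ctx <- routing_context(network, sm)
  all_ids <- network$nodes$node_id
  D <- lapply(setNames(c("K", "N", "M"), c("K", "N", "M")), function(p)
    list(offpeak = travel_time_matrix(network, sm, all_ids, all_ids, p, "offpeak"),
         rush = travel_time_matrix(network, sm, all_ids, all_ids, p, "rush")))
  nid <- as.character(all_ids)
  rw <- sm$rush_windows
  bucket_of <- function(t) {
    tod <- t %% 1440
    if (any(tod >= rw[, 1] & tod < rw[, 2])) "rush" else "offpeak"
  }

  m <- nrow(deployment)
  amb_id <- as.character(deployment$station_id)
  amb_base <- as.integer(deployment$node)
  amb_type <- deployment$type
  amb_state <- rep("idle_at_base", m)
  amb_node <- amb_base
  amb_next_t <- rep(Inf, m)
  amb_next_ev <- rep(NA_character_, m)
  amb_call <- rep(NA_integer_, m)
  amb_role <- rep(NA_character_, m)
  amb_busy_since <- rep(NA_real_, m)
  amb_busy <- rep(0, m)
  amb_km <- rep(0, m)
  amb_jobs <- rep(0L, m)
  routes <- vector("list", m)

  c_assign <- c_scene <- c_scene_dep <- c_hosp <- c_clear <- rep(NA_real_, n_call)
  c_transported <- rep(NA, n_call)
  c_hospital <- rep(NA_character_, n_call)
  c_primary <- c_support <- rep(NA_character_, n_call)
  c_support_drawn <- rep(FALSE, n_call)
  c_censored <- rep(FALSE, n_call)

  qK <- qN <- qM <- integer(0)
  censored_done <- FALSE

  ev_cap <- max(64L, n_call * 12L)
  ev_t <- numeric(ev_cap); ev_type <- character(ev_cap)
  ev_call <- integer(ev_cap); ev_amb <- character(ev_cap)
  ev_node <- integer(ev_cap); ev_n <- 0L
  log_ev <- function(t, type, call = NA_integer_, amb = NA_character_,
                     node = NA_integer_) {
    ev_n <<- ev_n + 1L
    if (ev_n > length(ev_t)) {
      grow <- length(ev_t)
      ev_t <<- c(ev_t, numeric(grow)); ev_type <<- c(ev_type, character(grow))
      ev_call <<- c(ev_call, integer(grow)); ev_amb <<- c(ev_amb, character(grow))
      ev_node <<- c(ev_node, integer(grow))
    }
    ev_t[ev_n] <<- t; ev_type[ev_n] <<- type; ev_call[ev_n] <<- call
    ev_amb[ev_n] <<- amb; ev_node[ev_n] <<- node
  }

  add_busy <- function(a, from, to) {
    amb_busy[a] <<- amb_busy[a] + max(0, min(to, horizon_min) -
                                        min(from, horizon_min))
  }

  est_time <- function(a, scene, pri, now) {
    Dm <- D[[pri]][[bucket_of(now)]]
    if (amb_state[a] == "idle_at_base")
      return(Dm[nid[match(amb_node[a], all_ids)], nid[match(scene, all_ids)]])
    pos <- position_en_route(routes[[a]], query_time = now)
    if (pos$arrived)
      return(Dm[nid[match(pos$node, all_ids)], nid[match(scene, all_ids)]])
    pos$time_to_next +
      Dm[nid[match(pos$next_node, all_ids)], nid[match(scene, all_ids)]]
  }

  start_leg <- function(a, to, pri, now) {
    if (amb_state[a] %in% c("returning")) {
      pos <- position_en_route(routes[[a]], query_time = now)
      if (pos$arrived) {
        amb_km[a] <<- amb_km[a] + routes[[a]]$total_length
        origin <- pos$node; depart <- now
      } else {
        amb_km[a] <<- amb_km[a] + traversed_length(network, routes[[a]], now)
        origin <- pos$next_node; depart <- now + pos$time_to_next
      }
    } else {
      origin <- amb_node[a]; depart <- now
    }
    r <- route_ctx(ctx, origin, to, pri, depart)
    routes[[a]] <<- r
    amb_next_t[a] <<- depart + r$total_time
    invisible(r)
  }

  start_return <- function(a, from, now) {
    amb_node[a] <<- from
    r <- route_ctx(ctx, from, amb_base[a], "M", now)
    routes[[a]] <<- r
    amb_state[a] <<- "returning"
    amb_call[a] <<- NA_integer_
    amb_role[a] <<- NA_character_
    amb_next_t[a] <<- now + r$total_time
    amb_next_ev[a] <<- "arrive_base"
    log_ev(now, "return", amb = amb_id[a], node = from)
  }

  dispatch_one <- function(a, cid, role, now) {
    if (amb_state[a] == "idle_at_base") amb_busy_since[a] <<- now
    scene <- stream$node[cid]
    log_ev(now, "assign", cid, amb_id[a], scene)
    start_leg(a, scene, stream$priority[cid], now)
    amb_state[a] <<- "to_scene"
    amb_next_ev[a] <<- "arrive_scene"
    amb_call[a] <<- cid
    amb_role[a] <<- role
    amb_jobs[a] <<- amb_jobs[a] + 1L
    if (role == "primary") { c_primary[cid] <<- amb_id[a]; c_assign[cid] <<- now }
    else { c_support[cid] <<- amb_id[a] }
  }

  dispatch_support_als <- function(cid, now) {
    avail <- which(amb_state %in% c("idle_at_base", "returning") &
                     amb_type == "ALS")
    if (!length(avail)) return(invisible(FALSE))
    est <- vapply(avail, est_time, numeric(1),
                  scene = stream$node[cid], pri = stream$priority[cid],
                  now = now)
    a <- avail[order(est, id_order_key(amb_id[avail]))][1]
    dispatch_one(a, cid, "support", now)
    invisible(TRUE)
  }

  try_dispatch <- function(cid, now) {
    avail <- which(amb_state %in% c("idle_at_base", "returning"))
    if (!length(avail)) return(FALSE)
    pri <- stream$priority[cid]
    est <- vapply(avail, est_time, numeric(1),
                  scene = stream$node[cid], pri = pri, now = now)
    names(est) <- amb_id[avail]
    dec <- dispatch_policy(pri, est, amb_type[avail], config$tau_M)
    if (is.na(dec$primary)) return(FALSE)
    dispatch_one(match(dec$primary, amb_id), cid, "primary", now)
    if (isTRUE(dec$dual_als)) dispatch_support_als(cid, now)
    TRUE
  }

  process_queue <- function(now) {
    repeat {
      if (length(qK)) {
        if (try_dispatch(qK[1], now)) { qK <<- qK[-1]; next } else break
      } else if (length(qN)) {
        if (try_dispatch(qN[1], now)) { qN <<- qN[-1]; next } else break
      } else if (length(qM)) {
        if (try_dispatch(qM[1], now)) { qM <<- qM[-1]; next } else break
      } else break
    }
  }

  onscene_draw <- function(cid, crew) {
    mu <- config$onscene_means[diag_key[cid], crew]
    if (config$onscene_sdlog == 0) return(mu)
    rlnorm(1, meanlog = log(mu) - config$onscene_sdlog^2 / 2,
           sdlog = config$onscene_sdlog)
  }

  handle_amb_event <- function(a, now) {
    ev <- amb_next_ev[a]
    amb_next_t[a] <<- Inf
    cid <- amb_call[a]
    if (ev == "arrive_scene") {
      scene <- stream$node[cid]
      amb_node[a] <<- scene
      amb_km[a] <<- amb_km[a] + routes[[a]]$total_length
      log_ev(now, "arrive_scene", cid, amb_id[a], scene)
      c_scene[cid] <<- min(c_scene[cid], now, na.rm = TRUE)
      if (amb_role[a] == "primary") {
        amb_state[a] <<- "on_scene"
        if (stream$priority[cid] == "N" && !c_support_drawn[cid]) {
          c_support_drawn[cid] <<- TRUE
          if (runif(1) < config$p_support) dispatch_support_als(cid, now)
        }
        dur <- onscene_draw(cid, amb_type[a])
        amb_next_t[a] <<- now + dur
        amb_next_ev[a] <<- "scene_depart"
      } else {
        # support: wait until the primary leaves the scene (never cancelled)
        amb_state[a] <<- "on_scene"
        if (!is.na(c_scene_dep[cid]) && c_scene_dep[cid] <= now) {
          start_return(a, scene, now)
          process_queue(now)
        }
      }
    } else if (ev == "scene_depart") {
      scene <- stream$node[cid]
      log_ev(now, "scene_depart", cid, amb_id[a], scene)
      c_scene_dep[cid] <<- now
      # release a waiting support ambulance
      s <- c_support[cid]
      if (!is.na(s)) {
        si <- match(s, amb_id)
        if (amb_state[si] == "on_scene") start_return(si, scene, now)
      }
      transported <- runif(1) < config$transport_prob[amb_type[a]]
      c_transported[cid] <<- transported
      if (transported) {
        adm <- hospital_admissible(hospitals, stream$age_class[cid],
                                   stream$diagnosis[cid])
        if (!length(adm))
          stop("no admissible hospital for diagnosis ", stream$diagnosis[cid],
               ", age class ", stream$age_class[cid])
        Dm <- D[[stream$priority[cid]]][[bucket_of(now)]]
        ht <- Dm[nid[match(scene, all_ids)],
                 nid[match(hospitals$node[adm], all_ids)]]
        h <- adm[order(ht, as.character(hospitals$hospital_id[adm]))][1]
        c_hospital[cid] <<- as.character(hospitals$hospital_id[h])
        amb_state[a] <<- "to_hospital"
        start_leg(a, hospitals$node[h], stream$priority[cid], now)
        amb_next_ev[a] <<- "arrive_hospital"
      } else {
        c_clear[cid] <<- now
        start_return(a, scene, now)
        process_queue(now)
      }
    } else if (ev == "arrive_hospital") {
      h <- match(c_hospital[cid], as.character(hospitals$hospital_id))
      amb_node[a] <<- hospitals$node[h]
      amb_km[a] <<- amb_km[a] + routes[[a]]$total_length
      log_ev(now, "arrive_hospital", cid, amb_id[a], hospitals$node[h])
      c_hosp[cid] <<- now
      amb_state[a] <<- "at_hospital"
      shape <- hospitals$dropoff_shape[h]
      drop <- if (is.infinite(shape)) hospitals$dropoff_mean[h] else
        rgamma(1, shape = shape, rate = shape / hospitals$dropoff_mean[h])
      amb_next_t[a] <<- now + drop
      amb_next_ev[a] <<- "dropoff_done"
    } else if (ev == "dropoff_done") {
      h <- match(c_hospital[cid], as.character(hospitals$hospital_id))
      log_ev(now, "dropoff_done", cid, amb_id[a], hospitals$node[h])
      c_clear[cid] <<- now
      start_return(a, hospitals$node[h], now)
      process_queue(now)
    } else if (ev == "arrive_base") {
      amb_state[a] <<- "idle_at_base"
      amb_node[a] <<- amb_base[a]
      amb_km[a] <<- amb_km[a] + routes[[a]]$total_length
      routes[a] <<- list(NULL)
      log_ev(now, "arrive_base", amb = amb_id[a], node = amb_base[a])
      add_busy(a, amb_busy_since[a], now)
      amb_busy_since[a] <<- NA_real_
    } else stop("unknown event ", ev)
  }

  ai <- 1L
  repeat {
    t_arr <- if (ai <= n_call) stream$t_min[ai] else Inf
    t_amb <- if (m) min(amb_next_t) else Inf
    tmin <- min(t_arr, t_amb)
    if (!is.finite(tmin)) break
    if (!censored_done && tmin > horizon_min) {
      for (cid in c(qK, qN, qM)) {
        c_censored[cid] <- TRUE
        log_ev(horizon_min, "censored", cid, node = stream$node[cid])
      }
      qK <- qN <- qM <- integer(0)
      censored_done <- TRUE
    }
    if (t_amb <= t_arr) {
      a <- which.min(amb_next_t)
      handle_amb_event(a, t_amb)
    } else {
      cid <- ai; ai <- ai + 1L
      log_ev(t_arr, "arrival", cid, node = stream$node[cid])
      if (!try_dispatch(cid, t_arr)) {
        if (stream$priority[cid] == "K") qK <- c(qK, cid)
        else if (stream$priority[cid] == "N") qN <- c(qN, cid)
        else qM <- c(qM, cid)
      }
    }
  }
  # ambulances mid-activity when events ran out cannot occur (the loop
  # drains); a remaining queue means there were no ambulances at all
  for (cid in c(qK, qN, qM)) {
    c_censored[cid] <- TRUE
    log_ev(horizon_min, "censored", cid, node = stream$node[cid])
  }

  calls <- stream
  calls$t_assign <- c_assign
  calls$t_scene <- c_scene
  calls$t_scene_depart <- c_scene_dep
  calls$t_hospital <- c_hosp
  calls$t_clear <- c_clear
  calls$response_time <- c_scene - c_assign
  calls$transported <- c_transported
  calls$hospital <- c_hospital
  calls$primary_amb <- c_primary
  calls$support_amb <- c_support
  calls$censored <- c_censored

  ambulances <- data.frame(
    station_id = amb_id, node = amb_base, type = amb_type,
    busy_min = amb_busy, km = amb_km, n_jobs = amb_jobs,
    workload_pct = 100 * amb_busy / horizon_min, stringsAsFactors = FALSE)

  events <- data.frame(time = ev_t[seq_len(ev_n)],
                       event = ev_type[seq_len(ev_n)],
                       call_id = ev_call[seq_len(ev_n)],
                       amb_id = ev_amb[seq_len(ev_n)],
                       node = ev_node[seq_len(ev_n)],
                       stringsAsFactors = FALSE)

  structure(list(calls = calls, ambulances = ambulances, events = events,
                 horizon_min = horizon_min, seed = seed),
            class = "ems_simlog")
}

#' @export
print.ems_simlog <- function(x, ...) {
  cat("<ems_simlog> ", nrow(x$calls), " calls over ",
      x$horizon_min / 1440, " days, ", nrow(x$ambulances),
      " ambulances, ", sum(x$calls$censored), " censored\n", sep = "")
  invisible(x)
}

#' Run independent simulation replications
#'
#' Derives one seed per replication from the master seed in `config` and
#' runs [run_replication()] with independent demand streams.
#'
#' @inheritParams run_replication
#' @return List of `ems_simlog` objects, class `ems_simlogs`.
#' @export
run_replications <- function(deployment, demand, config, network, sm,
                             hospitals, zones = NULL) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$replications)
  out <- lapply(seeds, function(s)
    run_replication(deployment, demand, config, network, sm, hospitals,
                    zones, seed = s))
  class(out) <- "ems_simlogs"
  out
}
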