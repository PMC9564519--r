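test_that("dispatch policy implements the tiered rules", {
  est <- c("1" = 5, "2" = 8, "3" = 12)
  # K: closest regardless of type; ALS closest -> single dispatch
  d <- dispatch_policy("K", est, c("ALS", "BLS", "ALS"))
  expect_equal(d$primary, "1")
  expect_false(d$dual_als)
  # K: closest is BLS -> concurrent ALS dispatch
  d2 <- dispatch_policy("K", est, c("BLS", "ALS", "ALS"))
  expect_equal(d2$primary, "1")
  expect_true(d2$dual_als)
  # N: closest BLS even when an ALS is nearer
  d3 <- dispatch_policy("N", est, c("ALS", "BLS", "BLS"))
  expect_equal(d3$primary, "2")
  # M: BLS within tau_M wins; beyond tau_M a closer ALS takes over
  d4 <- dispatch_policy("M", c("1" = 30, "2" = 10), c("BLS", "ALS"),
                        tau_M = 25)
  expect_equal(d4$primary, "2")
  d5 <- dispatch_policy("M", c("1" = 20, "2" = 10), c("BLS", "ALS"),
                        tau_M = 25)
  expect_equal(d5$primary, "1")
  # nobody available -> queue
  expect_true(is.na(dispatch_policy("K", numeric(0), character(0))$primary))
  # ties broken by lowest id
  d6 <- dispatch_policy("K", c("7" = 5, "2" = 5), c("ALS", "ALS"))
  expect_equal(d6$primary, "2")
})

test_that("zero demand yields an empty log with zero mileage", {
  w <- micro_world()
  cfg <- deterministic_config()
  log <- run_replication(w$deployment, manual_stream(numeric(0), integer(0),
                                                     character(0)),
                         cfg, w$net, w$sm, w$hospitals, seed = 1)
  expect_equal(nrow(log$events), 0)
  expect_equal(sum(log$ambulances$km), 0)
  expect_equal(sum(log$ambulances$busy_min), 0)
})

test_that("a hand-traced transported call has additive timestamps", {
  # travel 7 min (7 km main @60), scene 20, to-hospital 10, drop-off 15:
  # clear = arrival + 52 min
  w <- micro_world()
  cfg <- deterministic_config(onscene = 20, transport = 1)
  log <- run_replication(w$deployment, manual_stream(100, 2, "N"),
                         cfg, w$net, w$sm, w$hospitals, seed = 1)
  cc <- log$calls
  expect_equal(cc$t_assign, 100)
  expect_equal(cc$t_scene, 107)
  expect_equal(cc$response_time, 7)
  expect_equal(cc$t_scene_depart, 127)
  expect_equal(cc$t_hospital, 137)
  expect_equal(cc$t_clear, 152)
  expect_true(cc$transported)
  expect_equal(cc$hospital, "H1")
})

test_that("a non-transported call returns straight to base", {
  w <- micro_world()
  cfg <- deterministic_config(onscene = 20, transport = 0)
  log <- run_replication(w$deployment, manual_stream(0, 2, "N"),
                         cfg, w$net, w$sm, w$hospitals, seed = 1)
  cc <- log$calls
  expect_equal(cc$t_clear, 27)
  expect_false(cc$transported)
  expect_true(is.na(cc$t_hospital))
  expect_false("arrive_hospital" %in% log$events$event)
  # mileage: 7 km out + 7 km home
  expect_equal(sum(log$ambulances$km), 14)
})

test_that("an overlapping call waits for the release and is served en route", {
  # second call's assignment time equals the first call's release
  # (drop-off completion), and the ambulance is re-dispatched from the
  # hospital node without returning to base
  w <- micro_world()
  cfg <- deterministic_config(onscene = 20, transport = 1)
  log <- run_replication(w$deployment, manual_stream(c(0, 10), 2, "N"),
                         cfg, w$net, w$sm, w$hospitals, seed = 1)
  cc <- log$calls
  expect_equal(cc$t_clear[1], 52)
  expect_equal(cc$t_assign[2], 52)           # release of call 1
  # from the hospital (node 3) the scene is 10 km of main road at the
  # N-priority speed of 60 km/h
  expect_equal(cc$t_scene[2], 62)
  expect_equal(cc$response_time[2], 10)
  expect_equal(cc$t_clear[2], 62 + 20 + 10 + 15)
  # mileage: 7 + 10 + 0 (diverted at hospital node) + 10 + 10 + 17 home
  expect_equal(sum(log$ambulances$km), 54)
  # workload: busy without interruption from 0 until back home; the final
  # return from node 3 runs at the non-urgent 54 km/h
  expect_equal(log$ambulances$busy_min,
               cc$t_clear[2] + 17 / 54 * 60, tolerance = 1e-9)
})

test_that("K calls with a BLS primary trigger a concurrent ALS dispatch", {
  w <- micro_world(types = c("BLS", "ALS"))
  cfg <- deterministic_config(onscene = 20, transport = 0)
  log <- run_replication(w$deployment, manual_stream(0, 2, "K"),
                         cfg, w$net, w$sm, w$hospitals, seed = 1)
  cc <- log$calls
  expect_equal(cc$primary_amb, "1")
  expect_equal(cc$support_amb, "2")
  expect_equal(sum(log$events$event == "assign"), 2)
  # both start from node 1: response time is the first arrival
  expect_equal(cc$response_time, 7)
})

test_that("the queue is strict priority with FIFO inside classes", {
  w <- micro_world()
  # one ambulance; four calls pile up while it serves the first
  stream <- manual_stream(c(0, 1, 2, 3), 2, c("N", "M", "N", "K"))
  cfg <- deterministic_config(onscene = 20, transport = 0)
  log <- run_replication(w$deployment, stream, cfg, w$net, w$sm,
                         w$hospitals, seed = 1)
  cc <- log$calls
  expect_true(all(cc$t_assign[c(4, 3, 2)] ==
                    sort(cc$t_assign[c(4, 3, 2)])))   # K, then N, then M
  expect_equal(cc$t_assign[1], 0)
  expect_equal(cc$t_assign[4], 27)   # K served at first release
  expect_lt(cc$t_assign[3], cc$t_assign[2])
})

test_that("calls still queued at the horizon are censored, not served", {
  w <- micro_world()
  cfg <- deterministic_config(onscene = 2000, transport = 0,
                              horizon_days = 1)
  stream <- manual_stream(c(0, 5), 2, "N")
  log <- run_replication(w$deployment, stream, cfg, w$net, w$sm,
                         w$hospitals, seed = 1)
  expect_false(log$calls$censored[1])
  expect_true(log$calls$censored[2])
  expect_true(is.na(log$calls$response_time[2]))
  expect_true("censored" %in% log$events$event)
})

test_that("event logs are reproducible from the seed and conserve calls", {
  co <- generate_country(preset_tiny(seed = 3))
  cfg <- simulation_config(horizon_days = 2, replications = 1, seed = 5)
  dep <- co$stations[c("station_id", "node", "type")]
  a <- run_replication(dep, co$dist, cfg, co$network, speed_model(),
                       co$hospitals, co$zones, seed = 17)
  b <- run_replication(dep, co$dist, cfg, co$network, speed_model(),
                       co$hospitals, co$zones, seed = 17)
  expect_identical(a$events, b$events)
  expect_identical(a$calls, b$calls)
  c2 <- run_replication(dep, co$dist, cfg, co$network, speed_model(),
                        co$hospitals, co$zones, seed = 18)
  expect_false(identical(a$events, c2$events))
  # conservation: every call served or censored, exactly one primary
  cc <- a$calls
  expect_true(all(xor(!is.na(cc$t_scene), cc$censored)))
  expect_true(all(!is.na(cc$primary_amb[!cc$censored])))
  # response times never negative
  expect_true(all(cc$response_time[!cc$censored] >= 0))
})

test_that("no ambulance ever serves two calls at once", {
  co <- generate_country(preset_tiny(seed = 3))
  cfg <- simulation_config(horizon_days = 3, replications = 1, seed = 5)
  dep <- co$stations[c("station_id", "node", "type")]
  log <- run_replication(dep, co$dist, cfg, co$network, speed_model(),
                         co$hospitals, co$zones, seed = 21)
  ev <- log$events
  for (aid in unique(ev$amb_id[ev$event == "assign"])) {
    mine <- ev[!is.na(ev$amb_id) & ev$amb_id == aid, ]
    # between consecutive assignments there must be a release (return)
    assigns <- which(mine$event == "assign")
    for (k in seq_len(length(assigns) - 1)) {
      between <- mine$event[assigns[k]:assigns[k + 1]]
      expect_true("return" %in% between)
    }
  }
})

test_that("fleet workload matches the offered load in a single-node world", {
  # one node: travel vanishes, so per-call occupation is on-scene plus the
  # transported fraction of the deterministic drop-off; with lambda = 6/h
  # and 4 ambulances the expected busy fraction is lambda E[S] / m
  net <- road_network(data.frame(node_id = 1, x_km = 0, y_km = 0,
                                 built_up = FALSE),
                      data.frame(a = integer(0), b = integer(0),
                                 length_km = numeric(0),
                                 category = character(0)))
  zones <- demand_zones(
    data.frame(zone_id = "Z", level = "municipality", anchor_node = 1,
               population = 10, parent = NA_character_),
    list(Z = 1L), net)
  dist <- call_distribution(rep(6, 24), c(K = 0, N = 1, M = 0),
                            c(chest_pain = 0, severe_trauma = 0, stroke = 0,
                              severe_respiratory = 0, cardiac_arrest = 0,
                              other = 1))
  hosp <- data.frame(hospital_id = "H1", node = 1, admits = "both",
                     dropoff_shape = Inf, dropoff_mean = 15)
  dep <- data.frame(station_id = 1:4, node = 1, type = "BLS")
  cfg <- deterministic_config(onscene = 20, transport = 0.5,
                              horizon_days = 30)
  log <- run_replication(dep, dist, cfg, net, static_speed_model(), hosp,
                         zones, seed = 42)
  rho <- (6 / 60) * (20 + 0.5 * 15) / 4          # 0.6875
  got <- mean(log$ambulances$busy_min) / log$horizon_min
  expect_lt(abs(got - rho) / rho, 0.05)
})
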