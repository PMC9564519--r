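test_that("station capacity and fixing rules follow the stated arithmetic", {
  # a national system: 274 stations over a 5.4-million population gives a
  # capacity of ~19,708 inhabitants per station
  stations <- data.frame(station_id = 1:274, municipality = "X",
                         type = "BLS", node = 1)
  towns <- data.frame(municipality = "X", population = 5.4e6)
  fx <- apply_fixing_rules(stations, towns)
  expect_equal(fx$capacity, 5.4e6 / 274)
  expect_equal(round(fx$capacity), 19708)

  # rule 1, saturated town: P > kC fixes all k
  st <- data.frame(station_id = 1:4,
                   municipality = c("big", "big", "big", "rest"),
                   type = c("ALS", "BLS", "BLS", "BLS"), node = 1:4)
  tw <- data.frame(municipality = c("big", "rest"),
                   population = c(100000, 0))
  fx <- apply_fixing_rules(st, tw, total_population = 80000)  # C = 20000
  rep_big <- fx$report[fx$report$municipality == "big", ]
  expect_equal(rep_big$n_fixed, 3)         # 100000 > 3 * 20000
  expect_equal(rep_big$demand_scale, 1)

  # rule 1, partial: P = 50000, k = 3, C = 20000 -> fix floor(2.5) = 2,
  # demand scaled by 1 - 2*20000/50000
  tw2 <- data.frame(municipality = c("big", "rest"),
                    population = c(50000, 30000))
  fx2 <- apply_fixing_rules(st, tw2, total_population = 80000)
  rep2 <- fx2$report[fx2$report$municipality == "big", ]
  expect_equal(rep2$n_fixed, 2)
  expect_equal(rep2$demand_scale, 1 - 2 * 20000 / 50000)
  expect_true("1" %in% fx2$fixed_ids)      # ALS fixed first

  # rule 2: two stations, P = 0.8 C -> fix one
  st3 <- data.frame(station_id = 1:2, municipality = "s", type = "BLS",
                    node = 1)
  tw3 <- data.frame(municipality = "s", population = 16000)
  fx3 <- apply_fixing_rules(st3, tw3, total_population = 40000)  # C = 20000
  expect_equal(fx3$report$n_fixed, 1)
  expect_equal(fx3$report$rule, 2L)

  expect_error(apply_fixing_rules(
    data.frame(station_id = 1, municipality = "nowhere", type = "BLS",
               node = 1),
    towns), "unknown town")
})

test_that("relocation budgets reproduce the scenario arithmetic", {
  expect_equal(build_scenario(274, 0.4), 110L)
  expect_equal(build_scenario(274, 0.2), 55L)
  expect_equal(build_scenario(274, "unrestricted", free_station_count = 198),
               198L)
  expect_error(build_scenario(274, 0), "fraction")
  expect_error(build_scenario(274, 1.2), "fraction")
  expect_error(build_scenario(274, "unrestricted"), "free_station_count")
})

path_instance <- function(p = 1, q = 1, budget = Inf, cur = integer(0)) {
  # three nodes on a unit-time path, unit weights
  tmat <- matrix(c(0, 1, 2,
                   1, 0, 1,
                   2, 1, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("1", "2", "3"), c("z1", "z2", "z3")))
  location_instance(tmat, c(1, 1, 1), p, q, NULL, cur, budget)
}

test_that("the median of a path is its middle node", {
  sol <- solve_lower_level(path_instance())
  expect_equal(sol$y, 2)
  expect_equal(sol$Z_low, 2)
  expect_equal(unname(sol$x), c(2, 2, 2))
})

test_that("opening every site self-assigns all zones at zero cost", {
  inst <- path_instance(p = 3, q = 1)
  sol <- solve_lower_level(inst)
  expect_equal(sol$y, c(1, 2, 3))
  expect_equal(sol$Z_low, 0)
  expect_equal(unname(sol$x), c(1, 2, 3))
})

test_that("upper level collapses to the lower one when q = p", {
  inst <- path_instance(p = 2, q = 2)
  sol <- solve_pq_median(inst)
  expect_equal(sol$u, sol$y)
  expect_equal(sol$Z_up, sol$Z_low)
})

test_that("q = 1 equals a weighted linear scan over the open sites", {
  for (seed in 301:305) {
    inst <- random_instance(seed)
    inst$q <- 1
    inst$fixed$n_fixed_als[] <- 0L
    low <- solve_lower_level(inst)
    up <- solve_upper_level(inst, low$y)
    scan <- min(vapply(low$y, function(s)
      sum(inst$weights * inst$tmat[as.character(s), ]), numeric(1)))
    expect_equal(up$Z_up, scan, tolerance = 1e-9)
  }
})

test_that("a fixed ALS site is forced into the upper-level solution", {
  tmat <- matrix(runif(5 * 6, 0, 20), 5, 6,
                 dimnames = list(as.character(1:5), paste0("z", 1:6)))
  fixed <- data.frame(site = 4, n_fixed = 1L, n_fixed_als = 1L)
  inst <- location_instance(tmat, rep(1, 6), p = 3, q = 2, fixed)
  sol <- solve_pq_median(inst)
  expect_true(4 %in% sol$u)
  expect_true(all(sol$u %in% sol$y))
  # oracle over the remaining choices with the fixed site forced in
  expect_equal(sol$Z_up, oracle_upper(inst, sol$y), tolerance = 1e-9)
})

test_that("both levels match exhaustive enumeration on random instances", {
  for (seed in 101:140) {
    inst <- random_instance(seed)
    sol <- solve_pq_median(inst)
    expect_equal(sol$Z_low, oracle_lower(inst), tolerance = 1e-9,
                 info = paste("lower, seed", seed))
    expect_equal(sol$Z_up, oracle_upper(inst, sol$y), tolerance = 1e-9,
                 info = paste("upper, seed", seed))
  }
})

test_that("solution structure: nearest assignment, hierarchy, feasibility", {
  for (seed in 201:215) {
    inst <- random_instance(seed)
    sol <- solve_pq_median(inst)
    p_sites <- inst$p - sum(inst$fixed$n_fixed) + nrow(inst$fixed)
    expect_equal(length(sol$y), p_sites)
    expect_true(all(inst$fixed$site %in% sol$y))
    expect_gte(sol$Z_up, sol$Z_low - 1e-9)
    # reassigning any zone to any other open site never reduces cost
    for (z in colnames(inst$tmat)) {
      assigned <- inst$tmat[as.character(sol$x[z]), z]
      expect_equal(assigned, min(inst$tmat[as.character(sol$y), z]))
    }
    # relocation budget respected
    kept <- sum(sol$chosen_free_sites %in% inst$current_free_sites) +
      sum(inst$current_free_sites %in% inst$fixed$site)
    relocated <- sol$p_free - kept
    if (is.finite(inst$budget)) expect_lte(relocated, inst$budget)
  }
})

test_that("tightening the budget or fixing more sites never helps", {
  for (seed in 401:412) {
    inst <- random_instance(seed, with_fixed = FALSE, with_budget = FALSE)
    n_cur <- min(inst$p, nrow(inst$tmat))
    inst$current_free_sites <-
      as.integer(rownames(inst$tmat)[seq_len(n_cur)])
    z_prev <- Inf
    for (r in 0:inst$p) {
      inst$budget <- r
      z <- solve_lower_level(inst)$Z_low
      expect_lte(z, z_prev + 1e-9)
      z_prev <- z
    }
    # fixing monotonicity: force one extra site open
    inst$budget <- Inf
    free <- solve_lower_level(inst)$Z_low
    worst_site <- as.numeric(rownames(inst$tmat)[which.max(
      rowSums(inst$tmat * rep(inst$weights, each = nrow(inst$tmat))))])
    inst2 <- inst
    inst2$fixed <- data.frame(site = worst_site, n_fixed = 1L,
                              n_fixed_als = 0L)
    expect_gte(solve_lower_level(inst2)$Z_low, free - 1e-9)
  }
})

test_that("an impossible budget yields an infeasibility report", {
  inst <- path_instance(p = 2, q = 1, budget = 0, cur = 3L)
  # two free stations but only one current site may be kept and none moved
  expect_error(solve_lower_level(inst), "infeasible")
})

test_that("post-processing keeps addresses, relocates to central nodes", {
  tmat <- matrix(c(0, 9, 9,
                   9, 0, 9,
                   9, 9, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("10", "20", "30"), c("A", "B", "C")))
  muni <- data.frame(municipality = c("A", "B", "C"),
                     central_node = c(10, 20, 30))
  stations <- data.frame(station_id = 1:2, municipality = c("A", "B"),
                         node = c(11, 20), type = c("ALS", "BLS"))
  # identical multiset: stations keep their addresses, zero relocations
  inst <- location_instance(tmat, c(5, 4, 0.1), p = 2, q = 1,
                            current_free_sites = c(10, 20), budget = Inf)
  sol <- solve_pq_median(inst)
  expect_equal(sol$y, c(10, 20))
  post <- postprocess_solution(sol, stations, muni)
  expect_equal(post$summary$n_relocated, 0)
  expect_equal(post$placements$node, c(11, 20))
  # forcing a move: weights now pull one station to municipality C
  inst2 <- location_instance(tmat, c(5, 0.1, 4), p = 2, q = 1,
                             current_free_sites = c(10, 20), budget = Inf)
  sol2 <- solve_pq_median(inst2)
  expect_equal(sol2$y, c(10, 30))
  post2 <- postprocess_solution(sol2, stations, muni)
  expect_equal(post2$summary$n_relocated, 1)
  moved <- post2$placements[post2$placements$relocated, ]
  expect_equal(moved$municipality, "C")
  expect_equal(moved$node, 30L)     # central node of the new municipality
  # relocated count equals an independent recount: chosen sites whose
  # municipality hosts no current station
  site_town <- muni$municipality[match(sol2$chosen_free_sites,
                                       muni$central_node)]
  expect_equal(post2$summary$n_relocated,
               sum(!site_town %in% stations$municipality))
})

test_that("static indicators are the stated ratios of the solved model", {
  inst <- path_instance(p = 1, q = 1)
  sol <- solve_pq_median(inst)
  ind <- static_indicators(sol, inst, threshold_min = 15)
  expect_equal(ind$avg_time_closest, sol$Z_low / 3)
  expect_equal(ind$coverage_pct, 100)   # all t <= 15
  ind1 <- static_indicators(sol, inst, threshold_min = 0.5)
  expect_equal(ind1$coverage_pct, 100 / 3)   # only the median's own zone
  bad <- path_instance()
  bad$weights[] <- 0
  expect_error(static_indicators(sol, bad), "zero")
})
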