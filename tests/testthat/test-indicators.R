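fake_log <- function(rt, priority = rep("N", length(rt)),
                     diagnosis = rep("other", length(rt)),
                     zone_id = rep("Z", length(rt)),
                     censored = rep(FALSE, length(rt)),
                     workload = c(BLS = 30), km = 100,
                     horizon_min = 6000) {
  calls <- data.frame(call_id = seq_along(rt), response_time = rt,
                      priority = priority, diagnosis = diagnosis,
                      zone_id = zone_id, censored = censored,
                      stringsAsFactors = FALSE)
  ambulances <- data.frame(station_id = as.character(seq_along(workload)),
                           type = names(workload),
                           workload_pct = unname(workload),
                           km = rep(km / length(workload), length(workload)),
                           busy_min = unname(workload) / 100 * horizon_min,
                           stringsAsFactors = FALSE)
  structure(list(calls = calls, ambulances = ambulances,
                 events = data.frame(), horizon_min = horizon_min),
            class = "ems_simlog")
}

test_that("thresholds are inclusive and the workload is the busy fraction", {
  rep <- compute_indicators(fake_log(c(5, 15)))
  g <- function(i) rep$mean[rep$indicator == i]
  expect_equal(g("rt_all"), 10)
  expect_equal(g("pct_within_15"), 100)    # 15.0 counts as within 15
  expect_equal(g("workload_BLS"), 30)
  expect_true(is.na(g("rt_K")))            # no K calls: stratum absent
  expect_true(is.na(g("workload_ALS")))
})

test_that("multi-replication reports carry t-based confidence intervals", {
  logs <- structure(lapply(c(8, 10, 12, 14), fake_log), class = "ems_simlogs")
  rep <- compute_indicators(logs)
  row <- rep[rep$indicator == "rt_all", ]
  expect_equal(row$mean, 11)
  half <- qt(0.975, 3) * sd(c(8, 10, 12, 14)) / 2
  expect_equal(row$ci_hi - row$mean, half, tolerance = 1e-9)
  expect_true(row$ci_lo <= row$mean && row$mean <= row$ci_hi)
})

test_that("every indicator equals an independent recomputation", {
  co <- generate_country(preset_tiny(seed = 13))
  cfg <- simulation_config(horizon_days = 3, replications = 1, seed = 2)
  log <- run_replication(co$stations[c("station_id", "node", "type")],
                         co$dist, cfg, co$network, speed_model(),
                         co$hospitals, co$zones, seed = 31)
  rep <- compute_indicators(log)
  g <- function(i) rep$mean[rep$indicator == i]
  cc <- log$calls[!log$calls$censored & !is.na(log$calls$t_scene), ]
  rt <- cc$t_scene - cc$t_assign
  expect_equal(g("rt_all"), mean(rt))
  expect_equal(g("rt_K"), mean(rt[cc$priority == "K"]))
  expect_equal(g("pct_within_15"), 100 * mean(rt <= 15))
  fhq <- cc$diagnosis %in% fhq_diagnoses()
  expect_equal(g("rt_fhq"), mean(rt[fhq]))
  expect_equal(g("pct_fhq_within_8"), 100 * mean(rt[fhq] <= 8))
  expect_equal(g("mileage_km"), sum(log$ambulances$km))
  amb <- log$ambulances
  expect_equal(g("workload_BLS"),
               mean(100 * amb$busy_min[amb$type == "BLS"] / log$horizon_min))
})

test_that("coverage is monotone in the threshold and complete at infinity", {
  log <- fake_log(c(2, 7, 12, 19, 33))
  pct <- vapply(c(1, 5, 10, 20, 40, Inf), function(th)
    compute_indicators(log, threshold_min = th)$mean[5], numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_equal(pct[length(pct)], 100)
})

test_that("deployment comparison flags disjoint confidence intervals", {
  logs_a <- structure(lapply(c(10.00, 10.02, 10.04), fake_log),
                      class = "ems_simlogs")
  same <- compare_deployments(compute_indicators(logs_a),
                              compute_indicators(logs_a))
  expect_true(all(same$delta == 0 | is.na(same$delta)))
  expect_false(any(same$significant, na.rm = TRUE))
  logs_b <- structure(lapply(c(9.60, 9.62, 9.64), fake_log),
                      class = "ems_simlogs")
  cmp <- compare_deployments(compute_indicators(logs_a),
                             compute_indicators(logs_b))
  expect_true(cmp$significant[cmp$indicator == "rt_all"])
  expect_equal(cmp$delta[cmp$indicator == "rt_all"], -0.4, tolerance = 1e-9)
  short <- structure(lapply(c(1, 2), fake_log), class = "ems_simlogs")
  expect_error(compare_deployments(compute_indicators(logs_a),
                                   compute_indicators(short)),
               "replication count")
})

test_that("a known injected shift is recovered within its interval", {
  set.seed(5)
  base <- lapply(1:6, function(i) fake_log(rnorm(40, 11, 1)))
  shifted <- lapply(1:6, function(i) fake_log(rnorm(40, 9.5, 1)))
  cmp <- compare_deployments(
    compute_indicators(structure(base, class = "ems_simlogs")),
    compute_indicators(structure(shifted, class = "ems_simlogs")))
  d <- cmp$delta[cmp$indicator == "rt_all"]
  expect_lt(abs(d - (-1.5)), 0.5)
  expect_true(cmp$significant[cmp$indicator == "rt_all"])
})

test_that("the urban/rural gap is reported in seconds", {
  # class means of 11.02 and 12.47 minutes differ by 87 seconds
  log <- fake_log(c(11.02, 12.47), zone_id = c("U", "R"))
  rep <- urban_rural_report(log, c(U = "urban", R = "rural"))
  expect_equal(rep$urban_min, 11.02)
  expect_equal(rep$rural_min, 12.47)
  expect_equal(rep$gap_seconds, 87, tolerance = 1e-9)
  only_urban <- fake_log(5, zone_id = "U")
  rep2 <- urban_rural_report(only_urban, c(U = "urban", R = "rural"))
  expect_true(is.na(rep2$rural_min))
  expect_error(urban_rural_report(log, c(U = "urban")), "unclassified")
})

test_that("group reports equal a direct recomputation", {
  log <- fake_log(c(3, 6, 9, 30), zone_id = c("A", "A", "B", "B"))
  gr <- group_report(log, c(A = "west", B = "east"), threshold_min = 15)
  expect_equal(gr$mean_rt[gr$group == "west"], 4.5)
  expect_equal(gr$mean_rt[gr$group == "east"], 19.5)
  expect_equal(gr$pct_within[gr$group == "east"], 50)
})
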