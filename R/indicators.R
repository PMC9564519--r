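# Performance indicators with replication confidence intervals.
#
# The response time of a call is the interval between the dispatcher's
# ambulance assignment and the FIRST arrival at the scene (the definition
# used throughout); calls still queued at the horizon are censored and
# excluded from response-time statistics but counted.

rep_indicators <- function(log, threshold_min = 15, fhq_threshold_min = 8,
                           fhq = fhq_diagnoses()) {
  cc <- log$calls
  served <- !is.na(cc$response_time) & !cc$censored
  rt <- cc$response_time[served]
  pri <- cc$priority[served]
  is_fhq <- cc$diagnosis[served] %in% fhq
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  pct_or_na <- function(x, thr) if (length(x)) 100 * mean(x <= thr) else NA_real_
  amb <- log$ambulances
  c(rt_K = mean_or_na(rt[pri == "K"]),
    rt_N = mean_or_na(rt[pri == "N"]),
    rt_M = mean_or_na(rt[pri == "M"]),
    rt_all = mean_or_na(rt),
    pct_within_15 = pct_or_na(rt, threshold_min),
    rt_fhq = mean_or_na(rt[is_fhq]),
    pct_fhq_within_8 = pct_or_na(rt[is_fhq], fhq_threshold_min),
    workload_BLS = mean_or_na(amb$workload_pct[amb$type == "BLS"]),
    workload_ALS = mean_or_na(amb$workload_pct[amb$type == "ALS"]),
    mileage_km = sum(amb$km),
    n_calls = nrow(cc),
    n_censored = sum(cc$censored))
}

#' Compute the performance-indicator report
#'
#' Mean response time per priority and overall, 15-minute coverage, mean
#' response time and 8-minute coverage for the First Hour Quintet, mean
#' workload by ambulance type, and total mileage. Thresholds are inclusive.
#' For multi-replication input the report gives across-replication means
#' with t-based 95% confidence intervals (n - 1 degrees of freedom); a
#' stratum with no calls is reported as absent (`NA`), not as zero.
#'
#' @param x an `ems_simlog` or an `ems_simlogs` list of replications.
#' @param threshold_min response-time standard in minutes (default 15).
#' @param fhq_threshold_min threshold for the First Hour Quintet (default 8).
#' @param fhq diagnosis codes forming the quintet.
#' @return An object of class `ems_report`: data.frame with columns
#'   `indicator`, `mean`, `ci_lo`, `ci_hi`, plus attributes `n_reps` and the
#'   per-replication matrix.
#' @export
compute_indicators <- function(x, threshold_min = 15, fhq_threshold_min = 8,
                               fhq = fhq_diagnoses()) {
  logs <- if (inherits(x, "ems_simlog")) list(x) else x
  per <- t(vapply(logs, rep_indicators, numeric(12),
                  threshold_min = threshold_min,
                  fhq_threshold_min = fhq_threshold_min, fhq = fhq))
  n <- nrow(per)
  mu <- colMeans(per)
  if (n > 1) {
    se <- apply(per, 2, sd) / sqrt(n)
    half <- qt(0.975, df = n - 1) * se
    lo <- mu - half; hi <- mu + half
  } else {
    lo <- hi <- rep(NA_real_, length(mu))
  }
  out <- data.frame(indicator = names(mu), mean = unname(mu),
                    ci_lo = unname(lo), ci_hi = unname(hi),
                    stringsAsFactors = FALSE)
  attr(out, "n_reps") <- n
  attr(out, "per_rep") <- per
  class(out) <- c("ems_report", "data.frame")
  out
}

#' @export
print.ems_report <- function(x, ...) {
  cat("<ems_report> across ", attr(x, "n_reps"), " replication(s)\n", sep = "")
  print.data.frame(cbind(x["indicator"],
                         round(x[c("mean", "ci_lo", "ci_hi")], 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Compare two deployments indicator by indicator
#'
#' @param a,b `ems_report` objects computed with the same replication count.
#' @return data.frame with the two means, `delta = B - A` and a
#'   `significant` flag set when the 95% confidence intervals are disjoint.
#' @export
compare_deployments <- function(a, b) {
  stopifnot(inherits(a, "ems_report"), inherits(b, "ems_report"))
  if (attr(a, "n_reps") != attr(b, "n_reps"))
    stop("reports use different replication counts")
  if (!identical(a$indicator, b$indicator))
    stop("reports carry different indicators")
  data.frame(indicator = a$indicator, mean_A = a$mean, mean_B = b$mean,
             delta = b$mean - a$mean,
             significant = (a$ci_hi < b$ci_lo) | (b$ci_hi < a$ci_lo),
             stringsAsFactors = FALSE)
}

#' Urban/rural response-time report
#'
#' Mean response time in urban and rural areas and the gap between them in
#' seconds.
#'
#' @param x an `ems_simlog` or `ems_simlogs`.
#' @param classification named character vector mapping every zone id to
#'   `"urban"` or `"rural"`.
#' @return List with `urban_min`, `rural_min` (across-replication means of
#'   per-replication class means; `NA` when a class has no calls) and
#'   `gap_seconds`.
#' @export
urban_rural_report <- function(x, classification) {
  logs <- if (inherits(x, "ems_simlog")) list(x) else x
  if (!all(classification %in% c("urban", "rural")))
    stop("classification values must be urban or rural")
  per <- vapply(logs, function(log) {
    cc <- log$calls
    cl <- classification[cc$zone_id]
    if (anyNA(cl))
      stop("unclassified zone(s): ",
           paste(unique(cc$zone_id[is.na(cl)]), collapse = ", "))
    served <- !is.na(cc$response_time) & !cc$censored
    u <- cc$response_time[served & cl == "urban"]
    r <- cc$response_time[served & cl == "rural"]
    c(urban = if (length(u)) mean(u) else NA_real_,
      rural = if (length(r)) mean(r) else NA_real_)
  }, numeric(2))
  urban <- mean(per["urban", ])
  rural <- mean(per["rural", ])
  list(urban_min = urban, rural_min = rural,
       gap_seconds = abs(urban - rural) * 60)
}

#' Per-group indicator breakdown
#'
#' Mean response time and coverage for each group of zones (e.g. districts).
#'
#' @param x an `ems_simlog` or `ems_simlogs`.
#' @param grouping named character vector mapping zone ids to group labels.
#' @param threshold_min coverage threshold in minutes.
#' @return data.frame with one row per group: `group`, `mean_rt`,
#'   `pct_within`, `n_calls`.
#' @export
group_report <- function(x, grouping, threshold_min = 15) {
  logs <- if (inherits(x, "ems_simlog")) list(x) else x
  cc <- do.call(rbind, lapply(logs, function(l) l$calls))
  g <- grouping[cc$zone_id]
  if (anyNA(g))
    stop("zone(s) without group: ",
         paste(unique(cc$zone_id[is.na(g)]), collapse = ", "))
  served <- !is.na(cc$response_time) & !cc$censored
  groups <- sort(unique(g))
  do.call(rbind, lapply(groups, function(gr) {
    rt <- cc$response_time[served & g == gr]
    data.frame(group = gr,
               mean_rt = if (length(rt)) mean(rt) else NA_real_,
               pct_within = if (length(rt)) 100 * mean(rt <= threshold_min)
                 else NA_real_,
               n_calls = sum(g == gr), stringsAsFactors = FALSE)
  }))
}
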