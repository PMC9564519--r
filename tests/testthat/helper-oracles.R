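# Independent oracles: exhaustive enumeration for the median problems and
# simple-path enumeration for routing. These deliberately share no code
# with the implementation they check.

# minimum demand-weighted cost over all feasible site subsets
oracle_subset_cost <- function(tmat, b, forced, pool, is_cur, pick,
                               min_keep) {
  cost_of <- function(open) {
    sub <- tmat[as.character(open), , drop = FALSE]
    sum(b * apply(sub, 2, min))
  }
  sets <- if (pick == 0) list(integer(0)) else
    combn(seq_along(pool), pick, simplify = FALSE)
  best <- Inf
  for (s in sets) {
    if (sum(is_cur[s]) < min_keep) next
    best <- min(best, cost_of(c(forced, pool[s])))
  }
  best
}

# lower-level optimum by brute force, from the instance semantics
oracle_lower <- function(inst) {
  sites <- as.numeric(rownames(inst$tmat))
  forced <- as.numeric(inst$fixed$site)
  p_free <- inst$p - sum(inst$fixed$n_fixed)
  pool <- setdiff(sites, forced)
  is_cur <- pool %in% inst$current_free_sites
  base_keep <- sum(inst$current_free_sites %in% forced)
  min_keep <- max(0, p_free - inst$budget - base_keep)
  oracle_subset_cost(inst$tmat, inst$weights, forced, pool, is_cur,
                     p_free, min_keep)
}

# upper-level optimum by brute force given the open sites y
oracle_upper <- function(inst, y) {
  fixed_als <- as.numeric(inst$fixed$site[inst$fixed$n_fixed_als > 0])
  pool <- setdiff(sort(y), fixed_als)
  q_free <- inst$q - sum(inst$fixed$n_fixed_als)
  tm <- inst$tmat[as.character(sort(y)), , drop = FALSE]
  oracle_subset_cost(tm, inst$weights, fixed_als, pool,
                     rep(FALSE, length(pool)), q_free, 0)
}

# random feasible instance within the enumeration-tractable envelope
random_instance <- function(seed, with_fixed = TRUE, with_budget = TRUE) {
  set.seed(seed)
  nI <- sample(4:12, 1)
  nJ <- sample(3:10, 1)
  ids <- sort(sample(1:99, nI))
  tmat <- matrix(round(runif(nI * nJ, 0, 30), 3), nI, nJ,
                 dimnames = list(as.character(ids), paste0("z", 1:nJ)))
  b <- c(1, round(runif(nJ - 1, 0, 10)))
  p <- sample(1:min(4, nI - 1), 1)
  q <- sample(1:p, 1)
  fixed <- NULL
  if (with_fixed && p >= 2 && runif(1) < 0.7) {
    nfx_sites <- sample(1:(p - 1), 1)
    fsites <- sample(ids, nfx_sites)
    n_fixed <- rep(1L, nfx_sites)
    # a doubly-fixed site reduces the open-site count by one, so it is
    # only feasible when q stays below p
    if (runif(1) < 0.3 && p - nfx_sites >= 1 && q < p) n_fixed[1] <- 2L
    if (sum(n_fixed) > p) n_fixed[1] <- 1L
    n_als <- pmin(n_fixed, rbinom(nfx_sites, 1, 0.5))
    while (sum(n_als) > q) n_als[which.max(n_als)] <- 0L
    fixed <- data.frame(site = fsites, n_fixed = n_fixed,
                        n_fixed_als = n_als)
  }
  p_free <- p - if (is.null(fixed)) 0 else sum(fixed$n_fixed)
  pool <- setdiff(ids, if (is.null(fixed)) numeric(0) else fixed$site)
  n_cur <- sample(0:min(p_free + 2, length(pool)), 1)
  cur <- if (n_cur > 0) sample(pool, n_cur) else integer(0)
  budget <- Inf
  if (with_budget && runif(1) < 0.7) {
    # keep the instance feasible: at least p_free - r current sites must
    # be coverable by the available current sites
    rng <- max(0, p_free - length(cur)):max(p_free, 1)
    budget <- rng[sample.int(length(rng), 1)]
  }
  location_instance(tmat, b, p, q, fixed, cur, budget)
}

# travel time of the quickest simple path, by exhaustive enumeration under
# a static speed context
oracle_route_time <- function(network, sm, origin, dest, priority = "K",
                              bucket = "offpeak") {
  if (origin == dest) return(0)
  sp <- emsopt:::edge_speed_vectors(network, sm, priority)
  w <- network$edges$length_km / (if (bucket == "rush") sp$rush else sp$off) * 60
  oi <- match(origin, network$nodes$node_id)
  di <- match(dest, network$nodes$node_id)
  paths <- igraph::all_simple_paths(network$graph, from = oi, to = di)
  best <- Inf
  for (p in paths) {
    v <- as.integer(p)
    tt <- 0
    for (k in seq_len(length(v) - 1)) {
      a <- network$nodes$node_id[v[k]]; b <- network$nodes$node_id[v[k + 1]]
      hit <- which((network$edges$a == a & network$edges$b == b) |
                     (network$edges$a == b & network$edges$b == a))[1]
      tt <- tt + w[hit]
    }
    best <- min(best, tt)
  }
  best
}
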