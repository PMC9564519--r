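# emsopt

Redesign of tiered emergency medical service (EMS) station networks:
a hierarchical pq-median location optimizer coupled to an agent-based
discrete-event simulator of ambulance operations.

## The problem

EMS systems with a fixed fleet — advanced life support (ALS) ambulances
staffed by a physician for life-threatening cases, basic life support
(BLS) ambulances for the rest — can often improve response times without
buying a single vehicle, simply by moving base stations closer to where
patients actually are. `emsopt` is for health-services and operations
researchers who want to quantify that improvement for a mixed urban–rural
region: it finds provably optimal station placements under realistic
managerial constraints and then stress-tests the proposed designs in a
detailed stochastic simulation.

## The model

Demand zones `j` (municipalities nationwide; 250 m grid cells inside
towns) carry weights `b_j`, the count of historical life-threatening (K)
and urgent (N) calls. With `t_ij` the shortest travel time from candidate
site `i` to zone `j`, the lower level places all `p` stations:

    min  Σ_i Σ_j t_ij b_j x_ij
    s.t. Σ_i x_ij = 1   for every zone j
         x_ij ≤ y_i,  Σ_i y_i = p,  x, y binary

and the upper level selects `q ≤ p` of the opened sites for ALS units
(`u_i ≤ y_i`, `Σ u_i = q`) with the same weighted-travel-time objective —
a non-coherent hierarchical pq-median problem. Around the core model the
package implements the practical apparatus that makes solutions usable:
station-fixing rules based on a capacity `C = population / station count`,
relocation budgets (10–50% of the fleet, or unrestricted), post-processing
to municipal central nodes, and static indicators (average travel time
`Z / Σ b_j`, 15-minute theoretical coverage).

Both levels are solved to proven optimality by an exact branch-and-bound
(Rcpp); the simulator adds non-homogeneous Poisson arrivals, the tiered
dispatch policy (closest-any-type with concurrent ALS for K calls),
diagnosis/crew-dependent on-scene times, type-dependent hospital
transport, Erlang drop-offs, en-route re-dispatch and time-dependent
travel speeds. A synthetic-country generator makes everything runnable
and testable without external data.

## Worked example

```r
library(emsopt)

country <- generate_country(preset_tiny(seed = 7))
country
#> <ems_country> 10 municipalities, 42 road nodes, 8 stations (3 ALS),
#> 2 hospitals, 150,000 inhabitants

result <- run_pipeline(country, history_days = 60,
                       sim_config = simulation_config(horizon_days = 7,
                                                      replications = 5,
                                                      seed = 2),
                       seed = 9)

result$scenario_table[, c("scenario", "budget", "n_relocated",
                          "avg_time_closest", "coverage_pct")]
#>                  scenario budget n_relocated avg_time_closest coverage_pct
#> 10%                   10%      1           1             1.09         98.5
#> 20%                   20%      2           1             1.09         98.5
#> ...
#> unrestricted unrestricted      3           1             1.09         98.5

result$sim_current
#> <ems_report> across 5 replication(s)
#>         indicator     mean    ci_lo    ci_hi
#>            rt_all    7.047    6.106    7.987
#>     pct_within_15   90.089   86.733   93.445
#>  pct_fhq_within_8   79.790   68.813   90.766
#>      workload_BLS   14.496   12.072   16.919
#>        mileage_km 2227.644 1603.693 2851.595
#>  ...
```

Reading the output: on this tiny synthetic country the static average
travel time to the nearest station drops from 2.41 min (current) to 1.09
min once a single station is allowed to move — the optimum is reached
already at the 10% budget, so the scenario sweep flattens. `rt_all` is
the mean response time (dispatcher assignment to first scene arrival) in
minutes across five one-week replications with t-based 95% confidence
intervals; `pct_within_15` is the share of calls reached within the
15-minute standard, `pct_fhq_within_8` the 8-minute coverage of the First
Hour Quintet (chest pain, severe trauma, stroke, severe respiratory
difficulties, cardiac arrest); workloads are busy fractions of the
horizon by ambulance type.

Stage 2 then re-optimises station positions inside each town on a 250 m
grid (`result$stage2`), and `result$comparison` contrasts the simulated
current vs redesigned deployments indicator by indicator, flagging
differences whose confidence intervals are disjoint.

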