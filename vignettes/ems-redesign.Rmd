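---
title: "Redesigning a tiered EMS station network: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redesigning a tiered EMS station network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An emergency medical service (EMS) with a fixed fleet of ambulances wants
to relocate some of its base stations so that ambulances are closer to
future patients. The system is tiered: advanced life support (ALS)
ambulances carry a physician and attend life-threatening cases; basic life
support (BLS) ambulances handle the rest. `emsopt` implements a two-stage
redesign methodology for such systems operating over a mixed urban–rural
road network, together with an agent-based discrete-event simulator used
to evaluate candidate designs under realistic operations.

## The hierarchical pq-median model

Let $I$ be the candidate sites (road nodes), $J$ the demand zones,
$t_{ij}$ the shortest travel time from site $i$ to zone $j$, and $b_j$ the
demand weight of zone $j$ (the count of historical life-threatening and
urgent calls — the lowest priority class is excluded from the demand
model). The lower level places all $p$ stations:

$$\min \sum_{i \in I}\sum_{j \in J} t_{ij} b_j x_{ij}
\quad \text{s.t.} \quad \sum_i x_{ij} = 1,\; x_{ij} \le y_i,\;
\sum_i y_i = p,$$

and the upper level selects $q \le p$ of the opened sites for ALS
ambulances with the same objective restricted to the ALS tier
($u_i \le y_i$, $\sum_i u_i = q$). The system is *non-coherent*: a zone's
BLS catchment and ALS catchment need not nest. The average travel time of
a tier is its objective divided by total demand $\sum_j b_j$, and
theoretical coverage is the demand share whose nearest open station is
within a threshold (15 minutes by default, inclusive).

Because both levels are uncapacitated, every optimal solution assigns each
zone to its *nearest* open site. `emsopt` exploits this: the binary
program collapses to a site-subset selection problem, solved to proven
optimality by an exact branch-and-bound (`src/pmedian.cpp`) with an
admissible suffix-minimum bound. Optimality is required, not approximated;
the solver is verified against exhaustive enumeration on hundreds of
random instances in the test suite. Tie-breaks are everywhere
deterministic by lowest site id, so the reported optimum is the
lexicographically smallest optimal site set.

### Fixing rules and relocation budgets

An uncapacitated median model would happily serve a metropolis from one
site, so before optimisation two rules fix stations in high-demand towns
(`apply_fixing_rules()`). The *capacity* of a station is the average
population per station, $C = \text{total population} / \text{station
count}$. Rule 1: a town with $k$ stations and population $P > kC$ keeps
all $k$; otherwise $n = \lfloor P/C \rfloor$ stations are fixed and the
town's demand weight is scaled by $1 - nC/P$, the share absorbed by the
fixed stations. Rule 2: a town operating two stations although $P < C$
keeps one. We read "the necessary stations, obtained by dividing the
population by the capacity" as the *floor*: the ceiling would re-fix every
station in near-capacity towns and the rule would stop distinguishing
saturated from unsaturated towns. Within a town, ALS stations are fixed
before BLS ones (lowest id first) so that the immutable ALS sites stay
anchored; fixed BLS stations may still be upgraded by the upper level.

Redesign scenarios limit how many free stations may move to a *new
municipality*: the budget $r$ is the nearest integer of a fraction of the
station count (10–50%), or the whole free set when unrestricted. The
model formulation of the budget is
$\sum_{i \in \text{current free sites}} y_i \ge p_{\text{free}} - r$ at
municipality granularity, which matches the municipality-level relocation
accounting used in the scenario reports; a per-station multiset variant
would differ only in towns hosting several free stations.

### Post-processing

Stations not relocated by the model keep their current street addresses;
relocated stations are placed at the central node of their new
municipality. One station per ALS site is designated ALS (preferring a
station that is ALS today); type switches are counted over non-relocated
stations. A site-level model cannot express two ALS units at one node —
a granularity limit worth remembering when $q$ is large relative to the
number of towns.

## Travel times

Ambulance speed depends on road category, built-up context, call priority
and time of day. The shipped defaults are 90/72 km/h (highway), 60/48
(main) and 40/32 (local) off-peak/rush, scaled by 0.8 inside built-up
areas and by 0.9 for the non-urgent priority; rush windows default to
06:30–09:00 and 15:00–18:00. These are documented placeholders — real
deployments should calibrate them — and are fully overridable through
`speed_model()` / YAML.

Routing freezes each edge's speed at the moment the vehicle *enters* the
edge. This keeps travel deterministic and is standard in road-network
discrete-event models; its one caveat is a mild non-FIFO artifact in the
minutes before a rush window closes (a vehicle entering a long edge just
before the window ends keeps the slow speed). Route optimality is
therefore exact under static contexts — which is how it is tested — and a
very close label-setting approximation across bucket boundaries.

The matrix $t_{ij}$ fed to the optimiser uses a single static context:
off-peak, urgent-priority, open-road speeds. The source methodology does
not state which context feeds the MIP; a static matrix keeps the model
well defined, and the simulator applies the full time-dependent model
when evaluating the resulting designs. The context is exposed as
configuration (`travel_time_matrix()` arguments) for sensitivity runs.

## Demand model

Demand is represented at two levels: one zone per municipality, anchored
at its central road node, for the nationwide stage; and a square grid
(0.25 km cells by default) inside towns for the second stage, each cell
anchored at the road node nearest its centre. Grid candidates equal grid
anchors ($I = J$), mirroring the practice of co-locating candidate sites
with demand nodes.

Call arrivals follow a non-homogeneous Poisson process with hour-of-day
rates; day-of-week and month effects are omitted as flat, reflecting the
near-invariance seen in national dispatch data. Sampling draws per-hour
Poisson counts with uniform order statistics inside the hour; a call picks
its zone with probability proportional to population, a road node
uniformly within the zone, and its priority, diagnosis and age class
independently. Priority/diagnosis mixes are configuration with documented
defaults (10% life-threatening K, 45% urgent N, 45% non-urgent M; the
First Hour Quintet diagnoses at realistic single-digit shares) — they are
deliberately *not* asserted as any country's truth.

## The simulator

Each station houses exactly one ambulance. The dispatch policy mirrors
tiered practice:

* **K** — the closest available ambulance of any type; if it is a BLS,
  the closest available ALS is dispatched concurrently. The response time
  of a dual dispatch is the *first* arrival; per-ambulance timestamps are
  retained.
* **N** — the closest available BLS; when the crew starts on-scene care
  it requests ALS support with probability `p_support` (default 0.1).
* **M** — the closest available BLS unless it is farther than `tau_M`
  minutes (default 25) and a closer ALS is free, in which case the ALS
  responds.

`p_support` and `tau_M` are assumptions exposed as configuration: the
underlying dispatch rules say "the crew may require support" and "only if
the destination is too far" without quantifying either. Unserved calls
wait in a strict-priority queue (K > N > M, FIFO within class) re-examined
at every release; queue scanning stops at the first call that cannot be
served, which preserves strict priority at the cost of occasionally
idling an ALS behind a BLS-needing call — a deliberate fairness choice.
The support leg of a dual dispatch is never cancelled (the real
dispatcher's cancellation behaviour is unknown); the support ambulance
waits until the primary crew leaves the scene, then returns.

On-scene times are lognormal with means by (diagnosis, crew type),
defaults in the 20–30 minute band with BLS means at or above ALS means;
`onscene_sdlog = 0` makes them deterministic for validation. Transport to
hospital is Bernoulli per crew type (defaults 0.71 BLS, 0.53 ALS); the
destination is the nearest admissible hospital (age class and
specialisation match, ties by id), where drop-off time is Erlang with
per-hospital shape and mean (14–38 minutes; `shape = Inf` degenerates to
a constant, again for validation). Ambulances are dispatchable while idle
or while returning to base; a returning vehicle diverts at the next node
of its current route, and mileage counts exactly the traversed edges.
Calls still queued at the horizon are censored: counted, logged, excluded
from response-time statistics. Workload is the busy (non-idle) fraction
of the horizon, clipped to the horizon window.

Every replication is reproducible from its seed; `run_replications()`
derives independent per-replication seeds from the master seed and
reports across-replication means with t-based 95% confidence intervals,
the same presentation used for simulation tables in this literature.

## The synthetic country

`generate_country()` builds a self-contained world so the whole pipeline
is testable without any external data: log-normally distributed municipal
populations (a few towns dominate), a connected road network (local roads
inside municipalities, a spanning tree of main roads plus highways between
them, Euclidean lengths with a 1.2 circuity factor), population-
proportional stations with a 86/274 ALS share, hospitals in the largest
towns with Erlang drop-off means in 14–38 minutes, and a bimodal hourly
arrival profile peaking at 9–11 and 18–21 with a small-hours trough. The
default load is 13 calls per 100,000 inhabitants per day. The tiny preset
(10 municipalities, 8 stations) runs the full two-stage pipeline in
seconds; a country-scale preset (274 stations, 86 ALS, 8 towns, 5.4 M
inhabitants) reproduces the shape of the nationwide application.

What the generator does *not* emulate: real road geometry and turn
restrictions, commuter-driven ambient population shifts, seasonal or
day-of-week demand structure, hospital capacity constraints, and spatial
correlation between diagnosis mix and place. Passing tests on synthetic
data therefore demonstrate the correctness and internal consistency of
the method — optimality of the solver, fidelity of the event mechanics,
recovery of configured distributions — not the magnitude of improvements
attainable on any real system.

## Problem sizes and numerical choices

The test suite exercises the solver against exhaustive enumeration on
instances up to 12 candidate sites ($p \le 4$, $q \le 2$), where
enumeration is airtight; budget monotonicity on 50 instances; NHPP rate
recovery on 100-day streams; and the simulator on hand-traced
micro-scenarios with deterministic durations, on a single-node world
where the fleet workload must match the offered load $\lambda E[S]/m$,
and on 21-day runs that recover the transport probabilities from more
than $10^4$ served calls. Pipeline and simulation tests use the tiny
preset with horizons of a few days and a handful of replications — sizes
chosen so the full suite runs in well under a minute while every
mechanism is still exercised; the simulator's defaults (91 days, 10
replications) remain the recommended production setting.

Numerical conventions: all tie-breaks by lowest id (sites, ambulances,
hospitals); travel-time matrices must be finite (disconnected pairs are
errors, never silent sentinels); thresholds are inclusive; zero total
demand is an error for averages; empty strata are reported as absent
(`NA`), never as zero.

## Known limitations

* The lower level minimises travel from the nearest station *of any
  type*, while N and M calls can only be served by BLS units. On small
  fleets with a high ALS share, a design that is optimal for the combined
  tier can lengthen BLS-served response times — visible on the tiny
  preset, where the redesigned network improves K response but not always
  N/M. The effect fades as the BLS share grows toward realistic
  national proportions; it is inherent to the methodology, not to this
  implementation.
* One station per node in the optimisation model: multiplicity inside a
  town is carried only by fixed stations, and one station per ALS site is
  designated ALS.
* No cost model for opening/closing stations, no capacity constraints,
  no dynamic repositioning, no secondary inter-hospital transfers, no
  crew breaks — all deliberately out of scope.
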