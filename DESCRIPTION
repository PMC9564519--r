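Package: emsopt
Title: Two-Stage Redesign of Tiered Emergency Medical Service Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for redesigning the station network of a tiered (advanced
    and basic life support) emergency medical service operating over a mixed
    urban-rural road network. Provides the hierarchical pq-median location
    model with station-fixing rules and relocation-budget scenarios, solved
    to proven optimality by an exact branch-and-bound; a two-level spatial
    demand model (municipality zones nationwide, 250 m grid cells inside
    towns) driven by non-homogeneous Poisson call arrivals; an agent-based
    discrete-event simulator of ambulance operations with priority-dependent
    dispatch, en-route re-dispatch and time-dependent travel speeds; and the
    standard response-time, coverage, workload and mileage indicators with
    replication confidence intervals. A synthetic-country generator makes
    the whole pipeline runnable and testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
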