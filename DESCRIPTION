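Package: kar3team
Title: Single-Molecule Motility Analysis and Stochastic Modelling of
    Kinesin-14 Motor Teams
Version: 0.1.0
Authors@R:
    person("Kar3", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-molecule TIRF motility data of
    processive kinesin-14 heterodimers and for simulating elastically
    coupled motor teams. Includes a stochastic simulator of N motors
    linked by spring-like tails (full force-dependent and simplified
    variants, with grid fitting of stall force, binding and unbinding
    rates to size-resolved motility statistics), a synthetic-data
    generator for directed, diffusive and static trajectory populations
    and TIRF-like image stacks, a detection-and-linking tracking
    pipeline (median-filter shading correction, Gaussian smoothing,
    local-maximum detection, best-overlap linking), trajectory
    statistics (velocity and run-length distributions with censored
    exponential maximum likelihood, mean-squared-displacement power-law
    fitting, photobleaching step counting, constrained Gaussian-mixture
    fluorophore counting), and native molecular-weight determination
    from Stokes radius and sedimentation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
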