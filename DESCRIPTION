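Package: memax
Title: Growth-Rate Maximization for Multiscale Metabolism-and-Expression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solution methods for growth-rate maximization in multiscale
    constraint-based models of metabolism and macromolecular expression
    (ME models), where macromolecule dilution makes the problem bilinear in
    the growth rate and fluxes span many orders of magnitude. Provides an
    extended-precision (IEEE binary128) bounded-variable revised simplex
    with geometric-mean scaling, warm starts and residual certification;
    feasibility bisection and golden-section search on the growth rate; a
    warm-started sequential-linearization solver for the bilinear growth
    problem; warm-started flux variability analysis; gene-knockout
    essentiality screening; and a growth-coupled overproduction grid scan
    with proteome-sector accounting. Includes generators for desk-scale
    synthetic ME-like models, a versioned JSON model format with exact
    decimal coefficients, an exact rational vertex-enumeration oracle for
    small linear programs, and an MPS writer for cross-validation with
    external solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: GCC with __float128 and libquadmath
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
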