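Package: vortexflux
Title: Fitness Fluxes and Critical Population Sizes in Genetic Extinction Vortices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genetic component of extinction vortices in
    small populations. Implements a linkage-equilibrium model of deleterious and
    beneficial fitness fluxes built on the exact Moran fixation probability,
    locating the critical population size (Ncrit) at which net fitness flux is
    zero and the drought : meltdown ratio of flux derivatives that compares the
    importance of beneficial-mutation shortage (mutational drought) against
    deleterious fixation (mutational meltdown). A companion forward-time diploid
    Moran simulator over recombining linkage blocks re-derives these quantities
    under linkage disequilibrium, with optional per-mutation fixation tracking
    and neutral-tracer coalescent effective-size estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
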