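Package: senaccum
Title: Senescence Evolution by Catastrophic Accumulation of Age-Dependent
    Lethal Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the evolution of senescence in density-regulated,
    stationary populations where age-dependent dominant lethal mutations
    accumulate in the germline by genetic drift. Provides closed-form
    selection coefficients and drift-barrier critical ages for lethal
    mutations (with optional fecundity pleiotropy), the sequential-fixation
    iteration under which the maximum age at death collapses towards the
    age at first reproduction, the equilibrium interval for the maximum age
    at death when mutational effects can occur only at ages separated by a
    fixed grain, and a fast individual-based simulator (diploid, dominant
    lethals, density-dependent recruitment) exhibiting the decline, halting,
    and extinction regimes. Includes parameter-sweep tables and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
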