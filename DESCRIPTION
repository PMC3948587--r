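Package: migsel2
Title: Two-Locus Two-Deme Migration-Selection Balance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic continuous-time dynamics of two linked diallelic
    loci under divergent genic selection in two demes coupled by migration.
    Provides the coupled allele-frequency and linkage-disequilibrium
    differential equations, closed-form boundary and internal equilibria with
    their admissibility and stability conditions, perturbation approximations
    (weak migration, quasi-linkage equilibrium, complete linkage), critical
    migration-rate thresholds and the maximum migration rate permitting a
    stable two-locus polymorphism, bifurcation-diagram classification,
    migration load, a haplotype-based multilocus fixation index, invasion
    conditions for locally beneficial mutants linked to a polymorphic
    background, and the effective migration rate experienced by a neutral
    site located between the selected loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
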