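Package: genobuild
Title: Genotype Building: Founder-Parent Selection by Metaheuristic
    Optimisation of Haplotype-Block Fitness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects fixed-size founder-parent sets from a genotyped panel by
    maximising group fitness over haplotype-block values (Optimal Haplotype
    Selection, Optimal Population Value, or summed genomic estimated breeding
    values) with four seeded metaheuristics: a genetic algorithm, differential
    evolution over random keys, binary particle swarm optimisation with
    feasibility repair, and simulated annealing. Includes ridge-regression BLUP
    estimation of additive marker effects with REML tuning of the shrinkage
    ratio, linkage-disequilibrium haplotype-block construction, convergence
    benchmarking (normalised traces and area under the curve), a recurrent
    doubled-haploid breeding simulation for comparing founder strategies, and
    seeded synthetic-data generators for inbred panels with block-structured
    linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
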