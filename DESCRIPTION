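Package: fwdsim
Title: Individual-Based Forward Simulation of Evolve-and-Resequencing
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-generation, individual-based forward simulation of
    haplotype panels evolving under genetic drift, recombination and
    selection, aimed at the design and analysis of Evolve-and-Resequencing
    (E&R) experiments.  Founder haplotypes are supplied as nucleotides at
    biallelic SNPs and stored internally as a bit matrix.  Crossover counts
    per recombination-map window are derived from Haldane's mapping
    function and drawn from a Poisson distribution; sex-specific maps,
    hemizygous X chromosomes, selfing hermaphrodites and clonal
    reproduction are supported.  Selection may act directly on per-SNP
    selection coefficients (w-mode), through truncating selection on a
    quantitative trait (qt-mode), or through a trait-to-fitness mapping
    such as Gaussian stabilizing selection (qff-mode), with optional
    pairwise epistasis fitness tables, de novo mutation and migration.
    Output is written in the sync allele-count format consumed by Pool-Seq
    analysis tools.  Closed-form population-genetic expectations (Markov
    chain drift, the single-locus selection recursion, the breeder's
    equation, linkage-disequilibrium decay) are bundled for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
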