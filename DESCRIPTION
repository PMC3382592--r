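Package: htlmap
Title: Heterotic Trait Locus Mapping in Diallel Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps heterotic trait loci (HTLs) in multi-parent diallel
    populations of homozygous founder lines. Computes overdominant
    heterosis (ODH) together with mid-parent and best-parent heterosis
    from replicated field phenotypes, projects multi-allelic marker
    genotypes from founders onto their hybrids, and scans markers with a
    two-step procedure: a genotypic-group linear model with a
    permutation-based experiment-wise threshold, followed by one-sided
    Kolmogorov-Smirnov contrasts of each hetero-genotypic group against
    the pooled homozygotes. Supports population-structure cofactor
    adjustment, quantification of epistasis among detected loci by P/N
    recoding and sequential ANOVA, single-locus overdominance validation
    in an F2 with Hsu's multiple-comparisons-with-the-best, and a
    synthetic-data generator emulating the diallel design for testing
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
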