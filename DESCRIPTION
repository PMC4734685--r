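Package: rtgrecomb
Title: Loss-of-Heterozygosity and Recombination Analysis of Return-to-Growth Yeast Diploids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Genotype hybrid yeast diploids at dense SNP markers from parental
    allele depths, assemble loss-of-heterozygosity (LOH) tracts in mother-daughter
    cell pairs produced by meiotic reversion (Return To Growth), classify
    crossover, gene-conversion and non-crossover events, enumerate the
    probability that a crossover is masked by equational chromatid segregation
    and correct observed event counts accordingly, simulate RTG meioses with
    known ground truth, and map trait loci with a permutation-thresholded LOD
    scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
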