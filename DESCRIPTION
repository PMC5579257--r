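Package: targetgwas
Title: Screening Drug-Target Gene Regions for Disease-Association Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for interrogating the genomic neighborhoods of a
    drug's known target genes for case-control association signals. Builds
    flanked test regions from a drug-gene interaction table and gene
    coordinates, detects haplotype blocks by the Gabriel D'-confidence-interval
    method to derive an effective number of independent tests and a Bonferroni
    threshold, runs per-study additive-model logistic association adjusted for
    sex and age, combines studies by inverse-variance meta-analysis with a
    Cochran's Q heterogeneity gate, annotates lead SNPs through LD proxies and
    local eQTL/trait tables, and tests the target gene set for enrichment of
    disease-associated eSNPs by a one-sided Fisher exact test. Includes a
    founder-mosaic synthetic-data generator with planted effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
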