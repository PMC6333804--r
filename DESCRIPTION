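Package: sexscan
Title: Discovery of Sex-Determining Regions from Cohort Genotypes and
    Sex-Pooled Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate sex-determining regions in a sexed cohort by
    combining two genome-wide scans: an XY/ZW heterozygosity-pattern filter on
    cohort genotypes (variants heterozygous in every individual of the
    heterogametic sex and homozygous in the other) and a sliding-window
    differential scan of sex-pooled per-base read depth with Y-specific and
    X-like window classification and base-resolution breakpoint refinement.
    Candidate loci are ranked by concordant SNP and depth evidence. Candidate
    sequences are characterized by a CCHC zinc-knuckle motif scan,
    functional-versus-pseudogene copy classification, and a duplex in-silico
    PCR sex test. A seeded simulator emulates a diploid cohort with a
    male-specific insertion, an X-specific segment, fully sex-linked SNPs,
    autosomal Hardy-Weinberg SNPs and Poisson coverage, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
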