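Package: hostscreen
Title: Germplasm Diversity Assessment and Entropy-Weighted TOPSIS Host Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated germplasm-evaluation pipeline for screening elite
    host genotypes in parasitic-plant cultivation systems, built around the
    fourwing saltbush (Atriplex canescens) / desert broomrape (Cistanche
    deserticola) host system. Computes intraspecific ITS sequence diversity
    (GC content, polymorphic sites, nucleotide and haplotype diversity,
    neighbor-joining trees, minimum-spanning haplotype networks), descriptive
    and comparative phenotype statistics (monthly growth rates and phases,
    coefficients of variation, Shannon-Wiener phenotypic diversity, leaf-size
    classification, one-way ANOVA with Duncan's multiple range test),
    correlation screening with Benjamini-Hochberg FDR control, and
    multi-criteria genotype ranking by entropy-weighted TOPSIS with CRITIC
    weighting as a cross-check, including Spearman rank agreement.
    A seeded synthetic-data generator emulates the haplotype-sharing structure
    and trait tables of the study system so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
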