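Package: xcireact
Title: Allele-Specific Calling of X-Inactivation Escape and Reactivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies allele-specific expression from the active (Xa) and
    inactive (Xi) human X chromosome during cell-fusion reprogramming and
    calls Xi gene reactivation. Provides heterozygous-SNP ascertainment from
    isogenic clone pileups, dual-genome read disambiguation, per-SNP allele
    counting with base-quality accounting, per-gene Xa/Xi aggregation, a
    silenced/expressed beta-binomial mixture model fitted by EM that yields a
    per-gene escape probability (tau0), three-way gene classification across
    timepoints (escape, reactivation-sensitive, refractory), quantitative
    RFLP-qPCR allelic fractions with digestion-efficiency normalization,
    2^-DeltaCt relative expression, and rule-based RNA-FISH scoring of XIST
    patterns and allelic nascent-transcript signals. A synthetic-data
    generator emulates the statistical structure of the allele-specific
    RNA-seq so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
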