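Package: cyp2c19pgx
Title: Allele-Specific PCR Genotyping and Dose Guidance for CYP2C19
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design of mismatch-augmented allele-specific PCR (ARMS-style)
    genotyping assays for the CYP2C19 star alleles *2, *3 and *17, with an
    in-silico amplification simulator, diplotype assembly from the three
    diagnostic SNPs (rs4244285, rs4986893, rs12248560), translation of
    diplotypes into metabolizer phenotypes, and a provenance-tracked
    knowledge base of phenotype-conditioned pediatric dose recommendations
    for voriconazole, SSRIs, proton pump inhibitors and clopidogrel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
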