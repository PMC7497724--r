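Package: dosevcf
Title: Streaming Conversion of Oxford GEN Genotype Probabilities to VCF
    with Dosages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts Oxford/IMPUTE GEN genotype-probability files into
    BGZF-compressed, tabix-indexable VCF in a single bounded-memory pass.
    Each sample's posterior probabilities P(AA), P(AB), P(BB) yield a
    best-guess genotype (GT), the genotype probabilities (GP) and the
    expected alternate-allele dosage (DS = P(AB) + 2 P(BB)). Reads plain,
    gzip-compressed or standard-input streams, auto-detects the 5- and
    6-leading-column GEN dialects, and ships a seeded fixture generator
    plus an independent in-memory reference converter for testing.
License: MIT
Encoding: UTF-8
Imports:
    Rsamtools,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
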