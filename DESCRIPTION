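Package: hdsnode
Title: Privacy-Preserving Health Data Space Node Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale health data space node: privacy-preserving record
    linkage over keyed cryptographic long-term key (CLK) Bloom filter
    encodings with MinHash/LSH blocking, a pseudonymized person index with
    context-specific pseudonyms and authenticated AES-256 encryption at rest,
    rule-based de-identification of clinical free text, harmonization of
    heterogeneous source exports into a minimal OMOP-CDM-shaped data store
    (including FHIR QuestionnaireResponse conversion), a multi-level
    feature store with a minimal model store, and a four-level trust policy
    engine for node-to-node sharing. Ships deterministic synthetic-data
    generators (identities with planted duplicates, clinical notes with
    gold PII annotations, telehealth exports) so every component is
    testable without access to real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    openssl,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
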