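# hdsnode

A desk-scale R implementation of a *health data space node*: the building
block of a privacy-preserving registry infrastructure that links patient
records across institutions **without ever exchanging plaintext
identities**, harmonizes heterogeneous source exports into an
OMOP-CDM-shaped store, de-identifies clinical free text, and shares data
between nodes under an explicit four-level trust policy.

It is written for health-informatics engineers and registry methodologists
who want to study, test or teach these mechanisms end to end: every input
the toolkit needs (identities with planted duplicates, telehealth exports,
clinical notes with gold PII annotations, FHIR QuestionnaireResponses) is
produced by deterministic synthetic generators, so the whole pipeline runs
with no access to real patient data.

## The core mechanisms

**Privacy-preserving record linkage (PPRL).** Each person's identity
traits (first name, last name, date of birth, optional social security
number) are normalized, decomposed into padded bigrams, and hashed with
keyed HMAC-SHA-256 double hashing into one record-level *cryptographic
long-term key* (CLK) Bloom filter of 459 bits. For two filters A and B the
similarity is the Jaccard coefficient of their set bits,

```
J(A, B) = |A ∧ B| / |A ∨ B|,
```

which approximates the Jaccard coefficient of the underlying q-gram sets.
Pairs with `J ≥ 0.95` are **full matches** (consolidated automatically),
pairs with `0.80 ≤ J < 0.95` are **partial matches** (flagged for human
review), everything else is a non-match. To avoid comparing all pairs,
each filter gets a 64-permutation MinHash signature banded 16 × 4; only
LSH band collisions are scored (collision probability `1 − (1 − s⁴)¹⁶`,
i.e. > 0.999 at s = 0.8). The *duplication rate* is the percentage of
records implicated in full or flagged decisions.

**Pseudonymized person index.** Every person receives an independent
random 12-character pseudonym *per node context* (P1 at one node, P2 at
another, P3 centrally); encodings are stored encrypted (authenticated
AES-256) in the person index, cross-context links live only there, and
the health data store carries pseudonyms only — the two stores share no
other key.

**De-identification.** A rule engine (dictionaries, precursor promotion
such as "Dr. X", and regex classes) recognizes nine entity types —
healthcare professional, patient, person, location, phone number, e-mail
address, address, ZIP code, website — and replaces them with typed
placeholders (`[PATIENT-1]`) that are consistent across the whole corpus.
Evaluation is token-level: accuracy, sensitivity, specificity from a
corpus-wide confusion matrix.

**Harmonization, features, trust.** Versioned ETL converters pseudonymize
and map source payloads into ten OMOP CDM tables with
ICD-10/SNOMED-CT/LOINC/ATC demo vocabularies (brand drugs fall back to
their active ingredient); a FHIR QuestionnaireResponse becomes
1 VisitOccurrence + 1 SurveyConduct + n Observations. A multi-level
feature store (person / observation / measurement) quarantines registered
generator code until audited, recomputes affected features on every
ingest, and aggregates each level into a feature matrix. Node-to-node
sharing is gated by four strictly nested trust levels — artifacts only;
plus feature metadata; plus feature values + code; plus OMOP rows — with
levels 2–4 requiring a verified PPRL alignment (trait set, encoding
configuration and a keyed challenge–response on the shared secret).

## Worked example

```r
library(hdsnode)

ids <- generate_identities(1000, duplicate_rate = 0.007, seed = 7)
ids
#> <synthetic_identity_set> 1007 records, 7 planted duplicate pairs (seed 7)

cfg  <- encoding_config()
encs <- lapply(ids$records, encode_clk, config = cfg, secret = "node-secret")
encs[[1]]
#> <clk_encoding> 459 bits, 49 set (fill 10.7%), config 8a478136c0d2b946

sigs <- lapply(encs, minhash_signature, config = cfg, permutation_seed = 7L)
res  <- link_all(encs, sigs, linkage_thresholds(full = 0.95, partial = 0.80))
res
#> <linkage_result> 1007 records, 1007 clusters, 0 full matches, 7 flags, duplication rate 1.39%

head(res$flags[, c("a", "b", "similarity")], 3)
#>     a    b similarity
#> 1 319 1004  0.8800000
#> 2 327 1007  0.8421053
#> 3 597 1002  0.8627451
```

All 7 planted single-edit duplicates were flagged in the partial band
(review work for a human administrator), none was auto-consolidated, and
the duplication rate equals the planted ground truth: 14 implicated
records among 1,007 = 1.39%. Resolving a flag merges the clusters
(`resolve_flag(res, 1, "same_person")`) or puts the pair on a persistent
exclusion list.

De-identification with corpus-consistent placeholders:

```r
corp <- deidentify_corpus(generate_notes_with_pii(3, seed = 5))
corp
#> <deid_corpus> 3 notes, 6 redacted spans, 6 distinct placeholders
corp$results[[1]]$redacted_text
#> "Herr [PATIENT-1] meldet sich telefonisch. Begleitperson [PERSON-1] war anwesend. ..."
```

A complete four-node network (EMR + telehealth + register of deaths
sharing at trust level 4 into a central registry node) is one call:
`demo_network(n_patients = 20, days = 5, seed = 1)`.

A thin command-line wrapper for the generators, the linker and the
de-identifier is installed at `system.file("cli", "hds.R", package = "hdsnode")`.

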