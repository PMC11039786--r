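---
title: "Methods: privacy-preserving linkage, de-identification and harmonization in hdsnode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: privacy-preserving linkage, de-identification and harmonization in hdsnode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdsnode)
```

# Scope and model

`hdsnode` implements one *health data space node* — the unit of a
registry infrastructure in which each data source (a hospital EMR, a
telehealth system, a national register of deaths) keeps control of its
own data and shares with peers only what an explicit trust policy
permits. A node consists of five cooperating parts: a pseudonymization
layer with privacy-preserving record linkage (PPRL), a rule-based free
text de-identifier, an ETL framework into a minimal OMOP-CDM-shaped data
store, a multi-level feature store with a minimal model store, and a
policy engine for node-to-node exchange. This vignette documents the
methods, the defaults, and what the synthetic study conditions do and do
not establish.

# CLK Bloom filter encoding

## Procedure

Identity traits (patients: first name, last name, date of birth,
optionally a social security number; professionals: the first three;
clinical sites: the name) are normalized — lower case, trimmed,
whitespace collapsed, German umlauts transliterated (ä→ae, ö→oe, ü→ue,
ß→ss), other diacritics decomposed and stripped, dates rewritten to
ISO-8601. Each trait is decomposed into padded q-grams ("anna" → `_a an
nn na a_`), the q-gram sets of all traits are pooled (the record-level
*cryptographic long-term key* scope) and each q-gram sets
`hashes_per_gram` bits of one fixed-length Bloom filter by keyed double
hashing: two independent HMAC-SHA-256 digests of the q-gram under the
node secret give `h1`, `h2`, and bit `i` is `(h1 + i·h2) mod m`. Without
the secret the mapping from names to bits cannot be reproduced, which is
the defence against dictionary attacks on the encodings.

Similarity between two encodings is the Jaccard coefficient of their
set-bit patterns (two all-zero filters compare as 1, a degenerate case
that cannot arise from a valid record). We express all thresholds as
similarity; a Jaccard *distance* d corresponds to similarity 1 − d.

## Parameter defaults and calibration

| Parameter | Default | Unit / meaning |
|---|---|---|
| `bf_length_bits` | 459 | filter length in bits |
| `qgram_size` | 2 | q-gram length (bigrams) |
| `hashes_per_gram` | 2 | bits set per q-gram |
| `minhash_permutations` | 64 | MinHash signature length |
| `lsh_bands × lsh_rows` | 16 × 4 | LSH banding of the signature |

The filter length of 459 bits is the conventional value for this
encoding family and is treated as a default, not a constraint. Bigrams
with `_` padding are standard for person names. Per-trait q-gram pooling
(rather than hashing one concatenated string) avoids spurious cross-trait
q-grams at the trait boundaries.

`hashes_per_gram = 2` was fixed by a pre-registration numerical
calibration, not by convention. A typical patient record contributes
about 25–30 distinct bigrams; with k bits per gram the filter fill rate
grows with k, and every additional collision inflates the bitwise
Jaccard of *unrelated* records above their true q-gram Jaccard. In the
calibration (500 record pairs, half single-edit duplicates and half
unrelated, against a brute-force q-gram oracle) the mean absolute error
of the bitwise Jaccard was ≈ 0.01/0.06 (duplicates/unrelated) at k = 2
but ≈ 0.04/0.26 at k = 10. Since the package's own fidelity contract is
a mean absolute error ≤ 0.05, k = 2 (≈ 12% fill) is the default; larger
k buys more per-gram redundancy at the price of a systematic upward
similarity bias. The parameter remains exposed in `encoding_config()`.

## Blocking

Each encoding gets a MinHash signature over its set-bit index set, using
64 universal-hash permutations `h_j(x) = (a_j x + b_j) mod 463` (463 is
the smallest prime above the bit-index domain; `a_j`, `b_j` are drawn
deterministically from a permutation seed that all comparing parties
share). The expected per-slot agreement of two signatures equals the
bitwise Jaccard similarity. Signatures are banded 16 × 4; two records
are candidates iff they collide in at least one band, giving collision
probability `1 − (1 − s⁴)¹⁶` at similarity s — above 0.999 at the
partial threshold 0.8 and ~1 − 10⁻¹² at the full threshold 0.95, so
blocking recall is not the limiting factor at these problem sizes.
Candidate pairs are deduplicated before scoring.

# Linkage thresholds and decisions

Defaults are `full_match_min = 0.95` and `partial_match_min = 0.80`.
They were chosen — before any test was frozen — so that, under the
default encoder, an exact re-registration scores 1.0 (full) while one
single-character edit in a name (exact q-gram Jaccard ≈ 0.83–0.88 for
typical name lengths) lands in the partial band and is flagged rather
than silently merged. Both classification boundaries are inclusive at
the lower edge; classification is total and monotone in similarity.

Full matches consolidate automatically via union–find (a record that
full-matches several clusters merges them all). Partial matches are
flagged for human resolution: `same_person` merges the clusters and, in
the person index, keeps the *older* pseudonym (the newer becomes an
alias); `different_person` puts the pair on a persistent exclusion list
keyed by pseudonym pair so the same pair is never re-flagged. Every
decision and resolution is written to an append-only audit log.

The *duplication rate* is reported as the percentage of records
implicated in any full or flagged-partial decision. Note that planting a
fraction r of duplicate records therefore yields an expected rate of
about 2r/(1+r) × 100% (each planted pair implicates two records).

# Person index and encryption at rest

The node operates two stores with disjoint schemas and no shared keys
other than the pseudonym: the *person index* (pseudonyms + encrypted
encodings + cross-context links + flags) and the *data store* (OMOP
rows). Pseudonyms are 12 characters over a 32-symbol alphabet (A–Z and
2–9 minus I/O/0/1; ≈ 61 bits of entropy) from a cryptographically secure
source; collisions within a context are regenerated and logged.
Pseudonyms for one person in different contexts are generated
independently — nothing derives one from another; the link is a stored
fact in the person index only.

Encodings are encrypted at rest with authenticated AES-256: AES-256-CTR
with a fresh random 128-bit nonce per record plus an encrypt-then-MAC
HMAC-SHA-256 tag over nonce and ciphertext, verified before any
decryption. Encryption and MAC keys are derived independently from the
node secret, which lives outside both stores. An explicit
encrypt-then-MAC construction was chosen over the GCM interface of the
underlying crypto binding because the binding does not surface the GCM
authentication tag, which would have made the authenticated-mode
contract unverifiable; the MAC check restores exactly that contract
(wrong key or tampered ciphertext fails closed, no partial plaintext).

The MinHash blocking signatures are stored in plaintext alongside the
ciphertext: they are needed to select comparison candidates without
decrypting the whole index. A signature reveals strictly less than the
bit vector (64 min-indices), but it is derived data; deployments with a
stricter threat model should treat the index file as confidential as a
whole.

# Free-text de-identification

Nine entity types are recognized: healthcare professional, patient,
person, location, phone number, e-mail address, address, ZIP code,
website. Three rule families apply in a fixed precedence order —
structured regex classes (email > website > phone > ZIP > address >
location) first, then whole-token dictionary hits (internal names typed
*patient*, public names typed *person*), then precursor promotion
(titles/salutations such as "Dr.", "Herr" promote the following
capitalized token to a typed name span even when it is
out-of-dictionary). Within a class the longest match wins; a span is
dropped when it overlaps a span of a higher-precedence class, so the
result is always non-overlapping. The precedence reflects precision:
structured patterns rarely false-positive, dictionaries sometimes do,
promotion is the fallback. Regex defaults are Austrian-flavoured
(4-digit ZIP, +43 phone prefixes) and fully config-supplied, since such
rules do not translate across regions. The promotion rule requires a
capitalized-but-not-ALL-CAPS token, which also makes replacement a
fixpoint: placeholders like `[PATIENT-1]` match no rule class, so
re-running detection on redacted text finds nothing.

Each distinct (surface, type) pair maps to one placeholder `[TYPE-k]`
with a corpus-wide counter, so the same surname carries the same
placeholder in every note of a corpus; the map is injective in both
directions. Corpus processing drops author and patient metadata fields
from the output records.

Evaluation is **token-level**: notes are tokenized on whitespace with
offsets retained, a token is positive iff any span overlaps it, and
accuracy, sensitivity and specificity are computed from the pooled
confusion matrix. Span-level or message-level units would be defensible
alternatives; token-level is this package's documented, fixed choice
because it is reproducible from offsets alone and does not require
entity-boundary agreement.

# Harmonization (ETL) and curation

Converters are versioned, declarative transforms into a ten-table OMOP
CDM subset (Person, ObservationPeriod, VisitOccurrence,
ConditionOccurrence, DrugExposure, DeviceExposure, Measurement,
Observation, Note, SurveyConduct) with a deliberately minimal common
column set — desk-scale fidelity over schema completeness.
Pseudonymization strictly precedes transformation: converters reach
identities only through a `resolve_pseudonym` callback, so no trait can
reach a row. Every row carries provenance (converter id + version, batch
id); batches are fingerprinted so a byte-identical re-ingest is detected
and skipped; the batch log is append-only.

Decisions a reader should know:

* A blood-pressure reading becomes **two** Measurement rows (systolic,
  diastolic) sharing a reading-level `group_id`. The two-row form keeps
  one value per row (the CDM idiom) while the group id preserves the
  reading as a unit for consumers such as the pulse-pressure feature.
* Telemonitoring contacts have no exact standard concept; they are
  stored as VisitOccurrence rows with a custom source tag, and generic
  concepts are used for unsupervised home measurements at the cost of
  minor imprecision.
* Vocabulary mapping is deterministic lookup into a small packaged demo
  map (ICD-10, SNOMED-CT, LOINC, ATC); brand-name drugs missing from the
  map fall back to their active ingredient (`ingredient-fallback` note);
  fully unknown codes are *flagged* unmapped with the source value
  retained, never dropped. Full licensed vocabularies are out of scope —
  the lookup logic, not the content, is what is tested.
* A FHIR QuestionnaireResponse maps to exactly 1 VisitOccurrence (the
  act of completing the form) + 1 SurveyConduct (form identity and
  completion status) + one Observation per answered item, recursing into
  nested items.

Annotation corpora are built from Note rows only after passing the
de-identifier with one corpus-wide placeholder map; labels attach by
note id with referential integrity enforced.

# Feature and model store

Feature definitions carry metadata (author, timestamp, source code,
technology, description), a level (person / observation / measurement),
declared input tables and a version that must strictly increase. New
registrations are quarantined; only an administrator audit deploys them,
and quarantined code is never executed — the sandbox is procedural
(audit + state machine), mirroring an administrator-audit operating
model rather than technical isolation. Value sets are keyed by pseudonym
(person level) or `pseudonym|date` (observation/measurement level) and
stored as compact JSON-able structures with `computed_at` and the input
data version (batch count + fingerprint chain), which is how staleness
is detected. On every ingest, exactly the deployed features whose input
tables intersect the batch are recomputed; computation is transactional
per feature, so a failing generator records diagnostics without
poisoning stored values. The per-level feature matrix has one row per
key present in any value set and one column per deployed feature in
deterministic name order, with `NA` as the explicit missing marker.

The model store keeps externally developed artifacts as opaque
serialized blobs behind the same quarantine/audit gate; retrieval is
byte-exact and a deployed function artifact is applied to prediction
inputs as-is.

# Trust levels and node-to-node exchange

Four strictly nested sharing tiers: (1) artifacts only, (2) + feature
availability metadata, (3) + feature values with generator code, (4) +
OMOP rows. Levels 2–4 require a verified PPRL alignment: matching trait
set fingerprint, matching encoding configuration fingerprint (including
the blocking permutation seed) and a keyed challenge–response proof of
the shared secret — the mismatch report names the failing component
without transmitting key material. Level-3 payloads contain values and
code only, never data-store rows or note texts; level-4 pushes are
filtered by a per-peer table allow-list (the data transfer
specification), with refused tables stripped and reported. On receipt of
rows, the receiving node registers the sender's encodings under its own
context — consolidating with any prior registration of the same person —
and stores the rows under its own pseudonyms; the sender→receiver
pseudonym link is recorded in the receiving person index only. Transport
is in-process function calls; the exchange surface is the same one a
REST layer would wrap, which is deliberately out of scope here.

A labelling quirk worth noting: the canonical four-tier table in this
design space circulates with a duplicated "2" label on the third row;
the numbering used throughout this package (1 = artifacts, 2 = feature
information, 3 = feature values, 4 = all data) follows the prose
semantics of the tiers.

# Synthetic study conditions

The generators define the conditions under which the test suite and the
acceptance script run:

* **Identities**: names drawn from packaged Austrian/German pools (50
  first names, 50 surnames including umlauts), dates of birth uniform
  1930–1998, social security numbers present for 70% of records.
  Duplicates are planted at a configurable rate (0.7% in the
  deployment-scale runs, mirroring a realistic registry duplication
  level) with exactly one edit each, uniform over {substitution,
  deletion, insertion, adjacent transposition, day↔month swap} — the
  single-edit severity of typical typographic errors. Truth links pair
  each duplicate with its distinct base record, so they are trivially an
  equivalence relation.
* **Notes**: German-flavoured telehealth note templates; entity types
  round-robin so all nine types appear; every planted surface is
  recorded as a gold span; planted phones/emails/etc. are generated from
  the same surface families the default regex classes cover (verified by
  a cross-check test).
* **Telehealth export**: one record per patient per day per variable;
  per-patient baselines plus daily noise, clamped to configured
  physiologic bounds (systolic 95–180 mmHg, diastolic 55–110 mmHg, heart
  rate 45–130 bpm, weight 48–140 kg); wellbeing in {good, medium, bad};
  one medication with prescription and adherence flags; notes on ~15% of
  patient-days.

Problem sizes were chosen to exercise the mechanisms at meaningful scale
while keeping the full suite in the minutes range: 300 records × 20
seeds for the blocked-vs-exhaustive comparison, 1,000 base records × 10
seeds for duplication-rate recovery, 500 pairs for encoder fidelity, 200
notes for de-identification, a 20-patient four-node network.

What passing these conditions does *not* show: real names are not
uniform draws from a 50-name pool (frequency skew makes unrelated-pair
similarity higher in reality); real typos are not always single edits;
real clinical text is far messier than templated notes, and the
rule-based de-identifier's perfect recall on planted entities is a
property of the generator/rule co-design, not a claim about clinical
corpora; the demo vocabulary covers dozens, not thousands, of codes. The
package tests mechanism correctness, not field performance.

# Numerical and degenerate-input choices

* Bitwise Jaccard of two all-zero filters is defined as 1; MinHash of an
  all-zero filter is a degenerate-input error (it has no set-bit set).
* 48-bit prefixes of HMAC digests are used as integers (exact in a
  double); `h2` is reduced mod the filter length and forced to 1 if 0 so
  double hashing never degenerates to a single position.
* Classification boundaries are inclusive at the lower edge of each
  band; a pair blocked in several LSH bands is scored once.
* A deletion on a one-character name and a day↔month swap with day >
  12 degrade gracefully (no-op and substitution respectively), so a
  planted "duplicate" can occasionally be byte-identical to its base —
  then it is a full match by construction.
* Unparseable dates fail validation naming the trait; unmapped codes are
  flagged, not dropped; empty ingests write a batch log entry.

# Known limitations

* Keyed hashing is the only hardening of the encodings; salting,
  balancing or other frequency-attack countermeasures are out of scope.
* The person index must decrypt candidate encodings to score them, so
  the node secret is needed at registration time; a split-key or
  enclave design is not modelled.
* Only the CLK Bloom filter path is implemented; record-level hash
  alternatives (plain HMAC, Argon2) are not.
* The trust engine enforces payload *kinds*; it does not inspect
  payload semantics beyond the table allow-list.
* Features and models execute in-process after audit; there is no
  technical sandbox.
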