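test_that("trait normalization canonicalizes case, umlauts and dates", {
  rec <- identity_record(list(first_name = "  Anna ", last_name = "Müller",
                              date_of_birth = "01.02.1950"))
  tr <- normalize_traits(rec)
  expect_equal(unname(tr["first_name"]), "anna")
  expect_equal(unname(tr["last_name"]), "mueller")
  expect_equal(unname(tr["date_of_birth"]), "1950-02-01")
  expect_error(identity_record(list(first_name = "Anna", last_name = "",
                                    date_of_birth = "1950-01-01")),
               class = "hds_validation_error")
  expect_error(normalize_traits(identity_record(list(first_name = "A", last_name = "B",
                                                     date_of_birth = "not-a-date"))),
               class = "hds_validation_error")
})

test_that("padded q-gram extraction follows the set definition", {
  expect_setequal(extract_qgrams("anna", 2), c("_a", "an", "nn", "na", "a_"))
  expect_setequal(extract_qgrams("ab", 2), c("_a", "ab", "b_"))
  expect_identical(extract_qgrams("", 2), character(0))
  expect_error(extract_qgrams("anna", 0), class = "hds_config_error")
})

test_that("the default encoder emits deterministic 459-bit vectors", {
  cfg <- encoding_config()
  rec <- make_record("Anna", "Gruber")
  e1 <- encode_clk(rec, cfg, "secret-key")
  expect_length(e1$bits, 459)
  expect_equal(e1$set_count, sum(e1$bits))
  # identical normalized traits => identical vectors
  rec2 <- make_record("  ANNA", "gruber  ")
  expect_identical(encode_clk(rec2, cfg, "secret-key")$bits, e1$bits)
  expect_error(encode_clk(rec, cfg), class = "hds_key_error")
})

test_that("encodings under distinct secrets agree no better than unrelated records", {
  cfg <- encoding_config()
  rec <- make_record("Johanna", "Steiner")
  ea <- encode_clk(rec, cfg, "secret-A")
  eb <- encode_clk(rec, cfg, "secret-B")
  # null distribution: unrelated record pairs under one key stay below ~0.6
  expect_lt(jaccard_similarity(ea, eb), 0.6)
  expect_false(identical(ea$bits, eb$bits))
})

test_that("Jaccard similarity matches its set formula and guards configs", {
  cfg <- encoding_config()
  mk <- function(pos) {
    bits <- logical(459); bits[pos] <- TRUE
    structure(list(bits = bits, set_count = sum(bits),
                   config_fingerprint = cfg$fingerprint), class = "clk_encoding")
  }
  expect_equal(jaccard_similarity(mk(1:3), mk(1:3)), 1.0)
  expect_equal(jaccard_similarity(mk(1:3), mk(4:6)), 0.0)
  expect_equal(jaccard_similarity(mk(1:3), mk(2:4)), 0.5)
  expect_equal(jaccard_similarity(mk(integer(0)), mk(integer(0))), 1.0)
  other <- mk(1:3); other$config_fingerprint <- "different"
  expect_error(jaccard_similarity(mk(1:3), other), class = "hds_incompatibility_error")
})

test_that("Bloom filter Jaccard tracks the exact q-gram Jaccard", {
  cfg <- encoding_config()
  r1 <- make_record("anna", "maier")
  r2 <- make_record("anna", "mayer")
  bf <- jaccard_similarity(encode_clk(r1, cfg, "k"), encode_clk(r2, cfg, "k"))
  expect_lte(abs(bf - oracle_qgram_jaccard(r1, r2)), 0.10)

  # property over planted-duplicate pairs
  ids <- generate_identities(120, duplicate_rate = 0.5, seed = 21)
  encs <- lapply(ids$records, encode_clk, config = cfg, secret = "k")
  errs <- apply(ids$truth_links, 1, function(pr) {
    abs(jaccard_similarity(encs[[pr[1]]], encs[[pr[2]]]) -
          oracle_qgram_jaccard(ids$records[[pr[1]]], ids$records[[pr[2]]]))
  })
  expect_lte(mean(errs), 0.05)
})

test_that("adding a trait never clears existing bits (OR monotonicity)", {
  cfg <- encoding_config()
  without <- encode_clk(make_record("Eva", "Huber"), cfg, "k")
  with_ssn <- encode_clk(make_record("Eva", "Huber", ssn = "1234010150"), cfg, "k")
  expect_true(all(with_ssn$bits[without$bits]))
  expect_gte(with_ssn$set_count, without$set_count)
})

test_that("all encodings under one config share length and fingerprint", {
  cfg <- encoding_config()
  recs <- list(make_record("Anna", "Gruber"),
               identity_record(list(first_name = "Max", last_name = "Zangerl",
                                    date_of_birth = "1970-03-04"),
                               entity_kind = "healthcare_professional"),
               identity_record(list(name = "Kardiologie Innsbruck"),
                               entity_kind = "clinical_site"))
  encs <- lapply(recs, encode_clk, config = cfg, secret = "k")
  expect_true(all(vapply(encs, function(e) length(e$bits) == 459L, logical(1))))
  expect_length(unique(vapply(encs, `[[`, "", "config_fingerprint")), 1)
})

test_that("MinHash signatures estimate Jaccard and are deterministic", {
  cfg <- encoding_config()
  e1 <- encode_clk(make_record("Anna", "Maier"), cfg, "k")
  e2 <- encode_clk(make_record("Anna", "Mayer"), cfg, "k")
  s1 <- minhash_signature(e1, cfg, 5L)
  expect_identical(s1, minhash_signature(e1, cfg, 5L))
  expect_length(s1$values, 64)
  expect_length(s1$band_keys, 16)

  truth <- jaccard_similarity(e1, e2)
  agree <- vapply(1:100, function(seed) {
    mean(minhash_signature(e1, cfg, seed)$values ==
           minhash_signature(e2, cfg, seed)$values)
  }, numeric(1))
  expect_lte(abs(mean(agree) - truth), 0.15)

  # disjoint bit patterns agree almost never
  mk <- function(pos) {
    bits <- logical(459); bits[pos] <- TRUE
    structure(list(bits = bits, set_count = sum(bits),
                   config_fingerprint = cfg$fingerprint), class = "clk_encoding")
  }
  agree0 <- vapply(1:100, function(seed) {
    mean(minhash_signature(mk(1:40), cfg, seed)$values ==
           minhash_signature(mk(101:140), cfg, seed)$values)
  }, numeric(1))
  expect_lt(mean(agree0), 0.05)

  zero <- mk(integer(0))
  expect_error(minhash_signature(zero, cfg), class = "hds_validation_error")
})

test_that("encoding config invariants are enforced", {
  expect_error(encoding_config(lsh_bands = 10, lsh_rows = 4, minhash_permutations = 64),
               class = "hds_config_error")
  expect_error(encoding_config(bf_length_bits = 0), class = "hds_config_error")
  cfgs <- list(encoding_config(), encoding_config(qgram_size = 3))
  expect_false(cfgs[[1]]$fingerprint == cfgs[[2]]$fingerprint)
})
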