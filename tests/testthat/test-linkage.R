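test_that("classification is total, monotone and threshold-exact", {
  th <- linkage_thresholds(0.95, 0.80)
  expect_equal(classify_pair(1.0, th), "full")
  expect_equal(classify_pair(0.0, th), "non_match")
  expect_equal(classify_pair(0.90, th), "partial")
  expect_equal(classify_pair(0.95, th), "full")    # boundary inclusive
  expect_equal(classify_pair(0.80, th), "partial")
  expect_error(classify_pair(1.2, th), class = "hds_validation_error")
  expect_error(linkage_thresholds(0.8, 0.95), class = "hds_config_error")
  # monotone non-decreasing in similarity
  sims <- seq(0, 1, by = 0.01)
  ranks <- match(classify_pair(sims, th), c("non_match", "partial", "full"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("LSH blocking is sound: subset of all pairs, identical signatures always collide", {
  cfg <- encoding_config()
  ids <- generate_identities(60, duplicate_rate = 0.1, seed = 3)
  es <- encode_set(ids, cfg, "k")
  cand <- block_candidates(es$signatures)
  n <- length(es$signatures)
  expect_true(all(cand[, "a"] < cand[, "b"]))
  expect_lte(nrow(cand), choose(n, 2))
  # a record and its exact copy share a signature and must be blocked
  es2 <- list(signatures = c(es$signatures, es$signatures[1]))
  cand2 <- block_candidates(es2$signatures)
  expect_true(any(cand2[, "a"] == 1 & cand2[, "b"] == n + 1))
  expect_identical(nrow(block_candidates(es$signatures[1])), 0L)
  # mixed band structures rejected
  bad <- es$signatures
  bad[[2]] <- minhash_signature(es$encodings[[2]], cfg, permutation_seed = 99L)
  expect_error(block_candidates(bad), class = "hds_incompatibility_error")
})

test_that("blocked linkage reproduces exhaustive all-pairs linkage on planted duplicates", {
  cfg <- encoding_config()
  th <- linkage_thresholds()
  ids <- generate_identities(100, duplicate_rate = 0.1, seed = 17)
  es <- encode_set(ids, cfg, "k")
  res <- link_all(es$encodings, es$signatures, th)

  sim <- exhaustive_similarity(es$encodings)
  n <- length(es$encodings)
  oracle_full <- which(sim >= th$full_match_min & upper.tri(sim), arr.ind = TRUE)
  oracle_partial <- which(sim >= th$partial_match_min & sim < th$full_match_min &
                            upper.tri(sim), arr.ind = TRUE)
  got_full <- res$decisions[res$decisions$klass == "full", c("a", "b")]
  expect_setequal(paste(got_full$a, got_full$b),
                  paste(pmin(oracle_full[, 1], oracle_full[, 2]),
                        pmax(oracle_full[, 1], oracle_full[, 2])))
  # candidate set covers every oracle pair at or above the partial threshold
  cand_keys <- paste(res$flags$a, res$flags$b)
  oracle_keys <- paste(pmin(oracle_partial[, 1], oracle_partial[, 2]),
                       pmax(oracle_partial[, 1], oracle_partial[, 2]))
  expect_gte(mean(oracle_keys %in% cand_keys), 0.99)
  # clusters are a partition
  expect_setequal(unlist(res$clusters), seq_len(n))
})

test_that("duplicate-free input yields singleton clusters and zero rate", {
  cfg <- encoding_config()
  ids <- generate_identities(40, duplicate_rate = 0, seed = 23)
  es <- encode_set(ids, cfg, "k")
  res <- link_all(es$encodings, es$signatures)
  expect_true(all(lengths(res$clusters) == 1))
  expect_equal(nrow(res$flags), 0)
  expect_equal(res$duplication_rate, 0.0)
})

test_that("an exact copy consolidates into one cluster of size two", {
  cfg <- encoding_config()
  rec <- make_record("Anna", "Gruber")
  encs <- list(encode_clk(rec, cfg, "k"), encode_clk(rec, cfg, "k"))
  sigs <- lapply(encs, minhash_signature, config = cfg, permutation_seed = 7L)
  res <- link_all(encs, sigs)
  expect_length(res$clusters, 1)
  expect_equal(sort(res$clusters[[1]]), c(1, 2))
})

test_that("flag resolution merges or excludes and audits every verdict", {
  cfg <- encoding_config()
  ids <- generate_identities(80, duplicate_rate = 0.15, seed = 29)
  es <- encode_set(ids, cfg, "k")
  res <- link_all(es$encodings, es$signatures)
  expect_gte(nrow(res$flags), 2)  # planted single-edit typos yield partials
  n_clusters <- length(res$clusters)

  merged <- resolve_flag(res, 1, "same_person", resolver = "reviewer-1")
  expect_equal(length(merged$clusters), n_clusters - 1)
  kept <- resolve_flag(merged, 1, "different_person", resolver = "reviewer-1")
  expect_equal(length(kept$clusters), n_clusters - 1)
  expect_equal(nrow(kept$exclusions), 1)
  expect_length(kept$audit, 2)
  expect_error(resolve_flag(kept, 999, "same_person"), class = "hds_not_found_error")

  # excluded pairs are not re-flagged on a rerun
  rerun <- link_all(es$encodings, es$signatures, res$thresholds,
                    exclusions = kept$exclusions)
  key <- paste(kept$exclusions[1, 1], kept$exclusions[1, 2])
  expect_false(key %in% paste(rerun$flags$a, rerun$flags$b))
})

test_that("all-false-positive partials leave only full-match clusters", {
  # deployment-shaped scenario: full matches consolidate automatically,
  # every flagged partial is reviewed and found to be a different person
  cfg <- encoding_config()
  ids <- generate_identities(150, duplicate_rate = 0.12, seed = 31)
  es <- encode_set(ids, cfg, "k")
  res <- link_all(es$encodings, es$signatures)
  n_full_clusters <- length(res$clusters)
  while (nrow(res$flags) > 0) {
    res <- resolve_flag(res, 1, "different_person", resolver = "expert")
  }
  expect_length(res$clusters, n_full_clusters)  # only full matches merged
  expect_equal(sum(lengths(res$clusters) > 1),
               length(unique(res$decisions$a[res$decisions$klass == "full"])))
})

test_that("duplication rate counts implicated records as a percentage", {
  mk_result <- function(full_pairs, partial_pairs, n) {
    decisions <- rbind(
      if (length(full_pairs)) data.frame(a = full_pairs[[1]], b = full_pairs[[2]],
                                         similarity = 1, klass = "full",
                                         logged_at = "", stringsAsFactors = FALSE),
      if (length(partial_pairs)) data.frame(a = partial_pairs[[1]], b = partial_pairs[[2]],
                                            similarity = 0.9, klass = "partial",
                                            logged_at = "", stringsAsFactors = FALSE))
    structure(list(decisions = decisions %||% data.frame(),
                   flags = if (is.null(decisions)) data.frame() else
                     decisions[decisions$klass == "partial", , drop = FALSE],
                   n_records = n),
              class = "linkage_result")
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  empty <- mk_result(NULL, NULL, 100)
  expect_equal(duplication_rate(empty, 100), 0.0)
  # 28 implicated records among 4,000 -> 0.70%
  r <- mk_result(list(1:9, 101:109), list(201:205, 301:305), 4000)
  expect_equal(length(unique(c(1:9, 101:109, 201:205, 301:305))), 28)
  expect_equal(duplication_rate(r, 4000), 0.70)
  # one full pair among 200 records -> 1.0%
  r2 <- mk_result(list(1, 2), NULL, 200)
  expect_equal(duplication_rate(r2, 200), 1.0)
  expect_error(duplication_rate(r2, 0), class = "hds_validation_error")
})
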