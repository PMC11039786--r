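#' Linkage decision thresholds
#'
#' Similarity thresholds splitting pairwise Bloom filter comparisons into
#' full matches (auto-consolidated), partial matches (flagged for human
#' review) and non-matches. Defaults: full at 0.95, partial at 0.80 —
#' under the default encoder a single-character edit in a name typically
#' lands in the partial band.
#'
#' @param full_match_min minimum similarity of a full match.
#' @param partial_match_min minimum similarity of a partial match.
#' @return object of class `linkage_thresholds`.
#' @export
linkage_thresholds <- function(full_match_min = 0.95, partial_match_min = 0.80) {
  if (!(partial_match_min > 0 && partial_match_min < full_match_min && full_match_min <= 1)) {
    config_error("thresholds must satisfy 0 < partial_match_min < full_match_min <= 1")
  }
  structure(list(full_match_min = full_match_min, partial_match_min = partial_match_min),
            class = "linkage_thresholds")
}

#' Classify a pairwise similarity
#'
#' @param similarity Jaccard similarity in `[0, 1]`.
#' @param thresholds a [linkage_thresholds()].
#' @return `"full"`, `"partial"` or `"non_match"`.
#' @export
classify_pair <- function(similarity, thresholds = linkage_thresholds()) {
  if (!is.numeric(similarity) || any(is.na(similarity)) ||
      any(similarity < 0) || any(similarity > 1)) {
    validation_error("similarity must lie in [0, 1]")
  }
  ifelse(similarity >= thresholds$full_match_min, "full",
         ifelse(similarity >= thresholds$partial_match_min, "partial", "non_match"))
}

#' LSH candidate blocking over MinHash signatures
#'
#' A pair of records becomes a comparison candidate iff their MinHash
#' signatures collide in at least one LSH band. Candidates are
#' deduplicated (a pair colliding in several bands appears once).
#'
#' @param signatures list of [minhash_signature()] objects sharing one band
#'   structure (same configuration and permutation seed).
#' @return integer matrix with columns `a`, `b` (`a < b`) of candidate
#'   record indices; zero rows when fewer than two records.
#' @export
block_candidates <- function(signatures) {
  n <- length(signatures)
  if (n < 2L) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  fps <- vapply(signatures, function(s) paste0(s$config_fingerprint, "|", s$permutation_seed),
                character(1))
  if (length(unique(fps)) != 1L) {
    incompatibility_error("signatures mix band structures (config or permutation seed differ)")
  }
  buckets <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (key in signatures[[i]]$band_keys) {
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  pairs <- new.env(parent = emptyenv())
  for (key in ls(buckets)) {
    idx <- buckets[[key]]
    if (length(idx) < 2L) next
    cmb <- utils::combn(sort(idx), 2L)
    for (j in seq_len(ncol(cmb))) {
      pairs[[paste(cmb[1L, j], cmb[2L, j], sep = "-")]] <- cmb[, j]
    }
  }
  keys <- ls(pairs)
  out <- matrix(0L, nrow = length(keys), ncol = 2L, dimnames = list(NULL, c("a", "b")))
  for (r in seq_along(keys)) out[r, ] <- pairs[[keys[r]]]
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# Partition 1..n into the transitive closure of the given pairs
# (union-find with path compression).
clusters_from_pairs <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- match(roots, sort(unique(roots)))
  split(seq_len(n), membership)
}

#' Blocked linkage of a set of encodings
#'
#' Computes Bloom filter Jaccard similarity on the LSH-blocked candidate
#' pairs only, classifies each scored pair against the thresholds, merges
#' full matches into clusters (transitive closure via union-find) and
#' flags partial matches for human resolution. Every scored decision is
#' logged with its similarity and timestamp.
#'
#' @param encodings list of `clk_encoding` objects.
#' @param signatures list of matching [minhash_signature()] objects
#'   (aligned by record index).
#' @param thresholds a [linkage_thresholds()].
#' @param exclusions optional two-column matrix of record-index pairs
#'   confirmed to be different persons; these are never flagged again.
#' @return object of class `linkage_result`: `clusters` (list of integer
#'   vectors partitioning the records), `decisions` (log of scored pairs),
#'   `flags` (partial matches awaiting resolution), `duplication_rate`
#'   (percent), `n_records`, `thresholds`.
#' @export
link_all <- function(encodings, signatures, thresholds = linkage_thresholds(),
                     exclusions = NULL) {
  stopifnot(length(encodings) == length(signatures))
  n <- length(encodings)
  cand <- block_candidates(signatures)
  excl_keys <- character(0)
  if (!is.null(exclusions) && nrow(exclusions)) {
    excl_keys <- paste(pmin(exclusions[, 1L], exclusions[, 2L]),
                       pmax(exclusions[, 1L], exclusions[, 2L]), sep = "-")
  }
  decisions <- data.frame(a = integer(0), b = integer(0), similarity = numeric(0),
                          klass = character(0), logged_at = character(0),
                          stringsAsFactors = FALSE)
  if (nrow(cand)) {
    sims <- vapply(seq_len(nrow(cand)), function(r) {
      jaccard_similarity(encodings[[cand[r, 1L]]], encodings[[cand[r, 2L]]])
    }, numeric(1))
    klass <- classify_pair(sims, thresholds)
    keep <- klass != "non_match"
    decisions <- data.frame(a = cand[keep, 1L], b = cand[keep, 2L],
                            similarity = sims[keep], klass = klass[keep],
                            logged_at = rep(now_stamp(), sum(keep)),
                            stringsAsFactors = FALSE)
    excluded <- paste(decisions$a, decisions$b, sep = "-") %in% excl_keys
    decisions <- decisions[!(excluded & decisions$klass == "partial"), , drop = FALSE]
  }
  full_pairs <- as.matrix(decisions[decisions$klass == "full", c("a", "b"), drop = FALSE])
  res <- structure(
    list(clusters = clusters_from_pairs(n, full_pairs),
         decisions = decisions,
         flags = decisions[decisions$klass == "partial", , drop = FALSE],
         n_records = n,
         thresholds = thresholds,
         exclusions = exclusions,
         audit = list()),
    class = "linkage_result"
  )
  res$duplication_rate <- duplication_rate(res, n)
  res
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> %d records, %d clusters, %d full matches, %d flags, duplication rate %.2f%%\n",
              x$n_records, length(x$clusters), sum(x$decisions$klass == "full"),
              nrow(x$flags), x$duplication_rate))
  invisible(x)
}

#' Resolve a flagged partial match
#'
#' A human verdict on a flagged pair: `same_person` merges the two
#' clusters; `different_person` removes the flag and places the pair on
#' the persistent exclusion list so it is never flagged again. Every
#' resolution is appended to the result's audit trail.
#'
#' @param result a [link_all()] result.
#' @param flag_index row index into `result$flags`.
#' @param verdict `"same_person"` or `"different_person"`.
#' @param resolver identifier of the resolving actor.
#' @return the updated `linkage_result`.
#' @export
resolve_flag <- function(result, flag_index, verdict = c("same_person", "different_person"),
                         resolver = "admin") {
  stopifnot(inherits(result, "linkage_result"))
  verdict <- match.arg(verdict)
  if (!is_count(flag_index) || flag_index > nrow(result$flags)) {
    not_found_error("no such flag")
  }
  fl <- result$flags[flag_index, ]
  key <- paste(fl$a, fl$b, sep = "-")
  resolved <- vapply(result$audit, function(e) e$pair, character(1))
  if (key %in% resolved) conflict_error("flag already resolved")
  result$audit[[length(result$audit) + 1L]] <-
    list(pair = key, verdict = verdict, resolver = resolver, at = now_stamp())
  if (verdict == "same_person") {
    pairs <- rbind(do.call(rbind, lapply(result$clusters, function(cl) {
      if (length(cl) > 1L) cbind(cl[-length(cl)], cl[-1L]) else NULL
    })), c(fl$a, fl$b))
    result$clusters <- clusters_from_pairs(result$n_records, pairs)
  } else {
    result$exclusions <- rbind(result$exclusions, c(fl$a, fl$b))
  }
  result$flags <- result$flags[-flag_index, , drop = FALSE]
  result
}

#' Duplication rate
#'
#' Fraction of records implicated in any full-match or flagged
#' partial-match decision, expressed as a percentage of all registered
#' records.
#'
#' @param result a `linkage_result`.
#' @param total_records denominator (defaults to the result's record count).
#' @return percentage in `[0, 100]`.
#' @export
duplication_rate <- function(result, total_records = result$n_records) {
  stopifnot(inherits(result, "linkage_result"))
  if (!is_count(total_records)) validation_error("total_records must be >= 1")
  involved <- unique(c(result$decisions$a[result$decisions$klass == "full"],
                       result$decisions$b[result$decisions$klass == "full"],
                       result$flags$a, result$flags$b))
  100 * length(involved) / total_records
}
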