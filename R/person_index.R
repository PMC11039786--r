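#' Create a pseudonymized person index
#'
#' The person index is one of the node's two independent stores: it holds
#' context-specific pseudonyms and AES-256-GCM-encrypted Bloom filter
#' encodings, and it is the only place where cross-context links between
#' pseudonyms are traceable. It never stores plaintext traits, and the
#' health data store never stores encodings — only pseudonyms cross the
#' boundary.
#'
#' @param config the [encoding_config()] all registrations must share.
#' @param permutation_seed MinHash permutation seed shared across the index
#'   (and with aligned peer nodes).
#' @return an environment of class `person_index`.
#' @export
person_index <- function(config = encoding_config(), permutation_seed = 20459L) {
  idx <- new.env(parent = emptyenv())
  idx$config <- config
  idx$permutation_seed <- as.integer(permutation_seed)
  idx$contexts <- new.env(parent = emptyenv())   # context -> named list of entries
  idx$links <- list()                            # list of data.frames (pseudonym, context)
  idx$flags <- data.frame(context = character(0), pseudonym_a = character(0),
                          pseudonym_b = character(0), similarity = numeric(0),
                          logged_at = character(0), stringsAsFactors = FALSE)
  idx$exclusions <- character(0)                 # "context|pA|pB" keys, pA < pB
  idx$aliases <- list()                          # merged pseudonym -> surviving pseudonym
  idx$audit <- list()
  class(idx) <- "person_index"
  idx
}

#' @export
print.person_index <- function(x, ...) {
  ctxs <- ls(x$contexts)
  counts <- vapply(ctxs, function(cx) length(x$contexts[[cx]]), integer(1))
  cat("<person_index>", if (length(ctxs)) paste0(ctxs, " (", counts, ")", collapse = ", ")
      else "empty", "\n")
  invisible(x)
}

.pseudonym_alphabet <- c(setdiff(LETTERS, c("I", "O")), as.character(2:9))

#' Generate a random alphanumeric pseudonym
#'
#' 12 characters over A-Z and 2-9 excluding the ambiguous I/O/0/1, drawn
#' from a cryptographically secure source (32-symbol alphabet: 61 bits of
#' entropy). Collisions within a context are regenerated and logged.
#'
#' @param length pseudonym length.
#' @return character scalar.
#' @export
new_pseudonym <- function(length = 12L) {
  # 32 symbols divide 256 evenly, so the byte modulus is unbiased
  idx <- as.integer(openssl::rand_bytes(length)) %% length(.pseudonym_alphabet)
  paste(.pseudonym_alphabet[idx + 1L], collapse = "")
}

issue_pseudonym <- function(index, context) {
  entries <- index$contexts[[context]]
  repeat {
    p <- new_pseudonym()
    if (is.null(entries) || is.null(entries[[p]])) return(p)
    index$audit[[length(index$audit) + 1L]] <-
      list(event = "pseudonym_collision_regenerated", context = context, at = now_stamp())
  }
}

# Independent 256-bit encryption and MAC keys derived from the node secret.
aes_keys_from_secret <- function(secret) {
  if (is.raw(secret)) secret <- openssl::base64_encode(secret)
  list(enc = openssl::sha256(charToRaw(paste0("hds-aes-enc|", secret))),
       mac = openssl::sha256(charToRaw(paste0("hds-aes-mac|", secret))))
}

#' Encrypt / decrypt a Bloom filter encoding at rest
#'
#' Authenticated AES-256 encryption with a fresh random nonce per record:
#' AES-256-CTR for confidentiality plus an encrypt-then-MAC HMAC-SHA-256
#' tag over nonce and ciphertext. The tag is verified before any
#' decryption, so tampered ciphertext or a wrong key fails authentication
#' without releasing partial plaintext.
#'
#' @param encoding a `clk_encoding`.
#' @param key 256-bit raw key material, or any secret string; independent
#'   encryption and MAC keys are derived from it. Supplied from outside
#'   the persistence layer.
#' @return `encrypt_at_rest`: object of class `hds_ciphertext` (fields
#'   `iv`, `data`, `tag`); `decrypt_at_rest`: the restored `clk_encoding`.
#' @export
encrypt_at_rest <- function(encoding, key) {
  stopifnot(inherits(encoding, "clk_encoding"))
  k <- aes_keys_from_secret(key)
  iv <- openssl::rand_bytes(16)
  plain <- serialize(unclass(encoding), NULL, version = 2L)
  data <- as.raw(openssl::aes_ctr_encrypt(plain, key = k$enc, iv = iv))
  tag <- as.raw(openssl::sha256(c(iv, data), key = k$mac))
  structure(list(iv = iv, data = data, tag = tag), class = "hds_ciphertext")
}

#' @rdname encrypt_at_rest
#' @param ciphertext an `hds_ciphertext`.
#' @export
decrypt_at_rest <- function(ciphertext, key) {
  stopifnot(inherits(ciphertext, "hds_ciphertext"))
  k <- aes_keys_from_secret(key)
  expected <- as.raw(openssl::sha256(c(ciphertext$iv, ciphertext$data), key = k$mac))
  if (!identical(expected, as.raw(ciphertext$tag))) {
    key_error("authentication failed: wrong key or tampered ciphertext")
  }
  plain <- openssl::aes_ctr_decrypt(ciphertext$data, key = k$enc, iv = ciphertext$iv)
  structure(unserialize(plain), class = "clk_encoding")
}

#' Register an identity in the person index
#'
#' Encodes the record under the node secret, runs blocked linkage against
#' the already-registered encodings of the same context, and decides:
#' a full match returns the existing pseudonym (`consolidated`); a partial
#' match issues a new pseudonym but flags the pair for human review
#' (`flagged`); otherwise a fresh pseudonym is issued (`new`). Only the
#' encrypted encoding and the MinHash signature are persisted — the raw
#' traits are discarded.
#'
#' @param index a [person_index()].
#' @param record an [identity_record()].
#' @param context node context identifier.
#' @param secret node secret; the HMAC key for encoding, from which the
#'   at-rest AES key is derived. Held outside the index.
#' @param thresholds a [linkage_thresholds()].
#' @return list with `pseudonym`, `decision` (`new` / `consolidated` /
#'   `flagged`), and `similarity` of the best match (NA when none).
#' @export
register_identity <- function(index, record, context, secret,
                              thresholds = linkage_thresholds()) {
  stopifnot(inherits(index, "person_index"))
  enc <- encode_clk(record, index$config, secret)
  register_encoding(index, enc, context, secret, thresholds,
                    entity_kind = record$entity_kind)
}

#' Register a pre-computed encoding (cross-node path)
#'
#' The registration path used when a peer node shares an encoding produced
#' under the aligned configuration and shared secret: identical to
#' [register_identity()] but without access to any traits.
#'
#' @inheritParams register_identity
#' @param encoding a `clk_encoding` under the index's configuration.
#' @param entity_kind entity kind recorded with the entry.
#' @export
register_encoding <- function(index, encoding, context, secret,
                              thresholds = linkage_thresholds(),
                              entity_kind = "patient") {
  stopifnot(inherits(index, "person_index"), inherits(encoding, "clk_encoding"))
  if (encoding$config_fingerprint != index$config$fingerprint) {
    incompatibility_error("encoding configuration does not match the index")
  }
  sig <- minhash_signature(encoding, index$config, index$permutation_seed)
  entries <- index$contexts[[context]] %||% list()
  best_p <- NA_character_; best_sim <- NA_real_
  if (length(entries)) {
    cand <- character(0)
    keys <- new.env(parent = emptyenv())
    for (bk in sig$band_keys) keys[[bk]] <- TRUE
    for (p in names(entries)) {
      if (any(vapply(entries[[p]]$signature$band_keys,
                     function(bk) isTRUE(keys[[bk]]), logical(1)))) {
        cand <- c(cand, p)
      }
    }
    if (length(cand)) {
      sims <- vapply(cand, function(p) {
        jaccard_similarity(encoding, decrypt_at_rest(entries[[p]]$ciphertext, secret))
      }, numeric(1))
      best <- which.max(sims)
      best_p <- cand[best]; best_sim <- sims[best]
    }
  }
  decision <- if (!is.na(best_sim)) classify_pair(best_sim, thresholds) else "non_match"
  if (decision == "full") {
    index$audit[[length(index$audit) + 1L]] <-
      list(event = "consolidated", context = context, pseudonym = best_p,
           similarity = best_sim, at = now_stamp())
    return(list(pseudonym = best_p, decision = "consolidated", similarity = best_sim))
  }
  p <- issue_pseudonym(index, context)
  entries[[p]] <- list(pseudonym = p, entity_kind = entity_kind,
                       ciphertext = encrypt_at_rest(encoding, secret),
                       signature = sig, created_at = now_stamp())
  index$contexts[[context]] <- entries
  if (decision == "partial") {
    key <- paste(context, min(p, best_p), max(p, best_p), sep = "|")
    if (!(key %in% index$exclusions)) {
      index$flags <- rbind(index$flags, data.frame(
        context = context, pseudonym_a = best_p, pseudonym_b = p,
        similarity = best_sim, logged_at = now_stamp(), stringsAsFactors = FALSE))
      index$audit[[length(index$audit) + 1L]] <-
        list(event = "flagged", context = context, pair = c(best_p, p),
             similarity = best_sim, at = now_stamp())
      return(list(pseudonym = p, decision = "flagged", similarity = best_sim))
    }
  }
  index$audit[[length(index$audit) + 1L]] <-
    list(event = "registered", context = context, pseudonym = p, at = now_stamp())
  list(pseudonym = p, decision = "new", similarity = best_sim)
}

#' Resolve a flagged pair in the person index
#'
#' `same_person` merges the two pseudonyms, keeping the older one (the
#' newer becomes an alias); `different_person` places the pair on the
#' persistent exclusion list so it is never flagged again.
#'
#' @param index a [person_index()].
#' @param flag_index row index into `index$flags`.
#' @param verdict `"same_person"` or `"different_person"`.
#' @param resolver identifier of the resolving actor.
#' @export
index_resolve_flag <- function(index, flag_index,
                               verdict = c("same_person", "different_person"),
                               resolver = "admin") {
  verdict <- match.arg(verdict)
  if (!is_count(flag_index) || flag_index > nrow(index$flags)) not_found_error("no such flag")
  fl <- index$flags[flag_index, ]
  key <- paste(fl$context, min(fl$pseudonym_a, fl$pseudonym_b),
               max(fl$pseudonym_a, fl$pseudonym_b), sep = "|")
  if (verdict == "same_person") {
    # keep the older pseudonym (pseudonym_a pre-dates pseudonym_b)
    index$aliases[[fl$pseudonym_b]] <- fl$pseudonym_a
  } else {
    index$exclusions <- union(index$exclusions, key)
  }
  index$audit[[length(index$audit) + 1L]] <-
    list(event = "flag_resolved", key = key, verdict = verdict,
         resolver = resolver, at = now_stamp())
  index$flags <- index$flags[-flag_index, , drop = FALSE]
  invisible(index)
}

#' Canonical pseudonym after flag resolutions
#'
#' @param index a [person_index()].
#' @param pseudonym possibly-aliased pseudonym.
#' @return the surviving pseudonym.
#' @export
canonical_pseudonym <- function(index, pseudonym) {
  while (!is.null(index$aliases[[pseudonym]])) pseudonym <- index$aliases[[pseudonym]]
  pseudonym
}

#' Link pseudonyms of one person across contexts
#'
#' Records, inside the person index only, that two context-specific
#' pseudonyms refer to the same person. Link groups merge transitively. A
#' pseudonym cannot be linked to its own context (one pseudonym per
#' context per person).
#'
#' @param index a [person_index()].
#' @param pseudonym_a,context_a,pseudonym_b,context_b the two endpoints;
#'   each pseudonym must exist in its context.
#' @return data frame (`pseudonym`, `context`) — the full link group.
#' @export
link_contexts <- function(index, pseudonym_a, context_a, pseudonym_b, context_b) {
  for (pc in list(c(pseudonym_a, context_a), c(pseudonym_b, context_b))) {
    entries <- index$contexts[[pc[2]]]
    if (is.null(entries) || is.null(entries[[pc[1]]])) {
      not_found_error(sprintf("pseudonym '%s' unknown in context '%s'", pc[1], pc[2]))
    }
  }
  if (context_a == context_b) {
    validation_error("cannot link two pseudonyms within one context")
  }
  grp_of <- function(p, cx) {
    for (i in seq_along(index$links)) {
      g <- index$links[[i]]
      if (any(g$pseudonym == p & g$context == cx)) return(i)
    }
    NA_integer_
  }
  ia <- grp_of(pseudonym_a, context_a); ib <- grp_of(pseudonym_b, context_b)
  add <- data.frame(pseudonym = c(pseudonym_a, pseudonym_b),
                    context = c(context_a, context_b), stringsAsFactors = FALSE)
  if (is.na(ia) && is.na(ib)) {
    index$links[[length(index$links) + 1L]] <- add
    gi <- length(index$links)
  } else if (!is.na(ia) && !is.na(ib) && ia != ib) {
    index$links[[ia]] <- unique(rbind(index$links[[ia]], index$links[[ib]], add))
    index$links[[ib]] <- NULL
    gi <- if (ib < ia) ia - 1L else ia
  } else {
    gi <- if (!is.na(ia)) ia else ib
    index$links[[gi]] <- unique(rbind(index$links[[gi]], add))
  }
  g <- index$links[[gi]]
  if (anyDuplicated(g$context)) {
    validation_error("link would give one person two pseudonyms in one context")
  }
  g
}

#' Resolve a linked pseudonym into another context
#'
#' @param index a [person_index()].
#' @param pseudonym,context the known endpoint.
#' @param target_context the context whose pseudonym is wanted.
#' @return the pseudonym in `target_context`, or `NA` if not linked.
#' @export
resolve_link <- function(index, pseudonym, context, target_context) {
  for (g in index$links) {
    if (any(g$pseudonym == pseudonym & g$context == context)) {
      hit <- g$pseudonym[g$context == target_context]
      return(if (length(hit)) hit[[1]] else NA_character_)
    }
  }
  NA_character_
}

#' Export the person index (encrypted) as a portable JSON file
#'
#' The export carries pseudonyms, base64 ciphertexts and blocking
#' signatures — never a trait string or a plaintext bit vector.
#'
#' @param index a [person_index()].
#' @param path output path.
#' @export
export_index <- function(index, path) {
  ctxs <- ls(index$contexts)
  out <- list(
    config_fingerprint = index$config$fingerprint,
    permutation_seed = index$permutation_seed,
    contexts = setNames(lapply(ctxs, function(cx) {
      entries <- index$contexts[[cx]]
      lapply(unname(entries), function(e) {
        list(pseudonym = e$pseudonym, entity_kind = e$entity_kind,
             iv = as.character(openssl::base64_encode(e$ciphertext$iv)),
             ciphertext = as.character(openssl::base64_encode(e$ciphertext$data)),
             tag = as.character(openssl::base64_encode(e$ciphertext$tag)),
             signature = as.integer(e$signature$values),
             created_at = e$created_at)
      })
    }), ctxs),
    links = index$links
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
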