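#' The four trust levels and their payload permissions
#'
#' Sharing between nodes is organized in four strictly nested tiers:
#' level 1 shares artifacts only (e.g. algorithms, trained models); level
#' 2 adds feature availability metadata; level 3 adds computed feature
#' values together with the generator code (never raw data-store rows);
#' level 4 adds OMOP data-store rows. Levels 2-4 additionally require a
#' verified PPRL alignment between the peers.
#'
#' @return named list: level (as character) -> character vector of allowed
#'   payload kinds.
#' @export
trust_levels <- function() {
  l1 <- "artifact"
  l2 <- c(l1, "feature_meta")
  l3 <- c(l2, "feature_values")
  l4 <- c(l3, "omop_rows")
  list(`1` = l1, `2` = l2, `3` = l3, `4` = l4)
}

#' Sharing policy towards one peer node
#'
#' @param peer peer node context identifier.
#' @param level trust level 1-4.
#' @param allow_tables data transfer specification for level 4: the OMOP
#'   tables that may be shared (rows of other tables are stripped and
#'   reported).
#' @return object of class `sharing_policy`.
#' @export
sharing_policy <- function(peer, level, allow_tables = .omop_tables) {
  if (!is_count(level) || !(level %in% 1:4)) config_error("trust level must be 1, 2, 3 or 4")
  structure(list(peer = peer, level = as.integer(level),
                 allowed = trust_levels()[[as.character(level)]],
                 allow_tables = allow_tables),
            class = "sharing_policy")
}

#' Create an in-process health data space node
#'
#' Bundles the components of one node: the pseudonymized person index,
#' the OMOP-shaped data store, the feature store and the model store,
#' together with the node secret (held on the object, outside both
#' stores), its sharing policies and an audit log. Nodes are wired
#' in-process; transport is function calls.
#'
#' @param context node context identifier.
#' @param secret node secret (HMAC key; the at-rest key is derived from it).
#' @param config the [encoding_config()].
#' @param permutation_seed shared MinHash permutation seed.
#' @param thresholds [linkage_thresholds()] used at registration.
#' @return an environment of class `hds_node`.
#' @export
hds_node <- function(context, secret, config = encoding_config(),
                     permutation_seed = 20459L,
                     thresholds = linkage_thresholds()) {
  node <- new.env(parent = emptyenv())
  node$context <- context
  node$secret <- secret
  node$config <- config
  node$thresholds <- thresholds
  node$index <- person_index(config, permutation_seed)
  node$store <- omop_store(context)
  node$features <- feature_store()
  node$models <- model_store()
  node$policies <- list()
  node$shared_features <- list()
  node$shared_artifacts <- list()
  node$audit <- list()
  class(node) <- "hds_node"
  node
}

#' @export
print.hds_node <- function(x, ...) {
  cat("<hds_node>", x$context, "- policies:",
      if (length(x$policies)) paste(names(x$policies), collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Set the sharing policy towards a peer
#'
#' @param node an [hds_node()].
#' @param peer peer context identifier.
#' @param level trust level 1-4.
#' @param allow_tables level-4 table allow-list.
#' @export
set_policy <- function(node, peer, level, allow_tables = .omop_tables) {
  node$policies[[peer]] <- sharing_policy(peer, level, allow_tables)
  invisible(node)
}

node_audit <- function(node, ...) {
  node$audit[[length(node$audit) + 1L]] <- c(list(at = now_stamp()), list(...))
}

# Fingerprint of the identity trait set a node encodes (patients).
trait_set_fingerprint <- function(config) {
  fingerprint(list(traits = sort(intersect(config$trait_order,
                                           c("first_name", "last_name", "date_of_birth",
                                             "ssn", "name")))))
}

#' Produce this node's PPRL alignment proof
#'
#' The proof carries the trait-set fingerprint, the encoding configuration
#' fingerprint (plus MinHash permutation seed) and an HMAC over the
#' challenge nonce under the node secret — the secret itself is never
#' transmitted.
#'
#' @param node an [hds_node()].
#' @param nonce challenge nonce (raw or character).
#' @return list with `trait_fingerprint`, `config_fingerprint`,
#'   `permutation_seed`, `secret_proof`.
#' @export
alignment_proof <- function(node, nonce) {
  nonce_chr <- if (is.raw(nonce)) openssl::base64_encode(nonce) else as.character(nonce)
  list(trait_fingerprint = trait_set_fingerprint(node$config),
       config_fingerprint = node$config$fingerprint,
       permutation_seed = node$index$permutation_seed,
       secret_proof = paste0(as.character(openssl::sha256(charToRaw(nonce_chr),
                                                          key = node$secret))))
}

#' Verify PPRL alignment with a peer
#'
#' Both nodes must agree on (a) the identity trait set, (b) the encoding
#' configuration (including the blocking permutation seed) and (c) the
#' shared secret, proven by a keyed challenge-response. The mismatch
#' report names the failing component without leaking key material.
#'
#' @param node the verifying [hds_node()].
#' @param peer the peer [hds_node()] (in-process transport).
#' @return list with `verified` (logical) and `mismatches` (character
#'   vector naming failed components).
#' @export
verify_alignment <- function(node, peer) {
  nonce <- openssl::rand_bytes(16)
  mine <- alignment_proof(node, nonce)
  theirs <- alignment_proof(peer, nonce)
  mismatches <- character(0)
  if (mine$trait_fingerprint != theirs$trait_fingerprint) {
    mismatches <- c(mismatches, "trait_set_fingerprint")
  }
  if (mine$config_fingerprint != theirs$config_fingerprint ||
      mine$permutation_seed != theirs$permutation_seed) {
    mismatches <- c(mismatches, "encoding_config_fingerprint")
  }
  if (mine$secret_proof != theirs$secret_proof) {
    mismatches <- c(mismatches, "secret_challenge_response")
  }
  list(verified = length(mismatches) == 0L, mismatches = mismatches)
}

policy_for <- function(node, peer) {
  pol <- node$policies[[peer$context]]
  if (is.null(pol)) not_found_error(paste0("no sharing policy for peer: ", peer$context))
  pol
}

#' Share a payload with a peer under the configured policy
#'
#' Delivery requires the payload kind to be allowed at the configured
#' trust level, and a verified PPRL alignment for levels 2-4. Every
#' decision — delivered or denied — is audited with the rule applied.
#'
#' @param node sending [hds_node()].
#' @param peer receiving [hds_node()].
#' @param kind payload kind: `"artifact"`, `"feature_meta"`,
#'   `"feature_values"` or `"omop_rows"`.
#' @param payload the payload object.
#' @return list with `delivered` (logical) and `reason` (the violated rule
#'   when denied).
#' @export
share <- function(node, peer, kind, payload = NULL) {
  pol <- policy_for(node, peer)
  if (!kind %in% unlist(trust_levels()[["4"]])) {
    validation_error(paste0("unknown payload kind: ", kind))
  }
  deny <- function(reason) {
    node_audit(node, event = "share_denied", peer = peer$context, kind = kind,
               reason = reason)
    list(delivered = FALSE, reason = reason)
  }
  if (!kind %in% pol$allowed) {
    return(deny(sprintf("payload kind '%s' not allowed at trust level %d", kind, pol$level)))
  }
  if (pol$level >= 2L) {
    al <- verify_alignment(node, peer)
    if (!al$verified) {
      return(deny(paste0("PPRL alignment not verified: ",
                         paste(al$mismatches, collapse = ", "))))
    }
  }
  if (kind == "artifact") {
    peer$shared_artifacts[[node$context]] <-
      c(peer$shared_artifacts[[node$context]], list(payload))
  }
  node_audit(node, event = "share_delivered", peer = peer$context, kind = kind)
  list(delivered = TRUE, reason = NULL)
}

#' Push computed feature values (with generator code) to a peer
#'
#' Trust level 3 sharing: the payload contains feature values and the
#' source code used to compute them — never data-store rows or note
#' texts. Pseudonyms in the payload are those of the sending context,
#' produced under the aligned PPRL.
#'
#' @param node sending [hds_node()].
#' @param peer receiving [hds_node()].
#' @param names feature names (deployed, computed) to push.
#' @return delivery receipt: list with `delivered`, `features` (payload
#'   summaries) or `reason`.
#' @export
push_feature_results <- function(node, peer, names) {
  pol <- policy_for(node, peer)
  gate <- share(node, peer, "feature_values", payload = NULL)
  if (!gate$delivered) return(gate)
  payload <- lapply(names, function(nm) {
    keys <- grep(paste0("^", nm, "@"), names(node$features$values), value = TRUE)
    if (!length(keys)) not_found_error(paste0("no computed values for feature: ", nm))
    key <- keys[[length(keys)]]
    def <- node$features$features[[key]]
    list(name = def$name, version = def$version, level = def$level,
         values = node$features$values[[key]]$values,
         source_code = def$metadata$source_code)
  })
  names(payload) <- names
  peer$shared_features[[node$context]] <- payload
  node_audit(node, event = "features_pushed", peer = peer$context, features = names)
  list(delivered = TRUE, features = names)
}

# Register the sender's encodings at the receiver, yielding the mapping
# sender pseudonym -> receiver-context pseudonym; the link is recorded in
# the receiver's person index only.
map_pseudonyms_to_peer <- function(node, peer, pseudonyms) {
  entries <- node$index$contexts[[node$context]]
  vapply(unique(pseudonyms), function(p) {
    e <- entries[[p]]
    if (is.null(e)) not_found_error(paste0("pseudonym unknown at sender: ", p))
    enc <- decrypt_at_rest(e$ciphertext, node$secret)
    res <- register_encoding(peer$index, enc, peer$context, peer$secret,
                             peer$thresholds, entity_kind = e$entity_kind)
    local <- canonical_pseudonym(peer$index, res$pseudonym)
    gi <- NULL
    for (i in seq_along(peer$index$links)) {
      g <- peer$index$links[[i]]
      if (any(g$pseudonym == local & g$context == peer$context)) { gi <- i; break }
    }
    add <- data.frame(pseudonym = c(p, local), context = c(node$context, peer$context),
                      stringsAsFactors = FALSE)
    if (is.null(gi)) {
      peer$index$links[[length(peer$index$links) + 1L]] <- add
    } else {
      peer$index$links[[gi]] <- unique(rbind(peer$index$links[[gi]], add))
    }
    local
  }, character(1))
}

#' Push OMOP data-store rows to a peer (trust level 4)
#'
#' Rows are filtered by the policy's data transfer specification (table
#' allow-list); rows outside it are stripped and reported, never
#' delivered. For each implicated patient the sender shares the Bloom
#' filter encoding; the receiver registers it under its own context —
#' linking it to any already-known registration of the same person — and
#' stores the rows under its own context pseudonyms.
#'
#' @param node sending [hds_node()].
#' @param peer receiving [hds_node()].
#' @param tables tables to push (defaults to every non-empty table).
#' @return delivery receipt: `delivered`, per-table `counts`, `stripped`
#'   (tables refused by the allow-list).
#' @export
push_omop_rows <- function(node, peer, tables = NULL) {
  pol <- policy_for(node, peer)
  gate <- share(node, peer, "omop_rows", payload = NULL)
  if (!gate$delivered) return(gate)
  if (is.null(tables)) {
    tables <- names(Filter(nrow, node$store$tables))
  }
  stripped <- setdiff(tables, pol$allow_tables)
  tables <- intersect(tables, pol$allow_tables)
  counts <- integer(0)
  pmap <- character(0)
  batch_id <- sprintf("shared-%s-%04d", node$context, length(peer$store$batches) + 1L)
  for (tab in tables) {
    df <- node$store$tables[[tab]]
    if (nrow(df) == 0L) next
    need <- setdiff(unique(df$person_pseudonym), names(pmap))
    if (length(need)) pmap <- c(pmap, map_pseudonyms_to_peer(node, peer, need))
    df$person_pseudonym <- unname(pmap[df$person_pseudonym])
    df$row_id <- seq.int(peer$store$next_row_id, length.out = nrow(df))
    peer$store$next_row_id <- peer$store$next_row_id + nrow(df)
    df$batch_id <- batch_id
    peer$store$tables[[tab]] <- rbind(peer$store$tables[[tab]], df)
    counts[[tab]] <- nrow(df)
  }
  batch <- list(batch_id = batch_id, converter_id = paste0("shared-from-", node$context),
                converter_version = "1", counts = counts, skipped = FALSE,
                at = now_stamp())
  peer$store$batches[[length(peer$store$batches) + 1L]] <- batch
  for (hook in peer$store$update_hooks) hook(batch)
  node_audit(node, event = "omop_rows_pushed", peer = peer$context,
             counts = counts, stripped = stripped)
  list(delivered = TRUE, counts = counts, stripped = stripped)
}
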