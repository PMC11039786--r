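#' Identity record
#'
#' An identity record carries the identifying traits of one entity — a
#' patient (first name, last name, date of birth, optionally a social
#' security number), a healthcare professional (first name, last name, date
#' of birth) or a clinical site (name). These traits never enter the health
#' data store; they exist only to be encoded into a Bloom filter and
#' discarded.
#'
#' @param entity_kind one of `"patient"`, `"healthcare_professional"`,
#'   `"clinical_site"`.
#' @param traits named character vector/list of traits. Patients require
#'   `first_name`, `last_name`, `date_of_birth` (`ssn` optional);
#'   professionals require the same minus `ssn`; sites require `name`.
#' @param source_context identifier of the node the record originates from.
#' @return an object of class `identity_record`.
#' @export
identity_record <- function(traits,
                            entity_kind = c("patient", "healthcare_professional", "clinical_site"),
                            source_context = "local") {
  entity_kind <- match.arg(entity_kind)
  traits <- as.list(traits)
  required <- required_traits(entity_kind)
  for (tr in required) {
    val <- traits[[tr]]
    if (is.null(val) || !nzchar(trimws(as.character(val)))) {
      validation_error(sprintf("missing required trait '%s' for entity kind '%s'", tr, entity_kind))
    }
  }
  structure(
    list(entity_kind = entity_kind, traits = traits, source_context = source_context),
    class = "identity_record"
  )
}

required_traits <- function(entity_kind) {
  switch(entity_kind,
    patient = c("first_name", "last_name", "date_of_birth"),
    healthcare_professional = c("first_name", "last_name", "date_of_birth"),
    clinical_site = "name"
  )
}

#' @export
print.identity_record <- function(x, ...) {
  cat("<identity_record>", x$entity_kind, "from", x$source_context, "\n")
  cat("  traits:", paste(names(x$traits), collapse = ", "), "\n")
  invisible(x)
}

#' Encoding configuration for CLK Bloom filters
#'
#' Configuration of the cryptographic long-term key (CLK) encoder. All
#' records of a person's identity traits are decomposed into padded q-grams
#' and hashed into one fixed-length Bloom filter with keyed (HMAC) double
#' hashing. The companion MinHash/LSH parameters control candidate blocking.
#'
#' The secret HMAC key is deliberately *not* part of the configuration; it
#' is passed separately to [encode_clk()] and never serialized. The
#' `config_fingerprint` of an encoding covers only non-secret parameters.
#'
#' @param bf_length_bits Bloom filter length in bits. Default 459.
#' @param qgram_size q-gram length; default 2 (bigrams, standard CLK
#'   practice for person names).
#' @param hashes_per_gram number of bit positions set per q-gram (double
#'   hashing). Default 2: with a 459-bit filter and the ~30 distinct
#'   q-grams of a typical patient record this keeps the fill rate near
#'   12%, where bitwise Jaccard tracks exact q-gram Jaccard closely for
#'   similar and dissimilar pairs alike (higher k inflates the similarity
#'   of unrelated records through hash collisions).
#' @param minhash_permutations number of MinHash permutations; default 64.
#' @param lsh_bands,lsh_rows LSH banding of the signature;
#'   `lsh_bands * lsh_rows` must equal `minhash_permutations`. Default
#'   16 x 4: a candidate pair at bitwise similarity s collides in at least
#'   one band with probability 1 - (1 - s^4)^16, i.e. > 0.999 at s = 0.8.
#' @param trait_order order in which traits contribute q-grams; fixed so
#'   two nodes produce identical encodings for identical traits.
#' @param separator padding/boundary character for q-grams.
#' @return an object of class `encoding_config`.
#' @export
encoding_config <- function(bf_length_bits = 459L,
                            qgram_size = 2L,
                            hashes_per_gram = 2L,
                            minhash_permutations = 64L,
                            lsh_bands = 16L,
                            lsh_rows = 4L,
                            trait_order = c("first_name", "last_name", "date_of_birth", "ssn", "name"),
                            separator = "_") {
  if (!is_count(bf_length_bits)) config_error("bf_length_bits must be a positive integer")
  if (!is_count(qgram_size)) config_error("qgram_size must be a positive integer")
  if (!is_count(hashes_per_gram)) config_error("hashes_per_gram must be a positive integer")
  if (lsh_bands * lsh_rows != minhash_permutations) {
    config_error("lsh_bands * lsh_rows must equal minhash_permutations")
  }
  if (nchar(separator) != 1L) config_error("separator must be a single character")
  cfg <- structure(
    list(
      bf_length_bits = as.integer(bf_length_bits),
      qgram_size = as.integer(qgram_size),
      hashes_per_gram = as.integer(hashes_per_gram),
      minhash_permutations = as.integer(minhash_permutations),
      lsh_bands = as.integer(lsh_bands),
      lsh_rows = as.integer(lsh_rows),
      trait_order = trait_order,
      separator = separator
    ),
    class = "encoding_config"
  )
  cfg$fingerprint <- fingerprint(unclass(cfg))
  cfg
}

#' Normalize identity traits
#'
#' Canonicalizes trait strings before q-gram extraction: lower-case,
#' trimmed, internal whitespace collapsed, German umlauts transliterated
#' (ä→ae, ö→oe, ü→ue, ß→ss), remaining diacritics Unicode-decomposed and
#' stripped, and dates rewritten to ISO-8601 (`YYYY-MM-DD`).
#'
#' @param record an [identity_record()].
#' @param config an [encoding_config()].
#' @return named character vector of canonical trait strings, in
#'   `config$trait_order`.
#' @export
normalize_traits <- function(record, config = encoding_config()) {
  stopifnot(inherits(record, "identity_record"))
  keep <- intersect(config$trait_order, names(record$traits))
  required <- required_traits(record$entity_kind)
  missing <- setdiff(required, keep)
  if (length(missing)) {
    validation_error(paste0("missing required trait '", missing[[1]], "'"))
  }
  out <- vapply(keep, function(tr) {
    val <- as.character(record$traits[[tr]])
    if (tr %in% c("date_of_birth")) normalize_date(val) else normalize_string(val)
  }, character(1))
  out <- out[nzchar(out)]
  for (tr in required) {
    if (!nzchar(out[[tr]] %||% "")) {
      validation_error(paste0("required trait '", tr, "' empty after normalization"))
    }
  }
  out
}

normalize_string <- function(x) {
  x <- trimws(tolower(x))
  x <- gsub("ä", "ae", x, fixed = TRUE)
  x <- gsub("ö", "oe", x, fixed = TRUE)
  x <- gsub("ü", "ue", x, fixed = TRUE)
  x <- gsub("ß", "ss", x, fixed = TRUE)
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = "")
  gsub("[[:space:]]+", " ", x)
}

normalize_date <- function(x) {
  x <- trimws(x)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) return(x)
  # common European day-first form, e.g. "01.02.1950" -> "1950-02-01"
  m <- regmatches(x, regexec("^(\\d{1,2})[./](\\d{1,2})[./](\\d{4})$", x))[[1]]
  if (length(m) == 4L) {
    return(sprintf("%s-%02d-%02d", m[4], as.integer(m[3]), as.integer(m[2])))
  }
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (!is.na(d)) return(format(d, "%Y-%m-%d"))
  validation_error(paste0("unparseable date trait: '", x, "'"))
}

#' Extract padded q-grams
#'
#' Splits a canonical string into its set of q-grams after padding with one
#' boundary character on each side. Duplicate q-grams collapse (set
#' semantics), matching the unit hashed into a CLK Bloom filter.
#'
#' @param text canonical string.
#' @param q q-gram length (>= 1).
#' @param separator boundary/padding character.
#' @return character vector of unique q-grams (empty for empty input).
#' @export
extract_qgrams <- function(text, q = 2L, separator = "_") {
  if (!is_count(q)) config_error("q must be a positive integer")
  if (is.na(text) || !nzchar(text)) return(character(0))
  padded <- paste0(separator, text, separator)
  n <- nchar(padded)
  if (n < q) return(character(0))
  unique(substring(padded, seq_len(n - q + 1L), seq(q, n)))
}

# Union of padded q-gram sets over all traits of a record.
record_qgrams <- function(record, config = encoding_config()) {
  traits <- normalize_traits(record, config)
  unique(unlist(lapply(traits, extract_qgrams,
                       q = config$qgram_size, separator = config$separator),
                use.names = FALSE))
}

# Bit positions (0-based) for one q-gram under keyed double hashing:
# two independent HMAC-SHA-256 digests h1, h2; position_i = (h1 + i*h2) mod m.
gram_positions <- function(gram, config, secret) {
  m <- config$bf_length_bits
  k <- config$hashes_per_gram
  h1 <- raw_to_num(openssl::sha256(charToRaw(paste0("clk1|", gram)), key = secret))
  h2 <- raw_to_num(openssl::sha256(charToRaw(paste0("clk2|", gram)), key = secret))
  h2 <- h2 %% m
  if (h2 == 0) h2 <- 1
  unique(as.integer((h1 %% m + (0:(k - 1)) * h2) %% m))
}

# Per-secret, per-config memoisation of gram positions (name pools are
# small, so the same grams recur across thousands of records).
.gram_cache <- new.env(parent = emptyenv())

cached_gram_positions <- function(grams, config, secret) {
  cache_id <- paste0(config$fingerprint, "|", substr(sha256_hex(paste0("k|", secret)), 1, 12))
  env <- .gram_cache[[cache_id]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    .gram_cache[[cache_id]] <- env
  }
  lapply(grams, function(g) {
    pos <- env[[g]]
    if (is.null(pos)) {
      pos <- gram_positions(g, config, secret)
      env[[g]] <- pos
    }
    pos
  })
}

#' Encode an identity record as a CLK Bloom filter
#'
#' All traits' padded q-grams are pooled (the record-level CLK scope) and
#' each q-gram sets `hashes_per_gram` bit positions chosen by keyed
#' double hashing: two independent HMAC-SHA-256 digests of the q-gram under
#' the node secret give `h1`, `h2`, and position i is
#' `(h1 + i * h2) mod bf_length_bits`. Without the secret the encoding
#' cannot be reproduced or dictionary-attacked.
#'
#' @param record an [identity_record()].
#' @param config an [encoding_config()].
#' @param secret HMAC key (character or raw). Must be supplied from outside
#'   any persistence layer.
#' @return object of class `clk_encoding` with fields `bits` (logical
#'   vector of length `bf_length_bits`), `set_count` and
#'   `config_fingerprint`.
#' @export
encode_clk <- function(record, config = encoding_config(), secret) {
  if (missing(secret) || is.null(secret) || (is.character(secret) && !nzchar(secret))) {
    key_error("no HMAC secret supplied")
  }
  grams <- record_qgrams(record, config)
  bits <- logical(config$bf_length_bits)
  pos <- unlist(cached_gram_positions(grams, config, secret), use.names = FALSE)
  if (length(pos)) bits[pos + 1L] <- TRUE
  structure(
    list(bits = bits,
         set_count = sum(bits),
         config_fingerprint = config$fingerprint),
    class = "clk_encoding"
  )
}

#' @export
print.clk_encoding <- function(x, ...) {
  cat(sprintf("<clk_encoding> %d bits, %d set (fill %.1f%%), config %s\n",
              length(x$bits), x$set_count, 100 * x$set_count / length(x$bits),
              x$config_fingerprint))
  invisible(x)
}

#' Jaccard similarity of two Bloom filter encodings
#'
#' Bitwise Jaccard similarity `|a AND b| / |a OR b|` of the set-bit
#' patterns; the complement of the Jaccard distance. Two all-zero filters
#' compare as identical (similarity 1).
#'
#' @param a,b `clk_encoding` objects under the same configuration.
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  stopifnot(inherits(a, "clk_encoding"), inherits(b, "clk_encoding"))
  if (length(a$bits) != length(b$bits) || a$config_fingerprint != b$config_fingerprint) {
    incompatibility_error("encodings were produced under different configurations")
  }
  union_size <- sum(a$bits | b$bits)
  if (union_size == 0L) return(1.0)
  sum(a$bits & b$bits) / union_size
}

#' MinHash signature of a Bloom filter encoding
#'
#' MinHash over the encoding's set-bit index set with
#' `minhash_permutations` universal-hash permutations
#' `h_j(x) = (a_j x + b_j) mod p` (p prime, > filter length). The expected
#' fraction of agreeing signature slots equals the bitwise Jaccard
#' similarity. The signature is split into `lsh_bands` bands of `lsh_rows`
#' rows; band keys drive locality-sensitive-hash candidate blocking.
#'
#' @param encoding a `clk_encoding` with at least one set bit.
#' @param config the [encoding_config()] used to produce it.
#' @param permutation_seed integer seed shared by all parties comparing
#'   signatures.
#' @return object of class `minhash_signature` with `values` and `band_keys`.
#' @export
minhash_signature <- function(encoding, config = encoding_config(), permutation_seed = 20459L) {
  stopifnot(inherits(encoding, "clk_encoding"))
  if (encoding$set_count == 0L) {
    validation_error("cannot MinHash an all-zero Bloom filter")
  }
  nperm <- config$minhash_permutations
  p <- 463  # smallest prime >= 459-bit index domain
  ab <- with_seed(permutation_seed, {
    list(a = sample.int(p - 1L, nperm, replace = TRUE),
         b = sample.int(p, nperm, replace = TRUE) - 1L)
  })
  idx <- which(encoding$bits) - 1L          # 0-based set-bit indices
  # nperm x |idx| matrix of permuted indices; row minima are the signature
  hm <- (outer(ab$a, idx) + ab$b) %% p
  values <- as.integer(apply(hm, 1L, min))
  bands <- split(values, rep(seq_len(config$lsh_bands), each = config$lsh_rows))
  band_keys <- vapply(seq_along(bands), function(i) {
    paste0(i, ":", paste(bands[[i]], collapse = ","))
  }, character(1))
  structure(
    list(values = values, band_keys = band_keys,
         config_fingerprint = config$fingerprint,
         permutation_seed = as.integer(permutation_seed)),
    class = "minhash_signature"
  )
}
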