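# Independent brute-force oracle for record similarity: padded bigram sets
# per trait (written without reference to the package's q-gram code).
oracle_norm <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("ä", "ae", x, fixed = TRUE); x <- gsub("ö", "oe", x, fixed = TRUE)
  x <- gsub("ü", "ue", x, fixed = TRUE); x <- gsub("ß", "ss", x, fixed = TRUE)
  x
}
oracle_bigrams <- function(s) {
  p <- paste0("_", s, "_")
  n <- nchar(p)
  if (n < 2) return(character(0))
  unique(substring(p, seq_len(n - 1), seq(2, n)))
}
oracle_record_grams <- function(rec) {
  unique(unlist(lapply(rec$traits, function(v) oracle_bigrams(oracle_norm(v))),
                use.names = FALSE))
}
oracle_qgram_jaccard <- function(r1, r2) {
  g1 <- oracle_record_grams(r1); g2 <- oracle_record_grams(r2)
  length(intersect(g1, g2)) / length(union(g1, g2))
}

# Exhaustive all-pairs Bloom filter similarity matrix (matrix algebra, no
# blocking) — the oracle linkage strategy the blocked path is checked against.
exhaustive_similarity <- function(encodings) {
  B <- do.call(rbind, lapply(encodings, function(e) as.numeric(e$bits)))
  inter <- tcrossprod(B)
  ones <- rowSums(B)
  uni <- outer(ones, ones, "+") - inter
  sim <- inter / uni
  sim[uni == 0] <- 1
  sim
}

encode_set <- function(ids, cfg, secret, permutation_seed = 7L) {
  encs <- lapply(ids$records, encode_clk, config = cfg, secret = secret)
  sigs <- lapply(encs, minhash_signature, config = cfg,
                 permutation_seed = permutation_seed)
  list(encodings = encs, signatures = sigs)
}

make_record <- function(first, last, dob = "1950-01-01", ssn = NULL) {
  tr <- list(first_name = first, last_name = last, date_of_birth = dob)
  if (!is.null(ssn)) tr$ssn <- ssn
  identity_record(tr)
}
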