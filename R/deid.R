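#' De-identification rule set
#'
#' Rule-based recognition of nine entity types in clinical free text:
#' dictionary lookup (public and internal name dictionaries), precursor
#' promotion (titles/salutations that mark the following capitalized token
#' as a name even when it is out-of-dictionary) and regular-expression
#' classes for the structured types. Patterns default to Austrian
#' conventions (4-digit ZIP codes, +43 phone prefixes) and are fully
#' config-supplied, since such rules rarely translate across regions.
#'
#' @param public_names,internal_names character vectors of names
#'   (normalized to lower case internally). Internal names are typed as
#'   `patient`, public names as `person`.
#' @param precursors named character vector: precursor word -> entity type
#'   it promotes the following capitalized token to.
#' @param regex_rules named list: entity type -> character vector of PCRE
#'   patterns.
#' @return object of class `deid_ruleset`.
#' @export
deid_ruleset <- function(public_names, internal_names,
                         precursors = c(Dr = "healthcare_professional",
                                        DGKP = "healthcare_professional",
                                        OA = "healthcare_professional",
                                        Herr = "patient", Frau = "patient"),
                         regex_rules = default_regex_rules()) {
  for (p in unlist(regex_rules)) {
    ok <- tryCatch({ grepl(p, "x", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) config_error(paste0("regex does not compile: ", p))
  }
  bad <- setdiff(c(names(regex_rules), unname(precursors)), .deid_entity_types)
  if (length(bad)) config_error(paste0("unknown entity type: ", bad[[1]]))
  structure(
    list(public_names = unique(tolower(public_names)),
         internal_names = unique(tolower(internal_names)),
         precursors = precursors,
         regex_rules = regex_rules),
    class = "deid_ruleset"
  )
}

#' Default regular-expression classes
#'
#' Austrian-flavoured defaults for the structured entity types. The
#' `location` class is a dictionary-derived alternation (the packaged
#' place names); all others are structural patterns.
#'
#' @param locations place names compiled into the location pattern.
#' @param streets street-name stems for the address pattern.
#' @return named list of pattern vectors.
#' @export
default_regex_rules <- function(locations = .hds_locations, streets = .hds_streets) {
  esc <- function(x) gsub("([.|()\\^{}+$*?\\[\\]\\\\])", "\\\\\\1", x)
  list(
    email_address = "[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}",
    website = c("https?://[A-Za-z0-9./_-]+", "\\bwww\\.[A-Za-z0-9./_-]+"),
    phone_number = c("\\+43[ /-]?\\d{1,4}[ /-]?\\d{3,}(?:[ /-]\\d+)?",
                     "\\b0\\d{3,4}[ /-]\\d{3,}(?:[ /-]\\d+)?"),
    zip_code = "\\b[1-9]\\d{3}\\b",
    address = paste0("\\b(?:", paste(esc(streets), collapse = "|"),
                     "|[A-ZÄÖÜ][a-zäöüß]+(?:straße|strasse|gasse|weg|platz))",
                     "\\s+\\d+[a-z]?\\b"),
    location = paste0("\\b(?:", paste(esc(locations), collapse = "|"), ")\\b")
  )
}

#' Default rule set
#'
#' Built from the packaged dictionaries: internal names (the registry's
#' own name pools) typed `patient`, public names typed `person`.
#'
#' @return a [deid_ruleset()].
#' @export
default_ruleset <- function() {
  d <- default_dictionaries()
  deid_ruleset(public_names = d$public_names,
               internal_names = d$internal_names)
}

# Precedence of entity classes when spans overlap: structured patterns
# beat dictionaries, dictionaries beat precursor promotion.
.deid_precedence <- c("email_address", "website", "phone_number", "zip_code",
                      "address", "location", "dictionary", "precursor")

match_spans <- function(text, pattern, type) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      entity_type = character(0), surface = character(0),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L                      # 0-based, half-open
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len, entity_type = type,
             surface = substring(text, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

word_tokens <- function(text) {
  m <- gregexpr("[A-Za-zÄÖÜäöüß]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0), token = character(0),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len,
             token = substring(text, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

#' Detect PII entities in clinical text
#'
#' Applies the rule set in a fixed precedence order (structured regex
#' classes first, then whole-token dictionary hits, then precursor
#' promotion); within a class the longest match wins, and a span is
#' dropped if it overlaps one accepted by a higher-precedence class. The
#' result is a non-overlapping span list.
#'
#' @param text a single string.
#' @param rules a [deid_ruleset()].
#' @return data frame `start`, `end` (0-based half-open character
#'   offsets), `entity_type`, `surface`, ordered by `start`.
#' @export
detect_entities <- function(text, rules = default_ruleset()) {
  stopifnot(inherits(rules, "deid_ruleset"))
  empty <- data.frame(start = integer(0), end = integer(0),
                      entity_type = character(0), surface = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  accepted <- empty
  overlaps <- function(s, e) {
    any(accepted$start < e & s < accepted$end)
  }
  take <- function(cand) {
    if (!nrow(cand)) return(invisible(NULL))
    cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      if (!overlaps(cand$start[r], cand$end[r])) {
        accepted <<- rbind(accepted, cand[r, ])
      }
    }
  }
  # 1) structured regex classes, in precedence order
  for (type in intersect(.deid_precedence, names(rules$regex_rules))) {
    cand <- do.call(rbind, lapply(rules$regex_rules[[type]], match_spans,
                                  text = text, type = type))
    take(cand)
  }
  # 2) dictionary names (whole-token, case-insensitive)
  toks <- word_tokens(text)
  if (nrow(toks)) {
    low <- tolower(toks$token)
    is_int <- low %in% rules$internal_names
    is_pub <- !is_int & low %in% rules$public_names
    cand <- rbind(
      data.frame(start = toks$start[is_int], end = toks$end[is_int],
                 entity_type = rep("patient", sum(is_int)),
                 surface = toks$token[is_int], stringsAsFactors = FALSE),
      data.frame(start = toks$start[is_pub], end = toks$end[is_pub],
                 entity_type = rep("person", sum(is_pub)),
                 surface = toks$token[is_pub], stringsAsFactors = FALSE))
    take(cand)
  }
  # 3) precursor promotion of the following capitalized token
  if (length(rules$precursors) && nrow(toks) > 1L) {
    for (i in seq_len(nrow(toks) - 1L)) {
      pre <- toks$token[i]
      if (pre %in% names(rules$precursors)) {
        nxt <- toks$token[i + 1L]
        if (grepl("^[A-ZÄÖÜ][a-zäöüß]+$", nxt)) {  # capitalized word, not ALL-CAPS

          take(data.frame(start = toks$start[i + 1L], end = toks$end[i + 1L],
                          entity_type = unname(rules$precursors[[pre]]),
                          surface = nxt, stringsAsFactors = FALSE))
        }
      }
    }
  }
  accepted <- accepted[order(accepted$start), , drop = FALSE]
  rownames(accepted) <- NULL
  accepted
}

#' Corpus-wide placeholder map
#'
#' @return an environment of class `placeholder_map` holding the corpus
#'   counters and the (surface, type) -> placeholder assignments.
#' @export
placeholder_map <- function() {
  env <- new.env(parent = emptyenv())
  env$map <- list()
  env$counters <- list()
  class(env) <- "placeholder_map"
  env
}

placeholder_for <- function(pmap, surface, type) {
  key <- paste0(type, "|", surface)
  ph <- pmap$map[[key]]
  if (is.null(ph)) {
    k <- (pmap$counters[[type]] %||% 0L) + 1L
    pmap$counters[[type]] <- k
    ph <- sprintf("[%s-%d]", toupper(type), k)
    pmap$map[[key]] <- ph
  }
  ph
}

#' Replace detected spans with corpus-consistent typed placeholders
#'
#' Each distinct (surface, type) pair receives one placeholder
#' `[TYPE-k]` with a corpus-wide counter `k`; the same surface anywhere in
#' the corpus maps to the same placeholder. Text outside the spans is
#' preserved verbatim.
#'
#' @param text the original note text.
#' @param spans spans from [detect_entities()] (non-overlapping).
#' @param pmap a [placeholder_map()] shared across the corpus.
#' @return list with `redacted_text`, `spans`, `pmap`.
#' @export
assign_placeholders <- function(text, spans, pmap = placeholder_map()) {
  if (nrow(spans) == 0L) {
    return(list(redacted_text = text, spans = spans, pmap = pmap))
  }
  if (any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    hds_error("overlapping spans reached placeholder assignment", "hds_internal_error")
  }
  pieces <- character(0)
  cursor <- 0L
  for (r in seq_len(nrow(spans))) {
    pieces <- c(pieces,
                substring(text, cursor + 1L, spans$start[r]),
                placeholder_for(pmap, spans$surface[r], spans$entity_type[r]))
    cursor <- spans$end[r]
  }
  pieces <- c(pieces, substring(text, cursor + 1L, nchar(text)))
  list(redacted_text = paste(pieces, collapse = ""), spans = spans, pmap = pmap)
}

#' De-identify a corpus of clinical notes
#'
#' Runs detection and placeholder replacement over every note with one
#' shared placeholder map, so pseudonyms are consistent throughout the
#' corpus. Author and patient metadata fields of the input records are
#' dropped from the output.
#'
#' @param notes either a character vector of texts or a list of records
#'   with at least a `text` field (e.g. `synthetic_note` objects; their
#'   `author` / `patient_pseudonym` metadata is not carried over).
#' @param rules a [deid_ruleset()].
#' @return object of class `deid_corpus`: list of per-note results
#'   (`note_id`, `redacted_text`, `spans`) plus the shared `pmap`.
#' @export
deidentify_corpus <- function(notes, rules = default_ruleset()) {
  if (is.character(notes)) {
    notes <- lapply(seq_along(notes), function(i) {
      list(note_id = sprintf("note-%04d", i), text = notes[[i]])
    })
  }
  pmap <- placeholder_map()
  results <- lapply(notes, function(nt) {
    spans <- detect_entities(nt$text, rules)
    red <- assign_placeholders(nt$text, spans, pmap)
    list(note_id = nt$note_id %||% NA_character_,
         redacted_text = red$redacted_text, spans = spans)
  })
  structure(list(results = results, pmap = pmap), class = "deid_corpus")
}

#' @export
print.deid_corpus <- function(x, ...) {
  n_spans <- sum(vapply(x$results, function(r) nrow(r$spans), integer(1)))
  cat(sprintf("<deid_corpus> %d notes, %d redacted spans, %d distinct placeholders\n",
              length(x$results), n_spans, length(x$pmap$map)))
  invisible(x)
}

#' Token-level de-identification evaluation
#'
#' Tokenizes each note on whitespace (offsets retained); a token counts as
#' positive iff any span overlaps it. Predicted and gold token labels are
#' accumulated into one confusion matrix over the corpus.
#'
#' @param predicted,gold lists (one element per note) of span data frames
#'   with `start`/`end` columns.
#' @param texts character vector of the original note texts.
#' @return list with `accuracy`, `sensitivity`, `specificity` and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_deid <- function(predicted, gold, texts) {
  if (length(predicted) != length(texts) || length(gold) != length(texts)) {
    validation_error("predicted, gold and texts must align note-for-note")
  }
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(texts)) {
    m <- gregexpr("\\S+", texts[[i]], perl = TRUE)[[1]]
    if (m[1] == -1L) next
    tstart <- as.integer(m) - 1L
    tend <- tstart + attr(m, "match.length")
    covered <- function(spans) {
      if (is.null(spans) || nrow(spans) == 0L) return(logical(length(tstart)))
      vapply(seq_along(tstart), function(j) {
        any(spans$start < tend[j] & tstart[j] < spans$end)
      }, logical(1))
    }
    p <- covered(predicted[[i]]); g <- covered(gold[[i]])
    tp <- tp + sum(p & g); fp <- fp + sum(p & !g)
    fn <- fn + sum(!p & g); tn <- tn + sum(!p & !g)
  }
  total <- tp + fp + fn + tn
  list(accuracy = if (total) (tp + tn) / total else NA_real_,
       sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
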