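.omop_tables <- c("Person", "ObservationPeriod", "VisitOccurrence",
                  "ConditionOccurrence", "DrugExposure", "DeviceExposure",
                  "Measurement", "Observation", "Note", "SurveyConduct")

omop_empty_rows <- function() {
  data.frame(row_id = integer(0), person_pseudonym = character(0),
             concept_id = character(0), concept_name = character(0),
             vocabulary = character(0), source_value = character(0),
             value_as_number = numeric(0), value_as_string = character(0),
             unit = character(0), event_date = character(0),
             group_id = character(0), unmapped = logical(0),
             converter_id = character(0), converter_version = character(0),
             batch_id = character(0), stringsAsFactors = FALSE)
}

# One row of the minimal OMOP-shaped schema; unspecified fields default to NA.
omop_row <- function(person_pseudonym, concept = NULL, source_value = NA,
                     value_as_number = NA, value_as_string = NA, unit = NA,
                     event_date = NA, group_id = NA) {
  data.frame(row_id = NA_integer_, person_pseudonym = person_pseudonym,
             concept_id = concept$concept_id %||% NA_character_,
             concept_name = concept$concept_name %||% NA_character_,
             vocabulary = concept$vocabulary %||% NA_character_,
             source_value = as.character(source_value),
             value_as_number = as.numeric(value_as_number),
             value_as_string = as.character(value_as_string),
             unit = as.character(unit), event_date = as.character(event_date),
             group_id = as.character(group_id),
             unmapped = isTRUE(concept$unmapped),
             converter_id = NA_character_, converter_version = NA_character_,
             batch_id = NA_character_, stringsAsFactors = FALSE)
}

#' Create an empty OMOP-shaped data store
#'
#' The node's health data store: a minimal subset of ten OMOP CDM tables
#' (Person, ObservationPeriod, VisitOccurrence, ConditionOccurrence,
#' DrugExposure, DeviceExposure, Measurement, Observation, Note,
#' SurveyConduct), each with a compact common column set. The schema has
#' no column for identity traits or encodings; persons are referenced by
#' pseudonym only.
#'
#' @param node_context identifier of the owning node.
#' @return an environment of class `omop_store`.
#' @export
omop_store <- function(node_context = "local") {
  store <- new.env(parent = emptyenv())
  store$node_context <- node_context
  store$tables <- setNames(lapply(.omop_tables, function(t) omop_empty_rows()),
                           .omop_tables)
  store$batches <- list()
  store$batch_fingerprints <- character(0)
  store$query_log <- character(0)
  store$corpora <- list()
  store$next_row_id <- 1L
  store$update_hooks <- list()
  class(store) <- "omop_store"
  store
}

#' @export
print.omop_store <- function(x, ...) {
  counts <- vapply(x$tables, nrow, integer(1))
  cat("<omop_store>", x$node_context, "-",
      paste0(names(counts)[counts > 0], ":", counts[counts > 0], collapse = " "),
      sprintf("(%d batches)\n", length(x$batches)))
  invisible(x)
}

# ---- vocabulary mapping -----------------------------------------------------

#' Load a vocabulary map
#'
#' Deterministic lookup from (source vocabulary, source code) to a
#' standard concept in ICD-10, SNOMED-CT, LOINC or ATC, with an
#' active-ingredient fallback for drug brand names and an explicit
#' unmapped outcome (source values are never silently dropped). A small
#' demo map ships with the package; full licensed vocabularies are out of
#' scope — the lookup logic, not the content, is the tested part.
#'
#' @param path CSV with columns source_vocab, source_code, target_vocab,
#'   concept_code, concept_name, mapping_note. Defaults to the packaged
#'   demo map.
#' @param brand_ingredients data frame (`brand`, `ingredient`) used for the
#'   ingredient fallback.
#' @return object of class `vocabulary_map`.
#' @export
vocabulary_map <- function(path = system.file("extdata", "vocab_demo.csv", package = "hdsnode"),
                           brand_ingredients = .hds_drugs) {
  entries <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("source_vocab", "source_code", "target_vocab", "concept_code",
              "concept_name", "mapping_note")
  if (!all(needed %in% names(entries))) validation_error("vocabulary CSV missing columns")
  structure(list(entries = entries, brand_ingredients = brand_ingredients),
            class = "vocabulary_map")
}

#' Map a source code to a standard concept
#'
#' @param source_vocab source vocabulary label (e.g. `"local_lab"`,
#'   `"drug_brand"`, `"icd10_source"`).
#' @param source_code the code or term to map.
#' @param vmap a [vocabulary_map()].
#' @return list with `concept_id`, `concept_name`, `vocabulary`,
#'   `mapping_note` and `unmapped`; unknown codes come back with
#'   `unmapped = TRUE` and the source value preserved as the concept name.
#' @export
map_concept <- function(source_vocab, source_code, vmap) {
  stopifnot(inherits(vmap, "vocabulary_map"))
  e <- vmap$entries
  hit <- e[e$source_vocab == source_vocab & tolower(e$source_code) == tolower(source_code), ]
  if (nrow(hit)) {
    hit <- hit[1L, ]
    return(list(concept_id = hit$concept_code, concept_name = hit$concept_name,
                vocabulary = hit$target_vocab, mapping_note = hit$mapping_note,
                unmapped = FALSE))
  }
  if (source_vocab == "drug_brand") {
    bi <- vmap$brand_ingredients
    ing <- bi$ingredient[tolower(bi$brand) == tolower(source_code)]
    if (length(ing)) {
      sub <- map_concept("ingredient", ing[[1]], vmap)
      if (!sub$unmapped) {
        sub$mapping_note <- "ingredient-fallback"
        return(sub)
      }
    }
  }
  list(concept_id = NA_character_, concept_name = as.character(source_code),
       vocabulary = NA_character_, mapping_note = "unmapped", unmapped = TRUE)
}

# ---- converters -------------------------------------------------------------

#' Define an ETL converter
#'
#' A converter pseudonymizes and transforms one source payload kind into
#' rows of the OMOP-shaped store. `transform(payload, resolve_pseudonym,
#' vmap)` must return `list(rows = <named list of row data frames keyed by
#' table>, rejected = <data frame of per-record diagnostics>)`. The
#' `resolve_pseudonym(patient_key)` callback is the only path from a
#' source-local patient reference to a pseudonym; traits never reach the
#' transform output.
#'
#' @param id converter identifier.
#' @param version integer version; must strictly increase on change.
#' @param source_kind label of the accepted payload kind.
#' @param transform the transformation function.
#' @param target_tables tables the converter may write.
#' @param activation `"continuous"` or `"one_shot"`.
#' @return object of class `etl_converter`.
#' @export
etl_converter <- function(id, version, source_kind, transform, target_tables,
                          activation = c("continuous", "one_shot")) {
  activation <- match.arg(activation)
  stopifnot(is.function(transform))
  bad <- setdiff(target_tables, .omop_tables)
  if (length(bad)) config_error(paste0("unsupported OMOP table: ", bad[[1]]))
  structure(list(id = id, version = as.integer(version), source_kind = source_kind,
                 transform = transform, target_tables = target_tables,
                 activation = activation, active = TRUE),
            class = "etl_converter")
}

#' Ingest a payload through a converter
#'
#' Runs the converter's transform (pseudonymization first — the transform
#' only ever sees pseudonyms through `resolve_pseudonym`), stamps
#' provenance (converter id and version, batch id) on every row, appends
#' the rows to the store and writes a batch log entry with per-table
#' counts. Re-ingesting a byte-identical payload through the same
#' converter version is detected by batch fingerprint and skipped.
#'
#' @param store an [omop_store()].
#' @param payload the source payload.
#' @param converter an [etl_converter()].
#' @param resolve_pseudonym function mapping a source-local patient key to
#'   a pseudonym (typically wired to [register_identity()] /
#'   [resolve_link()] by the node).
#' @param vmap a [vocabulary_map()].
#' @return list with `rows_written`, `rejected`, `batch` (the log entry).
#' @export
ingest <- function(store, payload, converter, resolve_pseudonym,
                   vmap = vocabulary_map()) {
  stopifnot(inherits(store, "omop_store"), inherits(converter, "etl_converter"))
  if (!isTRUE(converter$active)) not_found_error("converter is not active")
  fp <- substr(sha256_hex(paste(converter$id, converter$version,
                                paste(deparse(payload), collapse = "\n"))), 1, 20)
  batch_id <- sprintf("batch-%04d", length(store$batches) + 1L)
  if (fp %in% store$batch_fingerprints) {
    batch <- list(batch_id = batch_id, converter_id = converter$id,
                  converter_version = converter$version, fingerprint = fp,
                  counts = integer(0), skipped = TRUE, at = now_stamp())
    store$batches[[length(store$batches) + 1L]] <- batch
    return(list(rows_written = 0L, rejected = NULL, batch = batch))
  }
  out <- converter$transform(payload, resolve_pseudonym, vmap)
  rows <- out$rows %||% list()
  bad <- setdiff(names(rows), converter$target_tables)
  if (length(bad)) validation_error(paste0("converter wrote undeclared table: ", bad[[1]]))
  counts <- integer(0)
  for (tab in names(rows)) {
    df <- rows[[tab]]
    if (is.null(df) || nrow(df) == 0L) next
    df$row_id <- seq.int(store$next_row_id, length.out = nrow(df))
    store$next_row_id <- store$next_row_id + nrow(df)
    df$converter_id <- converter$id
    df$converter_version <- as.character(converter$version)
    df$batch_id <- batch_id
    store$tables[[tab]] <- rbind(store$tables[[tab]], df)
    counts[[tab]] <- nrow(df)
  }
  store$batch_fingerprints <- c(store$batch_fingerprints, fp)
  batch <- list(batch_id = batch_id, converter_id = converter$id,
                converter_version = converter$version, fingerprint = fp,
                counts = counts, skipped = FALSE, at = now_stamp())
  store$batches[[length(store$batches) + 1L]] <- batch
  for (hook in store$update_hooks) hook(batch)
  list(rows_written = sum(counts), rejected = out$rejected, batch = batch)
}

# ---- built-in converters for the synthetic telehealth source ----------------

#' Built-in converters for the synthetic telehealth export
#'
#' `telehealth_measurements_converter()` writes two Measurement rows per
#' blood-pressure reading (systolic and diastolic as separate components
#' sharing the reading's `group_id`) plus one row per heart-rate and
#' bodyweight reading. `telehealth_observations_converter()` writes one
#' Observation per wellbeing score, one DrugExposure (brand mapped to its
#' active ingredient where needed) plus one adherence Observation per
#' medication record. `telehealth_notes_converter()` writes one Note row
#' per free-text note. `telehealth_visitation_converter()` stores each
#' telemonitoring day as a VisitOccurrence with a custom source tag
#' (home-telemonitoring contacts have no exact standard concept; a generic
#' one is used at the cost of minor imprecision).
#'
#' @name telehealth_converters
NULL

#' @rdname telehealth_converters
#' @export
telehealth_measurements_converter <- function() {
  etl_converter("telehealth-measurements", 1L, "telehealth_export",
    target_tables = "Measurement",
    transform = function(payload, resolve_pseudonym, vmap) {
      bp <- payload$blood_pressure
      rows <- list()
      add <- function(df) rows[[length(rows) + 1L]] <<- df
      for (r in seq_len(nrow(bp))) {
        p <- resolve_pseudonym(bp$patient_id[r])
        add(omop_row(p, map_concept("local_obs", "systolic_bp", vmap),
                     source_value = "systolic_bp", value_as_number = bp$systolic[r],
                     unit = "mmHg", event_date = bp$date[r], group_id = bp$reading_id[r]))
        add(omop_row(p, map_concept("local_obs", "diastolic_bp", vmap),
                     source_value = "diastolic_bp", value_as_number = bp$diastolic[r],
                     unit = "mmHg", event_date = bp$date[r], group_id = bp$reading_id[r]))
      }
      for (r in seq_len(nrow(payload$heart_rate))) {
        hr <- payload$heart_rate[r, ]
        add(omop_row(resolve_pseudonym(hr$patient_id), map_concept("local_obs", "heart_rate", vmap),
                     source_value = "heart_rate", value_as_number = hr$heart_rate,
                     unit = "bpm", event_date = hr$date))
      }
      for (r in seq_len(nrow(payload$bodyweight))) {
        bw <- payload$bodyweight[r, ]
        add(omop_row(resolve_pseudonym(bw$patient_id), map_concept("local_obs", "bodyweight", vmap),
                     source_value = "bodyweight", value_as_number = bw$bodyweight,
                     unit = "kg", event_date = bw$date))
      }
      list(rows = list(Measurement = do.call(rbind, rows)), rejected = NULL)
    })
}

#' @rdname telehealth_converters
#' @export
telehealth_observations_converter <- function() {
  etl_converter("telehealth-observations", 1L, "telehealth_export",
    target_tables = c("Observation", "DrugExposure"),
    transform = function(payload, resolve_pseudonym, vmap) {
      obs <- list(); drug <- list()
      for (r in seq_len(nrow(payload$wellbeing))) {
        w <- payload$wellbeing[r, ]
        obs[[length(obs) + 1L]] <-
          omop_row(resolve_pseudonym(w$patient_id), map_concept("local_obs", "wellbeing", vmap),
                   source_value = "wellbeing", value_as_string = w$wellbeing,
                   event_date = w$date)
      }
      for (r in seq_len(nrow(payload$medication))) {
        m <- payload$medication[r, ]
        p <- resolve_pseudonym(m$patient_id)
        drug[[length(drug) + 1L]] <-
          omop_row(p, map_concept("drug_brand", m$drug_brand, vmap),
                   source_value = m$drug_brand, event_date = m$date)
        obs[[length(obs) + 1L]] <-
          omop_row(p, map_concept("local_obs", "medication_adherence", vmap),
                   source_value = "medication_adherence",
                   value_as_string = if (isTRUE(m$intake_adherent)) "adherent" else "non_adherent",
                   event_date = m$date)
      }
      list(rows = list(Observation = do.call(rbind, obs),
                       DrugExposure = do.call(rbind, drug)), rejected = NULL)
    })
}

#' @rdname telehealth_converters
#' @export
telehealth_notes_converter <- function() {
  etl_converter("telehealth-notes", 1L, "telehealth_export",
    target_tables = "Note",
    transform = function(payload, resolve_pseudonym, vmap) {
      notes <- payload$notes
      if (is.null(notes) || nrow(notes) == 0L) {
        return(list(rows = list(), rejected = NULL))
      }
      rows <- lapply(seq_len(nrow(notes)), function(r) {
        omop_row(resolve_pseudonym(notes$patient_id[r]),
                 map_concept("local_obs", "clinical_note", vmap),
                 source_value = "clinical_note",
                 value_as_string = notes$note_text[r], event_date = notes$date[r])
      })
      list(rows = list(Note = do.call(rbind, rows)), rejected = NULL)
    })
}

#' @rdname telehealth_converters
#' @export
telehealth_visitation_converter <- function() {
  etl_converter("telehealth-visitation", 1L, "telehealth_export",
    target_tables = "VisitOccurrence",
    transform = function(payload, resolve_pseudonym, vmap) {
      bp <- payload$blood_pressure
      rows <- lapply(seq_len(nrow(bp)), function(r) {
        omop_row(resolve_pseudonym(bp$patient_id[r]),
                 map_concept("local_obs", "telehealth_contact", vmap),
                 source_value = "telehealth-visitation", event_date = bp$date[r])
      })
      list(rows = list(VisitOccurrence = do.call(rbind, rows)), rejected = NULL)
    })
}

#' Converter for a register-of-deaths export
#'
#' One Observation row ("date of death") per register record.
#'
#' @export
deaths_converter <- function() {
  etl_converter("register-of-deaths", 1L, "deaths_export",
    target_tables = "Observation",
    transform = function(payload, resolve_pseudonym, vmap) {
      rows <- lapply(seq_len(nrow(payload)), function(r) {
        omop_row(resolve_pseudonym(payload$patient_id[r]),
                 map_concept("local_obs", "date_of_death", vmap),
                 source_value = "date_of_death",
                 value_as_string = payload$date_of_death[r],
                 event_date = payload$date_of_death[r])
      })
      list(rows = list(Observation = do.call(rbind, rows)), rejected = NULL)
    })
}

#' Converter for an EMR demographics/diagnoses export
#'
#' Writes one Person row and one ObservationPeriod per patient, one
#' VisitOccurrence per admission and one ConditionOccurrence per ICD-10
#' coded diagnosis.
#'
#' @export
emr_converter <- function() {
  etl_converter("emr-demographics", 1L, "emr_export",
    target_tables = c("Person", "ObservationPeriod", "VisitOccurrence",
                      "ConditionOccurrence"),
    transform = function(payload, resolve_pseudonym, vmap) {
      person <- list(); period <- list(); visit <- list(); cond <- list()
      for (r in seq_len(nrow(payload$patients))) {
        pt <- payload$patients[r, ]
        p <- resolve_pseudonym(pt$patient_id)
        person[[length(person) + 1L]] <-
          omop_row(p, source_value = "person", value_as_string = pt$gender,
                   event_date = pt$year_of_birth)
        period[[length(period) + 1L]] <-
          omop_row(p, source_value = "observation_period",
                   event_date = pt$admission_date, value_as_string = pt$discharge_date)
        visit[[length(visit) + 1L]] <-
          omop_row(p, source_value = "inpatient_admission", event_date = pt$admission_date)
      }
      for (r in seq_len(nrow(payload$diagnoses))) {
        dg <- payload$diagnoses[r, ]
        cond[[length(cond) + 1L]] <-
          omop_row(resolve_pseudonym(dg$patient_id),
                   map_concept("icd10_source", dg$icd10, vmap),
                   source_value = dg$icd10, event_date = dg$date)
      }
      list(rows = list(Person = do.call(rbind, person),
                       ObservationPeriod = do.call(rbind, period),
                       VisitOccurrence = do.call(rbind, visit),
                       ConditionOccurrence = do.call(rbind, cond)),
           rejected = NULL)
    })
}

# ---- FHIR QuestionnaireResponse --------------------------------------------

count_answered_items <- function(items) {
  if (is.null(items)) return(list())
  out <- list()
  for (it in items) {
    if (!is.null(it$answer) && length(it$answer)) {
      ans <- it$answer[[1]]
      val <- ans$valueCoding$code %||% ans$valueString %||% ans$valueInteger %||%
        ans$valueDecimal %||% ans$valueBoolean %||% NA
      out[[length(out) + 1L]] <- list(linkId = it$linkId %||% NA_character_,
                                      text = it$text %||% NA_character_,
                                      value = val)
    }
    out <- c(out, count_answered_items(it$item))
  }
  out
}

#' Convert a FHIR QuestionnaireResponse to OMOP rows
#'
#' One completed form becomes exactly one VisitOccurrence (the act of
#' completing the form), one SurveyConduct (questionnaire identity and
#' completion status) and one Observation per answered item, all under the
#' subject's pseudonym.
#'
#' @param response FHIR R4 QuestionnaireResponse as a file path, JSON
#'   string, or parsed list.
#' @param resolve_pseudonym function mapping the FHIR subject reference to
#'   a pseudonym.
#' @return named list of row data frames (`VisitOccurrence`,
#'   `SurveyConduct`, `Observation`).
#' @export
fhir_questionnaire_etl <- function(response, resolve_pseudonym) {
  if (is.character(response)) {
    response <- tryCatch(
      jsonlite::fromJSON(response, simplifyVector = FALSE),
      error = function(e) hds_error(paste0("malformed FHIR document: ", conditionMessage(e)),
                                    "hds_parse_error"))
  }
  if (!identical(response$resourceType, "QuestionnaireResponse")) {
    hds_error("not a QuestionnaireResponse resource", "hds_parse_error")
  }
  subject <- response$subject$reference
  if (is.null(subject)) validation_error("QuestionnaireResponse has no subject reference")
  p <- resolve_pseudonym(subject)
  date <- substr(response$authored %||% NA_character_, 1, 10)
  answered <- count_answered_items(response$item)
  visit <- omop_row(p, source_value = "questionnaire_completion", event_date = date)
  survey <- omop_row(p, source_value = response$questionnaire %||% "questionnaire",
                     value_as_string = response$status %||% NA_character_,
                     event_date = date)
  obs <- if (length(answered)) {
    do.call(rbind, lapply(answered, function(a) {
      omop_row(p, source_value = a$linkId,
               value_as_string = as.character(a$value),
               value_as_number = suppressWarnings(as.numeric(a$value)),
               event_date = date)
    }))
  } else NULL
  list(VisitOccurrence = visit, SurveyConduct = survey, Observation = obs)
}

#' Converter wrapping [fhir_questionnaire_etl()]
#'
#' @export
fhir_questionnaire_converter <- function() {
  etl_converter("fhir-questionnaire", 1L, "fhir_questionnaire_response",
    target_tables = c("VisitOccurrence", "SurveyConduct", "Observation"),
    transform = function(payload, resolve_pseudonym, vmap) {
      list(rows = fhir_questionnaire_etl(payload, resolve_pseudonym), rejected = NULL)
    })
}

# ---- query / export ---------------------------------------------------------

#' Read rows of a store table (query text logged for audit)
#'
#' @param store an [omop_store()].
#' @param table table name.
#' @param query free-text description of the access, appended to the audit
#'   query log.
#' @return the table's data frame.
#' @export
query_table <- function(store, table, query = paste("SELECT * FROM", table)) {
  if (!table %in% .omop_tables) not_found_error(paste0("unknown table: ", table))
  store$query_log <- c(store$query_log, paste0(now_stamp(), " ", query))
  store$tables[[table]]
}

#' Export store tables to CSV or JSON
#'
#' Round-trip safe: [import_tables()] on the produced files restores row
#' counts and values exactly.
#'
#' @param store an [omop_store()].
#' @param tables table names to export.
#' @param format `"csv"` or `"json"`.
#' @param dir output directory.
#' @return invisible character vector of file paths.
#' @export
export_tables <- function(store, tables, format = c("csv", "json"), dir) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bad <- setdiff(tables, .omop_tables)
  if (length(bad)) not_found_error(paste0("unknown table: ", bad[[1]]))
  paths <- vapply(tables, function(tab) {
    df <- store$tables[[tab]]
    path <- file.path(dir, paste0(tab, ".", format))
    if (format == "csv") {
      write.csv(df, path, row.names = FALSE, na = "")
    } else {
      jsonlite::write_json(df, path, dataframe = "rows", na = "null", digits = NA)
    }
    path
  }, character(1))
  invisible(paths)
}

#' @rdname export_tables
#' @param paths files produced by [export_tables()] (table name inferred
#'   from the file name).
#' @export
import_tables <- function(store, paths) {
  for (path in paths) {
    tab <- sub("\\.(csv|json)$", "", basename(path))
    if (!tab %in% .omop_tables) not_found_error(paste0("unknown table: ", tab))
    df <- if (grepl("\\.csv$", path)) {
      read.csv(path, stringsAsFactors = FALSE,
               colClasses = sapply(omop_empty_rows(), class))
    } else {
      as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
    }
    store$tables[[tab]] <- rbind(store$tables[[tab]], df)
  }
  invisible(store)
}

#' Build a de-identified annotation corpus from stored notes
#'
#' Selects Note rows, passes their texts through the de-identifier (one
#' corpus-wide placeholder map) and registers the corpus in the store so
#' labels can be attached by note id and retrieved like any other data.
#'
#' @param store an [omop_store()].
#' @param note_filter optional predicate over the Note table rows.
#' @param rules a [deid_ruleset()].
#' @param corpus_id identifier for the stored corpus.
#' @return data frame (`note_id`, `text`) of de-identified entries.
#' @export
build_annotation_corpus <- function(store, note_filter = NULL,
                                    rules = default_ruleset(),
                                    corpus_id = "corpus-1") {
  notes <- store$tables$Note
  if (!is.null(note_filter)) notes <- notes[note_filter(notes), , drop = FALSE]
  if (nrow(notes) == 0L) {
    warning("empty note selection; corpus is empty")
    corpus <- data.frame(note_id = integer(0), text = character(0),
                         stringsAsFactors = FALSE)
  } else {
    deid <- deidentify_corpus(notes$value_as_string, rules)
    corpus <- data.frame(note_id = notes$row_id,
                         text = vapply(deid$results, `[[`, "", "redacted_text"),
                         stringsAsFactors = FALSE)
  }
  store$corpora[[corpus_id]] <- list(entries = corpus, labels = list())
  corpus
}

#' Attach a label to an annotation-corpus entry
#'
#' @param store an [omop_store()].
#' @param corpus_id the corpus.
#' @param note_id a `note_id` present in the corpus.
#' @param label arbitrary label value.
#' @export
attach_label <- function(store, corpus_id, note_id, label) {
  corp <- store$corpora[[corpus_id]]
  if (is.null(corp)) not_found_error("unknown corpus")
  if (!note_id %in% corp$entries$note_id) {
    not_found_error(paste0("note id not in corpus: ", note_id))
  }
  corp$labels[[as.character(note_id)]] <- label
  store$corpora[[corpus_id]] <- corp
  invisible(store)
}

#' Scan a store for leaked identity traits
#'
#' Utility for privacy checks on synthetic runs: searches every cell of
#' every table for the given trait strings (word-boundary,
#' case-insensitive).
#'
#' @param store an [omop_store()].
#' @param traits character vector of trait strings.
#' @return character vector of traits found (empty when clean).
#' @export
scan_for_traits <- function(store, traits) {
  blob <- paste(unlist(lapply(store$tables, function(df) {
    unlist(lapply(df, as.character), use.names = FALSE)
  })), collapse = "\n")
  traits <- unique(traits[nzchar(traits)])
  found <- vapply(traits, function(tr) {
    grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tr), "\\b"),
          blob, ignore.case = TRUE, perl = TRUE)
  }, logical(1))
  names(found)[found]
}
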